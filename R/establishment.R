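# Establishment submodel: within-season competitive growth toward
# soil-N-modulated carrying capacities, and the between-season
# mortality/fecundity transition.
#
# Within a growing season each species grows toward its monoculture
# equilibrium biomass B* (carrying capacity) at relative growth rate RGR,
# discounted by competition from superior resource competitors (lower R*),
# weighted by relative tissue nitrogen concentration q and spatiotemporal
# overlap:
#
#   dB_i/dt = RGR_ij * ( B*_ij - B_i - sum_{i' in mask(i)}
#                         (q_i'/q_i) * overlap[i,i'] * B_i' )

#' Soil-N modulation of carrying capacity and growth rate
#'
#' B*_ij = exp(Bstar_intercept_i + Bstar_slope_i * log(soil_N_j)) -- a
#' log-log regression with species-specific intercepts (the slope is
#' typically common across species, as fitted). RGR_ij =
#' max(0, RGR_intercept_i + RGR_slope_i * soil_N_j), a linear relation on
#' the natural scale with negative fitted values clamped to zero.
#'
#' @param traits a \code{\link{species_traits}} table.
#' @param soil_N per-plot total soil nitrogen, mg/kg (> 0).
#' @return list with species-by-plot matrices \code{Bstar} (g/m^2) and
#'   \code{RGR} (/day).
#' @export
modulate_by_soil_n <- function(traits, soil_N) {
  stop_if_not_positive(soil_N, "soil_N")
  Bstar <- exp(outer(traits$Bstar_intercept, rep(1, length(soil_N))) +
                 outer(traits$Bstar_slope, log(soil_N)))
  RGR <- outer(traits$RGR_intercept, rep(1, length(soil_N))) +
    outer(traits$RGR_slope, soil_N)
  RGR[RGR < 0] <- 0   # negative fitted growth rates clamp to zero
  dmn <- list(traits$species_id, names(soil_N))
  dimnames(Bstar) <- dimnames(RGR) <- dmn
  list(Bstar = Bstar, RGR = RGR)
}

#' Competitor sets under the R* hierarchy
#'
#' With the R* attribute on, species i is competed only by species with
#' strictly lower R* (superior resource competitors); ties compete in
#' neither direction. With R* off, competition is symmetric: every other
#' species competes with i (interspecific strength equal to intraspecific).
#'
#' @param traits a \code{\link{species_traits}} table.
#' @param r_star_on behaviour flag from \code{\link{apply_switches}}.
#' @return logical species-by-species matrix; \code{[i, i']} TRUE when i'
#'   competes with (is in the competition sum of) i. Diagonal FALSE.
#' @export
competitor_masks <- function(traits, r_star_on = TRUE) {
  r <- traits$R_star
  n <- length(r)
  m <- if (r_star_on) outer(r, r, function(ri, rj) rj < ri)
       else matrix(TRUE, n, n)
  diag(m) <- FALSE
  dimnames(m) <- list(traits$species_id, traits$species_id)
  m
}

#' Competition coefficient matrix
#'
#' W[i, i'] is the coefficient of competitor biomass B_i' in species i's
#' growth equation: (q_i'/q_i) * overlap[i, i'] where i' is in i's
#' competitor set, else 0. With the R* attribute off, interaction strength
#' is set equal to the intraspecific strength (q ratio 1), so
#' W[i, i'] = overlap[i, i'] for all pairs.
#'
#' @param traits effective trait table.
#' @param overlap an \code{\link{total_overlap}} result (or its
#'   \code{total} matrix).
#' @param mask competitor mask from \code{\link{competitor_masks}}.
#' @param r_star_on behaviour flag.
#' @return numeric species-by-species matrix, zero diagonal.
#' @export
competition_matrix <- function(traits, overlap, mask, r_star_on = TRUE) {
  ov <- if (inherits(overlap, "overlap_matrix")) overlap$total else overlap
  q <- traits$q
  qr <- if (r_star_on) outer(q, q, function(qi, qj) qj / qi)
        else matrix(1, length(q), length(q))
  W <- qr * ov * mask
  dimnames(W) <- dimnames(ov)
  W
}

#' Integrate within-season growth over one growing season
#'
#' Fixed-step 4th-order Runge-Kutta integration of the linear competition
#' system from t = 0 to t = t_end days (default 160, the growing-season
#' length), daily steps. Plots are independent within a season and are
#' integrated simultaneously (the system is linear, so the stage
#' evaluations vectorise across plots). Biomass is floored at zero: a
#' species driven to zero by competition stays at zero for the rest of the
#' season, and a species starting the season at zero biomass cannot appear
#' from nothing (growth requires established biomass; arrival is the
#' lottery's job).
#'
#' @param b species-by-plot season-start biomass matrix (g/m^2).
#' @param params list with \code{Bstar} and \code{RGR} matrices from
#'   \code{\link{modulate_by_soil_n}}.
#' @param W competition coefficient matrix from
#'   \code{\link{competition_matrix}}.
#' @param t_end season length, days.
#' @param dt integration step, days.
#' @param keep_daily if TRUE, also return the full daily trajectory.
#' @return end-of-season species-by-plot biomass matrix; with
#'   \code{keep_daily}, a list \code{(B_end, daily)} where \code{daily} is a
#'   species x plot x time array.
#' @export
grow_season <- function(b, params, W, t_end = 160, dt = 1,
                        keep_daily = FALSE) {
  if (any(!is.finite(b))) stop("non-finite season-start biomass", call. = FALSE)
  if (any(b < 0)) stop("negative season-start biomass", call. = FALSE)
  B <- b
  alive <- B > 0
  Bstar <- params$Bstar
  RGR <- params$RGR
  deriv <- function(B) {
    d <- RGR * (Bstar - B - W %*% B)
    d[!alive] <- 0
    d
  }
  nstep <- ceiling(t_end / dt)
  if (keep_daily) {
    daily <- array(0, dim = c(nrow(B), ncol(B), nstep + 1L))
    daily[, , 1L] <- B
  }
  for (s in seq_len(nstep)) {
    h <- min(dt, t_end - (s - 1) * dt)
    k1 <- deriv(B)
    k2 <- deriv(B + h / 2 * k1)
    k3 <- deriv(B + h / 2 * k2)
    k4 <- deriv(B + h * k3)
    B <- B + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    dead <- alive & (B <= 0)
    B[B < 0] <- 0
    B[dead] <- 0
    alive <- alive & !dead
    if (keep_daily) daily[, , s + 1L] <- B
  }
  if (keep_daily) list(B_end = B, daily = daily) else B
}

#' Overwinter transition
#'
#' Surviving biomass entering the next season: b = B_end (1 - m)(1 - f).
#' The fecundity fraction f is removed here because it was allocated to
#' seed (routed to seed rain) and is 'safe' from overwinter mortality m,
#' which acts only on the non-reproductive fraction.
#'
#' @param B_end species-by-plot end-of-season biomass matrix.
#' @param traits a \code{\link{species_traits}} table.
#' @return species-by-plot matrix of surviving biomass.
#' @export
overwinter <- function(B_end, traits) {
  if (any(B_end < 0)) stop("B_end must be >= 0", call. = FALSE)
  B_end * (1 - traits$mortality_m) * (1 - traits$fecundity_f)
}
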