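# Arrival submodel: wind dispersal of seeds among plots.
#
# Seed dispersal distance follows the WALD (Wald Analytical Long-distance
# Dispersal) kernel, an inverse-Gaussian distribution whose parameters
# derive from seed-release height, mean wind velocity and seed terminal
# velocity. The fraction of seed moving from every source plot to every
# destination plot is estimated once per run by Monte-Carlo simulation of a
# large number of seeds per species and source plot.

#' WALD kernel parameters from dispersal traits
#'
#' lambda = h^2 / sigma^2 (dispersion) and mu = h w / v (mean dispersal
#' distance), where h is seed-release height (m), w mean wind velocity
#' (m/s), v seed terminal velocity (m/s) and sigma^2 a dimensionless
#' turbulence parameter describing wind flow above the canopy (default 0.3).
#'
#' @param release_height seed-release height, m (vectorised over species).
#' @param wind_velocity mean wind velocity, m/s.
#' @param terminal_velocity seed terminal velocity, m/s.
#' @param sigma2 turbulence parameter, dimensionless.
#' @return list with numeric components \code{lambda} and \code{mu}.
#' @export
wald_params <- function(release_height, wind_velocity, terminal_velocity,
                        sigma2 = 0.3) {
  stop_if_not_positive(release_height, "release_height")
  stop_if_not_positive(wind_velocity, "wind_velocity")
  stop_if_not_positive(terminal_velocity, "terminal_velocity")
  stop_if_not_positive(sigma2, "sigma2")
  list(lambda = release_height^2 / sigma2,
       mu = release_height * wind_velocity / terminal_velocity)
}

#' WALD (inverse-Gaussian) dispersal distance density
#'
#' ps(d) = sqrt(lambda / (2 pi d^3)) * exp(-lambda (d - mu)^2 / (2 mu^2 d)).
#'
#' @param d dispersal distance, m (> 0).
#' @param lambda,mu kernel parameters, e.g. from \code{\link{wald_params}}.
#' @return probability density (1/m).
#' @export
wald_pdf <- function(d, lambda, mu) {
  if (any(d <= 0)) stop("d must be > 0", call. = FALSE)
  sqrt(lambda / (2 * pi * d^3)) * exp(-lambda * (d - mu)^2 / (2 * mu^2 * d))
}

# Inverse-Gaussian sampler (Michael-Schucany-Haas transform).
rinvgauss <- function(n, mu, lambda) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

# Precompute a grid locator for a plot matrix: plots are square, contiguous
# within blocks, so landing points map to (block, column, row) by integer
# arithmetic; points on walkways or outside all blocks return NA.
.plot_locator <- function(plots) {
  df <- plots$plots
  side <- df$side[1]
  blocks <- split(seq_len(nrow(df)), df$block_id)
  info <- lapply(blocks, function(idx) {
    x0 <- min(df$x[idx]) - side / 2
    y0 <- min(df$y[idx]) - side / 2
    ncol <- round((max(df$x[idx]) - min(df$x[idx])) / side) + 1L
    nrow <- round((max(df$y[idx]) - min(df$y[idx])) / side) + 1L
    grid <- matrix(NA_integer_, nrow = nrow, ncol = ncol)
    ci <- round((df$x[idx] - min(df$x[idx])) / side) + 1L
    ri <- round((df$y[idx] - min(df$y[idx])) / side) + 1L
    grid[cbind(ri, ci)] <- idx
    list(x0 = x0, y0 = y0, ncol = ncol, nrow = nrow, grid = grid)
  })
  function(x, y) {
    out <- rep(NA_integer_, length(x))
    for (b in info) {
      sel <- which(is.na(out) &
                     x >= b$x0 & x < b$x0 + b$ncol * side &
                     y >= b$y0 & y < b$y0 + b$nrow * side)
      if (!length(sel)) next
      ci <- floor((x[sel] - b$x0) / side) + 1L
      ri <- floor((y[sel] - b$y0) / side) + 1L
      out[sel] <- b$grid[cbind(ri, ci)]
    }
    out
  }
}

#' Monte-Carlo plot-to-plot dispersal fractions
#'
#' For every species and source plot, simulates \code{n_seeds} seeds: a
#' dispersal distance drawn from the species' WALD kernel, a direction
#' uniform on [0, 360) degrees, and a start point uniform within the source
#' plot (or the plot centre). Landing points are assigned to destination
#' plots by point-in-rectangle test; seeds landing on walkways or outside
#' the block array are absorbed and counted as lost. Counting guarantees
#' that for every (species, source) the destination fractions and the loss
#' sum to 1 exactly.
#'
#' With \code{dispersal_on = FALSE} the array is the identity: all seed
#' stays in the plot where it was produced and nothing is lost.
#'
#' @param plots a \code{\link{plot_matrix}}.
#' @param traits a \code{\link{species_traits}} table.
#' @param n_seeds Monte-Carlo seeds per species and source plot (default
#'   2e4).
#' @param wind_velocity mean wind velocity, m/s.
#' @param sigma2 turbulence parameter.
#' @param source \code{"area"} (start points uniform in the source plot) or
#'   \code{"centre"} (point source at the plot centre).
#' @param dispersal_on behaviour flag; FALSE yields the identity array.
#' @param seed optional RNG seed (restores the previous RNG state on exit).
#' @return list of class \code{"dispersal_array"}: \code{pd}, a per-species
#'   list of source-by-destination fraction matrices; \code{loss}, a
#'   species-by-source matrix of lost fractions.
#' @export
build_dispersal_array <- function(plots, traits, n_seeds = 2e4,
                                  wind_velocity = 3, sigma2 = 0.3,
                                  source = c("area", "centre"),
                                  dispersal_on = TRUE, seed = NULL) {
  source <- match.arg(source)
  df <- plots$plots
  np <- nrow(df)
  if (np == 0L) stop("empty plot set", call. = FALSE)
  ns <- nrow(traits)
  sp <- traits$species_id
  if (!dispersal_on) {
    pd <- lapply(seq_len(ns), function(i) diag(1, np))
    names(pd) <- sp
    loss <- matrix(0, ns, np, dimnames = list(sp, df$plot_id))
    return(structure(list(pd = pd, loss = loss, n_seeds = n_seeds),
                     class = "dispersal_array"))
  }
  if (n_seeds < 1) stop("n_seeds must be >= 1", call. = FALSE)
  locate <- .plot_locator(plots)
  side <- df$side[1]
  kp <- wald_params(traits$release_height, wind_velocity,
                    traits$terminal_velocity_v, sigma2)
  with_seed(seed, {
    pd <- vector("list", ns)
    loss <- matrix(0, ns, np, dimnames = list(sp, df$plot_id))
    for (i in seq_len(ns)) {
      m <- matrix(0, np, np, dimnames = list(df$plot_id, df$plot_id))
      for (j in seq_len(np)) {
        d <- rinvgauss(n_seeds, kp$mu[i], kp$lambda[i])
        theta <- stats::runif(n_seeds, 0, 2 * pi)
        if (source == "area") {
          sx <- df$x[j] + stats::runif(n_seeds, -side / 2, side / 2)
          sy <- df$y[j] + stats::runif(n_seeds, -side / 2, side / 2)
        } else {
          sx <- rep(df$x[j], n_seeds)
          sy <- rep(df$y[j], n_seeds)
        }
        dest <- locate(sx + d * cos(theta), sy + d * sin(theta))
        cnt <- tabulate(dest, nbins = np)
        m[j, ] <- cnt / n_seeds
        loss[i, j] <- (n_seeds - sum(cnt)) / n_seeds
      }
      pd[[i]] <- m
    }
    names(pd) <- sp
    structure(list(pd = pd, loss = loss, n_seeds = n_seeds),
              class = "dispersal_array")
  })
}

#' @export
print.dispersal_array <- function(x, ...) {
  np <- nrow(x$pd[[1]])
  cat(sprintf("dispersal_array: %d species x %d plots (%g seeds/source)\n",
              length(x$pd), np, x$n_seeds))
  cat(sprintf("  mean within-plot retention %.3f, mean loss %.3f\n",
              mean(vapply(x$pd, function(m) mean(diag(m)), numeric(1))),
              mean(x$loss)))
  invisible(x)
}

#' Annual seed rain arriving at each plot
#'
#' Seed biomass arriving at plot k is the end-of-season biomass of each
#' species in every source plot, multiplied by the fraction of biomass
#' allocated to reproduction (fecundity f) and by the plot-to-plot dispersal
#' fraction, summed over sources. Weeding then zeroes arrivals of species
#' that were never sown in the destination plot.
#'
#' @param B_end species-by-plot end-of-season biomass matrix (g/m^2).
#' @param traits a \code{\link{species_traits}} table (uses
#'   \code{fecundity_f}).
#' @param pd a \code{\link{build_dispersal_array}} result.
#' @param sown_mask plots-by-species logical matrix (weeding); NULL to skip
#'   weeding.
#' @return species-by-plot matrix of arriving seed biomass (g/m^2).
#' @export
seed_rain <- function(B_end, traits, pd, sown_mask = NULL) {
  ns <- nrow(traits)
  np <- nrow(pd$pd[[1]])
  if (!identical(dim(B_end), c(ns, np)))
    stop("B_end must be species x plots", call. = FALSE)
  if (any(B_end < 0)) stop("B_end must be >= 0", call. = FALSE)
  D <- matrix(0, ns, np, dimnames = dimnames(B_end))
  for (i in seq_len(ns)) {
    pm <- if (!is.null(names(pd$pd))) pd$pd[[traits$species_id[i]]]
          else pd$pd[[i]]
    D[i, ] <- as.numeric(crossprod(pm, B_end[i, ] * traits$fecundity_f[i]))
  }
  if (!is.null(sown_mask)) D[t(!sown_mask)] <- 0
  D
}
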