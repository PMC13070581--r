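# Lottery recruitment: converts arriving seed biomass into new adult
# biomass at the start of a season, under a plot-level soil-N budget.
#
# Each unit of arriving seed biomass of species i can found up to 1/f_i
# units of adult biomass (the equilibrium conversion: B adults produce B*f
# seed, so x seed implies about x/f adults), provided enough soil N remains
# accessible to the species. Accessible N is the growth-equation
# equilibrium headroom, which keeps recruitment and within-season dynamics
# mutually consistent:
#
#   headroom_N(i) = q_i * max(0, B*_ij - b_ij - sum_{i'} W[i,i'] b_i'j)
#
# With the lottery attribute on, seeds are drawn randomly and uniformly
# without replacement from the arriving pool and establish until no species
# has headroom left (ecological drift). With it off, unused resources are
# divided deterministically among species in proportion to their seed
# biomass, with redistribution of unused shares to a fixed point.

#' Plot-level establishable-nitrogen budget
#'
#' @param b species-by-plot biomass already present at establishment time
#'   (g/m^2).
#' @param Bstar species-by-plot carrying capacities.
#' @param W competition coefficient matrix
#'   (\code{\link{competition_matrix}}).
#' @param q per-species tissue N per unit biomass (mg N / g).
#' @return object of class \code{"nitrogen_budget"}; its \code{headroom}
#'   element is the species-by-plot establishable nitrogen
#'   (mg N equivalent per m^2).
#' @export
nitrogen_budget <- function(b, Bstar, W, q) {
  hb <- pmax(0, Bstar - b - W %*% b)       # headroom in focal-biomass units
  structure(list(headroom = q * hb, headroom_biomass = hb,
                 b = b, Bstar = Bstar, W = W, q = q),
            class = "nitrogen_budget")
}

# Biomass-unit headroom for one plot given current biomass vector.
.headroom_bio <- function(b, Bstar, W) pmax(0, Bstar - b - as.numeric(W %*% b))

# Multivariate hypergeometric draw: composition of k balls drawn without
# replacement from per-species counts.
.rmvhyper <- function(k, counts) {
  S <- length(counts)
  out <- integer(S)
  rem <- sum(counts)
  for (s in seq_len(S)) {
    if (k <= 0L) break
    x <- stats::rhyper(1L, counts[s], rem - counts[s], k)
    out[s] <- x
    k <- k - x
    rem <- rem - counts[s]
  }
  out
}

# Core single-plot lottery. seed_pool, Bstar, b0: per-species vectors for
# one plot. Returns established adult biomass per species.
#
# The sequential seed-by-seed process is accelerated exactly (in
# distribution): headrooms only decrease as colonisers establish, so a
# species that cannot establish now never can again and its remaining
# packets (which would all fail) are discarded; and any batch of m draws
# with m * max-per-packet-N-demand below every current headroom is
# guaranteed to establish in full, so only the batch's species composition
# (multivariate hypergeometric) is needed, not its order.
.lottery_plot <- function(seed_pool, Bstar, b0, W, q, f, packet_mass) {
  S <- length(seed_pool)
  if (any(f <= 0 & seed_pool > 0))
    stop("zero fecundity with non-zero seed pool", call. = FALSE)
  est <- numeric(S)
  b <- b0
  counts <- ifelse(f > 0, floor(seed_pool / packet_mass), 0)
  frac <- seed_pool - counts * packet_mass     # sub-packet remainders
  adult_per_packet <- ifelse(f > 0, packet_mass / f, 0)
  ndem <- q * adult_per_packet                  # N demand per packet
  active <- counts > 0
  while (any(active)) {
    hb <- .headroom_bio(b, Bstar, W)
    hN <- q * hb
    can <- active & (ndem <= hN) & (ndem > 0)
    # headroom is non-increasing: species that cannot establish now never will
    active <- can
    if (!any(active)) break
    delta <- max(ndem[active])
    m <- floor(min(hN[active]) / delta)
    m <- min(m, sum(counts[active]))
    if (m >= 1) {
      drawn <- integer(S)
      drawn[active] <- .rmvhyper(m, counts[active])
      est <- est + drawn * adult_per_packet
      b <- b + drawn * adult_per_packet
      counts <- counts - drawn
    } else {
      k <- sample.int(S, 1L, prob = counts * active)
      if (ndem[k] <= hN[k]) {
        est[k] <- est[k] + adult_per_packet[k]
        b[k] <- b[k] + adult_per_packet[k]
      } else {
        active[k] <- FALSE                      # fails now, fails forever
      }
      counts[k] <- counts[k] - 1L
    }
    active <- active & counts > 0
  }
  # establish the fractional tail packets (mass below one packet) in random
  # order, subject to the same budget rule
  idx <- which(frac > 0 & f > 0)
  if (length(idx)) {
    for (k in sample(idx, length(idx))) {
      a <- frac[k] / f[k]
      hb <- .headroom_bio(b, Bstar, W)
      if (q[k] * a <= q[k] * hb[k] && hb[k] > 0) {
        est[k] <- est[k] + a
        b[k] <- b[k] + a
      }
    }
  }
  est
}

# Deterministic single-plot allocation: common multiplier on seed-biomass
# weights, advanced until a species' demand is met or a headroom binds;
# finished/blocked species drop out and the remainder is redistributed.
.deterministic_plot <- function(seed_pool, Bstar, b0, W, q, f) {
  S <- length(seed_pool)
  if (any(f <= 0 & seed_pool > 0))
    stop("zero fecundity with non-zero seed pool", call. = FALSE)
  est <- numeric(S)
  b <- b0
  rem <- ifelse(f > 0, seed_pool / f, 0)        # remaining adult-biomass demand
  w0 <- seed_pool                               # allocation weights
  for (iter in seq_len(4L * S + 4L)) {
    hb <- .headroom_bio(b, Bstar, W)
    active <- rem > 1e-12 & hb > 1e-12 & w0 > 0
    if (!any(active)) break
    x <- ifelse(active, w0, 0)
    # per-unit-lambda depletion of species i's biomass headroom
    d <- x + as.numeric(W %*% x)
    lam_dem <- min(rem[active] / x[active])
    ok <- active & d > 0
    lam_head <- if (any(ok)) min(hb[ok] / d[ok]) else Inf
    lam <- min(lam_dem, lam_head)
    if (!is.finite(lam) || lam <= 0) break
    add <- lam * x
    est <- est + add
    b <- b + add
    rem <- pmax(0, rem - add)
  }
  est
}

#' Stochastic lottery establishment
#'
#' Discretises the arriving seed biomass into packets of
#' \code{packet_mass}, draws packets uniformly without replacement, and
#' converts each drawn packet of species i into \code{packet_mass}/f_i
#' adult biomass if the implied nitrogen demand fits the species' current
#' headroom; failed packets are discarded. Establishment ends when the
#' pool is exhausted or no species retains headroom.
#'
#' @param seed_pool per-species arriving seed biomass for one plot, or a
#'   species-by-plot matrix (g/m^2).
#' @param budget a \code{\link{nitrogen_budget}} built at establishment
#'   time (from survivors' biomass).
#' @param fecundity per-species seed allocation fraction f.
#' @param packet_mass seed packet mass, g: scalar or per-species vector
#'   (e.g. measured per-seed mass). Default 1e-3 g.
#' @param seed optional RNG seed.
#' @return established adult biomass, same shape as \code{seed_pool}.
#' @export
lottery_establish <- function(seed_pool, budget, fecundity,
                              packet_mass = 1e-3, seed = NULL) {
  .establish(seed_pool, budget, fecundity, packet_mass, seed,
             stochastic = TRUE)
}

#' Deterministic (lottery-off) establishment
#'
#' Divides establishable resources among species in proportion to their
#' seed biomass, capped at each species' full demand (seed biomass / f),
#' redistributing unused shares until a fixed point. In the
#' abundant-resource limit this equals the lottery's expectation,
#' seed_pool/f, exactly.
#'
#' @inheritParams lottery_establish
#' @return established adult biomass, same shape as \code{seed_pool}.
#' @export
deterministic_establish <- function(seed_pool, budget, fecundity) {
  .establish(seed_pool, budget, fecundity, NULL, NULL, stochastic = FALSE)
}

.establish <- function(seed_pool, budget, fecundity, packet_mass, seed,
                       stochastic) {
  stopifnot(inherits(budget, "nitrogen_budget"))
  vec_in <- is.null(dim(seed_pool))
  sp <- if (vec_in) matrix(seed_pool, ncol = 1) else seed_pool
  Bstar <- if (is.null(dim(budget$Bstar))) matrix(budget$Bstar, ncol = 1)
           else budget$Bstar
  b0 <- if (is.null(dim(budget$b))) matrix(budget$b, ncol = 1) else budget$b
  if (any(sp < 0)) stop("seed_pool must be >= 0", call. = FALSE)
  if (stochastic) {
    if (any(packet_mass <= 0)) stop("packet_mass must be > 0", call. = FALSE)
    packet_mass <- rep_len(packet_mass, nrow(sp))
  }
  out <- matrix(0, nrow(sp), ncol(sp), dimnames = dimnames(sp))
  with_seed(seed, {
    for (p in seq_len(ncol(sp))) {
      out[, p] <- if (stochastic)
        .lottery_plot(sp[, p], Bstar[, p], b0[, p], budget$W, budget$q,
                      fecundity, packet_mass)
      else
        .deterministic_plot(sp[, p], Bstar[, p], b0[, p], budget$W,
                            budget$q, fecundity)
    }
    if (vec_in) out[, 1] else out
  })
}
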