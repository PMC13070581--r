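# Soil-N modulation, competitor masks, within-season growth and the
# overwinter transition.

test_that("soil N modulates B* log-log and RGR linearly with a floor at zero", {
  tr <- toy_traits(2)
  # zero slopes: independent of soil N
  p <- modulate_by_soil_n(tr, c(a = 100, b = 1000))
  expect_equal(unname(p$Bstar[, 1]), rep(100, 2))
  expect_equal(unname(p$Bstar[, 2]), rep(100, 2))
  expect_equal(unname(p$RGR[, 1]), rep(0.05, 2))
  # unit log-log: B* = soil N
  tr$Bstar_intercept <- rep(0, 2)
  tr$Bstar_slope <- rep(1, 2)
  expect_equal(unname(modulate_by_soil_n(tr, 100)$Bstar[, 1]), rep(100, 2))
  # positive slope: strictly increasing in soil N
  tr$Bstar_slope <- rep(0.4, 2)
  p2 <- modulate_by_soil_n(tr, c(100, 200, 400))
  expect_true(all(diff(p2$Bstar[1, ]) > 0))
  # negative fitted RGR clamps to zero
  tr$RGR_intercept <- rep(0.01, 2)
  tr$RGR_slope <- rep(-1e-3, 2)
  expect_equal(unname(modulate_by_soil_n(tr, 1000)$RGR[, 1]), rep(0, 2))
  expect_error(modulate_by_soil_n(tr, -5), "positive")
})

test_that("competitor sets follow the strict R* hierarchy", {
  tr <- toy_traits(3)
  tr$R_star <- c(0.1, 0.2, 0.3)
  m <- competitor_masks(tr, r_star_on = TRUE)
  expect_equal(unname(which(m[3, ])), c(1, 2))  # worst competitor faces both
  expect_false(any(m[1, ]))                     # best competitor faces none
  # symmetric competition when R* is off
  m_off <- competitor_masks(tr, r_star_on = FALSE)
  expect_equal(unname(rowSums(m_off)), rep(2, 3))
  expect_false(any(diag(m_off)))
  # ties: strict inequality means no competition either way
  tr$R_star <- c(0.2, 0.2, 0.3)
  m_tie <- competitor_masks(tr, TRUE)
  expect_false(m_tie[1, 2])
  expect_false(m_tie[2, 1])
})

test_that("single-species growth matches the closed-form relaxation", {
  params <- list(Bstar = matrix(100), RGR = matrix(0.05))
  W <- matrix(0, 1, 1)
  # equilibrium is a fixed point
  expect_equal(as.numeric(grow_season(matrix(100), params, W)), 100)
  # closed form B(t) = B* - (B* - B0) exp(-RGR t) within 0.1% at dt = 1
  B_end <- grow_season(matrix(20), params, W, t_end = 160, dt = 1)
  closed <- 100 - (100 - 20) * exp(-0.05 * 160)
  expect_lt(abs(as.numeric(B_end) - closed) / closed, 1e-3)
  # boundedness: B stays within [B0, B*] envelope
  traj <- grow_season(matrix(20), params, W, keep_daily = TRUE)
  expect_true(all(traj$daily <= 100 + 1e-9 & traj$daily >= 20 - 1e-9))
})

test_that("two-species dynamics reach the algebraic fixed point", {
  params <- list(Bstar = matrix(c(100, 80), 2, 1),
                 RGR = matrix(c(0.06, 0.06), 2, 1))
  # species 2 superior: W[1,2] = 1 (overlap 1, equal q), no reverse impact
  W <- matrix(c(0, 0, 1, 0), 2, 2)
  B_end <- grow_season(matrix(c(10, 10), 2, 1), params, W,
                       t_end = 4000, dt = 1)
  expect_lt(abs(B_end[1, 1] - (100 - 80)) / 20, 5e-3)
  expect_lt(abs(B_end[2, 1] - 80) / 80, 5e-3)
  # when the superior's equilibrium exceeds B*_1, the inferior is excluded
  params$Bstar <- matrix(c(60, 80), 2, 1)
  B_ex <- grow_season(matrix(c(10, 10), 2, 1), params, W,
                      t_end = 4000, dt = 1)
  expect_equal(B_ex[1, 1], 0)
})

test_that("adding a competitor never increases end-of-season biomass", {
  params <- list(Bstar = matrix(c(100, 80), 2, 1),
                 RGR = matrix(c(0.05, 0.05), 2, 1))
  W_alone <- matrix(0, 2, 2)
  W_comp <- matrix(c(0, 0, 0.6, 0), 2, 2)  # W[1,2] = 0.6
  b0 <- matrix(c(30, 30), 2, 1)
  alone <- grow_season(b0, params, W_alone)
  with_comp <- grow_season(b0, params, W_comp)
  expect_lt(with_comp[1, 1], alone[1, 1])
  expect_equal(with_comp[2, 1], alone[2, 1])
})

test_that("removing a superior competitor increases the inferior's growth rate", {
  # nitrogen recycling: the growth law depends only on current biomass
  params <- list(Bstar = matrix(c(100, 80), 2, 1),
                 RGR = matrix(c(0.05, 0.05), 2, 1))
  W <- matrix(c(0, 0, 1, 0), 2, 2)
  b_with <- matrix(c(30, 40), 2, 1)
  b_without <- matrix(c(30, 0), 2, 1)
  d_with <- 0.05 * (100 - 30 - 40)
  d_without <- 0.05 * (100 - 30)
  # perturbation: a one-day step from each state
  s_with <- grow_season(b_with, params, W, t_end = 1, dt = 1)
  s_without <- grow_season(b_without, params, W, t_end = 1, dt = 1)
  expect_gt(s_without[1, 1] - b_without[1, 1], s_with[1, 1] - b_with[1, 1])
  expect_gt(d_without, d_with)
})

test_that("species cannot appear from zero biomass within a season", {
  params <- list(Bstar = matrix(c(100, 80), 2, 1),
                 RGR = matrix(c(0.05, 0.05), 2, 1))
  B_end <- grow_season(matrix(c(0, 10), 2, 1), params, matrix(0, 2, 2))
  expect_equal(B_end[1, 1], 0)
  expect_gt(B_end[2, 1], 10)
})

test_that("overwinter removes mortality from the non-reproductive fraction", {
  tr <- toy_traits(1)
  tr$mortality_m <- 0.1
  tr$fecundity_f <- 0.2
  expect_equal(as.numeric(overwinter(matrix(100), tr)), 72)
  tr$mortality_m <- 0; tr$fecundity_f <- 0
  expect_equal(as.numeric(overwinter(matrix(55), tr)), 55)
  tr$mortality_m <- 1; tr$fecundity_f <- 0.3
  expect_equal(as.numeric(overwinter(matrix(100), tr)), 0)
})
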