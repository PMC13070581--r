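# Lottery and deterministic recruitment under the plot nitrogen budget.

budget2 <- function(bstar = c(1e6, 1e6), b = c(0, 0),
                    W = matrix(0, 2, 2), q = c(10, 10))
  nitrogen_budget(b, bstar, W, q)

test_that("abundant resources convert all seed at 1/f exactly", {
  pool <- c(2, 1)
  f <- c(0.2, 0.25)
  est <- lottery_establish(pool, budget2(), f, packet_mass = 1e-3, seed = 1)
  expect_equal(est, pool / f)
  det <- deterministic_establish(pool, budget2(), f)
  expect_equal(det, pool / f)
})

test_that("zero headroom means zero establishment", {
  bud <- budget2(bstar = c(0, 0))
  expect_true(all(lottery_establish(c(2, 1), bud, c(0.2, 0.2),
                                    seed = 2) == 0))
  expect_true(all(deterministic_establish(c(2, 1), bud, c(0.2, 0.2)) == 0))
})

test_that("zero fecundity with a non-empty pool is rejected", {
  expect_error(lottery_establish(c(1, 1), budget2(), c(0, 0.2), seed = 1),
               "fecundity")
  expect_error(deterministic_establish(c(1, 1), budget2(), c(0, 0.2)),
               "fecundity")
})

test_that("expected lottery shares are proportional to seed pools", {
  # two identical species, pools 2:1, shared symmetric budget holding half
  # the total demand
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  q <- c(10, 10); f <- c(0.2, 0.2)
  pool <- c(2, 1)                 # demands 10 and 5; capacity 7.5 total
  bud <- nitrogen_budget(c(0, 0), c(7.5, 7.5), W, q)
  set.seed(9)
  r <- replicate(1000, lottery_establish(pool, bud, f, packet_mass = 1e-2))
  ratio <- rowMeans(r)[1] / rowMeans(r)[2]
  se_ratio <- stats::sd(r[1, ] / pmax(r[2, ], 1e-9)) / sqrt(1000)
  expect_lt(abs(ratio - 2), 3 * max(se_ratio, 0.01))
  # deterministic division is exactly proportional
  det <- deterministic_establish(pool, bud, f)
  expect_equal(det[1] / det[2], 2, tolerance = 1e-9)
  expect_equal(sum(det) * 10, 75, tolerance = 1e-9)  # budget exhausted
})

test_that("deterministic water-filling redistributes unused shares", {
  # species 1's demand is small; its unused share must flow to species 2
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  q <- c(10, 10)
  f <- c(0.5, 0.1)
  pool <- c(4, 1)                 # demands: 8 and 10
  bud <- nitrogen_budget(c(0, 0), c(12, 12), W, q)
  det <- deterministic_establish(pool, bud, f)
  # proportional-to-seed-biomass split of 12 would give (9.6, 2.4); species
  # 1 only demands 8, surplus goes to species 2
  expect_equal(det[1], 8, tolerance = 1e-8)
  expect_equal(det[2], 4, tolerance = 1e-8)
})

test_that("established biomass respects the per-species conversion cap", {
  set.seed(30)
  for (k in 1:200) {
    S <- sample(2:4, 1)
    pool <- runif(S, 0, 3)
    f <- runif(S, 0.05, 0.5)
    q <- runif(S, 5, 25)
    bstar <- runif(S, 0, 50)
    ov <- matrix(runif(S * S, 0, 1), S, S); diag(ov) <- 0
    est <- lottery_establish(pool, nitrogen_budget(numeric(S), bstar, ov, q),
                             f, packet_mass = 1e-2)
    expect_true(all(est <= pool / f + 1e-9))
  }
})

test_that("total nitrogen consumed never exceeds the initial budget", {
  set.seed(31)
  n_bad <- 0L
  for (k in 1:10000) {
    S <- sample(2:3, 1)
    pool <- runif(S, 0, 2)
    f <- runif(S, 0.05, 0.5)
    q <- runif(S, 5, 25)
    bstar <- runif(S, 0, 20)
    ov <- matrix(runif(S * S, 0, 1), S, S); diag(ov) <- 0
    bud <- nitrogen_budget(numeric(S), bstar, ov, q)
    est <- if (k %% 2 == 0)
      lottery_establish(pool, bud, f, packet_mass = 5e-2)
    else deterministic_establish(pool, bud, f)
    if (sum(q * est) > sum(bud$headroom) + 1e-6) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 0L)
})

test_that("lottery output is reproducible and insensitive to packet mass", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  bud <- nitrogen_budget(c(0, 0), c(7.5, 7.5), W, c(10, 10))
  a <- lottery_establish(c(2, 1), bud, c(0.2, 0.2), 1e-3, seed = 77)
  b <- lottery_establish(c(2, 1), bud, c(0.2, 0.2), 1e-3, seed = 77)
  expect_identical(a, b)
  # halving the packet mass changes mean allocations by less than MC noise
  set.seed(5)
  m1 <- rowMeans(replicate(400, lottery_establish(c(2, 1), bud,
                                                  c(0.2, 0.2), 1e-2)))
  m2 <- rowMeans(replicate(400, lottery_establish(c(2, 1), bud,
                                                  c(0.2, 0.2), 5e-3)))
  expect_lt(max(abs(m1 - m2)), 0.15)
})

test_that("matrix seed pools establish plot by plot", {
  pool <- matrix(c(2, 1, 0, 3), 2, 2)
  bstar <- matrix(1e6, 2, 2)
  bud <- nitrogen_budget(matrix(0, 2, 2), bstar, matrix(0, 2, 2), c(10, 10))
  est <- lottery_establish(pool, bud, c(0.2, 0.2), seed = 4)
  expect_equal(est, pool / 0.2)
})
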