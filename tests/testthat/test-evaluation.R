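# Scaled error metrics and the top-model importance analyses.

test_that("scaled RMSE identities and invariance", {
  expect_equal(scaled_rmse(c(3, 4), c(3, 4), c(10, 10)), 0)
  expect_equal(scaled_rmse(10, 6, 8), 0.5)
  # invariant to common rescaling of observed, predicted and B*
  y <- c(5, 9, 2); yh <- c(4, 10, 2.5); b <- c(8, 12, 6)
  expect_equal(scaled_rmse(y, yh, b), scaled_rmse(10 * y, 10 * yh, 10 * b))
  g <- c("a", "a", "b")
  pg <- scaled_rmse(y, yh, b, groups = g)
  expect_equal(unname(pg["b"]), abs(2 - 2.5) / 6)
  expect_error(scaled_rmse(1, 1, 0), "positive")
})

test_that("R-squared identities on scaled log biomass", {
  y <- c(2, 8, 20, 50, 3, 12)
  b <- rep(10, 6)
  expect_equal(r2_scaled(y, y, b), 1)
  # predicting the mean of the transformed observations gives R^2 = 0
  logy <- log(y / b + 1e-3)
  const <- (exp(mean(logy)) - 1e-3) * b
  expect_equal(r2_scaled(y, const, b), 0, tolerance = 1e-10)
  expect_error(r2_scaled(y[1:2], y[1:2], b[1:2]), "3 valid points")
  # summed level pools species within plots
  plot <- rep(c("p1", "p2", "p3"), each = 2)
  r2s <- r2_scaled(y, y * 1.01, b, level = "summed", plot = plot)
  expect_true(r2s <= 1 && r2s > 0.9)
})

# build a synthetic evaluation table with known structure
fake_eval <- function(n_plot = 4, seed = 1) {
  set.seed(seed)
  sc <- enumerate_scenarios(11)
  rows <- list()
  for (p in seq_len(n_plot)) {
    df <- sc
    df$replicate <- 1L
    df$plot_id <- paste0("p", p)
    df$rmse <- runif(nrow(sc), 1, 2)
    rows[[p]] <- df
  }
  out <- do.call(rbind, rows)
  out$richness <- 2L
  out
}

test_that("top_models with fraction 1 returns background frequencies", {
  ev <- fake_eval(2)
  tm <- top_models(ev, fraction = 1, complexity_axis = "attributes")
  for (k in unique(tm$frequencies$complexity)) {
    stratum <- ev[rowSums(ev[, switch_names()]) == k & ev$plot_id == "p1", ]
    bg <- colMeans(stratum[, switch_names()])
    got <- tm$frequencies[tm$frequencies$complexity == k &
                            tm$frequencies$plot_id == "p1", ]
    expect_equal(stats::setNames(got$freq, got$item), bg)
  }
})

test_that("a decisive attribute reaches frequency 1 in the top set", {
  ev <- fake_eval(3, seed = 2)
  # r_star halves the error wherever it is on: it must dominate the top 5%
  ev$rmse <- ifelse(ev$r_star, ev$rmse * 0.01, ev$rmse)
  tm <- top_models(ev, fraction = 0.05, complexity_axis = "attributes")
  fr <- tm$frequencies
  # complexity levels where both states exist in the stratum
  for (k in 2:10) {
    f <- fr[fr$complexity == k & fr$item == "r_star", "freq"]
    expect_true(all(f == 1))
  }
})

test_that("top-set size is the ceiling of fraction times stratum size", {
  ev <- fake_eval(1)
  tm <- top_models(ev, fraction = 0.05)
  fr <- tm$frequencies
  for (k in unique(fr$complexity)) {
    n_stratum <- sum(rowSums(ev[, switch_names()]) == k)
    expect_equal(unique(fr$n_selected[fr$complexity == k]),
                 ceiling(0.05 * n_stratum))
  }
})

test_that("mechanism-axis complexity uses the exactly-k rule", {
  ev <- fake_eval(1)
  tm <- top_models(ev, fraction = 0.2, complexity_axis = "mechanisms",
                   attrs_required = 2)
  expect_true(all(tm$frequencies$item %in% names(mechanism_groups())))
  expect_true(all(tm$frequencies$complexity %in% 0:4))
})

test_that("pair co-occurrence counts recover known composition", {
  sw <- as.data.frame(matrix(TRUE, 3, 11))
  names(sw) <- switch_names()
  m <- pair_cooccurrence(sw)
  expect_true(all(m == 3))
  # runs with exactly two attributes on: off-diagonal row sums equal
  # per-attribute selection counts
  sw2 <- as.data.frame(matrix(FALSE, 4, 11))
  names(sw2) <- switch_names()
  sw2$r_star <- c(TRUE, TRUE, FALSE, FALSE)
  sw2$b_star <- c(TRUE, FALSE, TRUE, FALSE)
  sw2$lottery <- c(FALSE, TRUE, TRUE, TRUE)
  sw2$root[4] <- TRUE
  m2 <- pair_cooccurrence(sw2)
  expect_equal(m2["r_star", "b_star"], 1L)
  expect_equal(m2["r_star", "lottery"], 1L)
  expect_equal(diag(m2)[["lottery"]], 3L)
  off <- m2; diag(off) <- 0L
  expect_equal(unname(rowSums(off)[c("r_star", "b_star", "lottery", "root")]),
               c(2, 2, 3, 1))
})

test_that("attribute correlations separate within- from between-mechanism blocks", {
  # identical effect vectors correlate at |r| = 1
  eff <- matrix(rnorm(30), 30, 1)[, rep(1, 11)]
  colnames(eff) <- switch_names()
  ac <- attribute_correlations(eff + 0)
  expect_equal(ac$overall, 1)
  # constructed block correlation: within-mechanism latent + noise
  set.seed(4)
  n <- 4000
  latent <- matrix(rnorm(n * 4), n, 4)
  shared <- rnorm(n)
  grp <- rep(names(mechanism_groups()), lengths(mechanism_groups()))
  eff2 <- sapply(seq_len(11), function(j) {
    g <- match(grp[j], names(mechanism_groups()))
    0.55 * shared + 0.9 * latent[, g] + 0.55 * rnorm(n)
  })
  colnames(eff2) <- switch_names()
  ac2 <- attribute_correlations(eff2)
  expect_gt(ac2$within, ac2$between)
  expect_gt(ac2$between, 0.1)
  # constant columns are excluded with a warning
  eff3 <- eff2
  eff3[, 1] <- 1
  expect_warning(attribute_correlations(eff3), "constant")
})

test_that("independent effect vectors give near-zero mean correlation", {
  set.seed(6)
  eff <- matrix(rnorm(11 * 5000), 5000, 11)
  colnames(eff) <- switch_names()
  expect_lt(attribute_correlations(eff)$overall, 0.05)
})
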