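# Switch application, scenario enumeration, mechanism status and trait
# imputation.

test_that("switched-off trait attributes take the across-species mean", {
  tr <- toy_traits(5)
  tr$fecundity_f <- c(0.1, 0.2, 0.3, 0.2, 0.2)
  pl <- one_plot(tr)
  eff <- apply_switches(tr, pl, switch_config(fecundity = FALSE))
  expect_equal(eff$traits$fecundity_f, rep(0.2, 5))
  # all on: identity
  eff_on <- apply_switches(tr, pl, switch_config())
  expect_equal(eff_on$traits, tr)
  expect_equal(eff_on$plots$b_init, pl$b_init)
})

test_that("height off averages canopy height but not seed-release height", {
  tr <- toy_traits(2)
  tr$height_h <- c(0.5, 1.0)
  tr$release_height <- c(0.5, 1.0)
  eff <- apply_switches(tr, one_plot(tr), switch_config(height = FALSE))
  expect_equal(eff$traits$height_h, c(0.75, 0.75))
  expect_equal(eff$traits$release_height, c(0.5, 1.0))
})

test_that("b_init off takes the within-plot mean over sown species only", {
  tr <- toy_traits(3)
  df <- data.frame(plot_id = "p1", block_id = "b1", x = 0, y = 0,
                   side = 0.75, soil_N = 500)
  sown <- matrix(c(TRUE, TRUE, FALSE), 1, 3,
                 dimnames = list("p1", tr$species_id))
  b_init <- matrix(c(2, 4, 0), 1, 3, dimnames = dimnames(sown))
  pl <- plot_matrix(df, sown, b_init)
  eff <- apply_switches(tr, pl, switch_config(b_init = FALSE))
  expect_equal(as.numeric(eff$plots$b_init), c(3, 3, 0))
})

test_that("apply_switches is idempotent and neutralises all trait fields", {
  tr <- small_traits()
  pl <- small_design(tr)
  cfg <- switch_config(.default = FALSE)
  once <- apply_switches(tr, pl, cfg)
  twice <- apply_switches(once$traits, once$plots, cfg)
  expect_equal(twice$traits, once$traits)
  expect_equal(twice$plots$b_init, once$plots$b_init)
  # neutral limit: switched fields identical across species
  for (col in c("R_star", "Bstar_intercept", "Bstar_slope", "fecundity_f",
                "rooting_depth_rd", "height_h", "pheno_start", "pheno_end",
                "mortality_m", "RGR_intercept", "RGR_slope"))
    expect_length(unique(once$traits[[col]]), 1)
})

test_that("apply_switches rejects unknown switches and empty traits", {
  tr <- toy_traits(2)
  expect_error(switch_config(gravity = FALSE), "unknown switch")
  expect_error(apply_switches(tr[0, ], one_plot(tr), switch_config()),
               "empty")
})

test_that("scenario enumeration is a complete, distinct factorial", {
  sc11 <- enumerate_scenarios(11)
  expect_equal(nrow(sc11), 2048)
  expect_equal(anyDuplicated(sc11$scenario_code), 0)
  expect_equal(nrow(enumerate_scenarios(1)), 2)
  sc3 <- enumerate_scenarios(3)
  expect_equal(nrow(sc3), 8)
  expect_equal(anyDuplicated(sc3[, switch_names()[1:3]]), 0)
  # contains all-off and all-on combinations of the varied attributes
  expect_true(any(rowSums(sc11[, switch_names()]) == 0))
  expect_true(any(rowSums(sc11[, switch_names()]) == 11))
  expect_error(enumerate_scenarios(0))
})

test_that("mechanism status follows the exactly/at-least attribute rule", {
  m1_only <- switch_config(.default = FALSE, r_star = TRUE, b_star = TRUE)
  st <- mechanism_status(m1_only, 2, "exactly")
  expect_equal(unname(st), c(TRUE, FALSE, FALSE, FALSE))
  st_all <- mechanism_status(switch_config(), 2, "exactly")
  # 4 on in the colonisation group and 3 in niche differentiation are not
  # 'exactly 2'
  expect_equal(unname(st_all), c(TRUE, FALSE, FALSE, TRUE))
  st_off <- mechanism_status(switch_config(.default = FALSE), 1, "at_least")
  expect_false(any(st_off))
  # a requirement larger than the group: M1/M4 (2 attributes) never 'on'
  st3 <- mechanism_status(switch_config(), 3, "exactly")
  expect_false(st3[["resource_competition"]])
  expect_false(st3[["growth_rates"]])
})

test_that("PCA imputation preserves observed cells and recovers low-rank structure", {
  m <- matrix(rnorm(20), 5, 4)
  expect_equal(impute_trait_pca(m), m)   # nothing missing: identity
  # all species identical on observed traits: imputed value = trait mean
  m2 <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  m2[, 4] <- c(5, 6, 7, 8, 9)            # one varying trait so PCA is defined
  m2[2, 2] <- NA
  imp <- impute_trait_pca(m2)
  expect_equal(imp[2, 2], 2, tolerance = 1e-6)
  expect_equal(imp[-2, ], m2[-2, ])
  # rank-1 trait matrix: deleted cell recovered within 1%
  set.seed(5)
  score <- rnorm(6)
  load <- runif(5, 0.5, 2)
  full <- outer(score, load)
  holed <- full
  holed[2, 3] <- NA
  imp1 <- impute_trait_pca(holed)
  expect_lt(abs(imp1[2, 3] - full[2, 3]) / abs(full[2, 3]), 0.01)
  expect_error(impute_trait_pca(matrix(c(NA, NA, 1, 2), 2, 2)),
               "no observed values")
})
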