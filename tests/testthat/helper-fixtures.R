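# Shared small fixtures, generated in code. The 2-block spec keeps the
# full 4 x 16 block geometry but trims the block count so whole-pipeline
# tests stay fast.

small_spec <- function() fixture_spec(n_blocks = 2L)

small_traits <- function(seed = 7L) make_traits(small_spec(), seed = seed)

small_design <- function(traits = small_traits(), seed = 8L)
  make_design(small_spec(), traits, seed = seed)

# Equal sowing: every species sown in every plot with equal seed biomass.
equal_sowing <- function(plots, b = 0.6) {
  sown <- matrix(TRUE, nrow(plots$plots), length(plots$species),
                 dimnames = dimnames(plots$sown))
  plot_matrix(plots$plots, sown, matrix(b, nrow(sown), ncol(sown),
                                        dimnames = dimnames(sown)))
}

# A single square plot at the origin, all species sown.
one_plot <- function(traits, side = 0.75, soil_N = 500) {
  df <- data.frame(plot_id = "p1", block_id = "b1", x = 0, y = 0,
                   side = side, soil_N = soil_N)
  n <- nrow(traits)
  sown <- matrix(TRUE, 1, n, dimnames = list("p1", traits$species_id))
  plot_matrix(df, sown, matrix(1, 1, n, dimnames = dimnames(sown)))
}

# Minimal hand-built trait table for arithmetic tests.
toy_traits <- function(n = 3) {
  species_traits(data.frame(
    species_id = paste0("s", seq_len(n)),
    R_star = seq(0.1, by = 0.1, length.out = n),
    Bstar_intercept = rep(log(100), n),
    Bstar_slope = rep(0, n),
    RGR_intercept = rep(0.05, n),
    RGR_slope = rep(0, n),
    fecundity_f = rep(0.2, n),
    mortality_m = rep(0.1, n),
    q = rep(10, n),
    height_h = rep(0.5, n),
    release_height = rep(0.5, n),
    terminal_velocity_v = rep(1, n),
    rooting_depth_rd = rep(100, n),
    pheno_start = rep(4L, n),
    pheno_end = rep(9L, n)))
}
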