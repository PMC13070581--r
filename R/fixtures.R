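# Synthetic fixtures emulating a sown-grassland biodiversity experiment:
# five perennial grasses sown in 1-5 species mixtures at three densities
# into blocks of contiguous square plots spanning a soil nitrogen gradient,
# with weeding (only sown species may colonise each plot). Everything is a
# pure function of (spec, seed), so the full pipeline is buildable and
# testable without external data.

#' Specification of a synthetic experiment
#'
#' Defaults mirror the layout of the emulated field experiment: 5 species,
#' 10 blocks of 64 contiguous 0.75 m x 0.75 m plots (4 x 16 grid, i.e.
#' 3 m x 12 m blocks) separated by 1 m walkways, a block-level soil N
#' gradient of ~100-1200 mg/kg, 43 sowing treatments at total densities of
#' 600, 3000 or 6000 seedlings/m^2 with 1-4 replicates each.
#'
#' @param n_species number of species (default 5).
#' @param n_blocks number of blocks (default 10).
#' @param block_ncol,block_nrow plot grid within a block (default 4 x 16).
#' @param plot_side plot side length, m (default 0.75).
#' @param walkway gap between blocks, m (default 1).
#' @param soil_N_range block-level total soil N range, mg/kg.
#' @param densities sowing densities, seedlings/m^2.
#' @param n_treatments number of distinct sowing treatments (default 43).
#' @param seed_mass_range per-seed mass range, g.
#' @param noise_sd lognormal observation noise sd (log scale).
#' @return list of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(n_species = 5L, n_blocks = 10L, block_ncol = 4L,
                         block_nrow = 16L, plot_side = 0.75, walkway = 1,
                         soil_N_range = c(100, 1200),
                         densities = c(600, 3000, 6000),
                         n_treatments = 43L,
                         seed_mass_range = c(2e-4, 2e-3),
                         noise_sd = 0.2) {
  spec <- list(n_species = as.integer(n_species),
               n_blocks = as.integer(n_blocks),
               block_ncol = as.integer(block_ncol),
               block_nrow = as.integer(block_nrow),
               plot_side = plot_side, walkway = walkway,
               soil_N_range = soil_N_range, densities = densities,
               n_treatments = as.integer(n_treatments),
               seed_mass_range = seed_mass_range, noise_sd = noise_sd)
  stopifnot(spec$n_species >= 2L, spec$n_blocks >= 1L,
            spec$block_ncol >= 1L, spec$block_nrow >= 1L,
            spec$plot_side > 0, all(spec$soil_N_range > 0),
            all(spec$densities > 0), all(spec$seed_mass_range > 0))
  class(spec) <- "fixture_spec"
  spec
}

#' Generate an internally consistent synthetic trait table
#'
#' Samples per-species traits within field-realistic ranges for perennial
#' grasses: pairwise-distinct R* (well-defined competitive hierarchy),
#' fecundity 0.05-0.4, mortality 0.1-0.6, canopy heights 0.2-1.2 m,
#' rooting depths 30-200 cm, phenology windows within April-October,
#' terminal velocities 0.3-3 m/s, tissue N 5-25 mg/g, and B*/RGR
#' regression coefficients that stay positive over the soil-N range (B*
#' slope common across species, as fitted; RGR slopes species-specific).
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param seed RNG seed.
#' @return a \code{\link{species_traits}} table with a \code{seed_mass}
#'   column.
#' @export
make_traits <- function(spec = fixture_spec(), seed = 1L) {
  n <- spec$n_species
  with_seed(seed, {
    ids <- paste0("sp", seq_len(n))
    # distinct R* by construction: jittered equally spaced ranks
    r_star <- sort(seq(0.2, 2, length.out = n) +
                     stats::runif(n, -0.05, 0.05))
    bstar_slope <- rep(stats::runif(1, 0.3, 0.5), n)
    # intercepts chosen so B* at 600 mg/kg lands in 60-220 g/m^2
    bstar600 <- stats::runif(n, 60, 220)
    bstar_int <- log(bstar600) - bstar_slope * log(600)
    rgr_int <- stats::runif(n, 0.04, 0.09)
    rgr_slope <- stats::runif(n, 2e-5, 8e-5)
    height <- stats::runif(n, 0.2, 1.2)
    tr <- data.frame(
      species_id = ids,
      R_star = r_star,
      Bstar_intercept = bstar_int,
      Bstar_slope = bstar_slope,
      RGR_intercept = rgr_int,
      RGR_slope = rgr_slope,
      fecundity_f = stats::runif(n, 0.05, 0.4),
      mortality_m = stats::runif(n, 0.1, 0.6),
      q = stats::runif(n, 5, 25),
      height_h = height,
      release_height = height * stats::runif(n, 0.8, 1),
      terminal_velocity_v = stats::runif(n, 0.3, 3),
      rooting_depth_rd = stats::runif(n, 30, 200),
      pheno_start = sample(4:6, n, replace = TRUE),
      seed_mass = stats::runif(n, spec$seed_mass_range[1],
                               spec$seed_mass_range[2]),
      stringsAsFactors = FALSE)
    tr$pheno_end <- tr$pheno_start + sample(2:4, n, replace = TRUE)
    tr$pheno_end <- pmin(tr$pheno_end, 10L)
    species_traits(tr)
  })
}

# Sowing treatment list with the design's marginal properties: all
# monocultures present at every density, plus 2-, 3- and n-species
# mixtures, each at one of the density levels; replicates 1-4 per block,
# padded/trimmed to fill the block exactly.
.make_treatments <- function(spec, species, seed_offset) {
  n_sp <- length(species)
  trts <- list()
  # monocultures for every species x density (needed for B* scaling)
  for (s in species) for (d in spec$densities)
    trts[[length(trts) + 1L]] <- list(species = s, density = d)
  combos2 <- utils::combn(species, min(2L, n_sp), simplify = FALSE)
  combos3 <- if (n_sp >= 3L) utils::combn(species, 3L, simplify = FALSE)
             else list()
  pool <- c(combos2, combos3, list(species))
  k <- 1L
  while (length(trts) < spec$n_treatments) {
    cmb <- pool[[(k - 1L) %% length(pool) + 1L]]
    d <- spec$densities[(k - 1L) %% length(spec$densities) + 1L]
    trts[[length(trts) + 1L]] <- list(species = cmb, density = d)
    k <- k + 1L
  }
  trts[seq_len(spec$n_treatments)]
}

#' Generate a synthetic experimental design
#'
#' Lays out \code{n_blocks} blocks of contiguous square plots (walkways
#' between blocks), assigns a monotone block-level soil N gradient with
#' within-block jitter, builds the treatment list (all monocultures at
#' every density, plus 2-, 3- and full mixtures) and assigns treatments to
#' plots with 1-4 replicates per block. Sown seed biomass per species is
#' (total density / richness) x per-seed mass, so total seedling density
#' is constant across richness levels.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param traits trait table from \code{\link{make_traits}} (per-seed
#'   masses).
#' @param seed RNG seed.
#' @return a \code{\link{plot_matrix}}.
#' @export
make_design <- function(spec = fixture_spec(), traits, seed = 1L) {
  with_seed(seed, {
    ppb <- spec$block_ncol * spec$block_nrow
    n_plots <- spec$n_blocks * ppb
    side <- spec$plot_side
    block_w <- spec$block_ncol * side
    soil_block <- seq(spec$soil_N_range[1], spec$soil_N_range[2],
                      length.out = max(spec$n_blocks, 2L))[seq_len(spec$n_blocks)]
    rows <- list()
    for (b in seq_len(spec$n_blocks)) {
      x0 <- (b - 1L) * (block_w + spec$walkway)
      ci <- rep(seq_len(spec$block_ncol), times = spec$block_nrow)
      ri <- rep(seq_len(spec$block_nrow), each = spec$block_ncol)
      rows[[b]] <- data.frame(
        plot_id = sprintf("b%02dp%02d", b, seq_len(ppb)),
        block_id = sprintf("b%02d", b),
        x = x0 + (ci - 0.5) * side,
        y = (ri - 0.5) * side,
        side = side,
        soil_N = pmax(50, soil_block[b] *
                        exp(stats::rnorm(ppb, 0, 0.08))),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    species <- traits$species_id
    trts <- .make_treatments(spec, species, seed)
    sown <- matrix(FALSE, n_plots, length(species),
                   dimnames = list(df$plot_id, species))
    b_init <- matrix(0, n_plots, length(species),
                     dimnames = list(df$plot_id, species))
    seed_mass <- if ("seed_mass" %in% names(traits)) traits$seed_mass
                 else rep(1e-3, length(species))
    for (b in seq_len(spec$n_blocks)) {
      # replicates 1-4 per treatment, padded to fill the block exactly
      reps <- rep(1L, length(trts))
      spare <- ppb - sum(reps)
      while (spare > 0L) {
        i <- sample.int(length(trts), 1L)
        if (reps[i] < 4L) { reps[i] <- reps[i] + 1L; spare <- spare - 1L }
      }
      assign_trt <- sample(rep(seq_along(trts), times = reps))
      pidx <- (b - 1L) * ppb + seq_len(ppb)
      for (p in seq_len(ppb)) {
        trt <- trts[[assign_trt[p]]]
        sp_i <- match(trt$species, species)
        per_sp_density <- trt$density / length(sp_i)
        sown[pidx[p], sp_i] <- TRUE
        b_init[pidx[p], sp_i] <- per_sp_density * seed_mass[sp_i]
      }
    }
    pm <- plot_matrix(df, sown, b_init)
    pm$treatments <- trts
    pm
  })
}

#' Generate synthetic observed biomass
#'
#' Runs the full model (all 11 attributes on) for \code{years} growing
#' seasons and multiplies the end-of-final-year biomass of each sown
#' species by lognormal noise exp(N(0, noise_sd^2)), emulating field
#' sampling error. With \code{noise_sd = 0} the observations equal the
#' full-model predictions exactly.
#'
#' @param traits trait table.
#' @param plots design from \code{\link{make_design}}.
#' @param noise_sd lognormal noise sd (log scale).
#' @param seed RNG seed (drives both the simulation and the noise).
#' @param years growing seasons (default 6).
#' @param ... passed to \code{\link{run_simulation}}.
#' @return data.frame with plot_id, species_id, biomass for every sown
#'   (species, plot) pair.
#' @export
make_observations <- function(traits, plots, noise_sd = 0.2, seed = 1L,
                              years = 6L, ...) {
  sim <- run_simulation(traits, plots, switch_config(), years = years,
                        seed = seed, keep_trajectory = FALSE, ...)
  obs <- sim_biomass(sim)
  sown <- plots$sown[cbind(match(obs$plot_id, rownames(plots$sown)),
                           match(obs$species_id, colnames(plots$sown)))]
  obs <- obs[sown, , drop = FALSE]
  with_seed(seed + 1L, {
    if (noise_sd > 0)
      obs$biomass <- obs$biomass *
        exp(stats::rnorm(nrow(obs), 0, noise_sd))
  })
  rownames(obs) <- NULL
  obs
}
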