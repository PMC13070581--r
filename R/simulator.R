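# Multi-year, multi-patch orchestration: arrival -> lottery -> growth ->
# overwinter, and the full-factorial scenario scan with replicates.

#' Run one multi-year metacommunity simulation
#'
#' Applies the attribute switches, builds the dispersal array (identity
#' when the dispersal attribute is off), then simulates: year 0 converts
#' the sown seed biomass (B_init) into adult biomass through the
#' establishment pathway; each subsequent growing season integrates the
#' competition ODE over 160 days, routes the fecundity fraction of
#' end-of-season biomass into seed rain (weeded to sown species),
#' overwinters the survivors, and establishes arriving seed through the
#' lottery (stochastic) or deterministic allocation. Reported annual
#' biomass is end-of-growing-season (peak) biomass, before overwintering.
#'
#' @param traits a \code{\link{species_traits}} table.
#' @param plots a \code{\link{plot_matrix}}.
#' @param config a \code{\link{switch_config}}.
#' @param years number of growing seasons to simulate (default 6).
#' @param seed RNG seed for this run (dispersal Monte-Carlo and lottery).
#' @param wind_velocity mean wind velocity, m/s (default 3).
#' @param sigma2 WALD turbulence parameter (default 0.3).
#' @param n_seeds dispersal Monte-Carlo seeds per species and plot
#'   (default 2e4).
#' @param packet_mass lottery packet mass, g; default uses the trait
#'   table's \code{seed_mass} column when present, else 1e-3 g.
#' @param t_end,dt growing-season length and ODE step, days.
#' @param pd optional precomputed \code{\link{build_dispersal_array}}
#'   result (reused across scenarios; the kernel is time-invariant and does
#'   not depend on the switches).
#' @param keep_trajectory keep per-year biomass matrices (default TRUE).
#' @return object of class \code{"mmniche_sim"}: list with \code{final}
#'   (species-by-plot end-of-season biomass in the last simulated year),
#'   \code{trajectory} (per-year list), \code{config}, \code{flags},
#'   \code{seed}, \code{traits}, \code{plots}.
#' @export
run_simulation <- function(traits, plots, config = switch_config(),
                           years = 6L, seed = NULL, wind_velocity = 3,
                           sigma2 = 0.3, n_seeds = 2e4, packet_mass = NULL,
                           t_end = 160, dt = 1, pd = NULL,
                           keep_trajectory = TRUE) {
  years <- as.integer(years)
  if (is.na(years) || years < 1L) stop("years must be >= 1", call. = FALSE)
  if (!all(plots$species %in% traits$species_id))
    stop("traits must cover all sown species", call. = FALSE)
  traits <- traits[match(plots$species, traits$species_id), , drop = FALSE]
  class(traits) <- c("species_traits", "data.frame")
  eff <- apply_switches(traits, plots, config)
  tr <- eff$traits
  pl <- eff$plots
  flags <- eff$flags
  if (is.null(packet_mass))
    packet_mass <- if ("seed_mass" %in% names(tr)) tr$seed_mass else 1e-3

  with_seed(seed, {
    if (is.null(pd) || !flags$dispersal_on)
      pd <- build_dispersal_array(pl, tr, n_seeds = n_seeds,
                                  wind_velocity = wind_velocity,
                                  sigma2 = sigma2,
                                  dispersal_on = flags$dispersal_on)
    soil_N <- stats::setNames(pl$plots$soil_N, pl$plots$plot_id)
    params <- modulate_by_soil_n(tr, soil_N)
    ov <- total_overlap(tr)
    mask <- competitor_masks(tr, flags$r_star_on)
    W <- competition_matrix(tr, ov, mask, flags$r_star_on)
    establish <- function(pool, b_now) {
      budget <- nitrogen_budget(b_now, params$Bstar, W, tr$q)
      if (flags$lottery_on)
        lottery_establish(pool, budget, tr$fecundity_f, packet_mass)
      else
        deterministic_establish(pool, budget, tr$fecundity_f)
    }
    zero <- matrix(0, nrow(tr), nrow(pl$plots),
                   dimnames = list(tr$species_id, pl$plots$plot_id))
    # year 0: sown seed enters through the same establishment pathway
    b <- establish(t(pl$b_init), zero)
    trajectory <- if (keep_trajectory) vector("list", years) else NULL
    B_end <- NULL
    for (y in seq_len(years)) {
      B_end <- grow_season(b, params, W, t_end = t_end, dt = dt)
      if (any(!is.finite(B_end)))
        stop(sprintf("non-finite biomass in year %d", y), call. = FALSE)
      if (keep_trajectory) trajectory[[y]] <- B_end
      if (y < years) {
        D <- seed_rain(B_end, tr, pd, pl$sown)
        surv <- overwinter(B_end, tr)
        b <- surv + establish(D, surv)
      }
    }
    structure(list(final = B_end, trajectory = trajectory,
                   config = as_switch_config(config), flags = flags,
                   seed = seed, years = years, traits = tr, plots = pl),
              class = "mmniche_sim")
  })
}

#' @export
print.mmniche_sim <- function(x, ...) {
  cat(sprintf("mmniche_sim: %d species x %d plots, %d growing seasons\n",
              nrow(x$final), ncol(x$final), x$years))
  cat(sprintf("  attributes on: %d/11; seed: %s\n", sum(x$config),
              x$seed %||% "<unset>"))
  cat("  final-year mean biomass by species (g/m^2):\n")
  print(round(rowMeans(x$final), 2))
  invisible(x)
}

#' @export
summary.mmniche_sim <- function(object, ...) {
  out <- data.frame(species_id = rownames(object$final),
                    mean_biomass = rowMeans(object$final),
                    max_biomass = apply(object$final, 1, max),
                    plots_occupied = rowSums(object$final > 0),
                    row.names = NULL)
  out
}

#' Long-format biomass table from a simulation
#' @param sim an \code{mmniche_sim}.
#' @param year year to extract (default final).
#' @return data.frame with plot_id, species_id, biomass.
#' @export
sim_biomass <- function(sim, year = sim$years) {
  B <- if (year == sim$years) sim$final else sim$trajectory[[year]]
  data.frame(plot_id = rep(colnames(B), each = nrow(B)),
             species_id = rep(rownames(B), times = ncol(B)),
             biomass = as.numeric(B), stringsAsFactors = FALSE)
}

#' Full-factorial (or subset) scenario scan with replicates
#'
#' Runs \code{run_simulation} for every scenario x replicate combination.
#' Per-run seeds are derived deterministically from the master seed, the
#' scenario's intrinsic bit code and the replicate index, so a scenario's
#' results never depend on which other scenarios are in the batch or on
#' execution order. The dispersal array is Monte-Carlo built once per
#' replicate (it does not depend on the switches beyond the dispersal
#' on/off flag) and shared across scenarios.
#'
#' @param traits a \code{\link{species_traits}} table.
#' @param plots a \code{\link{plot_matrix}}.
#' @param scenarios data.frame of switch columns (one row per scenario),
#'   e.g. from \code{\link{enumerate_scenarios}}; default the full 2^11.
#' @param replicates replicate simulations per scenario (default 10).
#' @param years growing seasons per run (default 6).
#' @param master_seed master RNG seed.
#' @param ... passed to \code{\link{run_simulation}}.
#' @return object of class \code{"mmniche_scan"}: \code{results} is a
#'   long-format data.frame (scenario_code, the 11 switch columns,
#'   replicate, seed, plot_id, species_id, biomass at the end of the final
#'   year); \code{scenarios}, \code{replicates}, \code{master_seed} record
#'   the design.
#' @export
run_factorial <- function(traits, plots, scenarios = enumerate_scenarios(),
                          replicates = 10L, years = 6L, master_seed = 1L,
                          ...) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be >= 1", call. = FALSE)
  scenarios <- as.data.frame(scenarios)
  cfgs <- lapply(seq_len(nrow(scenarios)), function(r)
    as_switch_config(scenarios[r, ]))
  codes <- vapply(cfgs, scenario_code, integer(1))
  if (anyDuplicated(codes)) stop("duplicate scenario entries", call. = FALSE)
  dots <- list(...)
  n_seeds <- dots$n_seeds %||% 2e4
  wind_velocity <- dots$wind_velocity %||% 3
  sigma2 <- dots$sigma2 %||% 0.3
  chunks <- vector("list", length(cfgs) * replicates)
  k <- 0L
  for (rep_i in seq_len(replicates)) {
    # shared dispersal Monte-Carlo for this replicate (scenario-independent)
    pd_rep <- build_dispersal_array(plots, traits, n_seeds = n_seeds,
                                    wind_velocity = wind_velocity,
                                    sigma2 = sigma2, dispersal_on = TRUE,
                                    seed = derive_seed(master_seed, 4096L,
                                                       rep_i))
    for (s in seq_along(cfgs)) {
      run_seed <- derive_seed(master_seed, codes[s], rep_i)
      sim <- run_simulation(traits, plots, cfgs[[s]], years = years,
                            seed = run_seed, pd = pd_rep,
                            keep_trajectory = FALSE, ...)
      bio <- sim_biomass(sim)
      sw <- as.list(unclass(cfgs[[s]]))
      k <- k + 1L
      chunks[[k]] <- cbind(
        data.frame(scenario_code = codes[s], replicate = rep_i,
                   seed = run_seed),
        as.data.frame(sw)[rep(1L, nrow(bio)), , drop = FALSE],
        bio, row.names = NULL)
    }
  }
  structure(list(results = do.call(rbind, chunks),
                 scenarios = scenarios, replicates = replicates,
                 master_seed = master_seed, years = years),
            class = "mmniche_scan")
}

#' @export
print.mmniche_scan <- function(x, ...) {
  cat(sprintf("mmniche_scan: %d scenarios x %d replicates (%d years, master seed %s)\n",
              nrow(x$scenarios), x$replicates, x$years, x$master_seed))
  cat(sprintf("  %d biomass records\n", nrow(x$results)))
  invisible(x)
}
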