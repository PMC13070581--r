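# Delimited-text readers/writers and run configuration. All tables are
# plain CSV; the plot table carries the per-species sowing design in wide
# columns sown_<species> / binit_<species>.

#' Read / write a species trait table
#'
#' CSV with one row per species and the trait schema columns (see
#' \code{\link{species_traits}}); missing values as empty cells are
#' rejected for required traits. Round-trip stable.
#'
#' @param path file path.
#' @return \code{read_traits}: a validated \code{species_traits} table.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  species_traits(df)
}

#' @rdname read_traits
#' @param traits trait table to write.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a plot matrix
#'
#' CSV with per-plot columns plot_id, block_id, x, y, side, soil_N and,
#' per species, \code{sown_<species_id>} (0/1) and \code{binit_<species_id>}
#' (g/m^2). Validation errors name the offending column and row.
#'
#' @param path file path.
#' @return \code{read_plots}: a \code{\link{plot_matrix}}.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sown_cols <- grep("^sown_", names(df), value = TRUE)
  binit_cols <- grep("^binit_", names(df), value = TRUE)
  if (!length(sown_cols) || !length(binit_cols))
    stop("plot file needs sown_<species> and binit_<species> columns",
         call. = FALSE)
  species <- sub("^sown_", "", sown_cols)
  if (!setequal(species, sub("^binit_", "", binit_cols)))
    stop("sown_/binit_ species columns do not match", call. = FALSE)
  sown <- as.matrix(df[, paste0("sown_", species), drop = FALSE]) > 0
  b_init <- as.matrix(df[, paste0("binit_", species), drop = FALSE])
  colnames(sown) <- colnames(b_init) <- species
  plot_matrix(df[, c("plot_id", "block_id", "x", "y", "side", "soil_N")],
              sown, b_init)
}

#' @rdname read_plots
#' @param plots \code{plot_matrix} to write.
#' @export
write_plots <- function(plots, path) {
  df <- plots$plots
  for (s in plots$species) {
    df[[paste0("sown_", s)]] <- as.integer(plots$sown[, s])
    df[[paste0("binit_", s)]] <- plots$b_init[, s]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write scan results as a long-format table
#'
#' One row per (scenario, replicate, plot, species): scenario_code, the 11
#' switch booleans, replicate, seed, plot_id, species_id,
#' predicted_biomass.
#'
#' @param scan an \code{mmniche_scan} (or its results data.frame).
#' @param path output CSV path.
#' @export
write_results <- function(scan, path) {
  res <- if (inherits(scan, "mmniche_scan")) scan$results else scan
  names(res)[names(res) == "biomass"] <- "predicted_biomass"
  utils::write.csv(res, path, row.names = FALSE)
  invisible(path)
}

.config_defaults <- list(
  years = 6L,
  replicates = 10L,          # replicate simulations per scenario
  master_seed = 1L,
  wind_velocity = 3,         # m/s
  sigma2 = 0.3,              # WALD turbulence parameter
  n_seeds = 2e4,             # dispersal Monte-Carlo seeds per species/plot
  t_end = 160,               # growing-season length, days
  dt = 1,                    # ODE step, days
  packet_mass = NULL         # lottery packet mass, g (NULL = seed_mass/1e-3)
)

#' Load a run configuration
#'
#' Reads a flat YAML (or JSON) key/value file. Recognised keys: paths
#' (\code{traits}, \code{plots}, \code{observed}, \code{output}), numeric
#' settings (\code{years}, \code{replicates}, \code{master_seed},
#' \code{wind_velocity}, \code{sigma2}, \code{n_seeds}, \code{t_end},
#' \code{dt}, \code{packet_mass}) and a \code{switches} block with the 11
#' attribute booleans. Omitted settings take the model's standard defaults
#' (sigma2 = 0.3, 160-day season, 2e4 dispersal seeds, 10 replicates),
#' which are logged via message when filled in.
#'
#' @param path YAML or JSON file.
#' @return list of class \code{"run_config"}: settings, \code{switches}
#'   (a \code{\link{switch_config}}) and any paths given.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw <- raw %||% list()
  cfg <- .config_defaults
  for (nm in names(cfg)) {
    if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
    else if (!is.null(cfg[[nm]]))
      message(sprintf("config: '%s' not given, using default %s",
                      nm, format(cfg[[nm]])))
  }
  sw <- raw$switches %||% list()
  unknown <- setdiff(names(sw), switch_names())
  if (length(unknown))
    stop("unknown switch name(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg$switches <- do.call(switch_config, as.list(sw))
  for (p in c("traits", "plots", "observed", "output"))
    cfg[[p]] <- raw[[p]]
  class(cfg) <- "run_config"
  cfg
}
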