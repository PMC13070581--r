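# Species trait table: the per-species parameters feeding the four
# mechanisms (resource competition, dispersal/colonisation, spatiotemporal
# niche differentiation, population growth rates).

.trait_columns <- c(
  "species_id",
  "R_star",                          # residual soil nitrate at equilibrium (mg/kg)
  "Bstar_intercept", "Bstar_slope",  # log biomass ~ log soil N
  "RGR_intercept", "RGR_slope",      # RGR (/day) ~ soil N (mg/kg)
  "fecundity_f",                     # fraction of biomass to seed, [0,1]
  "mortality_m",                     # overwinter biomass loss fraction, [0,1]
  "q",                               # tissue N per unit biomass (mg N / g)
  "height_h",                        # canopy height (m)
  "release_height",                  # seed-release height (m)
  "terminal_velocity_v",             # seed terminal velocity (m/s)
  "rooting_depth_rd",                # maximum rooting depth (cm)
  "pheno_start", "pheno_end"         # first/last active month (1-12)
)

#' Construct and validate a species trait table
#'
#' Builds the trait table consumed by every other module: one row per
#' species, with the resource-competition parameters (\code{R_star},
#' \code{B*} regression coefficients), colonisation parameters (fecundity,
#' seed-release height, terminal velocity), niche-differentiation traits
#' (rooting depth, canopy height, phenology window) and population growth
#' parameters (mortality, RGR regression coefficients). \code{release_height}
#' defaults to \code{height_h} when not supplied; the two are distinct traits
#' because the canopy-height attribute can be switched off without altering
#' dispersal.
#'
#' @param df data.frame containing the trait columns (see
#'   \code{\link{read_traits}} for the file schema). An optional
#'   \code{seed_mass} column (g per seed) is carried through and used as the
#'   default lottery packet mass.
#' @return the validated data.frame, with class \code{"species_traits"}
#'   prepended.
#' @export
species_traits <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty trait table", call. = FALSE)
  if (!"release_height" %in% names(df)) df$release_height <- df$height_h
  missing_cols <- setdiff(.trait_columns, names(df))
  if (length(missing_cols))
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$species_id))
    stop("duplicated species_id in trait table", call. = FALSE)
  validate_traits(df)
  class(df) <- c("species_traits", "data.frame")
  df
}

validate_traits <- function(df) {
  chk <- function(ok, msg) {
    bad <- which(!ok)
    if (length(bad))
      stop(sprintf("trait table: %s (row %s, species %s)", msg, bad[1],
                   df$species_id[bad[1]]), call. = FALSE)
  }
  num_cols <- setdiff(.trait_columns, "species_id")
  for (cl in num_cols)
    if (!is.numeric(df[[cl]]) || anyNA(df[[cl]]))
      stop(sprintf("trait table: column '%s' must be numeric with no missing values",
                   cl), call. = FALSE)
  chk(df$fecundity_f >= 0 & df$fecundity_f <= 1, "fecundity_f outside [0,1]")
  chk(df$mortality_m >= 0 & df$mortality_m <= 1, "mortality_m outside [0,1]")
  chk(df$q > 0, "q must be > 0")
  chk(df$height_h > 0, "height_h must be > 0")
  chk(df$release_height > 0, "release_height must be > 0")
  chk(df$terminal_velocity_v > 0, "terminal_velocity_v must be > 0")
  chk(df$rooting_depth_rd > 0, "rooting_depth_rd must be > 0")
  chk(df$R_star >= 0, "R_star must be >= 0")
  chk(df$pheno_start <= df$pheno_end, "pheno_start must be <= pheno_end")
  chk(df$pheno_start >= 1 & df$pheno_end <= 12, "phenology months outside 1..12")
  invisible(df)
}

#' Impute missing trait values via principal components
#'
#' Completes a species-by-trait matrix with missing entries, the way missing
#' demographic rates (e.g. mortality for species lacking direct estimates)
#' are interpolated from the full multivariate trait relationship. Columns
#' are standardised, missing cells start at the trait mean (0 on the
#' standardised scale), a principal-components decomposition is fitted, and
#' the missing cells are re-estimated from the reconstruction using the
#' leading components (those explaining at least \code{var_explained} of the
#' variance). The fill-decompose-reconstruct cycle is iterated to a fixed
#' point so that low-rank structure is recovered exactly; observed cells are
#' never altered.
#'
#' @param x numeric matrix, species in rows, traits in columns; \code{NA}
#'   marks missing cells.
#' @param var_explained minimum cumulative variance fraction retained.
#' @param tol convergence tolerance on imputed values between iterations.
#' @param max_iter iteration cap.
#' @return completed numeric matrix, same dimensions and dimnames.
#' @export
impute_trait_pca <- function(x, var_explained = 0.9, tol = 1e-8,
                             max_iter = 100L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 species and 2 traits", call. = FALSE)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (any(colSums(!miss) == 0L))
    stop("trait column with no observed values cannot be imputed", call. = FALSE)
  mu <- colMeans(x, na.rm = TRUE)
  sg <- apply(x, 2L, stats::sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sg, "/")
  z[miss] <- 0
  for (it in seq_len(max_iter)) {
    pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    k <- which(cumsum(ev) / sum(ev) >= var_explained)[1L]
    recon <- pc$x[, seq_len(k), drop = FALSE] %*%
      t(pc$rotation[, seq_len(k), drop = FALSE])
    recon <- sweep(recon, 2L, pc$center, "+")
    delta <- max(abs(recon[miss] - z[miss]))
    z[miss] <- recon[miss]
    if (delta < tol) break
  }
  out <- sweep(sweep(z, 2L, sg, "*"), 2L, mu, "+")
  x[miss] <- out[miss]
  x
}
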