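# Model evaluation: B*-scaled prediction error, log-scale R-squared, and
# the top-model attribute/mechanism importance analyses used to rank model
# variants.

#' B*-scaled root-mean-square error
#'
#' Prediction error scaled by the species' monoculture carrying capacity:
#' sqrt(mean(((y - yhat) / B*)^2)) within each group. Scaling by B*
#' removes the dependence of raw RMSE on average biomass, so errors are
#' comparable across species and soil-N levels; the statistic is invariant
#' to a common rescaling of observed, predicted and B*.
#'
#' @param observed,predicted,Bstar numeric vectors of equal length;
#'   \code{Bstar} must be positive.
#' @param groups optional grouping (factor or list of factors); NULL gives
#'   a single overall value.
#' @return numeric vector of per-group RMSE (named by group), or a scalar.
#' @export
scaled_rmse <- function(observed, predicted, Bstar, groups = NULL) {
  if (length(observed) == 0L) stop("empty group", call. = FALSE)
  if (any(!is.finite(Bstar)) || any(Bstar <= 0))
    stop("Bstar must be positive", call. = FALSE)
  e2 <- ((observed - predicted) / Bstar)^2
  if (is.null(groups)) return(sqrt(mean(e2)))
  sqrt(tapply(e2, groups, mean))
}

#' Coefficient of determination on log-scaled biomass
#'
#' R^2 = 1 - SS_res/SS_tot about the observed mean, computed on
#' log-transformed B*-scaled biomass (log(y/B* + eps); the small offset
#' admits zero biomass). At \code{level = "species"} each (species, plot)
#' record is a point; at \code{level = "summed"} observations, predictions
#' and B* are summed across species within each plot first
#' (sum(y)/sum(B*) vs sum(yhat)/sum(B*)).
#'
#' @param observed,predicted,Bstar numeric vectors of equal length.
#' @param level \code{"species"} or \code{"summed"}.
#' @param plot plot identifier per record (required for
#'   \code{level = "summed"}).
#' @param eps offset added to scaled biomass before the log (default 1e-3).
#' @param log_scale set FALSE for R^2 on the linear scaled values.
#' @return scalar R^2.
#' @export
r2_scaled <- function(observed, predicted, Bstar,
                      level = c("species", "summed"), plot = NULL,
                      eps = 1e-3, log_scale = TRUE) {
  level <- match.arg(level)
  if (any(!is.finite(Bstar)) || any(Bstar <= 0))
    stop("Bstar must be positive", call. = FALSE)
  if (level == "summed") {
    if (is.null(plot)) stop("'plot' required for summed level", call. = FALSE)
    y <- tapply(observed, plot, sum) / tapply(Bstar, plot, sum)
    yh <- tapply(predicted, plot, sum) / tapply(Bstar, plot, sum)
  } else {
    y <- observed / Bstar
    yh <- predicted / Bstar
  }
  if (log_scale) {
    y <- log(y + eps)
    yh <- log(yh + eps)
  }
  ok <- is.finite(y) & is.finite(yh)
  if (sum(ok) < 3L) stop("fewer than 3 valid points", call. = FALSE)
  y <- y[ok]; yh <- yh[ok]
  1 - sum((y - yh)^2) / sum((y - mean(y))^2)
}

#' Score a factorial scan against observations
#'
#' Joins scan predictions with an observed biomass table and computes the
#' B*-scaled error per (scenario, replicate, plot): species-level scaled
#' errors for the sown species, averaged (arithmetic mean) into a
#' community-level error per plot. B* for each (species, plot) comes from
#' the full (un-switched) trait table via the soil-N regression, as in
#' parameterisation.
#'
#' @param scan an \code{\link{run_factorial}} result (or its
#'   \code{results} data.frame).
#' @param observed data.frame with plot_id, species_id, biomass (e.g. from
#'   \code{\link{make_observations}}).
#' @param traits full trait table (for B*).
#' @param plots the \code{\link{plot_matrix}} (for soil N, sown masks,
#'   richness).
#' @return data.frame with one row per (scenario_code, replicate, plot_id):
#'   the 11 switch columns, \code{richness}, and \code{rmse} (community
#'   scaled error).
#' @export
evaluate_scan <- function(scan, observed, traits, plots) {
  res <- if (inherits(scan, "mmniche_scan")) scan$results else scan
  soil_N <- stats::setNames(plots$plots$soil_N, plots$plots$plot_id)
  Bstar <- modulate_by_soil_n(traits, soil_N)$Bstar
  key <- paste(res$plot_id, res$species_id)
  okey <- paste(observed$plot_id, observed$species_id)
  obs <- observed$biomass[match(key, okey)]
  bst <- Bstar[cbind(match(res$species_id, rownames(Bstar)),
                     match(res$plot_id, colnames(Bstar)))]
  sown <- plots$sown[cbind(match(res$plot_id, rownames(plots$sown)),
                           match(res$species_id, colnames(plots$sown)))]
  keep <- sown & !is.na(obs)
  err2 <- ((obs - res$biomass) / bst)^2
  df <- res[keep, c("scenario_code", "replicate", "plot_id",
                    switch_names())]
  df$err2 <- err2[keep]
  agg <- stats::aggregate(err2 ~ scenario_code + replicate + plot_id,
                          data = df, FUN = function(e) mean(sqrt(e)))
  names(agg)[names(agg) == "err2"] <- "rmse"
  sw <- df[!duplicated(paste(df$scenario_code, df$replicate, df$plot_id)),
           c("scenario_code", "replicate", "plot_id", switch_names())]
  out <- merge(agg, sw, by = c("scenario_code", "replicate", "plot_id"),
               sort = FALSE)
  rich <- plot_richness(plots)
  out$richness <- rich[match(out$plot_id, plots$plots$plot_id)]
  out
}

#' Attribute/mechanism inclusion frequencies in top-performing models
#'
#' For each plot and each model-complexity level (number of attributes on,
#' 1..11, or number of mechanisms on, 1..4 via
#' \code{\link{mechanism_status}}), selects the lowest-RMSE
#' \code{fraction} of runs and reports, per attribute (or mechanism), the
#' proportion of selected runs in which it is on. With \code{fraction = 1}
#' this returns the background frequencies of the stratum exactly.
#' Monocultures are excluded by default.
#'
#' @param eval data.frame from \code{\link{evaluate_scan}}.
#' @param fraction top fraction selected per stratum (default 0.05).
#' @param complexity_axis \code{"attributes"} or \code{"mechanisms"}.
#' @param attrs_required,mode mechanism-status rule (see
#'   \code{\link{mechanism_status}}).
#' @param include_monocultures include richness-1 plots (default FALSE).
#' @return list: \code{frequencies}, long data.frame (plot_id, complexity,
#'   item, freq, n_selected); \code{selected}, the selected runs with their
#'   switch settings (input to \code{\link{pair_cooccurrence}}).
#' @export
top_models <- function(eval, fraction = 0.05,
                       complexity_axis = c("attributes", "mechanisms"),
                       attrs_required = 2L, mode = "exactly",
                       include_monocultures = FALSE) {
  complexity_axis <- match.arg(complexity_axis)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (!include_monocultures && "richness" %in% names(eval))
    eval <- eval[eval$richness > 1L, , drop = FALSE]
  if (nrow(eval) == 0L) stop("no evaluation records", call. = FALSE)
  sw <- as.matrix(eval[, switch_names()])
  if (complexity_axis == "attributes") {
    complexity <- rowSums(sw)
    items <- sw
  } else {
    mech <- t(apply(sw, 1L, function(r)
      mechanism_status(stats::setNames(as.logical(r), switch_names()),
                       attrs_required, mode)))
    complexity <- rowSums(mech)
    items <- mech
  }
  strata <- split(seq_len(nrow(eval)),
                  list(plot = eval$plot_id, k = complexity), drop = TRUE)
  freq_rows <- list()
  sel_rows <- integer(0)
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    n_take <- ceiling(fraction * length(idx))
    take <- idx[order(eval$rmse[idx])][seq_len(n_take)]
    sel_rows <- c(sel_rows, take)
    freq_rows[[nm]] <- data.frame(
      plot_id = eval$plot_id[idx[1]],
      complexity = complexity[idx[1]],
      item = colnames(items),
      freq = colMeans(items[take, , drop = FALSE]),
      n_selected = n_take, row.names = NULL)
  }
  list(frequencies = do.call(rbind, c(freq_rows, make.row.names = FALSE)),
       selected = eval[sel_rows, , drop = FALSE])
}

#' Attribute co-occurrence counts in top model runs
#'
#' Counts, over the selected runs, how often each unordered attribute pair
#' is jointly on; the diagonal holds single-attribute on counts.
#'
#' @param top_sets data.frame of selected runs containing the 11 switch
#'   columns (e.g. \code{top_models(...)$selected}).
#' @return symmetric 11 x 11 integer matrix.
#' @export
pair_cooccurrence <- function(top_sets) {
  if (nrow(top_sets) == 0L) stop("empty top set", call. = FALSE)
  sw <- as.matrix(top_sets[, switch_names()]) * 1L
  m <- t(sw) %*% sw
  storage.mode(m) <- "integer"
  m
}

#' Per-attribute marginal error effects across plots
#'
#' For each attribute and plot, the mean community RMSE over runs with the
#' attribute off minus the mean over runs with it on: a positive effect
#' means switching the attribute on reduces error in that plot. These
#' effect vectors are the basis of the attribute-collinearity analysis.
#'
#' @param eval data.frame from \code{\link{evaluate_scan}}.
#' @return plots-by-attributes numeric matrix.
#' @export
attribute_effects <- function(eval) {
  plots <- sort(unique(eval$plot_id))
  out <- matrix(NA_real_, length(plots), 11L,
                dimnames = list(plots, switch_names()))
  for (p in seq_along(plots)) {
    sub <- eval[eval$plot_id == plots[p], , drop = FALSE]
    for (a in switch_names()) {
      on <- sub[[a]]
      if (any(on) && any(!on))
        out[p, a] <- mean(sub$rmse[!on]) - mean(sub$rmse[on])
    }
  }
  out
}

#' Mean absolute pairwise correlation among attribute effects
#'
#' Correlates the per-attribute effect vectors (across plots) for every
#' attribute pair and reports the mean |r| overall, within mechanisms and
#' between mechanisms. Attributes with constant (or undefined) effect
#' vectors are excluded with a warning.
#'
#' @param x either an \code{\link{evaluate_scan}} data.frame or a
#'   precomputed plots-by-attributes effect matrix
#'   (\code{\link{attribute_effects}}).
#' @return list with \code{overall}, \code{within}, \code{between} mean
#'   absolute correlations and the full correlation matrix \code{r}.
#' @export
attribute_correlations <- function(x) {
  eff <- if (is.matrix(x)) x else attribute_effects(x)
  sds <- apply(eff, 2L, stats::sd, na.rm = TRUE)
  keep <- is.finite(sds) & sds > 0
  if (!all(keep))
    warning("excluding constant/undefined attribute effect column(s): ",
            paste(colnames(eff)[!keep], collapse = ", "), call. = FALSE)
  eff <- eff[, keep, drop = FALSE]
  r <- stats::cor(eff, use = "pairwise.complete.obs")
  grp <- rep(names(.mechanism_groups),
             lengths(.mechanism_groups))[match(colnames(eff),
                                               unlist(.mechanism_groups))]
  same <- outer(grp, grp, "==")
  ut <- upper.tri(r)
  list(overall = mean(abs(r[ut]), na.rm = TRUE),
       within = mean(abs(r[ut & same]), na.rm = TRUE),
       between = mean(abs(r[ut & !same]), na.rm = TRUE),
       r = r)
}
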