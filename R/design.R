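# Plot matrix: geometry, block structure, soil N and sowing design of the
# patch array the metacommunity model runs on.

#' Construct and validate a plot matrix
#'
#' Container for the experimental design: per-plot geometry (centre
#' coordinates and side length of square plots, grouped into contiguous
#' blocks), total soil nitrogen, and the sowing design (which species were
#' sown in each plot, and with how much seed biomass). Weeding is encoded by
#' the sown mask: species never sown in a plot cannot colonise it.
#'
#' @param plots data.frame with columns \code{plot_id}, \code{block_id},
#'   \code{x}, \code{y} (plot-centre coordinates, m), \code{side} (m) and
#'   \code{soil_N} (total soil nitrogen, mg/kg).
#' @param sown logical matrix, plots x species (dimnames required), TRUE
#'   where the species was sown.
#' @param b_init numeric matrix, plots x species, sown seed biomass
#'   (g/m^2); must be zero wherever \code{sown} is FALSE.
#' @return list with elements \code{plots}, \code{sown}, \code{b_init},
#'   \code{species}, of class \code{"plot_matrix"}.
#' @export
plot_matrix <- function(plots, sown, b_init) {
  plots <- as.data.frame(plots, stringsAsFactors = FALSE)
  req <- c("plot_id", "block_id", "x", "y", "side", "soil_N")
  missing_cols <- setdiff(req, names(plots))
  if (length(missing_cols))
    stop("plot table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(plots$plot_id))
    stop("duplicated plot_id", call. = FALSE)
  sown <- as.matrix(sown)
  b_init <- as.matrix(b_init)
  if (is.null(colnames(sown)) || is.null(colnames(b_init)))
    stop("sown and b_init need species column names", call. = FALSE)
  if (!identical(dim(sown), dim(b_init)) || nrow(sown) != nrow(plots))
    stop("sown/b_init dimensions must be plots x species", call. = FALSE)
  if (any(!is.finite(plots$soil_N)) || any(plots$soil_N <= 0))
    stop("soil_N must be positive", call. = FALSE)
  if (any(plots$side <= 0)) stop("plot side must be positive", call. = FALSE)
  if (any(b_init < 0)) stop("b_init must be >= 0", call. = FALSE)
  if (any(b_init[!sown] != 0))
    stop("b_init must be zero where species not sown", call. = FALSE)
  rownames(sown) <- rownames(b_init) <- plots$plot_id
  out <- list(plots = plots, sown = sown, b_init = b_init,
              species = colnames(sown))
  class(out) <- "plot_matrix"
  out
}

#' @export
print.plot_matrix <- function(x, ...) {
  cat(sprintf("plot_matrix: %d plots in %d block(s), %d species\n",
              nrow(x$plots), length(unique(x$plots$block_id)),
              length(x$species)))
  cat(sprintf("  soil N %.0f-%.0f mg/kg; plot side %.2f m\n",
              min(x$plots$soil_N), max(x$plots$soil_N), x$plots$side[1]))
  invisible(x)
}

#' Sown species richness per plot
#' @param plots a \code{plot_matrix}.
#' @return integer vector, one entry per plot.
#' @export
plot_richness <- function(plots) rowSums(plots$sown)
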