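# Spatiotemporal niche differentiation: pairwise, possibly asymmetric
# overlap weights that discount interspecific competition. The convention
# throughout is that overlap[i, i'] weights the competitive impact OF
# species i' ON species i: the fraction of i's occupied space (or active
# season) that i' also occupies.

#' Belowground (rooting-zone) overlap
#'
#' Fraction of species i's rooting zone (0 to its maximum rooting depth)
#' shared with species i': min(rd_i, rd_i') / rd_i. A species rooting to
#' 50 cm is fully overlapped by one rooting to 100 cm (weight 1), while the
#' shallow rooter's impact on the deep rooter is halved (weight 0.5).
#'
#' @param rd_i focal species' maximum rooting depth, cm.
#' @param rd_other competitor's maximum rooting depth, cm.
#' @return overlap fraction in [0, 1].
#' @export
root_overlap <- function(rd_i, rd_other) {
  stop_if_not_positive(rd_i, "rd_i")
  stop_if_not_positive(rd_other, "rd_other")
  pmin(rd_i, rd_other) / rd_i
}

#' Aboveground (canopy) overlap
#'
#' Fraction of species i's aboveground space (0 to canopy height) shared
#' with species i': min(h_i, h_i') / h_i.
#'
#' @param h_i focal species' canopy height, m.
#' @param h_other competitor's canopy height, m.
#' @return overlap fraction in [0, 1].
#' @export
height_overlap <- function(h_i, h_other) {
  stop_if_not_positive(h_i, "h_i")
  stop_if_not_positive(h_other, "h_other")
  pmin(h_i, h_other) / h_i
}

#' Phenological overlap
#'
#' Fraction of species i's growing season (whole months, inclusive) during
#' which species i' is also active.
#'
#' @param start_i,end_i focal species' first and last active month (1-12).
#' @param start_other,end_other competitor's active months.
#' @return overlap fraction in [0, 1].
#' @export
pheno_overlap <- function(start_i, end_i, start_other, end_other) {
  if (any(start_i > end_i) || any(start_other > end_other))
    stop("invalid phenology range (start > end)", call. = FALSE)
  if (any(c(start_i, start_other) < 1) || any(c(end_i, end_other) > 12))
    stop("phenology months must be in 1..12", call. = FALSE)
  shared <- pmax(0, pmin(end_i, end_other) - pmax(start_i, start_other) + 1)
  shared / (end_i - start_i + 1)
}

#' Pairwise spatiotemporal overlap matrices
#'
#' Computes, for every ordered species pair, the root, height, spatial
#' (arithmetic mean of root and height), phenological and total overlap.
#' Total overlap is the product of spatial and phenological overlap:
#' competition requires co-occurrence in space and in time. Attribute
#' switches act upstream (via \code{\link{apply_switches}}) by replacing
#' the corresponding trait with the community mean, which drives that
#' component to 1 for every pair.
#'
#' @param traits a \code{\link{species_traits}} table (effective traits).
#' @return list of class \code{"overlap_matrix"} with square matrices
#'   \code{root}, \code{height}, \code{spatial}, \code{pheno},
#'   \code{total}; rows index the focal species i, columns the competitor
#'   i'. Diagonals are 1.
#' @export
total_overlap <- function(traits) {
  sp <- traits$species_id
  n <- length(sp)
  rd <- traits$rooting_depth_rd
  h <- traits$height_h
  ro <- outer(seq_len(n), seq_len(n),
              function(i, j) root_overlap(rd[i], rd[j]))
  ho <- outer(seq_len(n), seq_len(n),
              function(i, j) height_overlap(h[i], h[j]))
  po <- outer(seq_len(n), seq_len(n), function(i, j)
    pheno_overlap(traits$pheno_start[i], traits$pheno_end[i],
                  traits$pheno_start[j], traits$pheno_end[j]))
  sp_o <- (ro + ho) / 2
  tot <- sp_o * po
  dmn <- list(sp, sp)
  out <- list(root = ro, height = ho, spatial = sp_o, pheno = po,
              total = tot)
  out <- lapply(out, function(m) { dimnames(m) <- dmn; m })
  class(out) <- "overlap_matrix"
  out
}

#' @export
print.overlap_matrix <- function(x, digits = 3, ...) {
  cat("overlap_matrix (rows = focal species i, cols = competitor i')\n")
  cat("total overlap = spatial x phenological:\n")
  print(round(x$total, digits))
  invisible(x)
}
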