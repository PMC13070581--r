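# Attribute switches: the 11 booleans that factorially ablate the model.
# Switching an attribute off removes species-level differences in it
# (replacing trait values by the community mean) or disables a process
# (between-plot dispersal, the stochastic lottery, the R* competitive
# hierarchy).

.switch_names <- c("r_star", "b_star", "b_init", "fecundity", "dispersal",
                   "lottery", "root", "height", "phenology", "mortality",
                   "rgr")

.mechanism_groups <- list(
  resource_competition = c("r_star", "b_star"),
  dispersal_colonisation = c("b_init", "fecundity", "dispersal", "lottery"),
  niche_differentiation = c("root", "height", "phenology"),
  growth_rates = c("mortality", "rgr")
)

#' The 11 attribute switch names and their mechanism grouping
#' @return \code{switch_names()}: character vector of the 11 attribute
#'   names; \code{mechanism_groups()}: named list mapping the four
#'   mechanisms to their attributes.
#' @export
switch_names <- function() .switch_names

#' @rdname switch_names
#' @export
mechanism_groups <- function() .mechanism_groups

#' Construct an attribute switch configuration
#'
#' @param ... named logicals among the 11 switch names; unnamed defaults
#'   apply to the rest.
#' @param .default value for switches not named in \code{...}.
#' @return named logical vector of length 11 with class
#'   \code{"switch_config"}.
#' @examples
#' switch_config()                       # full model, everything on
#' switch_config(dispersal = FALSE)      # isolate plots from one another
#' switch_config(.default = FALSE)       # neutral limit
#' @export
switch_config <- function(..., .default = TRUE) {
  args <- list(...)
  if (length(args)) {
    if (is.null(names(args)) || any(names(args) == ""))
      stop("all switch arguments must be named", call. = FALSE)
    unknown <- setdiff(names(args), .switch_names)
    if (length(unknown))
      stop("unknown switch name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  cfg <- stats::setNames(rep(isTRUE(.default), 11L), .switch_names)
  for (nm in names(args)) cfg[nm] <- isTRUE(args[[nm]])
  class(cfg) <- "switch_config"
  cfg
}

as_switch_config <- function(x) {
  x <- unlist(x)[.switch_names]
  if (anyNA(x)) stop("incomplete switch configuration", call. = FALSE)
  cfg <- stats::setNames(as.logical(x), .switch_names)
  class(cfg) <- "switch_config"
  cfg
}

#' @export
print.switch_config <- function(x, ...) {
  on <- .switch_names[as.logical(x)]
  cat("switch_config:", sum(x), "of 11 attributes on\n")
  if (length(on)) cat("  on: ", paste(on, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Integer code of a switch configuration
#'
#' Bit-encodes the 11 switches (bit i set when attribute i is on, in the
#' order of \code{\link{switch_names}}), giving each of the 2048 scenarios a
#' stable identifier independent of batch composition.
#' @param config a \code{switch_config}.
#' @return integer in 0..2047.
#' @export
scenario_code <- function(config) {
  as.integer(sum(2L^(seq_along(.switch_names) - 1L) *
                   as.integer(config[.switch_names])))
}

#' Enumerate all on/off attribute combinations
#'
#' Full factorial over \code{n} attributes (the leading \code{n} names of
#' \code{\link{switch_names}}), in a deterministic order: scenario codes
#' 0, 1, ..., 2^n - 1, i.e. the all-off configuration first and the all-on
#' configuration last.
#'
#' @param n_attributes number of attributes to vary (default all 11).
#' @return data.frame with one row per scenario: \code{scenario_code} plus
#'   one logical column per attribute (remaining attributes, if any, are on).
#' @export
enumerate_scenarios <- function(n_attributes = 11L) {
  n_attributes <- as.integer(n_attributes)
  if (is.na(n_attributes) || n_attributes < 1L || n_attributes > 11L)
    stop("n_attributes must be in 1..11", call. = FALSE)
  vary <- .switch_names[seq_len(n_attributes)]
  codes <- seq_len(2L^n_attributes) - 1L
  cols <- lapply(seq_along(.switch_names), function(i) {
    nm <- .switch_names[i]
    if (nm %in% vary) bitwAnd(codes, 2L^(i - 1L)) > 0L
    else rep(TRUE, length(codes))
  })
  names(cols) <- .switch_names
  out <- as.data.frame(cols)
  out <- cbind(scenario_code = vapply(seq_len(nrow(out)), function(r)
    scenario_code(as_switch_config(out[r, ])), integer(1)), out)
  out
}

#' Mechanism on/off status of a configuration
#'
#' A mechanism counts as "on" when its attribute group has exactly (or at
#' least) \code{attrs_required} attributes switched on. The groups are
#' fixed: resource competition = \{r_star, b_star\}; dispersal and
#' colonisation = \{b_init, fecundity, dispersal, lottery\}; spatiotemporal
#' niche differentiation = \{root, height, phenology\}; population growth
#' rates = \{mortality, rgr\}. In "exactly" mode a requirement larger than a
#' group (e.g. 3 for a 2-attribute group) can never be met.
#'
#' @param config a \code{switch_config} (or coercible named logical).
#' @param attrs_required attributes needed per mechanism, in 1..4.
#' @param mode \code{"exactly"} or \code{"at_least"}.
#' @return named logical vector of length 4.
#' @export
mechanism_status <- function(config, attrs_required = 2L,
                             mode = c("exactly", "at_least")) {
  mode <- match.arg(mode)
  attrs_required <- as.integer(attrs_required)
  if (is.na(attrs_required) || attrs_required < 1L || attrs_required > 4L)
    stop("attrs_required must be in 1..4", call. = FALSE)
  cfg <- as_switch_config(config)
  n_on <- vapply(.mechanism_groups, function(g) sum(cfg[g]), numeric(1))
  if (mode == "exactly") n_on == attrs_required else n_on >= attrs_required
}

#' Apply attribute switches to traits and design
#'
#' Produces the effective trait table, effective plot matrix and behaviour
#' flags for one model scenario. For each switched-off trait-valued
#' attribute the relevant field(s) are replaced by the unweighted
#' across-species mean: \code{b_star} averages the B* regression
#' coefficients, \code{fecundity} the seed allocation fraction, \code{root}
#' the rooting depth, \code{height} the canopy height (seed-release height
#' is deliberately untouched, so dispersal is unchanged), \code{mortality}
#' the overwinter loss, \code{rgr} the RGR regression coefficients, and
#' \code{r_star} the R* value. \code{phenology} off gives every species the
#' community-wide window (earliest start to latest end), making all pairwise
#' temporal overlaps 1. \code{b_init} off replaces each plot's sown-species
#' seeding biomasses by their within-plot mean over the sown species only.
#' Three switches set behaviour flags consumed downstream without altering
#' values: \code{dispersal} off confines seeds to their natal plot,
#' \code{lottery} off makes establishment deterministic, and \code{r_star}
#' off makes competition symmetric (interspecific interaction strength equal
#' to intraspecific, every other species a competitor).
#'
#' The operation is idempotent: applying the same configuration twice equals
#' applying it once.
#'
#' @param traits a \code{\link{species_traits}} table.
#' @param plots a \code{\link{plot_matrix}}.
#' @param config a \code{\link{switch_config}}.
#' @return list with elements \code{traits}, \code{plots} and \code{flags}
#'   (logicals \code{dispersal_on}, \code{lottery_on}, \code{r_star_on}).
#' @export
apply_switches <- function(traits, plots, config = switch_config()) {
  if (nrow(traits) == 0L) stop("empty trait table", call. = FALSE)
  cfg <- as_switch_config(config)
  tr <- traits
  avg <- function(col) rep(mean(traits[[col]]), nrow(traits))
  if (!cfg[["r_star"]]) tr$R_star <- avg("R_star")
  if (!cfg[["b_star"]]) {
    tr$Bstar_intercept <- avg("Bstar_intercept")
    tr$Bstar_slope <- avg("Bstar_slope")
  }
  if (!cfg[["fecundity"]]) tr$fecundity_f <- avg("fecundity_f")
  if (!cfg[["root"]]) tr$rooting_depth_rd <- avg("rooting_depth_rd")
  if (!cfg[["height"]]) tr$height_h <- avg("height_h")
  if (!cfg[["phenology"]]) {
    tr$pheno_start <- rep(min(traits$pheno_start), nrow(traits))
    tr$pheno_end <- rep(max(traits$pheno_end), nrow(traits))
  }
  if (!cfg[["mortality"]]) tr$mortality_m <- avg("mortality_m")
  if (!cfg[["rgr"]]) {
    tr$RGR_intercept <- avg("RGR_intercept")
    tr$RGR_slope <- avg("RGR_slope")
  }
  pl <- plots
  if (!cfg[["b_init"]]) {
    bi <- plots$b_init
    sown <- plots$sown
    for (p in seq_len(nrow(bi))) {
      s <- sown[p, ]
      if (any(s)) bi[p, s] <- mean(plots$b_init[p, s])
    }
    pl$b_init <- bi
  }
  list(traits = tr, plots = pl,
       flags = list(dispersal_on = cfg[["dispersal"]],
                    lottery_on = cfg[["lottery"]],
                    r_star_on = cfg[["r_star"]]))
}
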