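# Descriptive and derived statistics of microneedle-created microchannels:
# area fractions, total channel area, depth fractions, penetration
# efficiency, spacing comparison and pore-uniformity (PPI) summaries.

#' Microchannel area fractions and totals
#'
#' Relates the mean pore area to the needle base area and to the skin
#' permeation area: the fraction of one needle's base that its channel
#' occupies, the total channel area of all channels, and that total as a
#' percentage of the permeation area.
#'
#' @param pores A [pore_set()] with an `area` column (sq.um).
#' @param base_side Needle base side (um), > 0.
#' @param permeation_area Skin permeation area A (sq.cm).
#' @param n_channels Number of channels created, >= 1. Defaults to the
#'   pore set's `n_expected` attribute.
#' @return A list with `mean_area` and `sd_area` (sq.um), `n_pores`,
#'   `fraction_of_base_area` (%), `total_channel_area_um2` (sq.um),
#'   `total_channel_area_cm2` (sq.cm) and `fraction_of_permeation_area` (%).
#' @examples
#' p <- pore_set("g", area = rep(9267.40, 10), n_expected = 100)
#' area_fractions(p, base_side = 164.03, permeation_area = 0.64,
#'                n_channels = 100)$fraction_of_permeation_area  # ~1.45
#' @export
area_fractions <- function(pores, base_side, permeation_area,
                           n_channels = attr(pores, "n_expected")) {
  stopifnot(inherits(pores, "pore_set"))
  if (is.null(pores$area)) stop("pore set has no area column", call. = FALSE)
  areas <- pores$area[!is.na(pores$area)]
  if (!length(areas)) stop("empty pore set", call. = FALSE)
  if (!is.numeric(base_side) || base_side <= 0) {
    stop("base side must be > 0", call. = FALSE)
  }
  if (is.null(n_channels) || n_channels < 1) {
    stop("n_channels must be >= 1", call. = FALSE)
  }
  mean_area <- mean(areas)
  total_um2 <- mean_area * n_channels
  list(group = attr(pores, "group"),
       mean_area = mean_area,
       sd_area = if (length(areas) > 1L) stats::sd(areas) else 0,
       n_pores = length(areas),
       n_channels = n_channels,
       fraction_of_base_area = 100 * mean_area / base_side^2,
       total_channel_area_um2 = total_um2,
       total_channel_area_cm2 = total_um2 / 1e8,
       fraction_of_permeation_area = 100 * total_um2 / (permeation_area * 1e8))
}

#' Penetration efficiency
#'
#' Percentage of the expected channels (needles on the array) actually
#' observed.
#'
#' @param observed Observed channel count.
#' @param expected Expected channel count, >= 1.
#' @return Penetration efficiency (%). Warns (does not fail) when more
#'   channels are observed than expected.
#' @export
penetration_efficiency <- function(observed, expected) {
  if (!is.numeric(expected) || expected < 1) {
    stop("expected channel count must be >= 1", call. = FALSE)
  }
  if (observed > expected) {
    warning("observed channel count (", observed,
            ") exceeds expected (", expected, ")")
  }
  100 * observed / expected
}

#' Channel depth as a fraction of needle length
#'
#' @param mean_depth Mean channel depth (um).
#' @param needle_length Needle length (um), > 0.
#' @return Depth fraction (%).
#' @export
depth_fraction <- function(mean_depth, needle_length) {
  if (!is.numeric(needle_length) || needle_length <= 0) {
    stop("needle length must be > 0", call. = FALSE)
  }
  100 * mean_depth / needle_length
}

#' Pore-uniformity summary of fluorescence intensity (PPI)
#'
#' Descriptive statistics of per-pore fluorescence intensity, with
#' zero-valued pores (channels with no measurable calcein flux) counted
#' separately but included in the mean and n.
#'
#' @param pores A [pore_set()] with an `intensity` column.
#' @return A list with `mean`, `sd`, `n` and `n_zero`.
#' @export
uniformity_summary <- function(pores) {
  stopifnot(inherits(pores, "pore_set"))
  if (is.null(pores$intensity)) {
    stop("pore set has no intensity column", call. = FALSE)
  }
  v <- pores$intensity[!is.na(pores$intensity)]
  if (!length(v)) stop("no intensity values present", call. = FALSE)
  list(group = attr(pores, "group"),
       mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v),
       n_zero = sum(v == 0))
}

#' Compare inter-pore spacing between two treatment groups
#'
#' Two-sample t-test on the spacing measurements (Student equal-variance by
#' default, matching [group_tests()]).
#'
#' @param pores_a,pores_b Two [pore_set()] objects with `spacing` columns.
#' @param var_equal Use the pooled-variance Student test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_spacing <- function(pores_a, pores_b, var_equal = TRUE) {
  get_spacing <- function(p) {
    stopifnot(inherits(p, "pore_set"))
    if (is.null(p$spacing)) stop("pore set has no spacing column", call. = FALSE)
    v <- p$spacing[!is.na(p$spacing)]
    if (length(v) < 2L) stop("need >= 2 spacing values per group", call. = FALSE)
    v
  }
  a <- get_spacing(pores_a)
  b <- get_spacing(pores_b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      # identical degenerate samples: no evidence of a difference
      return(structure(list(statistic = c(t = 0), p.value = 1,
                            estimate = c(mean_a = mean(a), mean_b = mean(b)),
                            method = "degenerate two-sample comparison"),
                       class = "htest"))
    }
    stop("zero variance in both groups", call. = FALSE)
  }
  stats::t.test(a, b, var.equal = var_equal)
}

#' Full geometry summary for one treatment group
#'
#' Combines per-metric descriptive statistics with the derived area and
#' depth fractions.
#'
#' @param pores A [pore_set()].
#' @param base_side Needle base side (um).
#' @param needle_length Needle length (um).
#' @param permeation_area Permeation area (sq.cm).
#' @param n_channels Channel count used for area totals; defaults to the
#'   number of observed (non-missing) area records' expected count.
#' @return A list combining [area_fractions()], [uniformity_summary()]
#'   (when intensity is present), depth statistics and
#'   [penetration_efficiency()] (when `n_expected` is known).
#' @export
geometry_summary <- function(pores, base_side, needle_length,
                             permeation_area,
                             n_channels = attr(pores, "n_expected")) {
  out <- area_fractions(pores, base_side, permeation_area, n_channels)
  if (!is.null(pores$depth)) {
    d <- pores$depth[!is.na(pores$depth)]
    if (length(d)) {
      out$mean_depth <- mean(d)
      out$sd_depth <- if (length(d) > 1L) stats::sd(d) else 0
      out$depth_fraction_of_length <- depth_fraction(mean(d), needle_length)
    }
  }
  if (!is.null(pores$intensity) && any(!is.na(pores$intensity))) {
    out$intensity <- uniformity_summary(pores)
  }
  n_exp <- attr(pores, "n_expected")
  if (!is.null(n_exp)) {
    observed <- nrow(pores)
    out$penetration_efficiency <- penetration_efficiency(min(observed, n_exp), n_exp)
  }
  out
}
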