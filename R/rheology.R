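# Derived quantities from oscillatory rheometry sweeps: linear viscoelastic
# (LVE) limit, flow point (G' = G'' crossover) and thixotropic recovery.

#' Linear viscoelastic (LVE) limit of an amplitude sweep
#'
#' The low-strain plateau of the storage modulus is estimated as the mean
#' G' of the first three points; the LVE limit is the largest strain up to
#' which G' stays within `tolerance` percent of that plateau (the first
#' point that deviates ends the region).
#'
#' @param sweep An amplitude [rheo_sweep()] with >= 5 points.
#' @param tolerance Allowed relative deviation from the plateau (%),
#'   default 5.
#' @return LVE limit strain (%).
#' @export
lve_limit <- function(sweep, tolerance = 5) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$kind != "amplitude") {
    stop("LVE limit requires an amplitude sweep", call. = FALSE)
  }
  if (length(sweep$x) < 5L) stop("need >= 5 points", call. = FALSE)
  plateau <- mean(sweep$g_prime[1:3])
  dev <- abs(sweep$g_prime - plateau) / plateau * 100
  beyond <- which(dev > tolerance)
  if (!length(beyond)) return(sweep$x[length(sweep$x)])
  sweep$x[max(1L, beyond[1L] - 1L)]
}

#' Flow point of an amplitude sweep
#'
#' Strain at which the storage and loss moduli cross (G' = G''), marking
#' the solid-to-fluid transition. The first crossing from G' > G'' to
#' G' <= G'' is located by linear interpolation in log-log coordinates,
#' appropriate for log-spaced sweeps.
#'
#' @param sweep An amplitude [rheo_sweep()] with G' > G'' at low strain and
#'   a crossing somewhere in range.
#' @return A list with `strain` (%) and `modulus` (Pa, the common modulus
#'   at the crossing).
#' @export
flow_point <- function(sweep) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$kind != "amplitude") {
    stop("flow point requires an amplitude sweep", call. = FALSE)
  }
  d <- log(sweep$g_prime) - log(sweep$g_double_prime)
  if (d[1L] <= 0) stop("G' does not exceed G'' at low strain", call. = FALSE)
  cross <- which(d[-length(d)] > 0 & d[-1L] <= 0)
  if (!length(cross)) stop("no flow point in range", call. = FALSE)
  i <- cross[1L]
  w <- d[i] / (d[i] - d[i + 1L])  # fraction of the way to the next point
  lx <- log(sweep$x[i]) + w * (log(sweep$x[i + 1L]) - log(sweep$x[i]))
  lg <- log(sweep$g_prime[i]) +
    w * (log(sweep$g_prime[i + 1L]) - log(sweep$g_prime[i]))
  list(strain = exp(lx), modulus = exp(lg))
}

#' Thixotropic recovery percentage
#'
#' Ratio of the storage modulus recovered after a high-shear interval to
#' its pre-shear plateau, from a three-interval oscillation-shear-
#' oscillation trace: 100 x mean G' over the final `post_window` seconds
#' divided by mean G' over the first `pre_window` seconds. Values above
#' 100% indicate post-shear stiffening and are reported as computed.
#'
#' @param sweep A thixotropy [rheo_sweep()] (x = time, s).
#' @param pre_window Length of the pre-shear averaging window from the
#'   start of the trace (s); default 100 (the full first interval of the
#'   standard protocol).
#' @param post_window Length of the averaging window at the end of the
#'   recovery interval (s); default 50.
#' @return Recovery (%). Scale-invariant in the moduli.
#' @export
thixotropic_recovery <- function(sweep, pre_window = 100, post_window = 50) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$kind != "thixotropy") {
    stop("recovery requires a thixotropy trace", call. = FALSE)
  }
  t <- sweep$x
  pre <- t <= t[1L] + pre_window
  post <- t >= t[length(t)] - post_window
  if (!any(pre) || !any(post)) {
    stop("averaging windows fall outside the trace", call. = FALSE)
  }
  if (max(t[pre]) >= min(t[post])) {
    stop("pre- and post-shear windows overlap; shorten the windows", call. = FALSE)
  }
  100 * mean(sweep$g_prime[post]) / mean(sweep$g_prime[pre])
}

#' Rheology report for a set of sweeps
#'
#' @param sweeps Named list of [rheo_sweep()] objects (as returned by
#'   [read_rheology_csv()]).
#' @param lve_tolerance Passed to [lve_limit()].
#' @param pre_window,post_window Passed to [thixotropic_recovery()].
#' @return A list with `lve_limit_strain`, `flow_point_strain`,
#'   `flow_point_modulus`, `recovery_percent` and `elastic_dominant` (per
#'   sweep, TRUE when G' > G'' everywhere); entries are `NULL` when the
#'   corresponding sweep kind is absent.
#' @export
rheology_report <- function(sweeps, lve_tolerance = 5,
                            pre_window = 100, post_window = 50) {
  kinds <- vapply(sweeps, function(s) s$kind, character(1L))
  out <- list(elastic_dominant = lapply(sweeps, function(s) {
    all(s$g_prime > s$g_double_prime)
  }))
  amp <- sweeps[kinds == "amplitude"]
  if (length(amp)) {
    a <- amp[[1L]]
    out$lve_limit_strain <- lve_limit(a, lve_tolerance)
    fp <- tryCatch(flow_point(a), error = function(e) NULL)
    if (!is.null(fp)) {
      out$flow_point_strain <- fp$strain
      out$flow_point_modulus <- fp$modulus
    }
  }
  thx <- sweeps[kinds == "thixotropy"]
  if (length(thx)) {
    out$recovery_percent <- thixotropic_recovery(thx[[1L]], pre_window,
                                                 post_window)
  }
  out
}
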