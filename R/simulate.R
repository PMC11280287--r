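# Synthetic-data generators with known ground truth: Fickian Franz-cell
# permeation series (with withdrawal/replacement dilution, optional donor
# depletion and multiplicative noise), pore sets and integrity records.

#' Ground truth of a simulated Franz-cell experiment
#'
#' @param D Membrane diffusion coefficient (sq.cm/h).
#' @param K Membrane/vehicle partition coefficient (dimensionless).
#' @param h Membrane thickness (cm).
#' @param C Donor concentration (ug/mL).
#' @param seed Integer seed controlling any noise draws.
#' @return An object of class `simulation_truth` carrying the inputs plus
#'   the implied `true_lag` = h^2/(6D) (h) and `true_flux` = K C D / h
#'   (ug/sq.cm/h).
#' @export
simulation_truth <- function(D, K, h, C, seed = 1L) {
  stopifnot(D > 0, K > 0, h > 0, C > 0)
  structure(list(D = D, K = K, h = h, C = C, seed = as.integer(seed),
                 true_lag = h^2 / (6 * D),
                 true_flux = K * C * D / h),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation ground truth\n")
  cat(sprintf("  D = %g sq.cm/h, K = %g, h = %g cm, C = %g ug/mL\n",
              x$D, x$K, x$h, x$C))
  cat(sprintf("  lag = %g h, steady flux = %g ug/sq.cm/h, seed = %d\n",
              x$true_lag, x$true_flux, x$seed))
  invisible(x)
}

#' Exact infinite-dose Fickian cumulative permeation
#'
#' Series solution for diffusion through a membrane of thickness h with a
#' constant donor concentration and a perfect-sink receptor:
#'
#' \deqn{Q(t) = K C h \left[\frac{Dt}{h^2} - \frac{1}{6}
#'   - \frac{2}{\pi^2}\sum_{n=1}^{\infty} \frac{(-1)^n}{n^2}
#'     e^{-D n^2 \pi^2 t / h^2}\right]}
#'
#' The sum is truncated once a term falls below `tol` relative to the
#' leading term, giving at least nine significant digits at typical IVPT
#' sampling times. As t grows, Q(t) approaches the straight line
#' `true_flux * (t - true_lag)`.
#'
#' @param times Times (h), >= 0. Vectorised.
#' @param truth A [simulation_truth()].
#' @param tol Relative truncation tolerance (default 1e-12).
#' @return Cumulative permeation per area (ug/sq.cm) at `times`.
#' @export
fickian_cumulative <- function(times, truth, tol = 1e-12) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (any(times < 0)) stop("negative times", call. = FALSE)
  D <- truth$D; h <- truth$h
  vapply(times, function(tt) {
    if (tt <= 0) return(0)
    lead <- D * tt / h^2 - 1 / 6
    s <- 0
    n <- 1L
    repeat {
      term <- ((-1)^n / n^2) * exp(-D * n^2 * pi^2 * tt / h^2)
      s <- s + term
      if (abs(term) < tol * max(abs(lead), .Machine$double.xmin)) break
      n <- n + 1L
      if (n > 1e6L) break
    }
    truth$K * truth$C * h * (lead - (2 / pi^2) * s)
  }, numeric(1L))
}

# receptor bookkeeping shared by both simulator modes: cumulative mass
# M(t_i) entering the receptor is turned into assayed concentrations under
# withdrawal/replacement. The assayed value is the pre-withdrawal
# concentration; then mass Vi*C is removed and the volume restored.
receptor_concentrations <- function(mass_in, V, Vi) {
  n <- length(mass_in)
  conc <- numeric(n)
  resident <- 0
  prev <- 0
  for (i in seq_len(n)) {
    resident <- resident + (mass_in[i] - prev)
    prev <- mass_in[i]
    ci <- resident / V
    conc[i] <- ci
    resident <- resident - Vi * ci
  }
  conc
}

#' Simulate a Franz-cell receptor time series
#'
#' Generates assayed receptor concentrations for one replicate, including
#' the withdrawal-and-replacement dilution that the cumulative-permeation
#' correction is designed to undo. Two transport modes:
#'
#' * `"infinite"`: the exact series solution of [fickian_cumulative()]
#'   (constant donor, perfect sink) drives the mass entering the receptor.
#' * `"finite_dose"`: the diffusion equation across the membrane is
#'   integrated with an explicit scheme, the donor compartment depleting
#'   from `cfg$donor_dose` dissolved in `cfg$donor_volume` (defaulting to
#'   dose/concentration) and the receptor accumulating (and being sampled)
#'   on the far side. The time step is stability-checked.
#'
#' Multiplicative lognormal noise with coefficient of variation `noise_cv`
#' (mean-one, so concentrations stay positive and unbiased) is applied to
#' the assayed concentrations.
#'
#' @param truth A [simulation_truth()].
#' @param cfg A [franz_config()].
#' @param times Sampling times (h), sorted, >= 0.
#' @param noise_cv Coefficient of variation of the assay noise (fraction,
#'   >= 0; default 0).
#' @param mode `"infinite"` (default) or `"finite_dose"`.
#' @param replicate Replicate label for the returned series.
#' @param seed Seed for the noise draws; defaults to `truth$seed`.
#' @param nx Number of interior membrane nodes for the finite-dose grid.
#' @param dt Time step (h) for the finite-dose scheme; chosen automatically
#'   at 40% of the stability limit when `NULL`. An explicit `dt` above the
#'   limit is an error naming the largest stable step.
#' @return A list with `series` (a [receptor_series()]), `truth`, and for
#'   the finite-dose mode `mass_balance`, a data.frame tracking donor,
#'   membrane, receptor and withdrawn mass at each sampling time.
#' @export
simulate_franz <- function(truth, cfg, times = c(0, 1, 2, 4, 6, 8, 22, 24),
                           noise_cv = 0,
                           mode = c("infinite", "finite_dose"),
                           replicate = "sim1", seed = truth$seed,
                           nx = 40L, dt = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  mode <- match.arg(mode)
  cfg <- validate_config(cfg)
  if (any(times < 0)) stop("negative times", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)

  mass_balance <- NULL
  if (mode == "infinite") {
    mass_in <- fickian_cumulative(times, truth) * cfg$permeation_area
  } else {
    fin <- finite_dose_mass(truth, cfg, times, nx = nx, dt = dt)
    mass_in <- fin$mass_in
    mass_balance <- fin$mass_balance
  }
  conc <- receptor_concentrations(mass_in, cfg$receptor_volume,
                                  cfg$sample_volume)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * stats::rlnorm(length(conc), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
  }
  list(series = receptor_series(replicate, times, conc),
       truth = truth,
       mass_balance = mass_balance)
}

# explicit finite-difference integration of membrane diffusion with a
# depleting, well-mixed donor and an accumulating, sampled receptor.
# Membrane concentration at the faces is partition-linked to the adjacent
# compartment: c(0) = K*C_donor, c(h) = K*C_receptor.
finite_dose_mass <- function(truth, cfg, times, nx = 40L, dt = NULL) {
  if (is.null(cfg$donor_dose)) {
    stop("finite-dose mode needs cfg$donor_dose", call. = FALSE)
  }
  D <- truth$D; h <- truth$h; K <- truth$K
  A <- cfg$permeation_area
  V <- cfg$receptor_volume
  Vi <- cfg$sample_volume
  Vd <- cfg$donor_volume %||% (cfg$donor_dose / truth$C)
  dx <- h / (nx + 1L)
  dt_max <- dx^2 / (2 * D)
  if (is.null(dt)) {
    dt <- 0.4 * dt_max
  } else if (dt > dt_max) {
    stop(sprintf(
      "finite-dose scheme unstable: dt = %.3g h exceeds the stability limit; use dt <= %.3g h",
      dt, dt_max), call. = FALSE)
  }
  cmem <- numeric(nx)            # interior node concentrations (ug/mL)
  Md <- cfg$donor_dose           # donor mass (ug)
  Mr <- 0                        # receptor resident mass (ug)
  withdrawn <- 0                 # mass removed by sampling (ug)
  mass_in <- numeric(length(times))
  entered <- 0                   # cumulative mass across the far face
  bal <- vector("list", length(times))
  tnow <- 0
  for (k in seq_along(times)) {
    tend <- times[k]
    while (tnow < tend - 1e-12) {
      step <- min(dt, tend - tnow)
      lam_s <- D * step / dx^2
      c0 <- K * Md / Vd          # donor-face membrane concentration
      ch <- K * Mr / V           # receptor-face membrane concentration
      full <- c(c0, cmem, ch)
      lap <- full[1:nx] - 2 * full[2:(nx + 1L)] + full[3:(nx + 2L)]
      cmem <- cmem + lam_s * lap
      # face fluxes (ug/sq.cm/h), one-sided differences
      j_in <- -D * (full[2L] - full[1L]) / dx
      j_out <- -D * (full[nx + 2L] - full[nx + 1L]) / dx
      Md <- Md - A * j_in * step
      Mr <- Mr + A * j_out * step
      entered <- entered + A * j_out * step
      tnow <- tnow + step
    }
    mass_in[k] <- entered
    Mmem <- A * dx * sum(cmem)   # trapezoid over interior nodes
    bal[[k]] <- data.frame(time_h = tend, donor = Md, membrane = Mmem,
                           receptor = Mr, withdrawn = withdrawn)
    # sampling: withdraw Vi at the resident concentration, replace buffer
    ci <- Mr / V
    withdrawn <- withdrawn + Vi * ci
    Mr <- Mr - Vi * ci
  }
  list(mass_in = mass_in, mass_balance = do.call(rbind, bal))
}

# truncated-normal draw (truncation at 0, resampling)
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= 0)
  }
  out
}

#' Simulate a per-pore measurement set
#'
#' Draws per-pore areas, depths, spacings and intensities from truncated
#' normal distributions (truncated at 0), with pores independently missing
#' at `miss_rate` and intensities zeroed with probability
#' `zero_intensity_prob` (channels with no measurable flux).
#'
#' @param group Group label.
#' @param n_expected Number of needles on the array.
#' @param area_mean,area_sd Pore area distribution (sq.um).
#' @param depth_mean,depth_sd Pore depth distribution (um); omitted when
#'   `NULL`.
#' @param spacing_mean,spacing_sd Spacing distribution (um); omitted when
#'   `NULL`.
#' @param intensity_mean,intensity_sd Intensity (PPI) distribution; omitted
#'   when `NULL`.
#' @param miss_rate Probability a pore is missing entirely (default 0).
#' @param zero_intensity_prob Probability an observed pore has zero
#'   intensity (default 0).
#' @param seed Integer seed.
#' @return A [pore_set()].
#' @export
simulate_pores <- function(group, n_expected,
                           area_mean, area_sd,
                           depth_mean = NULL, depth_sd = 0,
                           spacing_mean = NULL, spacing_sd = 0,
                           intensity_mean = NULL, intensity_sd = 0,
                           miss_rate = 0, zero_intensity_prob = 0,
                           seed = 1L) {
  if (miss_rate < 0 || miss_rate > 1) {
    stop("miss_rate must be in [0, 1]", call. = FALSE)
  }
  if (any(c(area_sd, depth_sd, spacing_sd, intensity_sd) < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (n_expected < 1) stop("n_expected must be >= 1", call. = FALSE)
  set.seed(seed)
  present <- stats::runif(n_expected) >= miss_rate
  n <- sum(present)
  if (n == 0L) stop("all pores missing; lower miss_rate", call. = FALSE)
  area <- rtruncnorm_pos(n, area_mean, area_sd)
  depth <- if (!is.null(depth_mean)) rtruncnorm_pos(n, depth_mean, depth_sd)
  spacing <- if (!is.null(spacing_mean)) rtruncnorm_pos(n, spacing_mean, spacing_sd)
  intensity <- NULL
  if (!is.null(intensity_mean)) {
    intensity <- rtruncnorm_pos(n, intensity_mean, intensity_sd)
    zero <- stats::runif(n) < zero_intensity_prob
    intensity[zero] <- 0
  }
  pore_set(group, area = area, depth = depth, spacing = spacing,
           intensity = intensity, n_expected = n_expected)
}

#' Simulate skin-integrity records
#'
#' Voltage drops are back-solved from the resistance relation so that
#' [skin_resistance()] reproduces the target exactly before noise:
#' `Vs = Vo Rs A / (RL + Rs A)`. TEWL values are normal draws.
#'
#' @param group Group label.
#' @param rs_target Target skin resistance (kOhm/sq.cm), >= 0.
#' @param tewl_mean,tewl_sd TEWL distribution (g/m^2/h).
#' @param cfg A [franz_config()].
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @return A data.frame with columns `group`, `replicate`, `vs_mv`,
#'   `tewl_g_m2h`.
#' @export
simulate_integrity <- function(group, rs_target, tewl_mean, tewl_sd,
                               cfg, n = 4L, seed = 1L) {
  cfg <- validate_config(cfg)
  if (rs_target < 0) stop("rs_target must be >= 0", call. = FALSE)
  set.seed(seed)
  vs <- invert_skin_resistance(rs_target, cfg)
  data.frame(group = group,
             replicate = paste0(group, "_", seq_len(n)),
             vs_mv = rep(vs, n),
             tewl_g_m2h = rtruncnorm_pos(n, tewl_mean, tewl_sd),
             stringsAsFactors = FALSE)
}

#' Voltage drop that yields a given skin resistance
#'
#' Inverse of [skin_resistance()]: `Vs = Vo Rs A / (RL + Rs A)`. Always
#' below Vo (the divider saturates), so any non-negative target is
#' attainable.
#'
#' @param rs Target resistance (kOhm/sq.cm), >= 0. Vectorised.
#' @param cfg A [franz_config()].
#' @return Voltage drop (mV).
#' @export
invert_skin_resistance <- function(rs, cfg) {
  cfg <- validate_config(cfg)
  if (any(rs < 0)) stop("resistance must be >= 0", call. = FALSE)
  ra <- rs * cfg$permeation_area
  cfg$fixed_voltage * ra / (cfg$load_resistance + ra)
}

#' Paper-style default simulation scenario
#'
#' The default Franz-cell configuration and sampling schedule used
#' throughout the package's examples and validation suite: 5 mL receptor,
#' 0.3 mL samples, 0.64 sq.cm permeation area, 1000 ug/mL donor (100 ug
#' dose in 0.1 mL), 0.031 cm skin thickness, 118 mL/h clearance, sampling
#' at 0, 1, 2, 4, 6, 8, 22 and 24 h.
#'
#' @return A list with `cfg` (a [franz_config()]) and `times`.
#' @export
default_scenario <- function() {
  list(cfg = franz_config(receptor_volume = 5, sample_volume = 0.3,
                          permeation_area = 0.64,
                          donor_concentration = 1000, donor_dose = 100,
                          donor_volume = 0.1, skin_thickness = 0.031,
                          clearance = 118),
       times = c(0, 1, 2, 4, 6, 8, 22, 24))
}
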