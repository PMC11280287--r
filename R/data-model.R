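# Domain objects and CSV/YAML readers shared by every analysis stage.
#
# Unit conventions are fixed at this boundary and never converted downstream:
# time in hours, volumes in mL, amounts in ug, lengths in cm (skin) or um
# (pores), areas in sq.cm (cell) or sq.um (pores), voltages in mV,
# resistance in kOhm, clearance in mL/h, TEWL in g/m^2/h, moduli in Pa.

#' Franz diffusion cell configuration
#'
#' Physical constants of one diffusion-cell experiment. Defaults for the
#' skin-resistance circuit follow the standard measurement setup: a fixed
#' 100 mV source across the tissue in series with a 100 kOhm load resistor.
#'
#' @param receptor_volume Receptor chamber volume V (mL).
#' @param sample_volume Withdrawn sample volume Vi (mL); replaced with fresh
#'   buffer at each sampling time. Must be smaller than `receptor_volume`.
#' @param permeation_area Effective permeation area A (sq.cm).
#' @param donor_concentration Drug concentration in the donor vehicle C
#'   (ug/mL). Needed for the permeability coefficient.
#' @param donor_dose Total drug amount applied in the donor chamber (ug).
#' @param donor_volume Applied donor volume (mL), optional. When given
#'   together with `donor_concentration` and `donor_dose`, consistency
#'   `donor_dose = donor_concentration * donor_volume` is checked to 1%.
#' @param skin_thickness Membrane (skin) thickness h (cm).
#' @param clearance Systemic clearance Cl (mL/h) used for the steady-state
#'   plasma concentration extrapolation.
#' @param fixed_voltage Source voltage Vo of the resistance circuit (mV).
#' @param load_resistance Load resistance RL of the circuit (kOhm).
#'
#' @return An object of class `franz_config` (a named list).
#' @examples
#' cfg <- franz_config(receptor_volume = 5, sample_volume = 0.3,
#'                     permeation_area = 0.64, donor_concentration = 1000,
#'                     donor_dose = 100, skin_thickness = 0.031,
#'                     clearance = 118)
#' cfg$fixed_voltage  # 100 mV default
#' @export
franz_config <- function(receptor_volume,
                         sample_volume,
                         permeation_area,
                         donor_concentration = NULL,
                         donor_dose = NULL,
                         donor_volume = NULL,
                         skin_thickness,
                         clearance = NULL,
                         fixed_voltage = 100,
                         load_resistance = 100) {
  cfg <- structure(
    list(receptor_volume = receptor_volume,
         sample_volume = sample_volume,
         permeation_area = permeation_area,
         donor_concentration = donor_concentration,
         donor_dose = donor_dose,
         donor_volume = donor_volume,
         skin_thickness = skin_thickness,
         clearance = clearance,
         fixed_voltage = fixed_voltage,
         load_resistance = load_resistance),
    class = "franz_config")
  validate_config(cfg)
}

#' Validate a Franz-cell configuration
#'
#' Applies circuit defaults (Vo = 100 mV, RL = 100 kOhm) when missing and
#' checks all invariants: strictly positive fields, sample volume smaller
#' than receptor volume, and (when all three are present) consistency of
#' donor dose with concentration times applied volume to 1%.
#'
#' @param cfg A `franz_config` or a plain named list with the same fields.
#' @return The validated `franz_config`.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list", call. = FALSE)
  if (is.null(cfg$fixed_voltage)) cfg$fixed_voltage <- 100
  if (is.null(cfg$load_resistance)) cfg$load_resistance <- 100
  required <- c("receptor_volume", "sample_volume", "permeation_area",
                "skin_thickness")
  for (f in required) {
    if (is.null(cfg[[f]])) stop("config field '", f, "' is missing", call. = FALSE)
  }
  numeric_fields <- c(required, "donor_concentration", "donor_dose",
                      "donor_volume", "clearance", "fixed_voltage",
                      "load_resistance")
  for (f in numeric_fields) {
    v <- cfg[[f]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field '", f, "' must be a single finite number", call. = FALSE)
    }
    if (v <= 0) stop("config field '", f, "' must be strictly positive", call. = FALSE)
  }
  if (cfg$sample_volume >= cfg$receptor_volume) {
    stop("sample volume exceeds receptor volume", call. = FALSE)
  }
  if (!is.null(cfg$donor_dose) && !is.null(cfg$donor_concentration) &&
      !is.null(cfg$donor_volume)) {
    expected <- cfg$donor_concentration * cfg$donor_volume
    if (abs(cfg$donor_dose - expected) > 0.01 * expected) {
      stop("donor_dose (", cfg$donor_dose, " ug) inconsistent with ",
           "donor_concentration * donor_volume (", expected, " ug)",
           call. = FALSE)
    }
  }
  class(cfg) <- "franz_config"
  cfg
}

#' @export
print.franz_config <- function(x, ...) {
  cat("Franz diffusion cell configuration\n")
  cat(sprintf("  receptor volume     : %g mL\n", x$receptor_volume))
  cat(sprintf("  sample volume       : %g mL\n", x$sample_volume))
  cat(sprintf("  permeation area     : %g sq.cm\n", x$permeation_area))
  if (!is.null(x$donor_concentration))
    cat(sprintf("  donor concentration : %g ug/mL\n", x$donor_concentration))
  if (!is.null(x$donor_dose))
    cat(sprintf("  donor dose          : %g ug\n", x$donor_dose))
  cat(sprintf("  skin thickness      : %g cm\n", x$skin_thickness))
  if (!is.null(x$clearance))
    cat(sprintf("  clearance           : %g mL/h\n", x$clearance))
  cat(sprintf("  circuit             : Vo = %g mV, RL = %g kOhm\n",
              x$fixed_voltage, x$load_resistance))
  invisible(x)
}

#' Read a Franz-cell configuration from YAML or JSON
#'
#' Keys must match the `franz_config()` argument names.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `franz_config`.
#' @export
read_franz_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)", call. = FALSE)
  }
  validate_config(raw)
}

#' Receptor concentration time series for one replicate
#'
#' @param replicate Replicate label.
#' @param times Sampling times (h), strictly increasing, all >= 0. The 0 h
#'   sample (assayed or assumed zero) is permitted and carried.
#' @param concentrations Assayed receptor concentrations (ug/mL), same
#'   length as `times`, all >= 0.
#' @return An object of class `receptor_series`.
#' @export
receptor_series <- function(replicate, times, concentrations) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations)) {
    stop("times and concentrations must have the same length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty receptor series", call. = FALSE)
  if (anyNA(times) || anyNA(concentrations)) {
    stop("receptor series contains missing values", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing (replicate '", replicate, "')",
         call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0 (replicate '", replicate, "')",
         call. = FALSE)
  }
  structure(list(replicate = as.character(replicate),
                 times = times,
                 concentrations = concentrations),
            class = "receptor_series")
}

#' @export
print.receptor_series <- function(x, ...) {
  cat(sprintf("Receptor series '%s': %d samples over %g-%g h\n",
              x$replicate, length(x$times), min(x$times), max(x$times)))
  print(data.frame(time_h = x$times, conc_ug_per_ml = x$concentrations),
        row.names = FALSE)
  invisible(x)
}

# internal: read a CSV, insisting on named columns and numeric content
read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column '", missing[1L], "' in ", basename(path), call. = FALSE)
  }
  for (col in numeric_cols) {
    raw <- df[[col]]
    blank <- is.na(raw) | !nzchar(trimws(raw))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !blank)
    if (length(bad)) {
      stop("non-numeric value '", raw[bad[1L]], "' in column '", col,
           "', row ", bad[1L], " of ", basename(path), call. = FALSE)
    }
    df[[col]] <- val
  }
  df
}

#' Read receptor-chamber concentration series from CSV
#'
#' Expects columns `replicate`, `time_h`, `conc_ug_per_ml`. Rows are sorted
#' by time within each replicate; duplicate (replicate, time) rows are
#' rejected.
#'
#' @param path CSV file path.
#' @return A named list of [receptor_series()] objects, one per replicate.
#' @export
read_receptor_csv <- function(path) {
  df <- read_checked_csv(path,
                         required = c("replicate", "time_h", "conc_ug_per_ml"),
                         numeric_cols = c("time_h", "conc_ug_per_ml"))
  if (nrow(df) == 0L) stop("no data rows in ", basename(path), call. = FALSE)
  out <- lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    if (anyDuplicated(d$time_h)) {
      stop("duplicate sampling time ", d$time_h[duplicated(d$time_h)][1L],
           " h for replicate '", d$replicate[1L], "'", call. = FALSE)
    }
    receptor_series(d$replicate[1L], d$time_h, d$conc_ug_per_ml)
  })
  out[order(names(out))]
}

#' Write receptor series to CSV
#'
#' Inverse of [read_receptor_csv()]; values are written at full double
#' precision so that a read/write round trip is lossless.
#'
#' @param series A `receptor_series` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_receptor_csv <- function(series, path) {
  if (inherits(series, "receptor_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(replicate = s$replicate,
               time_h = sprintf("%.17g", s$times),
               conc_ug_per_ml = sprintf("%.17g", s$concentrations),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-pore microchannel measurements for one treatment group
#'
#' @param group Treatment group label.
#' @param area Pore areas (sq.um), optional, > 0 where present.
#' @param depth Pore depths (um), optional, > 0 where present.
#' @param spacing Inter-pore spacing (um), optional, > 0 where present.
#' @param intensity Per-pore fluorescence intensity (Pore Permeability
#'   Index, arbitrary units), optional, >= 0. Zero values are meaningful:
#'   they mark channels with no measurable calcein flux.
#' @param n_expected Number of needles on the array (expected channel
#'   count). The number of measured pores may be smaller (missed pores).
#' @return An object of class `pore_set`: a data.frame of the per-pore
#'   records with attributes `group` and `n_expected`.
#' @export
pore_set <- function(group, area = NULL, depth = NULL, spacing = NULL,
                     intensity = NULL, n_expected = NULL) {
  cols <- list(area = area, depth = depth, spacing = spacing,
               intensity = intensity)
  cols <- cols[!vapply(cols, is.null, logical(1L))]
  if (!length(cols)) stop("pore set needs at least one measurement column", call. = FALSE)
  n <- max(vapply(cols, length, integer(1L)))
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (length(v) != n) stop("pore measurement lengths differ", call. = FALSE)
    ok <- !is.na(v)
    if (nm == "intensity") {
      if (any(v[ok] < 0)) stop("intensity must be >= 0", call. = FALSE)
    } else if (any(v[ok] <= 0)) {
      stop(nm, " must be > 0 where present", call. = FALSE)
    }
  }
  df <- as.data.frame(lapply(cols, as.numeric))
  if (!is.null(n_expected)) {
    if (n_expected < 1) stop("n_expected must be >= 1", call. = FALSE)
    if (nrow(df) > n_expected) {
      warning("more measured pores (", nrow(df), ") than expected channels (",
              n_expected, ")")
    }
  }
  structure(df, group = as.character(group), n_expected = n_expected,
            class = c("pore_set", "data.frame"))
}

#' Read per-pore measurements from CSV
#'
#' Expects columns `group`, `pore_id`, `area_um2`, `depth_um`, `spacing_um`,
#' `intensity`; measurement cells may be blank (missing pores are excluded
#' listwise per metric downstream).
#'
#' @param path CSV file path.
#' @param n_expected Optional named vector of expected channel counts per
#'   group.
#' @return A named list of [pore_set()] objects, one per group.
#' @export
read_pores_csv <- function(path, n_expected = NULL) {
  df <- read_checked_csv(path,
                         required = c("group", "pore_id", "area_um2",
                                      "depth_um", "spacing_um", "intensity"),
                         numeric_cols = c("area_um2", "depth_um",
                                          "spacing_um", "intensity"))
  out <- lapply(split(df, df$group), function(d) {
    g <- d$group[1L]
    pore_set(g, area = d$area_um2, depth = d$depth_um,
             spacing = d$spacing_um, intensity = d$intensity,
             n_expected = if (!is.null(n_expected)) n_expected[[g]] else NULL)
  })
  out[order(names(out))]
}

#' Read skin-integrity measurements from CSV
#'
#' Expects columns `group`, `replicate`, `vs_mv` (voltage drop across the
#' tissue, mV) and `tewl_g_m2h` (transepidermal water loss).
#'
#' @param path CSV file path.
#' @return A data.frame with those columns.
#' @export
read_integrity_csv <- function(path) {
  df <- read_checked_csv(path,
                         required = c("group", "replicate", "vs_mv",
                                      "tewl_g_m2h"),
                         numeric_cols = c("vs_mv", "tewl_g_m2h"))
  if (any(df$vs_mv < 0, na.rm = TRUE)) stop("vs_mv must be >= 0", call. = FALSE)
  if (any(df$tewl_g_m2h <= 0, na.rm = TRUE)) stop("tewl_g_m2h must be > 0", call. = FALSE)
  df
}

#' Read skin-disposition amounts from CSV
#'
#' Expects columns `group`, `replicate`, `epidermis_ug_cm2`,
#' `dermis_ug_cm2`, `q24_ug_cm2` (all ug/sq.cm, >= 0).
#'
#' @param path CSV file path.
#' @return A data.frame with those columns.
#' @export
read_disposition_csv <- function(path) {
  df <- read_checked_csv(path,
                         required = c("group", "replicate", "epidermis_ug_cm2",
                                      "dermis_ug_cm2", "q24_ug_cm2"),
                         numeric_cols = c("epidermis_ug_cm2", "dermis_ug_cm2",
                                          "q24_ug_cm2"))
  num <- c("epidermis_ug_cm2", "dermis_ug_cm2", "q24_ug_cm2")
  if (any(as.matrix(df[num]) < 0, na.rm = TRUE)) {
    stop("disposition amounts must be >= 0", call. = FALSE)
  }
  df
}

#' Oscillatory rheology sweep
#'
#' @param kind One of `"amplitude"` (x = strain %), `"frequency"` (x =
#'   angular frequency, rad/s) or `"thixotropy"` (x = time, s).
#' @param x Strictly increasing abscissa.
#' @param g_prime Storage modulus G' (Pa), > 0.
#' @param g_double_prime Loss modulus G'' (Pa), > 0.
#' @return An object of class `rheo_sweep`.
#' @export
rheo_sweep <- function(kind = c("amplitude", "frequency", "thixotropy"),
                       x, g_prime, g_double_prime) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  g_prime <- as.numeric(g_prime)
  g_double_prime <- as.numeric(g_double_prime)
  if (length(x) != length(g_prime) || length(x) != length(g_double_prime)) {
    stop("x, g_prime and g_double_prime must have the same length", call. = FALSE)
  }
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (any(g_prime <= 0) || any(g_double_prime <= 0)) {
    stop("moduli must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, x = x, g_prime = g_prime,
                 g_double_prime = g_double_prime),
            class = "rheo_sweep")
}

#' Read rheology sweeps from CSV
#'
#' Expects columns `kind`, `x`, `g_prime_pa`, `g_double_prime_pa`; one sweep
#' per `kind` value.
#'
#' @param path CSV file path.
#' @return A named list of [rheo_sweep()] objects.
#' @export
read_rheology_csv <- function(path) {
  df <- read_checked_csv(path,
                         required = c("kind", "x", "g_prime_pa",
                                      "g_double_prime_pa"),
                         numeric_cols = c("x", "g_prime_pa",
                                          "g_double_prime_pa"))
  out <- lapply(split(df, df$kind), function(d) {
    d <- d[order(d$x), , drop = FALSE]
    rheo_sweep(d$kind[1L], d$x, d$g_prime_pa, d$g_double_prime_pa)
  })
  out[order(names(out))]
}
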