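# Orchestration of the full analysis: reads a bundle description, runs
# every stage whose inputs are present, and writes the report files.

read_bundle <- function(bundle) {
  if (is.character(bundle)) {
    if (!file.exists(bundle)) stop("bundle file not found: ", bundle, call. = FALSE)
    base <- dirname(normalizePath(bundle))
    b <- yaml::read_yaml(bundle)
    # resolve file paths relative to the bundle location
    for (f in c("receptor", "pores", "integrity", "disposition", "rheology",
                "config", "group_map")) {
      if (!is.null(b[[f]]) && !file.exists(b[[f]])) {
        cand <- file.path(base, b[[f]])
        if (file.exists(cand)) b[[f]] <- cand
      }
    }
    b
  } else if (is.list(bundle)) {
    bundle
  } else {
    stop("bundle must be a YAML path or a list", call. = FALSE)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full IVPT analysis
#'
#' Composes all stages into one reproducible run. The bundle (a YAML file
#' or an equivalent list) names the input files and study metadata:
#'
#' * `config`: Franz-cell configuration (YAML/JSON), required.
#' * `receptor`: receptor concentration CSV, plus `group_map` (CSV with
#'   columns `replicate`, `group`) when replicates belong to several
#'   groups.
#' * `pores`, `integrity`, `disposition`, `rheology`: optional stage input
#'   CSVs.
#' * `needle`: list with `length_um`, `base_side_um`, `n_needles`.
#' * `dense_extrapolate`: logical; scale flux and Css to a densely packed
#'   1 sq.cm area using the observed mean pore area (requires `pores`).
#' * `css_target_ug_l`: target plasma concentration for array sizing.
#' * `r2_threshold`, `min_points`: segment-fit settings.
#'
#' Outputs written to `out_dir`: `table2.csv` (per-group permeation
#' parameters, mean and SD), `per_replicate.json`, `geometry.json`,
#' `integrity_report.json`, `disposition.csv`, `rheo.json` and
#' `manifest.json` (input digests, configuration snapshot, package
#' version). Stages without inputs are skipped; a failing stage aborts the
#' run, names itself in the error, and leaves no partial outputs behind.
#'
#' @param bundle Path to a bundle YAML or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_ivpt_analysis <- function(bundle, out_dir) {
  b <- read_bundle(bundle)
  if (is.null(b$config)) stop("bundle must name a config file", call. = FALSE)
  cfg <- stage("config", if (is.character(b$config)) {
    read_franz_config(b$config)
  } else {
    validate_config(b$config)
  })

  if (isTRUE(b$dense_extrapolate) && is.null(b$pores)) {
    stop("dense extrapolation requested but no pores file in bundle", call. = FALSE)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(fname, writer) {
    path <- file.path(out_dir, fname)
    writer(path)
    written <<- c(written, path)
    path
  }
  on_fail_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }

  results <- list(config = cfg)
  tryCatch({
    # --- microchannel geometry -------------------------------------------
    pores <- NULL
    if (!is.null(b$pores)) {
      pores <- stage("geometry", read_pores_csv(
        b$pores,
        n_expected = if (!is.null(b$needle$n_needles)) {
          g <- names(read_pores_groups(b$pores))
          stats::setNames(rep(b$needle$n_needles, length(g)), g)
        }))
      geo <- stage("geometry", lapply(pores, function(p) {
        geometry_summary(p,
                         base_side = b$needle$base_side_um %||% stop("needle base_side_um missing"),
                         needle_length = b$needle$length_um %||% stop("needle length_um missing"),
                         permeation_area = cfg$permeation_area,
                         n_channels = attr(p, "n_expected") %||% nrow(p))
      }))
      results$geometry <- geo
      emit("geometry.json", function(p) {
        jsonlite::write_json(geo, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      })
    }

    # --- permeation -------------------------------------------------------
    if (!is.null(b$receptor)) {
      series <- stage("permeation", read_receptor_csv(b$receptor))
      gm <- if (!is.null(b$group_map)) {
        m <- utils::read.csv(b$group_map, stringsAsFactors = FALSE)
        stats::setNames(m$group, m$replicate)
      } else {
        stats::setNames(rep("all", length(series)), names(series))
      }
      summaries <- stage("permeation", {
        lapply(split(names(series), gm[names(series)]), function(reps) {
          profs <- lapply(series[reps], cumulative_permeation, cfg = cfg)
          grp <- gm[[reps[1L]]]
          nd <- na <- NULL
          if (isTRUE(b$dense_extrapolate)) {
            ps <- pores[[grp]] %||% pores[[1L]]
            nd <- dense_channel_count(mean(ps$area, na.rm = TRUE))
            na <- round_half_up(attr(ps, "n_expected") %||% nrow(ps))
          }
          summarize_group(grp, profs, cfg,
                          n_dense = nd, n_actual = na,
                          r2_threshold = b$r2_threshold %||% 0.95,
                          min_points = b$min_points %||% 3)
        })
      })
      results$permeation <- summaries
      tab <- do.call(rbind, lapply(summaries, function(s) {
        data.frame(group = s$group,
                   n = nrow(s$replicates),
                   q24_mean = s$mean$q24, q24_sd = s$sd$q24,
                   t_lag_mean = s$mean$t_lag, t_lag_sd = s$sd$t_lag,
                   j_mean = s$mean$j_area, j_sd = s$sd$j_area,
                   d_mean = s$mean$d, d_sd = s$sd$d,
                   kp_mean = s$mean$kp, kp_sd = s$sd$kp,
                   css_mean = s$mean$css, css_sd = s$sd$css,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(b$css_target_ug_l) && !is.null(cfg$clearance)) {
        tab$required_area_cm2 <- vapply(summaries, function(s) {
          jd <- s$mean$j_dense
          j <- if (!is.na(jd)) jd else s$mean$j_area
          if (is.na(j) || j <= 0) NA_real_ else {
            required_array_area(b$css_target_ug_l, cfg$clearance, j)
          }
        }, numeric(1L))
      }
      rownames(tab) <- NULL
      emit("table2.csv", function(p) utils::write.csv(tab, p, row.names = FALSE))
      emit("per_replicate.json", function(p) {
        jsonlite::write_json(lapply(summaries, function(s) s$replicates),
                             p, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                             pretty = TRUE)
      })
    }

    # --- skin integrity ---------------------------------------------------
    if (!is.null(b$integrity)) {
      integ <- stage("integrity", {
        summarize_integrity(read_integrity_csv(b$integrity), cfg)
      })
      results$integrity <- integ
      emit("integrity_report.json", function(p) {
        out <- list(per_group = integ$per_group,
                    tewl_anova = integ$tewl_tests$anova,
                    tewl_tukey = integ$tewl_tests$tukey,
                    resistance_anova = integ$resistance_tests$anova,
                    resistance_tukey = integ$resistance_tests$tukey)
        jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", pretty = TRUE)
      })
    }

    # --- disposition ------------------------------------------------------
    if (!is.null(b$disposition)) {
      disp <- stage("disposition", {
        summarize_disposition(read_disposition_csv(b$disposition), cfg,
                              convention = b$efficiency_convention %||% "paper")
      })
      results$disposition <- disp
      emit("disposition.csv", function(p) {
        utils::write.csv(disp$per_group, p, row.names = FALSE)
      })
    }

    # --- rheology ---------------------------------------------------------
    if (!is.null(b$rheology)) {
      rheo <- stage("rheology", rheology_report(read_rheology_csv(b$rheology)))
      results$rheology <- rheo
      emit("rheo.json", function(p) {
        jsonlite::write_json(rheo, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      })
    }

    # --- manifest ---------------------------------------------------------
    inputs <- Filter(is.character, b[c("receptor", "pores", "integrity",
                                       "disposition", "rheology", "config",
                                       "group_map")])
    manifest <- list(
      package = "ivptr",
      version = as.character(utils::packageVersion("ivptr")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      config = unclass(cfg),
      inputs = lapply(inputs, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      }),
      settings = b[intersect(names(b), c("r2_threshold", "min_points",
                                         "dense_extrapolate",
                                         "css_target_ug_l",
                                         "efficiency_convention", "needle"))])
    emit("manifest.json", function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  }, error = on_fail_cleanup)

  invisible(results)
}

# group labels present in a pores CSV without building full pore sets
read_pores_groups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df, df$group)
}
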