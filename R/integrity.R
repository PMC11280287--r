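# Skin-integrity metrics: electrical resistance from the voltage-divider
# measurement, and the group-comparison statistics used across the pipeline
# (Student t, one-way ANOVA with Tukey HSD).

#' Skin electrical resistance from the voltage-divider measurement
#'
#' The skin sits in series with a load resistor RL under a fixed source
#' voltage Vo; the voltage drop Vs measured across the tissue gives
#'
#' \deqn{R_s = \frac{V_s R_L}{A (V_o - V_s)}}
#'
#' normalised by the permeation area A. Rs grows without bound as Vs
#' approaches Vo (intact, highly resistive skin) and is 0 at Vs = 0.
#'
#' @param vs Voltage drop across the tissue (mV); `0 <= vs < Vo`.
#'   Vectorised.
#' @param cfg A [franz_config()] supplying `permeation_area`,
#'   `fixed_voltage` (Vo) and `load_resistance` (RL).
#' @return Skin resistance (kOhm/sq.cm).
#' @examples
#' cfg <- franz_config(5, 0.3, 0.64, skin_thickness = 0.031)
#' skin_resistance(50, cfg)  # 156.25
#' @export
skin_resistance <- function(vs, cfg) {
  cfg <- validate_config(cfg)
  if (any(vs < 0)) stop("voltage drop must be >= 0", call. = FALSE)
  if (any(vs >= cfg$fixed_voltage)) {
    stop("voltage drop exceeds source", call. = FALSE)
  }
  vs * cfg$load_resistance /
    (cfg$permeation_area * (cfg$fixed_voltage - vs))
}

#' Group-comparison statistics
#'
#' One-way ANOVA with Tukey HSD adjusted pairwise comparisons, plus
#' unadjusted two-sided pairwise t-tests (Student equal-variance by
#' default). This is the single statistics contract every stage of the
#' pipeline delegates to.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values`; >= 2 groups with
#'   >= 2 values each.
#' @param alpha Significance threshold (default 0.05), two-sided.
#' @param var_equal Pairwise t-tests use the pooled-variance Student test
#'   when `TRUE` (default); `FALSE` gives Welch.
#' @return A list of class `group_tests` with `anova` (F statistic, df,
#'   p-value), `tukey` (data.frame of pairwise contrasts with adjusted
#'   p-values and significance flags at `alpha`) and `t_tests` (data.frame
#'   of unadjusted pairwise t-tests).
#' @export
group_tests <- function(values, groups, alpha = 0.05, var_equal = TRUE) {
  groups <- factor(groups)
  if (length(values) != length(groups)) {
    stop("values and groups must have the same length", call. = FALSE)
  }
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop("fewer than 2 values in group '",
         names(counts)[counts < 2L][1L], "'", call. = FALSE)
  }
  if (all(tapply(values, groups, stats::var) == 0)) {
    means <- tapply(values, groups, mean)
    if (length(unique(means)) > 1L) {
      stop("zero pooled variance with unequal group means", call. = FALSE)
    }
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  anova_res <- list(f_statistic = tab[1L, "F value"],
                    df = unname(tab[["Df"]]),
                    p_value = tab[1L, "Pr(>F)"])
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  tukey <- data.frame(contrast = rownames(tk),
                      diff = tk[, "diff"],
                      lwr = tk[, "lwr"],
                      upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL,
                      stringsAsFactors = FALSE)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  t_tests <- do.call(rbind, apply(pairs, 2L, function(pr) {
    a <- values[groups == pr[1L]]
    b <- values[groups == pr[2L]]
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
      return(data.frame(contrast = paste(pr[2L], pr[1L], sep = "-"),
                        t_statistic = 0, p_value = 1, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    ht <- stats::t.test(b, a, var.equal = var_equal)
    data.frame(contrast = paste(pr[2L], pr[1L], sep = "-"),
               t_statistic = unname(ht$statistic),
               p_value = ht$p.value,
               significant = ht$p.value < alpha,
               stringsAsFactors = FALSE)
  }))
  structure(list(anova = anova_res, tukey = tukey, t_tests = t_tests,
                 alpha = alpha),
            class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df[1L], x$anova$df[2L], x$anova$f_statistic,
              x$anova$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Summarise skin-integrity measurements per group
#'
#' Converts voltage drops into skin resistance and reports group mean and
#' SD of resistance and TEWL, plus the ANOVA/Tukey comparison of TEWL
#' across groups.
#'
#' @param integrity A data.frame as returned by [read_integrity_csv()].
#' @param cfg A [franz_config()].
#' @param alpha Significance threshold for the group tests.
#' @return A list with `per_group` (data.frame of means and SDs), `tewl_tests`
#'   and `resistance_tests` ([group_tests()] results, `NULL` when fewer than
#'   two groups are present).
#' @export
summarize_integrity <- function(integrity, cfg, alpha = 0.05) {
  cfg <- validate_config(cfg)
  rs <- skin_resistance(integrity$vs_mv, cfg)
  per_group <- do.call(rbind, lapply(split(seq_len(nrow(integrity)),
                                           integrity$group), function(idx) {
    data.frame(group = integrity$group[idx][1L],
               n = length(idx),
               rs_mean = mean(rs[idx]),
               rs_sd = if (length(idx) > 1L) stats::sd(rs[idx]) else 0,
               tewl_mean = mean(integrity$tewl_g_m2h[idx]),
               tewl_sd = if (length(idx) > 1L) stats::sd(integrity$tewl_g_m2h[idx]) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  multi <- length(unique(integrity$group)) >= 2L &&
    all(table(integrity$group) >= 2L)
  # noiseless (or saturated) measurements can be exactly constant within
  # groups; the comparison is then undefined and reported as absent
  safe_tests <- function(values) {
    if (!multi) return(NULL)
    tryCatch(group_tests(values, integrity$group, alpha),
             error = function(e) {
               if (grepl("zero pooled variance", conditionMessage(e))) NULL
               else stop(e)
             })
  }
  list(per_group = per_group,
       tewl_tests = safe_tests(integrity$tewl_g_m2h),
       resistance_tests = safe_tests(rs))
}
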