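# Skin-disposition metrics: topical selectivity, total delivery and
# delivery efficiency.

#' Topical selectivity
#'
#' Percentage of the total delivered drug that is retained within the skin
#' layers rather than permeating into the receptor:
#' TS = 100 Qs / (Qs + Q24).
#'
#' @param qs Skin disposition (epidermis + dermis), ug/sq.cm, >= 0.
#' @param q24 Cumulative receptor delivery at 24 h, ug/sq.cm, >= 0.
#' @return Topical selectivity (%). Vectorised.
#' @examples
#' topical_selectivity(2.53, 0)  # 100
#' @export
topical_selectivity <- function(qs, q24) {
  if (any(qs < 0) || any(q24 < 0)) {
    stop("disposition amounts must be >= 0", call. = FALSE)
  }
  if (any(qs + q24 <= 0)) stop("no delivery: Qs + Q24 is zero", call. = FALSE)
  100 * qs / (qs + q24)
}

#' Total drug delivery
#'
#' Sum of the amount deposited in the skin layers and the amount that
#' reached the receptor chamber over 24 h.
#'
#' @param qs Skin disposition (ug/sq.cm), >= 0.
#' @param q24 Receptor delivery at 24 h (ug/sq.cm), >= 0.
#' @return Total delivery (ug/sq.cm). Vectorised.
#' @export
total_delivery <- function(qs, q24) {
  if (any(qs < 0) || any(q24 < 0)) {
    stop("disposition amounts must be >= 0", call. = FALSE)
  }
  qs + q24
}

#' Delivery efficiency
#'
#' Fraction of the applied donor dose that was delivered into and across
#' the skin. Two conventions are offered:
#'
#' * `"paper"`: `100 * total / donor_dose` with the total left in ug/sq.cm.
#'   Against a 100 ug dose this makes the efficiency numerically equal to
#'   the total delivery. It is dimensionally loose (an areal amount divided
#'   by a mass) but matches the convention of published permeation tables.
#' * `"strict"`: `100 * total * A / donor_dose` — the delivered mass over
#'   the whole permeation area divided by the applied mass.
#'
#' The two agree only when A = 1 sq.cm.
#'
#' @param total Total delivery (ug/sq.cm).
#' @param cfg A [franz_config()] with `donor_dose` (and `permeation_area`
#'   for the strict convention).
#' @param convention `"paper"` (default) or `"strict"`.
#' @return Delivery efficiency (%). Vectorised over `total`.
#' @export
delivery_efficiency <- function(total, cfg,
                                convention = c("paper", "strict")) {
  convention <- match.arg(convention)
  cfg <- validate_config(cfg)
  if (is.null(cfg$donor_dose)) stop("config needs donor_dose", call. = FALSE)
  switch(convention,
         paper = 100 * total / cfg$donor_dose,
         strict = 100 * total * cfg$permeation_area / cfg$donor_dose)
}

#' Summarise skin disposition per group
#'
#' Computes, per replicate, the skin disposition Qs (epidermis + dermis),
#' total delivery, delivery efficiency and topical selectivity, then the
#' group mean and SD (n-1) of each.
#'
#' @param disposition A data.frame as returned by [read_disposition_csv()].
#' @param cfg A [franz_config()] with `donor_dose` set.
#' @param convention Efficiency convention, see [delivery_efficiency()].
#' @return A list with `per_replicate` and `per_group` data.frames.
#' @export
summarize_disposition <- function(disposition, cfg,
                                  convention = c("paper", "strict")) {
  convention <- match.arg(convention)
  cfg <- validate_config(cfg)
  qs <- disposition$epidermis_ug_cm2 + disposition$dermis_ug_cm2
  q24 <- disposition$q24_ug_cm2
  per_rep <- data.frame(group = disposition$group,
                        replicate = disposition$replicate,
                        epidermis = disposition$epidermis_ug_cm2,
                        dermis = disposition$dermis_ug_cm2,
                        qs = qs,
                        q24 = q24,
                        total_delivery = total_delivery(qs, q24),
                        stringsAsFactors = FALSE)
  per_rep$delivery_efficiency <-
    delivery_efficiency(per_rep$total_delivery, cfg, convention)
  per_rep$topical_selectivity <- topical_selectivity(qs, q24)
  num <- c("epidermis", "dermis", "qs", "q24", "total_delivery",
           "delivery_efficiency", "topical_selectivity")
  per_group <- do.call(rbind, lapply(split(per_rep, per_rep$group),
                                     function(d) {
    row <- data.frame(group = d$group[1L], n = nrow(d),
                      stringsAsFactors = FALSE)
    for (v in num) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]])
      row[[paste0(v, "_sd")]] <- if (nrow(d) > 1L) stats::sd(d[[v]]) else 0
    }
    row
  }))
  rownames(per_group) <- NULL
  list(per_replicate = per_rep, per_group = per_group,
       convention = convention)
}
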