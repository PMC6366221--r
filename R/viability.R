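# Biocidal effect of the tested inhibitors, expressed as cell mortality
# relative to the untreated control suspension.

#' Cell mortality from viable counts
#'
#' `M = (1 - Cv/Ct) * 100`, where `Cv` is the viable count of the treated
#' sample and `Ct` of the control. The reported mortality is clamped to
#' \[0, 100\]; the raw value is returned alongside for diagnostics (growth
#' during the assay gives a negative raw value).
#'
#' @param cv Viable cells per ml in the treated sample (>= 0).
#' @param ct Viable cells per ml in the control (> 0).
#' @return A list with `mortality` (clamped percent) and `raw` (unclamped).
#' @examples
#' mortality(2.5e7, 1e8)$mortality  # 75
#' @export
mortality <- function(cv, ct) {
  if (any(ct <= 0)) stop("control count ct must be positive", call. = FALSE)
  if (any(cv < 0)) stop("treated count cv must be non-negative", call. = FALSE)
  raw <- (1 - cv / ct) * 100
  if (any(raw < 0))
    message("treated count exceeds control; mortality clamped to 0")
  list(mortality = pmin(pmax(raw, 0), 100), raw = raw)
}

#' Mortality table from a counts manifest
#'
#' Replicate counts are averaged per (strain, condition) before the ratio;
#' the standard error of the mortality is propagated from the replicate
#' standard errors of the two means by the delta method.
#'
#' @param counts A data.frame with columns `strain`, `condition`,
#'   `replicate`, `cfu_per_ml` (or a path to such a CSV).
#' @param control_condition Condition label of the control (default
#'   `"RC_0"`).
#' @return A data.frame with columns `strain`, `condition`, `cv`, `ct`,
#'   `mortality`, `mortality_raw`, `se`.
#' @export
mortality_table <- function(counts, control_condition = "RC_0") {
  if (is.character(counts))
    counts <- utils::read.csv(counts, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "replicate", "cfu_per_ml")
  if (!all(need %in% names(counts)))
    stop("counts table must have columns strain, condition, replicate, cfu_per_ml",
         call. = FALSE)
  out <- list()
  for (strain in unique(counts$strain)) {
    cs <- counts[counts$strain == strain, ]
    ctrl <- cs$cfu_per_ml[cs$condition == control_condition]
    if (length(ctrl) == 0L)
      stop(sprintf("no control counts for strain '%s'", strain),
           call. = FALSE)
    ct <- mean(ctrl)
    se_ct <- if (length(ctrl) > 1L) stats::sd(ctrl) / sqrt(length(ctrl)) else 0
    for (cond in setdiff(unique(cs$condition), control_condition)) {
      trt <- cs$cfu_per_ml[cs$condition == cond]
      cv <- mean(trt)
      se_cv <- if (length(trt) > 1L) stats::sd(trt) / sqrt(length(trt)) else 0
      m <- mortality(cv, ct)
      # delta method on M(cv, ct) = (1 - cv/ct) * 100
      se <- 100 * sqrt(se_cv^2 / ct^2 + cv^2 * se_ct^2 / ct^4)
      out[[length(out) + 1L]] <- data.frame(
        strain = strain, condition = cond, cv = cv, ct = ct,
        mortality = m$mortality, mortality_raw = m$raw, se = se,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
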