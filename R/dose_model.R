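# Inverse-calibration dose models: per-window quadratic "primary" models
# RC = a*SI^2 + b*SI + c, weighted per-strain "general" models combining
# the spectral regions, quartile classification of predicted relative
# concentrations, and evaluation statistics.

#' Relative-concentration scale
#'
#' The default dose scale of the bioassay: control plus low/medium/high
#' inhibitor levels mapped to relative concentrations 0, 25, 50, 100.
#'
#' @param values Named numeric vector overriding the default mapping.
#' @return Named numeric vector of condition label -> RC value.
#' @export
rc_scale <- function(values = c(RC_0 = 0, RC_L = 25, RC_M = 50, RC_H = 100)) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  values
}

#' Fit a primary quadratic inverse-calibration model
#'
#' Ordinary least-squares fit of `RC = a*SI^2 + b*SI + c` on replicate-level
#' (SI, RC) points of one strain and one spectral window.
#'
#' @param si Stress-index values (>= 3 points, >= 3 distinct).
#' @param rc Matching relative concentrations.
#' @param strain,window Metadata stored on the model.
#' @return A `primary_model` object: list with `a`, `b`, `c`, `r2`,
#'   `strain`, `window`, `n`.
#' @examples
#' m <- fit_primary(0:3, c(0, 3, 10, 21))  # exact RC = 2*SI^2 + SI
#' c(m$a, m$b, m$c, m$r2)
#' @export
fit_primary <- function(si, rc, strain = NA_character_,
                        window = NA_character_) {
  stopifnot(length(si) == length(rc))
  if (length(unique(si)) < 3L)
    stop("primary fit needs at least 3 distinct SI values", call. = FALSE)
  fit <- stats::lm(rc ~ si + I(si^2))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((rc - mean(rc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(a = unname(cf[["I(si^2)"]]), b = unname(cf[["si"]]),
                 c = unname(cf[["(Intercept)"]]), r2 = r2,
                 strain = strain, window = window, n = length(si)),
            class = "primary_model")
}

#' Create a primary model from known coefficients
#'
#' Used to evaluate published model parameters or generator truth values
#' without refitting.
#'
#' @param a,b,c Quadratic coefficients (RC per SI^2, RC per SI, RC).
#' @param r2 Goodness of fit to attach (default `NA`).
#' @param strain,window Metadata.
#' @return A `primary_model` object.
#' @export
primary_model <- function(a, b, c, r2 = NA_real_, strain = NA_character_,
                          window = NA_character_) {
  structure(list(a = a, b = b, c = c, r2 = r2, strain = strain,
                 window = window, n = NA_integer_), class = "primary_model")
}

#' @export
print.primary_model <- function(x, ...) {
  cat(sprintf(
    "<primary_model> %s/%s: RC = %.4g*SI^2 + %.4g*SI + %.4g (R2 = %.3f)\n",
    x$strain, x$window, x$a, x$b, x$c, x$r2))
  invisible(x)
}

#' Predict relative concentration from one primary model
#'
#' `a*si^2 + b*si + c`; the raw value is returned (it can be negative for
#' small SI) — clamping happens only at classification.
#'
#' @param m A `primary_model`.
#' @param si Stress-index value(s), >= 0.
#' @return Predicted RC value(s).
#' @export
predict_primary <- function(m, si) {
  stopifnot(inherits(m, "primary_model"))
  m$a * si^2 + m$b * si + m$c
}

#' Build a weighted general model
#'
#' Combines the per-window primary models of one strain with non-negative
#' weights; the prediction is the weight-normalized combination, so the
#' model is invariant under rescaling all weights.
#'
#' @param primaries Named list of `primary_model` objects, names are window
#'   labels (typically `W1`..`W4`, `WS`).
#' @param weights Named non-negative weights over (a subset of) the same
#'   window labels, not all zero.
#' @param strain Metadata.
#' @return A `general_model` object.
#' @export
general_model <- function(primaries, weights, strain = NA_character_) {
  stopifnot(is.list(primaries), !is.null(names(primaries)))
  weights <- weights[weights != 0]
  if (length(weights) == 0L || all(weights == 0))
    stop("all weights are zero", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  missing <- setdiff(names(weights), names(primaries))
  if (length(missing))
    stop(sprintf("no primary model for weighted window(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(primaries = primaries, weights = weights, strain = strain),
            class = "general_model")
}

#' @export
print.general_model <- function(x, ...) {
  cat(sprintf("<general_model> %s: weights %s\n", x$strain,
              paste(sprintf("%s=%g", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Predict relative concentration from a general model
#'
#' @param g A [general_model()].
#' @param si_by_window Named numeric vector of SI values; every window with
#'   nonzero weight must be present.
#' @return Predicted RC (scalar).
#' @export
predict_general <- function(g, si_by_window) {
  stopifnot(inherits(g, "general_model"))
  w <- g$weights
  missing <- setdiff(names(w), names(si_by_window))
  if (length(missing))
    stop(sprintf("missing SI for weighted window(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  preds <- vapply(names(w), function(win) {
    predict_primary(g$primaries[[win]], si_by_window[[win]])
  }, numeric(1))
  sum(w * preds) / sum(w)
}

#' Classify a predicted relative concentration into quartiles
#'
#' `CRC = floor(rc/25 + 1/2)` (round-half-up of `rc/25`), mapping the
#' expected doses 25, 50, 100 to classes 1, 2, 4. Negative predictions map
#' to class 0 with a note.
#'
#' @param rc Predicted RC value(s), finite.
#' @return Integer class(es), >= 0.
#' @examples
#' classify_crc(c(25, 50, 100))  # 1 2 4
#' @export
classify_crc <- function(rc) {
  stopifnot(all(is.finite(rc)))
  cls <- floor(rc / 25 + 0.5)
  if (any(cls < 0)) {
    message("negative predicted RC classified as 0")
    cls <- pmax(cls, 0)
  }
  as.integer(cls)
}

#' Pearson correlation between predicted and expected concentrations
#'
#' @param predicted,expected Equal-length (>= 3) non-constant numeric
#'   vectors.
#' @return Sample Pearson correlation coefficient.
#' @export
pearson_r <- function(predicted, expected) {
  if (length(predicted) != length(expected) || length(predicted) < 3L)
    stop("need equal-length sequences of at least 3 values", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(expected) == 0)
    stop("constant input sequence", call. = FALSE)
  stats::cor(predicted, expected)
}

#' Two-sample t-test of predicted against expected concentrations
#'
#' Two-sided Student t-test with pooled (equal) variance. A degenerate
#' zero-variance comparison returns p = 1 when the means agree and p = 0
#' otherwise.
#'
#' @param predicted,expected Numeric vectors of length >= 2.
#' @return Two-sided p-value.
#' @export
ttest_predicted_vs_expected <- function(predicted, expected) {
  if (length(predicted) < 2L || length(expected) < 2L)
    stop("both samples need at least 2 values", call. = FALSE)
  scale <- max(abs(c(predicted, expected)), 1)
  if (stats::sd(predicted) < 1e-12 * scale &&
      stats::sd(expected) < 1e-12 * scale) {
    return(if (abs(mean(predicted) - mean(expected)) < 1e-12 * scale) 1 else 0)
  }
  stats::t.test(predicted, expected, var.equal = TRUE)$p.value
}

# all compositions of `total` units into k parts (weight grids on the
# simplex at resolution 1/total)
weight_grid <- function(k, total) {
  if (k == 1L) return(matrix(total, ncol = 1))
  out <- list()
  for (first in 0:total) {
    rest <- weight_grid(k - 1L, total - first)
    out[[first + 1L]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}

#' Select general-model weights
#'
#' Strategies: `"manual"` echoes the supplied weights; `"best_r2"` puts
#' weight 1 on the region model (`W1`..`W4`) with the highest R^2;
#' `"grid"` exhaustively searches weight vectors on the simplex (step 0.1
#' by default) minimizing the squared prediction error against the expected
#' concentrations, breaking ties toward fewer nonzero weights and then
#' toward windows with higher R^2.
#'
#' @param primaries Named list of `primary_model` objects.
#' @param strategy `"manual"`, `"best_r2"` or `"grid"`.
#' @param weights Manual weights (for `strategy = "manual"`).
#' @param si_by_level For `"grid"`: matrix of SI values, rows named by
#'   window, columns named by dose level.
#' @param expected For `"grid"`: named RC values of the same dose levels.
#' @param windows Candidate windows for `"best_r2"`/`"grid"` (default
#'   `W1`..`W4`, the region-based general model).
#' @param step Grid resolution on the simplex (default 0.1).
#' @param strain Metadata for the returned model.
#' @return A [general_model()].
#' @export
select_weights <- function(primaries,
                           strategy = c("best_r2", "grid", "manual"),
                           weights = NULL, si_by_level = NULL,
                           expected = NULL,
                           windows = c("W1", "W2", "W3", "W4"),
                           step = 0.1, strain = NA_character_) {
  strategy <- match.arg(strategy)
  windows <- intersect(windows, names(primaries))
  if (length(windows) == 0L)
    stop("no candidate windows among the fitted primaries", call. = FALSE)
  if (strategy == "manual") {
    if (is.null(weights)) stop("manual strategy needs weights", call. = FALSE)
    return(general_model(primaries, weights, strain = strain))
  }
  r2 <- vapply(primaries[windows], function(m) m$r2, numeric(1))
  if (strategy == "best_r2") {
    w <- stats::setNames(0 * r2, windows)
    w[which.max(r2)] <- 1
    return(general_model(primaries, w, strain = strain))
  }
  # grid strategy
  if (is.null(si_by_level) || is.null(expected))
    stop("grid strategy needs si_by_level and expected", call. = FALSE)
  si_by_level <- as.matrix(si_by_level)
  levels <- colnames(si_by_level)
  if (!all(levels %in% names(expected)))
    stop("expected RCs missing for some dose levels", call. = FALSE)
  # per-window predictions at each level
  pred <- vapply(levels, function(lv) {
    vapply(windows, function(win) {
      predict_primary(primaries[[win]], si_by_level[win, lv])
    }, numeric(1))
  }, numeric(length(windows)))       # windows x levels
  total <- round(1 / step)
  grid <- weight_grid(length(windows), total) / total
  sse <- apply(grid, 1, function(w) {
    sum((colSums(w * pred) / sum(w) - expected[levels])^2)
  })
  nnz <- rowSums(grid > 0)
  r2score <- as.vector(grid %*% r2)
  ord <- order(round(sse, 10), nnz, -r2score)
  w <- stats::setNames(grid[ord[1], ], windows)
  general_model(primaries, w, strain = strain)
}

#' Evaluate a general model against the expected dose scale
#'
#' Predicts the RC of each dose level, classifies the predictions into
#' quartiles, and computes the Pearson correlation and pooled two-sample
#' t-test p-value against the expected concentrations.
#'
#' @param g A [general_model()].
#' @param si_by_level Matrix of SI values, rows named by window, columns
#'   named by dose level (typically `RC_L`, `RC_M`, `RC_H`).
#' @param expected Named expected RC values of the same levels (default the
#'   non-control part of [rc_scale()]).
#' @return A `prediction_report`: list with `table` (level, expected,
#'   predicted, crc, expected_crc, match), `r`, `p_value`, `strain`,
#'   `weights`.
#' @export
build_report <- function(g, si_by_level,
                         expected = rc_scale()[c("RC_L", "RC_M", "RC_H")]) {
  stopifnot(inherits(g, "general_model"))
  si_by_level <- as.matrix(si_by_level)
  levels <- colnames(si_by_level)
  if (!all(levels %in% names(expected)))
    stop("expected RCs missing for some dose levels", call. = FALSE)
  predicted <- vapply(levels, function(lv) {
    predict_general(g, stats::setNames(si_by_level[, lv],
                                       rownames(si_by_level)))
  }, numeric(1))
  exp_rc <- unname(expected[levels])
  tab <- data.frame(
    level = levels, expected = exp_rc, predicted = unname(predicted),
    crc = classify_crc(unname(predicted)), expected_crc = classify_crc(exp_rc),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$match <- tab$crc == tab$expected_crc
  structure(list(table = tab,
                 r = pearson_r(predicted, exp_rc),
                 p_value = ttest_predicted_vs_expected(predicted, exp_rc),
                 strain = g$strain, weights = g$weights),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s (r = %.2f, t-test p = %.2f)\n",
              x$strain, x$r, x$p_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit all primary models from a replicate-level SI table
#'
#' @param points A data.frame as returned by [si_points()].
#' @param windows Window labels to fit (default `W1`..`W4` and `WS`; the
#'   typing region `W5` is excluded from modelling).
#' @return Nested named list: `strain -> window -> primary_model`.
#' @export
fit_primaries <- function(points,
                          windows = c("W1", "W2", "W3", "W4", "WS")) {
  stopifnot(all(c("strain", "window", "si", "rc") %in% names(points)))
  out <- list()
  for (strain in unique(points$strain)) {
    ms <- list()
    for (win in windows) {
      p <- points[points$strain == strain & points$window == win, ]
      if (nrow(p) == 0L) next
      ms[[win]] <- fit_primary(p$si, p$rc, strain = strain, window = win)
    }
    out[[strain]] <- ms
  }
  out
}

#' Flatten fitted primaries to a coefficient table
#'
#' @param primaries Output of [fit_primaries()].
#' @return A data.frame with columns `strain`, `window`, `a`, `b`, `c`, `r2`.
#' @export
primaries_table <- function(primaries) {
  rows <- list()
  for (strain in names(primaries)) {
    for (win in names(primaries[[strain]])) {
      m <- primaries[[strain]][[win]]
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, window = win, a = m$a, b = m$b, c = m$c, r2 = m$r2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
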