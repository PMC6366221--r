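# Spectral stress indexes: length-normalized Euclidean distances between
# stressed and control spectra, per biochemical window. The divisor is the
# ratio (points in whole spectrum)/(points in window), so for the whole
# spectrum the index is the raw Euclidean distance (GSI).

#' Standard biochemical spectral windows
#'
#' The five analysis regions plus the whole recorded range:
#' fatty acids W1 (3000-2800 cm^-1), amides W2 (1800-1500), mixed region W3
#' (1500-1200), carbohydrates W4 (1200-900), typing region W5 (900-700) and
#' WS, the whole spectrum. The typing region responds to strain identity
#' rather than stress and is computed but excluded from dose models.
#'
#' @param grid_range Length-2 recorded range used for WS (default
#'   `c(400, 4000)`).
#' @return A data.frame with columns `window`, `lo`, `hi`.
#' @export
spectral_windows <- function(grid_range = c(400, 4000)) {
  data.frame(
    window = c("W1", "W2", "W3", "W4", "W5", "WS"),
    lo = c(2800, 1500, 1200, 900, 700, min(grid_range)),
    hi = c(3000, 1800, 1500, 1200, 900, max(grid_range)),
    stringsAsFactors = FALSE)
}

#' Slice a spectrum to one spectral window
#'
#' Both bounds are inclusive, so boundary points shared by adjacent windows
#' (e.g. 1500 cm^-1) belong to both.
#'
#' @param s An [ftir_spectrum()].
#' @param lo,hi Window bounds in cm^-1.
#' @return An [ftir_spectrum()] restricted to `[lo, hi]`.
#' @export
window_slice <- function(s, lo, hi) {
  stopifnot(inherits(s, "ftir_spectrum"))
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (sum(keep) < 2L)
    stop(sprintf("window [%g, %g] selects fewer than 2 grid points", lo, hi),
         call. = FALSE)
  ftir_spectrum(s$wavenumbers[keep], s$intensities[keep], strain = s$strain,
                condition = s$condition, replicate = s$replicate)
}

#' Stress index of one window
#'
#' `SI = ED_w / (n_total / n_w)` where `ED_w` is the Euclidean distance
#' between the two intensity vectors restricted to the window, `n_w` the
#' number of grid points inside the window and `n_total` the number of
#' points of the whole spectrum. For the whole-spectrum window the divisor
#' is 1 and the index is the global stress index (GSI).
#'
#' @param stress,control Two [ftir_spectrum()] objects on the same grid
#'   (normally preprocessed).
#' @param lo,hi Window bounds in cm^-1.
#' @param n_total Number of points of the whole spectrum; defaults to the
#'   shared grid length.
#' @return Scalar SI >= 0.
#' @export
stress_index <- function(stress, control, lo, hi,
                         n_total = length(stress$wavenumbers)) {
  stopifnot(inherits(stress, "ftir_spectrum"),
            inherits(control, "ftir_spectrum"))
  if (!isTRUE(all.equal(stress$wavenumbers, control$wavenumbers,
                        tolerance = 0)))
    stop("stress and control spectra are not on the same grid", call. = FALSE)
  keep <- stress$wavenumbers >= lo & stress$wavenumbers <= hi
  n_w <- sum(keep)
  if (n_w < 1L) stop("window contains no grid points", call. = FALSE)
  ed <- sqrt(sum((stress$intensities[keep] - control$intensities[keep])^2))
  ed / (n_total / n_w)
}

si_all_windows <- function(stress, control, windows, n_total) {
  vapply(seq_len(nrow(windows)), function(i) {
    stress_index(stress, control, windows$lo[i], windows$hi[i],
                 n_total = n_total)
  }, numeric(1))
}

#' Stress-index table of a spectrum set
#'
#' For every strain and non-control condition, computes the window-wise SI
#' between the replicate-averaged stressed spectrum and the
#' replicate-averaged control spectrum. Replicate spread is reported as the
#' standard deviation of the SIs of all (stressed replicate, control
#' replicate) pairings.
#'
#' @param set A preprocessed [ftir_set()].
#' @param control_condition Condition label of the unstressed control
#'   (default `"RC_0"`).
#' @param windows Window table, see [spectral_windows()]; defaults to the
#'   standard windows with WS equal to the set's grid range.
#' @param per_replicate If `TRUE`, the SI column holds the mean of the
#'   per-pairing SIs instead of the SI of the averaged spectra (the two
#'   differ slightly under noise).
#' @return A data.frame with columns `strain`, `condition`, `window`, `si`,
#'   `si_sd`.
#' @export
compute_si_table <- function(set, control_condition = "RC_0", windows = NULL,
                             per_replicate = FALSE) {
  stopifnot(inherits(set, "ftir_set"))
  if (is.null(windows)) windows <- spectral_windows(range(set$grid))
  man <- set_manifest(set)
  n_total <- length(set$grid)
  out <- list()
  for (strain in unique(man$strain)) {
    ctrl_idx <- group_indices(set, strain, control_condition)
    if (length(ctrl_idx) == 0L)
      stop(sprintf("no control condition '%s' for strain '%s'",
                   control_condition, strain), call. = FALSE)
    ctrl_mean <- average_replicates(set, strain, control_condition)
    conds <- setdiff(unique(man$condition[man$strain == strain]),
                     control_condition)
    for (cond in conds) {
      idx <- group_indices(set, strain, cond)
      si_mean_spec <- si_all_windows(average_replicates(set, strain, cond),
                                     ctrl_mean, windows, n_total)
      pair_si <- sapply(idx, function(i) {
        sapply(ctrl_idx, function(j) {
          si_all_windows(set$spectra[[i]], set$spectra[[j]], windows, n_total)
        })
      })
      pair_si <- matrix(pair_si, nrow = nrow(windows))
      spread <- apply(pair_si, 1, stats::sd)
      si <- if (per_replicate) rowMeans(pair_si) else si_mean_spec
      out[[length(out) + 1L]] <- data.frame(
        strain = strain, condition = cond, window = windows$window,
        si = si, si_sd = spread, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Replicate-level stress-index points for model fitting
#'
#' Computes one SI per stressed replicate (against the replicate-averaged
#' control) and appends, for every control replicate, the exact control
#' point SI = 0 at RC = 0. These are the (SI, RC) points the primary
#' quadratic models are fitted on.
#'
#' @param set A preprocessed [ftir_set()].
#' @param rc_map Named numeric vector mapping condition labels to
#'   relative-concentration values, e.g. [rc_scale()].
#' @param control_condition Control condition label.
#' @param windows Window table; defaults as in [compute_si_table()].
#' @return A data.frame with columns `strain`, `condition`, `replicate`,
#'   `window`, `si`, `rc`.
#' @export
si_points <- function(set, rc_map = rc_scale(), control_condition = "RC_0",
                      windows = NULL) {
  stopifnot(inherits(set, "ftir_set"))
  if (is.null(windows)) windows <- spectral_windows(range(set$grid))
  man <- set_manifest(set)
  n_total <- length(set$grid)
  out <- list()
  for (strain in unique(man$strain)) {
    ctrl_idx <- group_indices(set, strain, control_condition)
    if (length(ctrl_idx) == 0L)
      stop(sprintf("no control condition '%s' for strain '%s'",
                   control_condition, strain), call. = FALSE)
    ctrl_mean <- average_replicates(set, strain, control_condition)
    for (i in ctrl_idx) {
      out[[length(out) + 1L]] <- data.frame(
        strain = strain, condition = control_condition,
        replicate = set$spectra[[i]]$replicate, window = windows$window,
        si = 0, rc = 0, stringsAsFactors = FALSE)
    }
    conds <- setdiff(unique(man$condition[man$strain == strain]),
                     control_condition)
    for (cond in conds) {
      if (!cond %in% names(rc_map))
        stop(sprintf("condition '%s' missing from rc_map", cond),
             call. = FALSE)
      for (i in group_indices(set, strain, cond)) {
        si <- si_all_windows(set$spectra[[i]], ctrl_mean, windows, n_total)
        out[[length(out) + 1L]] <- data.frame(
          strain = strain, condition = cond,
          replicate = set$spectra[[i]]$replicate, window = windows$window,
          si = si, rc = unname(rc_map[cond]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Replicate spectral variability
#'
#' Mean pairwise full-spectrum Euclidean distance among the replicate
#' spectra of each (strain, condition) group — the "variability between
#' replicas throughout the spectra" used to calibrate synthetic noise.
#'
#' @param set A preprocessed [ftir_set()].
#' @return A data.frame with columns `strain`, `condition`, `spread`.
#' @export
replicate_spread <- function(set) {
  stopifnot(inherits(set, "ftir_set"))
  man <- set_manifest(set)
  groups <- unique(man[c("strain", "condition")])
  spread <- numeric(nrow(groups))
  for (g in seq_len(nrow(groups))) {
    idx <- group_indices(set, groups$strain[g], groups$condition[g])
    if (length(idx) < 2L) { spread[g] <- NA_real_; next }
    pairs <- utils::combn(idx, 2)
    spread[g] <- mean(apply(pairs, 2, function(p) {
      sqrt(sum((set$spectra[[p[1]]]$intensities -
                set$spectra[[p[2]]]$intensities)^2))
    }))
  }
  data.frame(strain = groups$strain, condition = groups$condition,
             spread = spread, stringsAsFactors = FALSE, row.names = NULL)
}
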