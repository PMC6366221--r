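#' Construct an FTIR spectrum
#'
#' An `ftir_spectrum` holds one replicate measurement: a strictly monotone
#' wavenumber grid (stored descending, instrument convention 4000 -> 400
#' cm^-1) and the matching absorbance intensities, plus sample metadata.
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1). Any strictly
#'   monotone order is accepted; values are stored descending.
#' @param intensities Numeric vector of absorbances, same length.
#' @param strain,condition,replicate Sample metadata (scalars).
#' @return An object of class `ftir_spectrum`: a list with elements
#'   `wavenumbers`, `intensities`, `strain`, `condition`, `replicate`.
#' @examples
#' s <- ftir_spectrum(c(1000, 998, 996), c(0.1, 0.4, 0.2))
#' s$wavenumbers
#' @export
ftir_spectrum <- function(wavenumbers, intensities,
                          strain = NA_character_, condition = NA_character_,
                          replicate = NA_integer_) {
  if (!is.numeric(wavenumbers) || !is.numeric(intensities))
    stop("wavenumbers and intensities must be numeric", call. = FALSE)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumbers in spectrum", call. = FALSE)
  if (any(!is.finite(wavenumbers)))
    stop("non-finite wavenumbers", call. = FALSE)
  ord <- order(wavenumbers, decreasing = TRUE)
  structure(
    list(wavenumbers = as.numeric(wavenumbers[ord]),
         intensities = as.numeric(intensities[ord]),
         strain = strain, condition = condition, replicate = replicate),
    class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %d points, %g to %g cm^-1\n",
              length(x$wavenumbers), x$wavenumbers[1],
              x$wavenumbers[length(x$wavenumbers)]))
  cat(sprintf("  strain=%s condition=%s replicate=%s\n",
              x$strain, x$condition, x$replicate))
  invisible(x)
}

#' Read a spectrum from two-column delimited text
#'
#' Accepts the plain export dialect (wavenumber, absorbance per row; comma,
#' tab or whitespace separated) and JCAMP-DX-like files whose `##XYDATA`
#' block lists one x,y pair per line. Lines starting with `#` (including
#' `##`-prefixed JCAMP label lines) are treated as comments and skipped.
#'
#' @param path Path to a text file (or a connection).
#' @param strain,condition,replicate Metadata to attach.
#' @return An [ftir_spectrum()] with the grid sorted descending.
#' @seealso [write_spectrum_table()]
#' @export
read_spectrum_table <- function(path, strain = NA_character_,
                                condition = NA_character_,
                                replicate = NA_integer_) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data rows in spectrum file", call. = FALSE)
  lineno <- which(keep)
  rows <- lines[keep]
  # split on comma, semicolon, tab or runs of spaces
  parts <- strsplit(trimws(rows), "\\s*[,;]\\s*|\\s+")
  wn <- numeric(length(parts)); ab <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L)
      stop(sprintf("line %d: expected two numeric columns", lineno[i]),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(v)))
      stop(sprintf("line %d: non-numeric value '%s'", lineno[i],
                   paste(p[1:2], collapse = ",")), call. = FALSE)
    wn[i] <- v[1]; ab[i] <- v[2]
  }
  if (anyDuplicated(wn))
    stop("duplicate wavenumbers in spectrum file", call. = FALSE)
  ftir_spectrum(wn, ab, strain = strain, condition = condition,
                replicate = replicate)
}

#' Write a spectrum as two-column delimited text
#'
#' Emits `wavenumber,absorbance` rows (grid descending) after a single
#' `#wavenumber,absorbance` comment header. Values are formatted at a fixed
#' number of significant digits so a given spectrum always serializes to
#' identical bytes.
#'
#' @param s An [ftir_spectrum()].
#' @param path Output file path.
#' @param digits Significant digits used for formatting (default 10, which
#'   keeps absorbance round-trip error below 1e-9 on unit-scale spectra).
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(s, path, digits = 10L) {
  stopifnot(inherits(s, "ftir_spectrum"))
  fmt <- paste0("%.", digits, "g")
  lines <- c("#wavenumber,absorbance",
             sprintf(paste0(fmt, ",", fmt), s$wavenumbers, s$intensities))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation between the measured points; extrapolation outside
#' the measured span is refused.
#'
#' @param s An [ftir_spectrum()].
#' @param grid Target wavenumbers (any order; stored descending).
#' @return An [ftir_spectrum()] on `grid` with metadata preserved.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "ftir_spectrum"))
  rng <- range(s$wavenumbers)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop("target grid extends outside the measured span; no extrapolation",
         call. = FALSE)
  g <- sort(as.numeric(grid), decreasing = TRUE)
  y <- stats::approx(rev(s$wavenumbers), rev(s$intensities), xout = g,
                     method = "linear", ties = "ordered")$y
  ftir_spectrum(g, y, strain = s$strain, condition = s$condition,
                replicate = s$replicate)
}

#' Collect spectra on a common grid
#'
#' A `ftir_set` is a collection of [ftir_spectrum()] objects resampled onto
#' one shared wavenumber grid, grouped implicitly by their (strain,
#' condition) metadata.
#'
#' @param spectra List of [ftir_spectrum()] objects.
#' @param grid Common grid; default is the grid of the first spectrum.
#' @return An object of class `ftir_set` with elements `spectra` and `grid`.
#' @export
ftir_set <- function(spectra, grid = NULL) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  if (is.null(grid)) grid <- spectra[[1]]$wavenumbers
  grid <- sort(as.numeric(grid), decreasing = TRUE)
  spectra <- lapply(spectra, function(s) {
    if (identical(s$wavenumbers, grid)) s else resample_to_grid(s, grid)
  })
  structure(list(spectra = spectra, grid = grid), class = "ftir_set")
}

#' @export
print.ftir_set <- function(x, ...) {
  m <- set_manifest(x)
  cat(sprintf("<ftir_set> %d spectra on %d-point grid (%g to %g cm^-1)\n",
              length(x$spectra), length(x$grid), x$grid[1],
              x$grid[length(x$grid)]))
  cat(sprintf("  %d strain(s) x %d condition(s)\n",
              length(unique(m$strain)), length(unique(m$condition))))
  invisible(x)
}

#' Tabulate the metadata of a spectrum set
#'
#' @param set An [ftir_set()].
#' @return A data.frame with one row per spectrum: `index`, `strain`,
#'   `condition`, `replicate`.
#' @export
set_manifest <- function(set) {
  stopifnot(inherits(set, "ftir_set"))
  data.frame(
    index = seq_along(set$spectra),
    strain = vapply(set$spectra, function(s) as.character(s$strain), ""),
    condition = vapply(set$spectra, function(s) as.character(s$condition), ""),
    replicate = vapply(set$spectra, function(s) as.integer(s$replicate), 1L),
    stringsAsFactors = FALSE)
}

group_indices <- function(set, strain, condition) {
  m <- set_manifest(set)
  m$index[m$strain == strain & m$condition == condition]
}

#' Average the replicate spectra of one (strain, condition) group
#'
#' Point-wise arithmetic mean of the replicate intensities on the shared
#' grid.
#'
#' @param set An [ftir_set()].
#' @param strain,condition Group selectors.
#' @return An [ftir_spectrum()] with `replicate = NA`.
#' @export
average_replicates <- function(set, strain, condition) {
  idx <- group_indices(set, strain, condition)
  if (length(idx) == 0L)
    stop(sprintf("no replicates for strain '%s', condition '%s'",
                 strain, condition), call. = FALSE)
  ys <- vapply(set$spectra[idx], function(s) s$intensities,
               numeric(length(set$grid)))
  ftir_spectrum(set$grid, rowMeans(as.matrix(ys)),
                strain = strain, condition = condition)
}

#' Read a spectrum set from a manifest table
#'
#' The manifest is a CSV with columns `file`, `strain`, `condition`,
#' `replicate` (and optionally `rc`, the relative-concentration value of
#' the condition). File paths are resolved relative to the manifest.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param grid Optional common grid to resample onto.
#' @return An [ftir_set()].
#' @export
read_spectrum_set <- function(manifest_path, grid = NULL) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "strain", "condition", "replicate")
  if (!all(need %in% names(man)))
    stop("manifest must have columns file, strain, condition, replicate",
         call. = FALSE)
  base <- dirname(manifest_path)
  spectra <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    read_spectrum_table(f, strain = man$strain[i],
                        condition = man$condition[i],
                        replicate = man$replicate[i])
  })
  ftir_set(spectra, grid = grid)
}

#' Default working wavenumber grid
#'
#' 4000 to 400 cm^-1 at the given spacing, descending (1801 points at the
#' default 2 cm^-1 spacing, a typical export density for 4 cm^-1
#' interferometric resolution).
#'
#' @param from,to Grid end points in cm^-1.
#' @param by Spacing in cm^-1.
#' @export
default_grid <- function(from = 4000, to = 400, by = 2) {
  seq(from, to, by = -abs(by))
}
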