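# Synthetic FTIR bioassay experiments: Gaussian-band yeast fingerprints,
# strain-specific dose-dependent perturbations per biochemical window,
# replicate variability, and Poisson viable counts from logistic kill
# curves.
#
# Replicate-to-replicate variation has three components mirroring what
# dominates washed-cell transmission measurements: (i) a smooth random
# bump field over the band-populated regions (biomass composition /
# deposit variation — the dominant term, spread over many smooth degrees
# of freedom and therefore largely orthogonal to any one stress-response
# direction), (ii) small per-band amplitude jitter, and (iii) white
# detector noise. Only (iii) is seen by the band-free 2100-1900 cm^-1
# noise window, so the signal-to-noise quality test and the replicate
# spectral spread can be calibrated independently.

#' Default peak table of the synthetic yeast fingerprint
#'
#' Gaussian bands at the canonical positions of a S. cerevisiae absorbance
#' spectrum: CH stretches (2925, 2852 cm^-1), amide A (3290), amide I/II
#' (1655, 1545), CH bending (1455), amide III / phosphate (1240),
#' phosphate and carbohydrate C-O (1080, 1045) and a typing-region band
#' (852). `width` is the Gaussian standard deviation in cm^-1.
#'
#' @return A data.frame with columns `center`, `width`, `amplitude`.
#' @export
default_peak_table <- function() {
  data.frame(
    center    = c(3290, 2925, 2852, 1655, 1545, 1455, 1240, 1080, 1045, 852),
    width     = c(  90,   14,   11,   28,   25,   18,   30,   35,   25,  22),
    amplitude = c(0.65, 0.40, 0.22, 1.00, 0.62, 0.28, 0.30, 0.45, 0.55, 0.10))
}

#' Biosensor strain response profiles
#'
#' The three response archetypes of the bioassay, named after the
#' S. cerevisiae biosensor strains: a resistant strain (Fm17; low
#' mortality, low spectral response), a sensitive strain (DSM70449;
#' high mortality, lowest spectral response) and an intermediate-tolerance
#' strain (Fp84; low mortality, high metabolomic response). `response` is
#' the relative band-amplitude change at RC = 100 per window; the kill
#' curve is a logistic in RC with the given midpoint and steepness,
#' normalized to survival 1 at RC = 0.
#'
#' @return A named list of profiles; each profile is a list with `name`,
#'   `class`, `response` (named W1..W5), `mort_mid`, `mort_steep`.
#' @export
strain_profiles <- function() {
  prof <- function(name, class, response, mort_mid, mort_steep) {
    list(name = name, class = class,
         response = stats::setNames(response, c("W1", "W2", "W3", "W4", "W5")),
         mort_mid = mort_mid, mort_steep = mort_steep)
  }
  list(
    Fp84 = prof("Fp84", "intermediate",
                c(0.50, 0.40, 0.65, 0.55, 0.03), mort_mid = 120,
                mort_steep = 20),
    Fm17 = prof("Fm17", "resistant",
                c(0.45, 0.30, 0.35, 0.40, 0.03), mort_mid = 150,
                mort_steep = 25),
    DSM70449 = prof("DSM70449", "sensitive",
                    c(0.25, 0.30, 0.25, 0.35, 0.03), mort_mid = 30,
                    mort_steep = 12))
}

#' Synthetic experiment configuration
#'
#' @param grid Wavenumber grid (default [default_grid()]: 4000-400 cm^-1
#'   at 2 cm^-1, 1801 points).
#' @param peaks Peak table, see [default_peak_table()].
#' @param replicates Replicates per (strain, condition) (default 3).
#' @param noise_sd White detector noise, absorbance units (default 5e-5;
#'   keeps the quality-test SNR comfortably above 4000 for unit-scale
#'   spectra).
#' @param amp_jitter_sd Relative per-band amplitude jitter between
#'   replicates (default 0.005).
#' @param bump_sd,bump_n,bump_width,bump_regions Smooth replicate bump
#'   field: `bump_n` Gaussian bumps with amplitudes `N(0, bump_sd)`
#'   (absorbance units), widths drawn uniformly from `bump_width` (cm^-1)
#'   and centers drawn uniformly from the band-populated `bump_regions`
#'   (2-column matrix of intervals). `bump_sd` is calibrated so the
#'   preprocessed replicate spectral spread sits near 2.5e-2.
#' @param drift_sd Standard deviation of the random quadratic baseline
#'   drift coefficients, absorbance units (default 0.01).
#' @param rc_levels Named condition -> RC mapping (default [rc_scale()]).
#' @param gamma Dose-response exponent: band perturbations scale with
#'   `(rc/100)^gamma`. The default 0.5 makes RC an exactly quadratic
#'   function of the perturbation amplitude, the regime the quadratic
#'   primary models assume.
#' @param ct Control viable count, cells per ml (default 1e8).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid = default_grid(),
                             peaks = default_peak_table(),
                             replicates = 3L, noise_sd = 5e-5,
                             amp_jitter_sd = 0.005, bump_sd = 0.0055,
                             bump_n = 30L, bump_width = c(20, 60),
                             bump_regions = rbind(c(700, 1800),
                                                  c(2800, 3100)),
                             drift_sd = 0.01, rc_levels = rc_scale(),
                             gamma = 0.5, ct = 1e8) {
  if (nrow(peaks) == 0L) stop("empty peak table", call. = FALSE)
  structure(list(grid = sort(as.numeric(grid), decreasing = TRUE),
                 peaks = peaks, replicates = as.integer(replicates),
                 noise_sd = noise_sd, amp_jitter_sd = amp_jitter_sd,
                 bump_sd = bump_sd, bump_n = as.integer(bump_n),
                 bump_width = bump_width, bump_regions = bump_regions,
                 drift_sd = drift_sd, rc_levels = rc_levels, gamma = gamma,
                 ct = ct),
            class = "synthetic_config")
}

# Gaussian band design matrix: grid points x bands
band_matrix <- function(grid, peaks) {
  vapply(seq_len(nrow(peaks)), function(k) {
    exp(-(grid - peaks$center[k])^2 / (2 * peaks$width[k]^2))
  }, numeric(length(grid)))
}

# window label of each band center (NA outside the analysis windows)
band_windows <- function(peaks) {
  w <- spectral_windows()
  w <- w[w$window != "WS", ]
  out <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(w))) {
    inw <- peaks$center >= w$lo[i] & peaks$center <= w$hi[i]
    out[inw] <- w$window[i]
  }
  out
}

# survival fraction from the profile's logistic kill curve, normalized so
# that survival(0) = 1
kill_survival <- function(profile, rc) {
  l <- function(r) 1 / (1 + exp((r - profile$mort_mid) / profile$mort_steep))
  l(rc) / l(0)
}

#' Generate one synthetic stressed spectrum
#'
#' Sum of Gaussian bands whose amplitudes are scaled, per biochemical
#' window, by `1 + response_w * (rc/100)^gamma`, plus mild random quadratic
#' baseline drift, per-band replicate amplitude jitter and white noise.
#' At `rc = 0` the perturbation vanishes and the spectrum is a control.
#' Randomness comes from the current RNG state; seed via [set.seed()] or
#' use [generate_experiment()].
#'
#' @param cfg A [synthetic_config()].
#' @param profile A strain profile, see [strain_profiles()].
#' @param rc Relative concentration (>= 0).
#' @param condition,replicate Metadata for the produced spectrum.
#' @param jitter,noise,drift Logical switches for the three stochastic
#'   components (all `TRUE`; turn off for exact closed-form output).
#' @return An [ftir_spectrum()].
#' @export
generate_stressed_spectrum <- function(cfg, profile, rc,
                                       condition = NA_character_,
                                       replicate = NA_integer_,
                                       jitter = TRUE, noise = TRUE,
                                       drift = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"), rc >= 0)
  g <- band_matrix(cfg$grid, cfg$peaks)
  amp <- cfg$peaks$amplitude
  bw <- band_windows(cfg$peaks)
  dose <- (rc / 100)^cfg$gamma
  resp <- ifelse(is.na(bw), 0, profile$response[bw])
  amp <- amp * (1 + resp * dose)
  if (jitter && cfg$amp_jitter_sd > 0)
    amp <- amp * pmax(1 + stats::rnorm(length(amp), 0, cfg$amp_jitter_sd), 0)
  y <- as.vector(g %*% amp)
  if (jitter && cfg$bump_sd > 0 && cfg$bump_n > 0) {
    spans <- cfg$bump_regions[, 2] - cfg$bump_regions[, 1]
    region <- sample.int(nrow(cfg$bump_regions), cfg$bump_n, replace = TRUE,
                         prob = spans / sum(spans))
    centers <- cfg$bump_regions[region, 1] +
      stats::runif(cfg$bump_n) * spans[region]
    widths <- stats::runif(cfg$bump_n, cfg$bump_width[1], cfg$bump_width[2])
    amps <- stats::rnorm(cfg$bump_n, 0, cfg$bump_sd)
    for (j in seq_len(cfg$bump_n))
      y <- y + amps[j] * exp(-(cfg$grid - centers[j])^2 / (2 * widths[j]^2))
  }
  if (drift && cfg$drift_sd > 0) {
    t <- (cfg$grid - min(cfg$grid)) / diff(range(cfg$grid))
    d <- stats::rnorm(2, 0, cfg$drift_sd)
    y <- y + 2 * cfg$drift_sd + d[1] * t + d[2] * t^2
  }
  if (noise && cfg$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, cfg$noise_sd)
  ftir_spectrum(cfg$grid, y, strain = profile$name, condition = condition,
                replicate = replicate)
}

#' Generate one synthetic control spectrum
#'
#' Equivalent to [generate_stressed_spectrum()] at `rc = 0`: the pure
#' Gaussian-band fingerprint plus drift, jitter and noise.
#'
#' @inheritParams generate_stressed_spectrum
#' @return An [ftir_spectrum()].
#' @export
generate_control_spectrum <- function(cfg, profile = strain_profiles()[[1]],
                                      condition = "RC_0",
                                      replicate = NA_integer_,
                                      jitter = TRUE, noise = TRUE,
                                      drift = TRUE) {
  generate_stressed_spectrum(cfg, profile, rc = 0, condition = condition,
                             replicate = replicate, jitter = jitter,
                             noise = noise, drift = drift)
}

#' Generate a complete synthetic bioassay experiment
#'
#' Full factorial strains x RC levels x replicates of spectra, plus viable
#' counts drawn as Poisson around `ct * survival(rc)` with survival from
#' each strain's logistic kill curve, plus a truth table recording the
#' generating parameters.
#'
#' @param cfg A [synthetic_config()].
#' @param profiles List of strain profiles (default [strain_profiles()]).
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   output.
#' @return A list with `set` (an [ftir_set()]), `counts` (data.frame:
#'   strain, condition, replicate, cfu_per_ml) and `truth` (data.frame of
#'   generating survival/mortality and response parameters per strain and
#'   condition).
#' @export
generate_experiment <- function(cfg, profiles = strain_profiles(),
                                seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), length(profiles) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  spectra <- list()
  counts <- list()
  truth <- list()
  for (profile in profiles) {
    for (cond in names(cfg$rc_levels)) {
      rc <- cfg$rc_levels[[cond]]
      surv <- kill_survival(profile, rc)
      for (rep in seq_len(cfg$replicates)) {
        spectra[[length(spectra) + 1L]] <-
          generate_stressed_spectrum(cfg, profile, rc, condition = cond,
                                     replicate = rep)
        counts[[length(counts) + 1L]] <- data.frame(
          strain = profile$name, condition = cond, replicate = rep,
          cfu_per_ml = stats::rpois(1, cfg$ct * surv),
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        strain = profile$name, class = profile$class, condition = cond,
        rc = rc, survival = surv, mortality = (1 - surv) * 100,
        stringsAsFactors = FALSE)
    }
  }
  list(set = ftir_set(spectra, grid = cfg$grid),
       counts = do.call(rbind, counts), truth = do.call(rbind, truth))
}

#' Simulate replicate (SI, RC) points from a known quadratic model
#'
#' Inverts `RC = a*SI^2 + b*SI + c` at each dose level (taking the larger
#' root, the physically increasing branch) and adds Gaussian noise to the
#' SI values. Used for coefficient-recovery experiments on the fitting
#' machinery itself.
#'
#' @param m A `primary_model` (see [primary_model()]); must have a real
#'   non-negative SI root at every requested level.
#' @param rc_levels RC values to invert (default `c(0, 25, 50, 100)`).
#' @param replicates Replicates per level (default 3).
#' @param sigma SI noise standard deviation (default 0).
#' @param seed Optional seed.
#' @return A data.frame with columns `rc`, `replicate`, `si`.
#' @export
simulate_si_from_model <- function(m, rc_levels = c(0, 25, 50, 100),
                                   replicates = 3L, sigma = 0,
                                   seed = NULL) {
  stopifnot(inherits(m, "primary_model"))
  if (!is.null(seed)) set.seed(seed)
  disc <- m$b^2 - 4 * m$a * (m$c - rc_levels)
  if (any(disc < 0))
    stop("model has no real SI root at some requested RC level",
         call. = FALSE)
  si_true <- (-m$b + sqrt(disc)) / (2 * m$a)
  if (any(si_true < 0))
    stop("model inversion gives negative SI at some RC level", call. = FALSE)
  out <- expand.grid(replicate = seq_len(replicates), rc = rc_levels)
  out$si <- rep(si_true, each = replicates) +
    if (sigma > 0) stats::rnorm(nrow(out), 0, sigma) else 0
  out[c("rc", "replicate", "si")]
}
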