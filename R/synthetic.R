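#' Configuration for a synthetic EEG cohort
#'
#' Builds a validated configuration for the synthetic three-class EEG cohort
#' generator. Each subject is a 19-channel recording in which every channel
#' is a sum of four narrow-band oscillations (delta, theta, alpha, beta; a
#' random center frequency inside the band and a random phase per channel),
#' 1/f background noise, and sparse high-amplitude spike artifacts.
#'
#' Class structure enters through multiplicative band gains relative to the
#' healthy-control (HC) reference: AD gains are > 1 for delta/theta and < 1
#' for alpha/beta — the classical slowing of EEG rhythms in Alzheimer's
#' disease — and MCI gains sit strictly between HC and AD in every band.
#'
#' Amplitudes are expressed on a normalized recording scale (proportional
#' to microvolts after amplifier gain normalization). The default scale is
#' deliberately small: the adaptive artifact-attenuation rule divides the
#' threshold corridor width by the fixed constant 100, so it attenuates
#' only while `3 * sd(sub-band) < 100` and amplifies beyond that; the
#' defaults keep every sub-band safely inside the attenuating regime (see
#' the methods vignette). All downstream features and classifiers are
#' scale-equivariant, so this choice does not affect class separability.
#'
#' @param n_ad,n_mci,n_hc subject counts per class (defaults 49, 37, 23).
#' @param duration_s recording length in seconds (default 300).
#' @param fs sampling rate in Hz (default 256).
#' @param band_defs named list of band frequency ranges in Hz.
#' @param band_amplitudes named vector of peak oscillation amplitudes in
#'   microvolts for the HC reference.
#' @param class_band_gains named list (HC, MCI, AD) of per-band gain vectors.
#' @param noise_exponent slope of the 1/f background (power ~ 1/f^exponent).
#' @param noise_scale RMS of the background noise in microvolts.
#' @param artifact_rate expected spike artifacts per minute per channel.
#' @param artifact_amplitude peak artifact amplitude in microvolts.
#' @param seed master seed; all per-subject randomness derives from it.
#' @return A list of class `SyntheticCohortConfig`.
#' @examples
#' cfg <- cohortConfig(n_ad = 2, n_mci = 1, n_hc = 1, duration_s = 10)
#' cohort <- generateCohort(cfg)
#' table(cohort$labels)
#' @export
cohortConfig <- function(n_ad = 49, n_mci = 37, n_hc = 23,
                         duration_s = 300, fs = 256,
                         band_defs = list(delta = c(0.5, 4),
                                          theta = c(4, 7),
                                          alpha = c(8, 13),
                                          beta  = c(13, 30)),
                         band_amplitudes = c(delta = 2.5, theta = 2.5,
                                             alpha = 5, beta = 2),
                         class_band_gains = list(
                             HC  = c(delta = 1,    theta = 1,    alpha = 1,    beta = 1),
                             MCI = c(delta = 1.20, theta = 1.25, alpha = 0.80, beta = 0.85),
                             AD  = c(delta = 1.40, theta = 1.50, alpha = 0.60, beta = 0.70)),
                         noise_exponent = 1,
                         noise_scale = 2,
                         artifact_rate = 2,
                         artifact_amplitude = 20,
                         seed = 1L) {
    stopifnot(n_ad >= 0, n_mci >= 0, n_hc >= 0,
              duration_s > 0, fs > 0,
              noise_scale >= 0, artifact_rate >= 0)
    bands <- names(band_defs)
    if (!setequal(names(band_amplitudes), bands))
        stop("band_amplitudes must name the same bands as band_defs")
    for (cl in c("HC", "MCI", "AD"))
        if (!setequal(names(class_band_gains[[cl]]), bands))
            stop("class_band_gains$", cl, " must name the same bands as band_defs")
    hi <- vapply(band_defs, max, numeric(1))
    lo <- vapply(band_defs, min, numeric(1))
    if (any(hi > fs / 2)) stop("band ranges must lie below fs/2")
    ord <- order(lo)
    if (any(hi[ord][-length(ord)] > lo[ord][-1]))
        stop("band ranges must not overlap")
    if (any(class_band_gains$HC != 1))
        stop("HC gains must all be 1 (HC is the reference class)")
    structure(list(n_ad = as.integer(n_ad), n_mci = as.integer(n_mci),
                   n_hc = as.integer(n_hc),
                   duration_s = duration_s, fs = fs,
                   band_defs = band_defs,
                   band_amplitudes = band_amplitudes[bands],
                   class_band_gains = lapply(class_band_gains, `[`, bands),
                   noise_exponent = noise_exponent,
                   noise_scale = noise_scale,
                   artifact_rate = artifact_rate,
                   artifact_amplitude = artifact_amplitude,
                   seed = as.integer(seed)),
              class = "SyntheticCohortConfig")
}

# Evaluate expr with a private RNG state seeded from `seed`, restoring the
# caller's state afterwards.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Cohort labels in generation order
#'
#' @param config a [cohortConfig()] object.
#' @return Character vector of length `n_ad + n_mci + n_hc` with labels in
#'   the fixed generation order AD, MCI, HC.
#' @export
cohortLabels <- function(config) {
    rep(c("AD", "MCI", "HC"),
        times = c(config$n_ad, config$n_mci, config$n_hc))
}

#' Per-subject seeds derived from the master seed
#'
#' Counter-based derivation: subject i receives
#' `(seed * 48271 + i * 16807) mod (2^31 - 1)`, so cohorts are reproducible
#' and subjects mutually independent.
#'
#' @param config a [cohortConfig()] object.
#' @return Integer vector of per-subject seeds.
#' @export
subjectSeeds <- function(config) {
    n <- config$n_ad + config$n_mci + config$n_hc
    m <- 2147483647
    s <- (as.numeric(config$seed) %% m) * 48271 %% m
    as.integer((s + seq_len(n) * 16807) %% m)
}

#' Generate one synthetic EEG subject
#'
#' Each of the 19 montage channels is built independently as the sum of four
#' band-limited oscillations (one random center frequency and phase per
#' channel and band, amplitudes scaled by the class band gains), spectrally
#' shaped 1/f noise, and Poisson-placed triangular spike artifacts of
#' 50-100 ms duration and random sign. Output is fully determined by
#' `subject_seed`.
#'
#' @param label `"HC"`, `"MCI"` or `"AD"`.
#' @param config a [cohortConfig()] object.
#' @param subject_seed integer seed for this subject.
#' @return A [Recording-class] with 19 channels.
#' @export
generateSubject <- function(label, config, subject_seed) {
    if (!label %in% c("HC", "MCI", "AD"))
        stop("unknown class label: ", label)
    gains <- config$class_band_gains[[label]]
    n <- round(config$duration_s * config$fs)
    fs <- config$fs
    chans <- montageChannels()
    nc <- length(chans)
    bands <- names(config$band_defs)
    t <- (seq_len(n) - 1) / fs
    .withSeed(subject_seed, {
        mat <- matrix(0, n, nc, dimnames = list(NULL, chans))
        # band oscillations: one random center frequency and phase per
        # channel and band, drawn channel-major for reproducibility
        for (ch in seq_len(nc)) {
            x <- numeric(n)
            for (b in bands) {
                rng <- config$band_defs[[b]]
                f0 <- runif(1, rng[1], rng[2])
                ph <- runif(1, 0, 2 * pi)
                x <- x + gains[[b]] * config$band_amplitudes[[b]] *
                    sin(2 * pi * f0 * t + ph)
            }
            mat[, ch] <- x
        }
        if (config$noise_scale > 0)
            mat <- mat + .oneOverFNoise(n, nc, fs, config$noise_exponent,
                                        config$noise_scale)
        if (config$artifact_rate > 0)
            for (ch in seq_len(nc))
                mat[, ch] <- mat[, ch] +
                    .spikeTrain(n, fs, config$artifact_rate,
                                config$artifact_amplitude)
        Recording(mat, fs)
    })
}

# 1/f^exponent noise for nc channels at once, by spectral shaping of white
# noise, each channel scaled to the requested RMS.
.oneOverFNoise <- function(n, nc, fs, exponent, rms) {
    w <- matrix(rnorm(n * nc), n, nc)
    W <- stats::mvfft(w)
    f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
    shape <- c(0, f[-1]^(-exponent / 2))
    x <- Re(stats::mvfft(W * shape, inverse = TRUE)) / n
    sweep(x, 2, apply(x, 2, stats::sd) / rms, "/")
}

# Sparse triangular spike transients: Poisson count, uniform positions,
# width uniform in 50-100 ms, random sign.
.spikeTrain <- function(n, fs, rate_per_min, amplitude) {
    x <- numeric(n)
    k <- rpois(1, rate_per_min * n / fs / 60)
    if (k == 0) return(x)
    for (i in seq_len(k)) {
        width <- round(runif(1, 0.05, 0.1) * fs)
        center <- sample.int(n, 1)
        half <- width %/% 2
        idx <- (center - half):(center + half)
        tri <- 1 - abs(seq(-half, half)) / (half + 1)
        ok <- idx >= 1 & idx <= n
        x[idx[ok]] <- x[idx[ok]] + sample(c(-1, 1), 1) * amplitude * tri[ok]
    }
    x
}

#' Generate a full synthetic cohort
#'
#' Generates `n_ad + n_mci + n_hc` subjects (order AD, MCI, HC) with
#' per-subject seeds derived from the master seed via [subjectSeeds()].
#' For large cohorts consider iterating [generateSubject()] with
#' [cohortLabels()] and [subjectSeeds()] instead of materializing every
#' recording at once.
#'
#' @param config a [cohortConfig()] object.
#' @return A list with elements `recordings` (list of [Recording-class])
#'   and `labels` (character vector).
#' @export
generateCohort <- function(config) {
    labels <- cohortLabels(config)
    seeds <- subjectSeeds(config)
    recs <- lapply(seq_along(labels), function(i)
        generateSubject(labels[i], config, seeds[i]))
    list(recordings = recs, labels = labels)
}
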