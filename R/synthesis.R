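#' Harmonic partial frequencies below the Nyquist limit
#'
#' Returns `n * f0` for `n = 1 ... n_max`, where `n_max` is the largest
#' integer with `n * f0` strictly below the Nyquist frequency. A component at
#' exactly Nyquist is unrepresentable in sine phase, so the bound is strict.
#'
#' @param f0 fundamental frequency in Hz (`0 < f0 < nyquist`).
#' @param cfg a [synth_config()].
#' @return numeric vector of partial frequencies in Hz.
#' @export
make_harmonic_partials <- function(f0, cfg = synth_config()) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0 || f0 >= cfg$nyquist) {
    stop("f0 must be a single frequency in (0, nyquist)")
  }
  n_max <- ceiling(cfg$nyquist / f0) - 1L
  # guard against f0 dividing nyquist exactly under floating point
  if (n_max * f0 >= cfg$nyquist) n_max <- n_max - 1L
  (1:n_max) * f0
}

#' Draw a per-partial jitter pattern by rejection sampling
#'
#' A jitter pattern is one multiplicative perturbation `u[n]` per harmonic
#' index `n`; the fundamental is never jittered (`u[1] = 0`) and `u[n]` for
#' `n >= 2` is uniform on `(jitter_low, jitter_high)`. Because one pattern is
#' carried across every fundamental in a stimulus block, a candidate is
#' accepted only if, for EVERY F0 on `cfg$f0_grid`, the surviving jittered
#' partials (those still below Nyquist) are pairwise spaced at least
#' `cfg$min_spacing` Hz apart. On any conflict the whole pattern is redrawn.
#'
#' @param cfg a [synth_config()].
#' @param n_partials number of entries in the pattern (`>= 1`). Defaults to
#'   the maximum harmonic count over the F0 grid, so the pattern can be
#'   applied to any grid F0.
#' @param seed optional integer seed recorded in the pattern; `NULL` draws
#'   from (and records nothing about) the current RNG stream.
#' @param max_draws rejection-sampling cap on whole-pattern draws.
#' @return an object of class `jitter_pattern` with fields `values`,
#'   `pattern_id`, `rng_seed`.
#' @export
draw_jitter_pattern <- function(cfg = synth_config(), n_partials = NULL,
                                seed = NULL, max_draws = 10000) {
  if (is.null(n_partials)) {
    n_partials <- length(make_harmonic_partials(min(cfg$f0_grid), cfg))
  }
  stopifnot(n_partials >= 1)
  values <- with_seed(seed, {
    ok <- FALSE
    for (draw in seq_len(max_draws)) {
      u <- c(0, stats::runif(n_partials - 1L, cfg$jitter_low, cfg$jitter_high))
      if (jitter_pattern_valid(u, cfg)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("rejection sampling exhausted after ", max_draws, " pattern draws")
    }
    u
  })
  structure(
    list(
      values = values,
      pattern_id = paste0("jp-", substr(digest_vec(values), 1, 12)),
      rng_seed = seed
    ),
    class = "jitter_pattern"
  )
}

# Spacing check behind the rejection sampler: pattern must be usable at every
# grid F0 (the same jittering is carried from one fundamental to the next).
jitter_pattern_valid <- function(u, cfg) {
  for (f0 in cfg$f0_grid) {
    n <- min(length(u), length(make_harmonic_partials(f0, cfg)))
    freqs <- (1:n) * f0 * (1 + u[1:n])
    freqs <- sort(freqs[freqs < cfg$nyquist])
    if (length(freqs) > 1L && min(diff(freqs)) < cfg$min_spacing) return(FALSE)
  }
  TRUE
}

# cheap deterministic id for a numeric vector (no digest dependency):
# two rolling polynomial hashes over the byte representation, mod 2^31 - 1
digest_vec <- function(x) {
  b <- as.integer(writeBin(as.double(x), raw()))
  h1 <- 0
  h2 <- 7
  for (v in b) {
    h1 <- (h1 * 31 + v) %% 2147483647
    h2 <- (h2 * 131 + v) %% 2147483647
  }
  paste0(sprintf("%08x", h1), sprintf("%08x", h2))
}

#' Apply a jitter pattern to the harmonic series of an F0
#'
#' Partial `n` is moved to `n * f0 * (1 + u[n])`; the fundamental is left
#' untouched (`u[1] = 0`). Jittered partials landing at or above Nyquist are
#' dropped, and the result is sorted ascending.
#'
#' @param f0 fundamental frequency in Hz.
#' @param pattern a [draw_jitter_pattern()] result, or `NULL` for a harmonic
#'   (identity) spectrum.
#' @param cfg a [synth_config()].
#' @param condition condition label stored on the tone specification.
#' @return an object of class `tone_spec` with fields `f0`, `partial_freqs`,
#'   `partial_amps`, `phase`, `condition`, `pattern_id`.
#' @export
apply_jitter <- function(f0, pattern = NULL, cfg = synth_config(),
                         condition = if (is.null(pattern)) "harmonic" else "inharmonic") {
  harm <- make_harmonic_partials(f0, cfg)
  if (is.null(pattern)) {
    freqs <- harm
    pid <- NA_character_
  } else {
    u <- pattern$values
    if (length(u) < length(harm)) {
      stop("pattern has ", length(u), " entries but ", length(harm),
           " partials are needed for f0 = ", f0)
    }
    n <- length(harm)
    freqs <- harm * (1 + u[1:n])
    freqs <- sort(freqs[freqs < cfg$nyquist])
    pid <- pattern$pattern_id
  }
  if (length(freqs) > 1L && min(diff(freqs)) < cfg$min_spacing) {
    stop("jittered partials violate the ", cfg$min_spacing,
         " Hz minimum spacing; pattern should have been rejected upstream")
  }
  structure(
    list(
      f0 = f0,
      partial_freqs = freqs,
      partial_amps = rep(1, length(freqs)),
      phase = "sine",
      condition = condition,
      pattern_id = pid
    ),
    class = "tone_spec"
  )
}

#' Synthesize a complex tone from a tone specification
#'
#' Sums equal-amplitude zero-phase sines at the specified partial frequencies,
#' applies the on/off ramp envelope, and scales by `1 / n_partials` so the
#' raw (pre-normalization) waveform stays in `[-1, 1]`.
#'
#' @param spec a [apply_jitter()] tone spec.
#' @param cfg a [synth_config()].
#' @return an object of class `waveform`: list with `samples`, `sample_rate`.
#' @export
synthesize_tone <- function(spec, cfg = synth_config()) {
  stopifnot(inherits(spec, "tone_spec"))
  if (length(spec$partial_freqs) == 0L) stop("empty partial list")
  n <- round(cfg$duration * cfg$sample_rate)
  t <- (0:(n - 1)) / cfg$sample_rate
  # one outer product: time x partials, then weighted row sums
  ph <- outer(t, 2 * pi * spec$partial_freqs)
  x <- as.vector(sin(ph) %*% spec$partial_amps) / sum(spec$partial_amps)
  x <- x * ramp_envelope(n, cfg)
  structure(list(samples = x, sample_rate = cfg$sample_rate),
            class = "waveform")
}

ramp_envelope <- function(n, cfg) {
  nr <- round(cfg$ramp * cfg$sample_rate)
  env <- rep(1, n)
  if (nr > 0) {
    up <- if (cfg$ramp_shape == "linear") {
      seq(0, 1, length.out = nr)
    } else {
      0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    }
    env[1:nr] <- up
    env[(n - nr + 1):n] <- rev(up)
  }
  env
}

#' Build the per-F0 sound pool
#'
#' Writes one harmonic WAV per grid F0 plus `n_inharmonic_per_f0` jittered
#' WAVs per F0 to `out_dir`, each loudness-normalized to the configured
#' target. Jitter patterns are shared across F0s (the same pattern is applied
#' to every fundamental, as in a stimulus block). A CSV manifest mapping
#' `file, f0_hz, condition, pattern_id, seed` is written alongside.
#'
#' @param cfg a [synth_config()].
#' @param n_inharmonic_per_f0 number of inharmonic exemplars per F0.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; the pool is byte-reproducible given the seed.
#' @param write_wavs set `FALSE` to skip disk output and return waveforms
#'   in memory (manifest gains a `waveform` list-column).
#' @param keep_partials if `TRUE`, the manifest gains a `partials`
#'   list-column with each sound's sorted surviving partial frequencies
#'   (its spectral recipe), used by the partial-series entropy summary.
#' @return the manifest as a data.frame, invisibly annotated with
#'   `attr(, "out_dir")`.
#' @export
build_sound_pool <- function(cfg = synth_config(), n_inharmonic_per_f0 = 100,
                             out_dir = NULL, seed = 1, write_wavs = TRUE,
                             keep_partials = FALSE) {
  stopifnot(n_inharmonic_per_f0 >= 1)
  if (write_wavs) {
    if (is.null(out_dir)) stop("out_dir required when write_wavs = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  }
  rows <- list()
  waves <- list()
  partials <- list()
  with_seed(seed, {
    patterns <- replicate(n_inharmonic_per_f0,
                          draw_jitter_pattern(cfg), simplify = FALSE)
    k <- 0L
    for (f0 in cfg$f0_grid) {
      specs <- c(list(apply_jitter(f0, NULL, cfg)),
                 lapply(patterns, function(p) apply_jitter(f0, p, cfg)))
      for (sp in specs) {
        k <- k + 1L
        w <- normalize_loudness(synthesize_tone(sp, cfg), cfg$target_loudness)
        fname <- sprintf("%s_f0-%d_%s.wav", sp$condition, as.integer(f0),
                         if (is.na(sp$pattern_id)) "h" else sp$pattern_id)
        if (write_wavs) {
          write_wav(w$samples, file.path(out_dir, fname), cfg$sample_rate)
        } else {
          waves[[k]] <- w
        }
        if (keep_partials) partials[[k]] <- sp$partial_freqs
        rows[[k]] <- data.frame(
          file = fname, f0_hz = f0, condition = sp$condition,
          pattern_id = sp$pattern_id, seed = seed,
          partials_hz = paste(format(sp$partial_freqs, digits = 15,
                                     trim = TRUE, scientific = FALSE),
                              collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  })
  manifest <- do.call(rbind, rows)
  if (write_wavs) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    attr(manifest, "out_dir") <- out_dir
  } else {
    manifest$waveform <- waves
  }
  if (keep_partials) manifest$partials <- partials
  manifest
}
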