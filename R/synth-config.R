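#' Synthesis configuration for complex-tone stimuli
#'
#' Bundles the constants of the tone-synthesis procedure: 70-ms tones built
#' from partials up to the Nyquist limit at a 48-kHz sampling rate, 5-ms
#' on/off ramps, loudness normalization to -12 LUFS, a fundamental-frequency
#' grid of 500-800 Hz in 50-Hz steps, per-partial jitter drawn from
#' U(-0.5, 0.5), and a 30-Hz minimum spacing between jittered partials.
#'
#' @param sample_rate sampling rate in Hz.
#' @param duration tone duration in seconds.
#' @param ramp onset/offset ramp duration in seconds (`2 * ramp <= duration`).
#' @param target_loudness loudness-normalization target in LUFS.
#' @param bit_depth bit depth of written WAV files.
#' @param f0_grid strictly increasing vector of fundamental frequencies (Hz).
#' @param jitter_low,jitter_high bounds of the uniform jitter distribution.
#' @param min_spacing minimum allowed gap between jittered partials (Hz).
#' @param ramp_shape `"linear"` or `"cosine"` (raised-cosine) ramps.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 48000,
                         duration = 0.070,
                         ramp = 0.005,
                         target_loudness = -12,
                         bit_depth = 16,
                         f0_grid = seq(500, 800, by = 50),
                         jitter_low = -0.5,
                         jitter_high = 0.5,
                         min_spacing = 30,
                         ramp_shape = c("linear", "cosine")) {
  ramp_shape <- match.arg(ramp_shape)
  stopifnot(
    sample_rate > 0, duration > 0, ramp > 0, 2 * ramp <= duration,
    all(f0_grid > 0), !is.unsorted(f0_grid, strictly = TRUE),
    jitter_low < jitter_high, min_spacing > 0, bit_depth == 16
  )
  structure(
    list(
      sample_rate = sample_rate,
      nyquist = sample_rate / 2,
      duration = duration,
      ramp = ramp,
      target_loudness = target_loudness,
      bit_depth = bit_depth,
      f0_grid = f0_grid,
      jitter_low = jitter_low,
      jitter_high = jitter_high,
      min_spacing = min_spacing,
      ramp_shape = ramp_shape
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %g Hz, %g ms tones, %g ms %s ramps\n",
              x$sample_rate, 1000 * x$duration, 1000 * x$ramp, x$ramp_shape))
  cat(sprintf("  F0 grid: %s Hz\n", paste(x$f0_grid, collapse = ", ")))
  cat(sprintf("  jitter U(%g, %g), min spacing %g Hz, target %g LUFS\n",
              x$jitter_low, x$jitter_high, x$min_spacing, x$target_loudness))
  invisible(x)
}

# Restore RNG state on exit when a function accepts an explicit seed.
# With seed = NULL the caller's RNG stream is consumed as usual.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
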