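#' Approximate-entropy configuration
#'
#' Defaults follow the common reference implementation: embedding dimension
#' `m = 2`, tolerance `r = 0.2` times the (population) standard deviation of
#' the series, Chebyshev distance.
#'
#' @param embed_m embedding dimension (`>= 1`).
#' @param tolerance_r tolerance as a fraction of the signal SD (`> 0`), or
#'   the absolute tolerance when `relative = FALSE`.
#' @param relative whether `tolerance_r` is SD-relative.
#' @return an object of class `apen_config`.
#' @export
apen_config <- function(embed_m = 2L, tolerance_r = 0.2, relative = TRUE) {
  stopifnot(embed_m >= 1, tolerance_r > 0)
  structure(list(embed_m = as.integer(embed_m), tolerance_r = tolerance_r,
                 relative = relative),
            class = "apen_config")
}

#' Approximate entropy of a time series
#'
#' Pincus' ApEn: `Phi_m(r) - Phi_{m+1}(r)` with Chebyshev distance and
#' self-matches included. Low values indicate a regular (e.g. periodic)
#' series; disorder increases ApEn.
#'
#' @param x numeric vector, `length(x) > embed_m + 1`.
#' @param cfg an [apen_config()].
#' @return ApEn (unitless scalar).
#' @export
approximate_entropy <- function(x, cfg = apen_config()) {
  stopifnot(is.numeric(x))
  if (length(x) <= cfg$embed_m + 1L) {
    stop("series too short: need length > embed_m + 1")
  }
  if (cfg$relative) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("constant series: SD-relative tolerance undefined")
    r <- cfg$tolerance_r * s
  } else {
    r <- cfg$tolerance_r
  }
  apen_cpp(as.numeric(x), cfg$embed_m, r)
}

#' Approximate-entropy summary of a sound pool
#'
#' Computes ApEn on every (normalized) waveform of a pool built by
#' [build_sound_pool()] and summarizes per condition and F0, plus per
#' condition overall. The harmonic condition has a single exemplar per F0,
#' so its per-F0 SD is `NA` and its overall spread is across F0s.
#'
#' @param pool a manifest data.frame from [build_sound_pool()]. If it has no
#'   `waveform` column, WAVs are read from `dir` (or `attr(pool, "out_dir")`).
#' @param cfg an [apen_config()].
#' @param dir directory holding the pool WAV files.
#' @param on what to treat as the sound's time series: `"waveform"` (the
#'   full normalized 70-ms waveform) or `"partials"` (the sorted series of
#'   surviving partial frequencies, i.e. the sound's spectral recipe). The
#'   waveform reading is the face-value one; the partial-series reading is
#'   the only one whose pool summary lands on the scale the study reports
#'   (see the methods vignette), because a 48-kHz broadband waveform is
#'   sample-to-sample unpredictable regardless of harmonicity.
#' @param downsample optional integer decimation factor applied to the
#'   waveform before ApEn (default 1 = none).
#' @param synth_cfg a [synth_config()], used to rebuild partial series from
#'   the manifest when `on = "partials"` and the pool lacks waveforms.
#' @return list with `per_f0` (condition, f0_hz, mean, sd, n) and `overall`
#'   (condition, mean, sd, n) data.frames, plus `values` (per-sound ApEn
#'   appended to the manifest columns).
#' @export
pool_entropy_summary <- function(pool, cfg = apen_config(), dir = NULL,
                                 on = c("waveform", "partials"),
                                 downsample = 1L,
                                 synth_cfg = synth_config()) {
  on <- match.arg(on)
  stopifnot(nrow(pool) > 0)
  if (on == "partials") {
    get_series <- if (!is.null(pool[["partials"]])) {
      function(i) pool[["partials"]][[i]]
    } else if (!is.null(pool[["partials_hz"]])) {
      function(i) as.numeric(strsplit(pool[["partials_hz"]][i], ";")[[1]])
    } else {
      stop("pool manifest carries no partial series; rebuild the pool")
    }
  } else if (!is.null(pool$waveform)) {
    get_series <- function(i) pool$waveform[[i]]$samples
  } else {
    d <- if (is.null(dir)) attr(pool, "out_dir") else dir
    if (is.null(d)) stop("pool has no waveforms and no directory is known")
    get_series <- function(i) read_wav(file.path(d, pool$file[i]))$samples
  }
  apen <- vapply(seq_len(nrow(pool)), function(i) {
    x <- get_series(i)
    if (on == "waveform" && downsample > 1L) {
      x <- x[seq(1L, length(x), by = downsample)]
    }
    approximate_entropy(x, cfg)
  }, numeric(1))

  values <- data.frame(
    file = pool$file, f0_hz = pool$f0_hz, condition = pool$condition,
    apen = apen, stringsAsFactors = FALSE
  )
  per_f0 <- do.call(rbind, lapply(
    split(values, list(values$condition, values$f0_hz), drop = TRUE),
    function(g) data.frame(
      condition = g$condition[1], f0_hz = g$f0_hz[1],
      mean = mean(g$apen),
      sd = if (nrow(g) > 1) stats::sd(g$apen) else NA_real_,
      n = nrow(g), stringsAsFactors = FALSE
    )
  ))
  per_f0 <- per_f0[order(per_f0$condition, per_f0$f0_hz), ]
  rownames(per_f0) <- NULL
  overall <- do.call(rbind, lapply(split(values, values$condition), function(g) {
    # inharmonic: mean/SD of the per-F0 distribution means, matching how the
    # per-F0 violin summaries collapse; harmonic: across its 7 single values
    pf <- per_f0[per_f0$condition == g$condition[1], ]
    data.frame(condition = g$condition[1],
               mean = mean(pf$mean), sd = stats::sd(pf$mean),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(overall) <- NULL
  list(per_f0 = per_f0, overall = overall, values = values)
}
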