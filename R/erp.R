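#' ERP analysis configuration
#'
#' Windows and constants of the peak-measure pipeline: zero-phase 30-Hz
#' low-pass, 100-ms pre-stimulus baseline, MMN peak search in 70-250 ms
#' (most negative), P3a in 150-400 ms (most positive), mean amplitude over
#' the 50-ms window centered at the peak, and a fixed 141-ms center for the
#' P2 window.
#'
#' @param lowpass low-pass cutoff in Hz.
#' @param filter_order Butterworth order (applied forward-backward).
#' @param baseline baseline window in ms, `c(start, end)`.
#' @param mmn_window,p3a_window peak-search windows in ms.
#' @param mean_amp_halfwidth half-width of the mean-amplitude window in ms.
#' @param p2_latency global grand-average P2 peak latency in ms.
#' @param p2_halfwidth half-width of the P2 averaging window in ms.
#' @param roi frontocentral channel names.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(lowpass = 30, filter_order = 4,
                            baseline = c(-100, 0),
                            mmn_window = c(70, 250),
                            p3a_window = c(150, 400),
                            mean_amp_halfwidth = 25,
                            p2_latency = 141, p2_halfwidth = 25,
                            roi = c("F3", "Fz", "F4", "FC1", "FC2")) {
  stopifnot(lowpass > 0, filter_order >= 1, mean_amp_halfwidth > 0,
            p2_halfwidth > 0, baseline[1] < baseline[2],
            mmn_window[1] < mmn_window[2], p3a_window[1] < p3a_window[2])
  structure(list(lowpass = lowpass, filter_order = filter_order,
                 baseline = baseline, mmn_window = mmn_window,
                 p3a_window = p3a_window,
                 mean_amp_halfwidth = mean_amp_halfwidth,
                 p2_latency = p2_latency, p2_halfwidth = p2_halfwidth,
                 roi = roi),
            class = "analysis_config")
}

# zero-phase Butterworth low-pass along the last margin of a matrix
# (rows = channels, cols = time) or a vector
lowpass_matrix <- function(x, srate, cutoff, order = 4) {
  if (cutoff >= srate / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff / (srate / 2), type = "low")
  filt1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Low-pass filter an epoch set
#'
#' Zero-phase (forward-backward) Butterworth low-pass applied per trial and
#' channel. DC is preserved.
#'
#' @param epochs an `epoch_set` (see [simulate_subject()]).
#' @param cfg an [analysis_config()].
#' @return the filtered `epoch_set`.
#' @export
lowpass_epochs <- function(epochs, cfg = analysis_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  srate <- epochs$srate
  if (cfg$lowpass >= srate / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(cfg$filter_order, cfg$lowpass / (srate / 2), "low")
  d <- epochs$data
  dm <- dim(d)
  # filter along time for every trial x channel
  m <- matrix(aperm(d, c(3, 1, 2)), nrow = dm[3])
  for (j in seq_len(ncol(m))) m[, j] <- signal::filtfilt(bf, m[, j])
  epochs$data <- aperm(array(m, c(dm[3], dm[1], dm[2])), c(2, 3, 1))
  epochs
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#'
#' @param epochs an `epoch_set`.
#' @param cfg an [analysis_config()].
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, cfg = analysis_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times >= cfg$baseline[1] & epochs$times <= cfg$baseline[2]
  if (!any(sel)) stop("baseline window outside epoch")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over time (3rd dim)
  epochs
}

#' Average selected trials into an ERP
#'
#' @param epochs an `epoch_set`.
#' @param selector logical vector over trials, or a function of the label
#'   data.frame returning one (e.g. `function(l) l$role == "standard"`).
#' @return an object of class `erp`: list with `data` (channels x time
#'   matrix), `n_trials`, `times`, `montage`, `provenance`.
#' @export
average_erp <- function(epochs, selector) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- if (is.function(selector)) selector(epochs$labels) else selector
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("empty selection: no trials match")
  d <- epochs$data[keep, , , drop = FALSE]
  m <- matrix(colMeans(matrix(d, nrow = dim(d)[1])), dim(d)[2], dim(d)[3])
  rownames(m) <- epochs$montage$names
  structure(list(data = m, n_trials = sum(keep), times = epochs$times,
                 montage = epochs$montage,
                 provenance = list(subject = epochs$subject_id)),
            class = "erp")
}

#' Difference wave between two ERPs
#'
#' Elementwise `a - b`; covers both deviant-minus-standard (mismatch) and
#' cross-condition (ORN) contrasts.
#'
#' @param a,b `erp` objects on matching montage and time axes.
#' @return an `erp`.
#' @export
difference_wave <- function(a, b) {
  stopifnot(inherits(a, "erp"), inherits(b, "erp"))
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$times, b$times)) ||
      !identical(a$montage$names, b$montage$names)) {
    stop("ERPs have mismatching axes")
  }
  out <- a
  out$data <- a$data - b$data
  out$n_trials <- NA_integer_
  out$provenance <- list(a = a$provenance, b = b$provenance, op = "difference")
  out
}

#' Mean trace over a region of interest
#'
#' Unweighted mean over the named channels.
#'
#' @param erp an `erp`, or a channels x time matrix with channel rownames.
#' @param roi channel names.
#' @return numeric time series.
#' @export
roi_trace <- function(erp, roi) {
  m <- if (inherits(erp, "erp")) erp$data else erp
  missing <- setdiff(roi, rownames(m))
  if (length(missing)) stop("unknown channels: ", paste(missing, collapse = ", "))
  colMeans(m[roi, , drop = FALSE])
}

#' Peak latency and mean amplitude of MMN or P3a
#'
#' Finds the most negative (MMN) or most positive (P3a) sample within the
#' component window (ties broken to the earliest sample) and averages the
#' trace over the 50-ms window centered at that latency, clipping the
#' averaging window at the epoch edges if necessary (`clipped` flag).
#'
#' @param trace numeric ROI time series.
#' @param times time axis in ms, same length as `trace`.
#' @param component `"mmn"` or `"p3a"`.
#' @param cfg an [analysis_config()].
#' @return list with `latency_ms`, `mean_amp`, `peak_amp`, `clipped`,
#'   `flat` (all-equal trace tie-break flag).
#' @export
peak_and_mean_amplitude <- function(trace, times, component = c("mmn", "p3a"),
                                    cfg = analysis_config()) {
  component <- match.arg(component)
  stopifnot(length(trace) == length(times))
  win <- if (component == "mmn") cfg$mmn_window else cfg$p3a_window
  sel <- which(times >= win[1] & times <= win[2])
  if (!length(sel)) stop("component window outside trace")
  v <- trace[sel]
  k <- if (component == "mmn") which.min(v) else which.max(v)  # earliest tie
  flat <- length(unique(v)) == 1L
  lat <- times[sel[k]]
  res <- window_mean(trace, times, lat, cfg$mean_amp_halfwidth)
  list(latency_ms = lat, mean_amp = res$mean, peak_amp = v[k],
       clipped = res$clipped, flat = flat)
}

#' P2 mean amplitude around the fixed grand-average latency
#'
#' Mean of a standard or deviant ROI trace (not a difference wave) over the
#' window centered at the global grand-average P2 peak latency (141 ms).
#'
#' @param trace numeric ROI time series.
#' @param times time axis in ms.
#' @param cfg an [analysis_config()].
#' @return mean amplitude (scalar).
#' @export
p2_mean_amplitude <- function(trace, times, cfg = analysis_config()) {
  window_mean(trace, times, cfg$p2_latency, cfg$p2_halfwidth)$mean
}

window_mean <- function(trace, times, center, halfwidth) {
  sel <- times >= center - halfwidth & times <= center + halfwidth
  clipped <- (center - halfwidth) < times[1] || (center + halfwidth) > times[length(times)]
  list(mean = mean(trace[sel]), clipped = clipped)
}
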