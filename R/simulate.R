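#' ERP component templates
#'
#' Gaussian time courses with frontocentral Gaussian topographies. Latencies
#' are seeded from the grand-average findings the generator emulates: N1 at
#' 100 ms, P2 at 141 ms, an MMN centered in the 120-180 ms negativity range,
#' a P3a centered in the 216-286 ms positivity range, and an ORN in the P2
#' latency range. Widths are Gaussian SDs in ms.
#'
#' @return data.frame with `name`, `latency_ms`, `width_ms`, `deviant_only`.
#' @export
erp_components <- function() {
  data.frame(
    name = c("N1", "P2", "MMN", "P3a", "ORN"),
    latency_ms = c(100, 141, 150, 250, 141),
    width_ms = c(25, 40, 25, 40, 25),
    deviant_only = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default condition-by-component amplitude table
#'
#' Amplitudes in microvolts for each component in each harmonicity
#' condition, separately for standards and (first-order) deviants. The
#' pattern mirrors the phenomenon under study: an N1-P2 base response on
#' every tone; an MMN and P3a on deviants in the harmonic and inharmonic
#' conditions but no deviance response at all in the changing condition
#' (where the per-sound jitter makes F0 changes undetectable); and an
#' ORN-like negativity on every inharmonic and changing tone.
#'
#' @return data.frame with `component`, `condition`, `standard`, `deviant`
#'   (µV).
#' @export
default_effect_table <- function() {
  conds <- c("harmonic", "inharmonic", "changing")
  rbind(
    data.frame(component = "N1", condition = conds,
               standard = -2, deviant = -2),
    data.frame(component = "P2", condition = conds,
               standard = 2, deviant = 2),
    data.frame(component = "MMN", condition = conds,
               standard = 0, deviant = c(-1.0, -0.7, 0)),
    data.frame(component = "P3a", condition = conds,
               standard = 0, deviant = c(0.8, 2.0, 0)),
    data.frame(component = "ORN", condition = conds,
               standard = c(0, -1.0, -1.0), deviant = c(0, -1.0, -1.0))
  )
}

#' Simulation design for the synthetic EEG study
#'
#' @param n_subjects number of simulated participants.
#' @param effect_table amplitude table, see [default_effect_table()].
#' @param subject_sd SD (µV) of the per-subject, per-component amplitude
#'   intercept (shared across conditions).
#' @param subject_cond_sd SD (µV) of the per-subject, per-component,
#'   per-condition amplitude deviation; this is what sets the error term of
#'   the within-subject condition contrasts.
#' @param noise_white_sd,noise_pink_sd single-trial per-channel noise SDs
#'   (µV) for the white and 1/f components.
#' @param window epoch window in ms, `c(start, end)`.
#' @param srate sampling rate in Hz.
#' @param montage a [default_montage()]-style montage.
#' @param paradigm a [paradigm_config()]; each subject's trial labels come
#'   from one generated block per condition.
#' @param seed integer master seed; per-subject seeds derive from it.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n_subjects = 35,
                              effect_table = default_effect_table(),
                              subject_sd = 0.25,
                              subject_cond_sd = 0.8,
                              noise_white_sd = 3,
                              noise_pink_sd = 3,
                              window = c(-100, 450),
                              srate = 1000,
                              montage = default_montage(),
                              paradigm = paradigm_config(),
                              seed = 1905) {
  stopifnot(n_subjects >= 2, window[1] < 0, window[2] > 0, srate > 0)
  structure(
    list(n_subjects = as.integer(n_subjects), effect_table = effect_table,
         subject_sd = subject_sd, subject_cond_sd = subject_cond_sd,
         noise_white_sd = noise_white_sd, noise_pink_sd = noise_pink_sd,
         window = window, srate = srate, montage = montage,
         paradigm = paradigm, seed = as.integer(seed)),
    class = "simulation_design"
  )
}

design_times <- function(design) {
  seq(design$window[1], design$window[2], by = 1000 / design$srate)
}

subject_seed <- function(design, subject_id) {
  as.integer((as.numeric(design$seed) + 7919 * subject_id) %% 2147483647)
}

# Gaussian topography on the unit disc, centered between Fz and FCz
component_topography <- function(montage, center = c(0, 0.37), spread = 0.45) {
  d2 <- (montage$pos[, 1] - center[1])^2 + (montage$pos[, 2] - center[2])^2
  w <- exp(-d2 / (2 * spread^2))
  names(w) <- montage$names
  w
}

# component time courses: time x component matrix of unit-peak Gaussians
component_timecourses <- function(times, comps = erp_components()) {
  g <- sapply(seq_len(nrow(comps)), function(i) {
    exp(-(times - comps$latency_ms[i])^2 / (2 * comps$width_ms[i]^2))
  })
  colnames(g) <- comps$name
  g
}

# 1/f ("pink") noise, time x n matrix with unit expected column SD.
# Synthesized at the next 2-3-5-smooth length (mixed-radix FFTs at awkward
# prime lengths are an order of magnitude slower) and truncated.
pink_noise_matrix <- function(n_time, n_cols) {
  nf <- stats::nextn(n_time, c(2, 3, 5))
  w <- matrix(stats::rnorm(nf * n_cols), nf, n_cols)
  f <- seq_len(nf) - 1L
  f <- pmin(f, nf - f)              # two-sided frequency index
  sc <- ifelse(f == 0, 0, 1 / sqrt(f))
  sc <- sc / sqrt(mean(sc^2))       # unit expected variance
  fw <- stats::mvfft(w) * sc
  out <- Re(stats::mvfft(fw, inverse = TRUE)) / nf
  out[seq_len(n_time), , drop = FALSE]
}

#' Simulate one participant's epoched EEG
#'
#' Each trial is the superposition of the component templates (Gaussian
#' time course x frontocentral topography x amplitude) plus per-channel
#' 1/f and white noise. Component amplitudes are the effect-table values for
#' the trial's condition and role, offset by a per-subject intercept
#' (`subject_sd`) and a per-subject-per-condition deviation
#' (`subject_cond_sd`). MMN and P3a are injected on first-order deviants
#' only. Deterministic given `(design$seed, subject_id)`.
#'
#' @param design a [simulation_design()].
#' @param subject_id integer subject index.
#' @param event_tables named list of `event_table`s (one per condition);
#'   generated from the design's paradigm config when `NULL`.
#' @return an object of class `epoch_set`: list with `data` (trials x
#'   channels x time, µV), `labels`, `times`, `srate`, `montage`,
#'   `subject_id`.
#' @export
simulate_subject <- function(design, subject_id, event_tables = NULL) {
  ctx <- subject_context(design, subject_id, event_tables)
  conds <- c("harmonic", "inharmonic", "changing")
  data_list <- lapply(conds, function(cc) condition_epochs(design, ctx, cc))
  labels_list <- lapply(conds, function(cc) {
    tab <- ctx$event_tables[[cc]]
    data.frame(condition = cc, role = tab$role,
               deviant_order = tab$deviant_order, shift_hz = tab$shift_hz,
               stringsAsFactors = FALSE)
  })
  nch <- length(design$montage$names)
  nt <- length(ctx$times)
  ntr_all <- sum(vapply(data_list, function(d) dim(d)[1], integer(1)))
  data <- array(0, c(ntr_all, nch, nt))
  at <- 0L
  for (d in data_list) {
    data[at + seq_len(dim(d)[1]), , ] <- d
    at <- at + dim(d)[1]
  }
  structure(
    list(data = data, labels = do.call(rbind, labels_list),
         times = ctx$times, srate = design$srate, montage = design$montage,
         subject_id = subject_id, seed = ctx$seed),
    class = "epoch_set"
  )
}

# Draw everything subject-level (event tables, amplitude offsets, one RNG
# substream seed per condition) so conditions can be built independently.
subject_context <- function(design, subject_id, event_tables = NULL) {
  sseed <- subject_seed(design, subject_id)
  comps <- erp_components()
  conds <- c("harmonic", "inharmonic", "changing")
  with_seed(sseed, {
    if (is.null(event_tables)) {
      nb <- design$paradigm$n_blocks_per_condition
      event_tables <- lapply(conds, function(cc) {
        blocks <- lapply(seq_len(nb), function(b) generate_block(cc, design$paradigm))
        tab <- do.call(rbind, blocks)
        attr(tab, "config") <- design$paradigm
        tab
      })
      names(event_tables) <- conds
    }
    off_subj <- stats::rnorm(nrow(comps), 0, design$subject_sd)
    off_cond <- matrix(stats::rnorm(nrow(comps) * 3, 0, design$subject_cond_sd),
                       nrow(comps), 3, dimnames = list(comps$name, conds))
    cond_seeds <- sample.int(2147483646, 3)
    list(seed = sseed, times = design_times(design),
         event_tables = event_tables, off_subj = off_subj,
         off_cond = off_cond, cond_seeds = stats::setNames(cond_seeds, conds))
  })
}

# One condition's trials x channels x time array for a subject context
condition_epochs <- function(design, ctx, cc) {
  comps <- erp_components()
  times <- ctx$times
  nt <- length(times)
  mont <- design$montage
  nch <- length(mont$names)
  g <- component_timecourses(times, comps)            # time x comp
  topo <- component_topography(mont)                  # channel
  fields <- t(vapply(seq_len(nrow(comps)), function(i) {
    as.vector(outer(topo, g[, i]))
  }, numeric(nch * nt)))

  tab <- ctx$event_tables[[cc]]
  ntr <- nrow(tab)
  is_dev1 <- !is.na(tab$deviant_order) & tab$deviant_order == 1L
  et <- design$effect_table
  amp <- matrix(0, ntr, nrow(comps))
  ci <- match(cc, colnames(ctx$off_cond))
  for (k in seq_len(nrow(comps))) {
    row <- et[et$component == comps$name[k] & et$condition == cc, ]
    base <- ifelse(is_dev1, row$deviant, row$standard)
    offs <- ctx$off_subj[k] + ctx$off_cond[k, ci]
    # subject variability attaches to responses that exist: a component
    # with zero amplitude in this condition/role is absent, not variable
    a <- ifelse(base != 0, base + offs, 0)
    if (comps$deviant_only[k]) a[!is_dev1] <- 0
    amp[, k] <- a
  }
  with_seed(ctx$cond_seeds[[cc]], {
    sig <- amp %*% fields                             # trials x (ch*time)
    noise <- design$noise_white_sd * stats::rnorm(ntr * nch * nt) +
      design$noise_pink_sd * as.vector(pink_noise_matrix(nt, ntr * nch))
    # noise is laid out time-major per (trial, channel); reshape to match
    nz <- aperm(array(noise, c(nt, ntr, nch)), c(2, 3, 1))
    array(as.vector(sig), c(ntr, nch, nt)) + nz
  })
}

#' Simulate the full multi-participant dataset
#'
#' @param design a [simulation_design()].
#' @return list of `epoch_set`s with a `manifest` attribute recording the
#'   per-subject seeds.
#' @export
simulate_dataset <- function(design) {
  sets <- lapply(seq_len(design$n_subjects), function(s) {
    simulate_subject(design, s)
  })
  attr(sets, "manifest") <- data.frame(
    subject = seq_len(design$n_subjects),
    seed = vapply(seq_len(design$n_subjects),
                  function(s) subject_seed(design, s), integer(1))
  )
  sets
}

#' Noise-free analytic template of a condition/role average
#'
#' The expected (noise-free, zero-offset) channels x time field for a given
#' condition and role under an effect table; used to verify that the
#' generator's grand average matches the analytic superposition.
#'
#' @param design a [simulation_design()].
#' @param condition condition name.
#' @param role `"standard"` or `"deviant"` (first-order).
#' @return channels x time matrix (µV).
#' @export
template_erp <- function(design, condition, role = c("standard", "deviant")) {
  role <- match.arg(role)
  times <- design_times(design)
  comps <- erp_components()
  g <- component_timecourses(times, comps)
  topo <- component_topography(design$montage)
  et <- design$effect_table
  out <- matrix(0, length(design$montage$names), length(times),
                dimnames = list(design$montage$names, NULL))
  for (k in seq_len(nrow(comps))) {
    row <- et[et$component == comps$name[k] & et$condition == condition, ]
    a <- if (role == "deviant") row$deviant else row$standard
    if (comps$deviant_only[k] && role == "standard") a <- 0
    out <- out + a * outer(topo, g[, k])
  }
  out
}

#' Save / load an epoch set (portable binary array + JSON sidecar)
#'
#' `save_epochs()` writes the data as little-endian float64 with a JSON
#' sidecar holding dimensions, channel names, times and labels;
#' `load_epochs()` restores the `epoch_set`.
#'
#' @param epochs an `epoch_set`.
#' @param path basename path; `.bin` and `.json` suffixes are appended.
#' @return `save_epochs`: `path` invisibly; `load_epochs`: an `epoch_set`.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(dim = dim(epochs$data), channels = epochs$montage$names,
         roi = epochs$montage$roi, pos = unname(epochs$montage$pos),
         times = epochs$times, srate = epochs$srate,
         subject_id = epochs$subject_id, labels = epochs$labels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(path, ".bin"), "rb")
  v <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  close(con)
  pos <- as.matrix(meta$pos)
  dimnames(pos) <- list(meta$channels, c("x", "y"))
  mont <- structure(list(names = meta$channels, pos = pos, roi = meta$roi,
                         reference = "averaged mastoids"),
                    class = "montage")
  labels <- as.data.frame(meta$labels, stringsAsFactors = FALSE)
  labels$deviant_order <- as.integer(labels$deviant_order)
  labels$shift_hz <- as.numeric(labels$shift_hz)
  structure(
    list(data = array(v, meta$dim), labels = labels,
         times = meta$times, srate = meta$srate, montage = mont,
         subject_id = meta$subject_id),
    class = "epoch_set"
  )
}

#' Null subject-level difference ERPs (reduced-scale generator)
#'
#' Generates subject-level deviant-minus-standard difference ERPs under the
#' null hypothesis of no deviance effect: each subject's difference wave is
#' the average of `n_trials_equiv` single-trial noise fields (1/f plus
#' white), i.e. pure noise scaled by `1 / sqrt(n_trials_equiv)`. Used for
#' family-wise error calibration of the cluster permutation test, where
#' simulating full epoch sets for hundreds of Monte-Carlo repetitions would
#' be wasteful.
#'
#' @param n_subjects number of subjects.
#' @param montage a montage (defaults to [mini_montage()]).
#' @param times time axis in ms.
#' @param noise_white_sd,noise_pink_sd single-trial noise SDs (µV).
#' @param n_trials_equiv equivalent number of averaged trials.
#' @return array `n_subjects x channels x time`.
#' @export
simulate_null_diff_erps <- function(n_subjects = 20,
                                    montage = mini_montage(),
                                    times = seq(-100, 450, by = 1),
                                    noise_white_sd = 3, noise_pink_sd = 3,
                                    n_trials_equiv = 50) {
  nch <- length(montage$names)
  nt <- length(times)
  scale <- 1 / sqrt(n_trials_equiv)
  w <- noise_white_sd * scale * stats::rnorm(n_subjects * nch * nt)
  p <- noise_pink_sd * scale *
    as.vector(pink_noise_matrix(nt, n_subjects * nch))
  aperm(array(w + p, c(nt, n_subjects, nch)), c(2, 3, 1))
}
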