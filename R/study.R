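#' Simulate a full study and reduce it to subject-level ERPs
#'
#' Runs the generator subject by subject and applies the ERP pipeline:
#' averaging of standards and first-order deviants per condition, zero-phase
#' 30-Hz low-pass and baseline correction (both linear, so they are applied
#' to the subject averages; the result equals filtering every trial).
#'
#' Two generation methods are available. `"epochs"` builds every
#' single-trial epoch and averages them. `"average"` (default) draws each
#' subject-condition-role average directly: the signal part is the exact
#' trial mean implied by the event table, and the noise part is one
#' 1/f-plus-white field scaled by `1/sqrt(n_trials)` — the exact
#' distribution of the mean of that many independent noise trials. The two
#' methods are equal in distribution; `"average"` is far cheaper.
#'
#' @param design a [simulation_design()].
#' @param cfg an [analysis_config()].
#' @param deviant_order which deviant order to average as "deviant".
#' @param method `"average"` or `"epochs"` (see above).
#' @return an object of class `erp_study`: list with `erps` — for each
#'   condition, `standard` and `deviant` arrays `n_subjects x channels x
#'   time` — plus `times`, `montage`, `design`, `cfg`.
#' @export
simulate_study <- function(design = simulation_design(),
                           cfg = analysis_config(), deviant_order = 1L,
                           method = c("average", "epochs")) {
  method <- match.arg(method)
  times <- design_times(design)
  nt <- length(times)
  nch <- length(design$montage$names)
  conds <- c("harmonic", "inharmonic", "changing")
  erps <- lapply(conds, function(cc) {
    list(standard = array(0, c(design$n_subjects, nch, nt)),
         deviant = array(0, c(design$n_subjects, nch, nt)))
  })
  names(erps) <- conds
  bf <- signal::butter(cfg$filter_order, cfg$lowpass / (design$srate / 2), "low")
  bl_sel <- times >= cfg$baseline[1] & times <= cfg$baseline[2]
  post <- function(m) {
    for (r in seq_len(nrow(m))) m[r, ] <- signal::filtfilt(bf, m[r, ])
    m - rowMeans(m[, bl_sel, drop = FALSE])
  }
  for (s in seq_len(design$n_subjects)) {
    ctx <- subject_context(design, s)
    for (cc in conds) {
      tab <- ctx$event_tables[[cc]]
      std_keep <- tab$role == "standard"
      dev_keep <- !is.na(tab$deviant_order) &
        tab$deviant_order == deviant_order & tab$role == "deviant"
      if (method == "epochs") {
        d <- condition_epochs(design, ctx, cc)
        mean_of <- function(keep) {
          matrix(colMeans(matrix(d[keep, , , drop = FALSE], nrow = sum(keep))),
                 nch, nt)
        }
        erps[[cc]]$standard[s, , ] <- post(mean_of(std_keep))
        erps[[cc]]$deviant[s, , ] <- post(mean_of(dev_keep))
        rm(d)
      } else {
        avg <- condition_averages(design, ctx, cc,
                                  list(standard = std_keep, deviant = dev_keep))
        erps[[cc]]$standard[s, , ] <- post(avg$standard)
        erps[[cc]]$deviant[s, , ] <- post(avg$deviant)
      }
    }
  }
  structure(list(erps = erps, times = times, montage = design$montage,
                 design = design, cfg = cfg),
            class = "erp_study")
}

# Direct draw of trial-averaged condition/role fields for one subject:
# signal = per-trial template mean over the selected trials, noise = one
# 1/f + white field at SD / sqrt(n_trials) (exact for iid noise averaging).
condition_averages <- function(design, ctx, cc, keeps) {
  comps <- erp_components()
  times <- ctx$times
  nt <- length(times)
  mont <- design$montage
  nch <- length(mont$names)
  g <- component_timecourses(times, comps)
  topo <- component_topography(mont)
  tab <- ctx$event_tables[[cc]]
  et <- design$effect_table
  ci <- match(cc, colnames(ctx$off_cond))
  is_dev1 <- !is.na(tab$deviant_order) & tab$deviant_order == 1L
  amp_for <- function(keep) {
    a <- numeric(nrow(comps))
    for (k in seq_len(nrow(comps))) {
      row <- et[et$component == comps$name[k] & et$condition == cc, ]
      base <- ifelse(is_dev1, row$deviant, row$standard)
      offs <- ctx$off_subj[k] + ctx$off_cond[k, ci]
      per_trial <- ifelse(base != 0, base + offs, 0)
      if (comps$deviant_only[k]) per_trial[!is_dev1] <- 0
      a[k] <- mean(per_trial[keep])
    }
    a
  }
  with_seed(ctx$cond_seeds[[cc]], {
    out <- lapply(keeps, function(keep) {
      n <- sum(keep)
      sig <- matrix(0, nch, nt)
      a <- amp_for(keep)
      for (k in seq_len(nrow(comps))) sig <- sig + a[k] * outer(topo, g[, k])
      scale <- 1 / sqrt(n)
      noise <- design$noise_white_sd * scale * stats::rnorm(nch * nt) +
        design$noise_pink_sd * scale * as.vector(pink_noise_matrix(nt, nch))
      sig + matrix(noise, nch, nt, byrow = TRUE)
    })
    out
  })
}

#' Per-subject mismatch (deviant - standard) difference ERPs
#'
#' @param study an `erp_study`.
#' @param condition condition name.
#' @return array `n_subjects x channels x time`.
#' @export
study_difference_erps <- function(study, condition) {
  e <- study$erps[[condition]]
  if (is.null(e)) stop("unknown condition: ", condition)
  e$deviant - e$standard
}

#' Peak measures table for MMN and P3a
#'
#' For every subject and condition, extracts the MMN and P3a peak latency
#' and 50-ms mean amplitude from the frontocentral ROI trace of the
#' mismatch difference wave.
#'
#' @param study an `erp_study`.
#' @return data.frame: `subject`, `condition`, `component`, `latency_ms`,
#'   `mean_amp`.
#' @export
study_peak_measures <- function(study) {
  conds <- names(study$erps)
  roi_idx <- match(study$cfg$roi, study$montage$names)
  rows <- list()
  for (cc in conds) {
    diffs <- study_difference_erps(study, cc)
    for (s in seq_len(dim(diffs)[1])) {
      trace <- colMeans(diffs[s, roi_idx, ])
      for (comp in c("mmn", "p3a")) {
        pm <- peak_and_mean_amplitude(trace, study$times, comp, study$cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cc, component = toupper(comp),
          latency_ms = pm$latency_ms, mean_amp = pm$mean_amp,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' P2 mean-amplitude table (standards and deviants)
#'
#' Mean ROI amplitude in the fixed window around the grand-average P2
#' latency, separately for standard and deviant ERPs in every condition;
#' input to the two-way repeated-measures ANOVA probing the ORN.
#'
#' @param study an `erp_study`.
#' @return data.frame: `subject`, `condition`, `deviance`, `value`.
#' @export
study_p2_table <- function(study) {
  conds <- names(study$erps)
  roi_idx <- match(study$cfg$roi, study$montage$names)
  rows <- list()
  for (cc in conds) {
    for (role in c("standard", "deviant")) {
      a <- study$erps[[cc]][[role]]
      for (s in seq_len(dim(a)[1])) {
        trace <- colMeans(a[s, roi_idx, ])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = cc, deviance = role,
          value = p2_mean_amplitude(trace, study$times, study$cfg),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Mismatch cluster tests per condition
#'
#' Deviant-vs-standard spatio-temporal cluster permutation test (paired t)
#' in each condition, plus the three-condition repeated-measures F test on
#' the difference ERPs.
#'
#' @param study an `erp_study`.
#' @param cluster_cfg a [cluster_config()].
#' @param adjacency optional [channel_adjacency()]; defaults to the study
#'   montage's.
#' @return list with one `cluster_test_result` per condition and `rm_F` for
#'   the omnibus test.
#' @export
study_cluster_tests <- function(study, cluster_cfg = cluster_config(seed = 1),
                                adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- channel_adjacency(study$montage)
  conds <- names(study$erps)
  diffs <- lapply(conds, function(cc) study_difference_erps(study, cc))
  names(diffs) <- conds
  out <- lapply(diffs, function(d) {
    permutation_test(d, adjacency, cluster_cfg, "paired_t", study$times)
  })
  out$rm_F <- permutation_test(unname(diffs), adjacency, cluster_cfg,
                               "rm_F", study$times)
  out
}

#' Condition-level inference on a peak-measure component
#'
#' One-way repeated-measures ANOVA plus Tukey HSD contrasts and the
#' null-model comparison for one component's mean amplitudes.
#'
#' @param measures a [study_peak_measures()] table.
#' @param component `"MMN"` or `"P3a"`.
#' @param value_col column to analyze (`"mean_amp"` or `"latency_ms"`).
#' @return list with `anova`, `contrasts`, `comparison`.
#' @export
peak_condition_inference <- function(measures, component = "MMN",
                                     value_col = "mean_amp") {
  sub <- measures[toupper(measures$component) == toupper(component), ]
  tab <- data.frame(subject = sub$subject, condition = sub$condition,
                    value = sub[[value_col]])
  fit <- rm_anova_oneway(tab)
  list(anova = fit, contrasts = tukey_contrasts(fit),
       comparison = model_comparison(fit))
}
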