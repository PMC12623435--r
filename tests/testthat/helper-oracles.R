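# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition with the dumbest possible
# code, so they share nothing with the package implementations they check.

# Pincus ApEn by the literal double loop over embedded templates
apen_oracle <- function(x, m = 2, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    emb <- sapply(seq_len(nt), function(i) x[i:(i + mm - 1)])
    emb <- matrix(emb, nrow = mm)
    C <- numeric(nt)
    for (i in seq_len(nt)) {
      d <- apply(abs(emb - emb[, i]), 2, max)
      C[i] <- mean(d <= r)
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

# flood-fill cluster labelling on a channels x time map by repeated
# neighbour expansion over an explicit cell list
cluster_oracle <- function(stat, threshold, adj_mat, tail = "two.sided") {
  nch <- nrow(stat)
  nt <- ncol(stat)
  signs <- if (tail == "two.sided") c(1, -1) else 1
  masses <- numeric(0)
  assigned <- matrix(FALSE, nch, nt)
  for (s in signs) {
    supra <- which(s * stat > threshold & !assigned, arr.ind = TRUE)
    while (nrow(supra) > 0) {
      comp <- supra[1, , drop = FALSE]
      repeat {
        grew <- FALSE
        for (i in seq_len(nrow(supra))) {
          cell <- supra[i, ]
          if (assigned[cell[1], cell[2]]) next
          touches <- any(apply(comp, 1, function(cc) {
            (cc[1] == cell[1] && abs(cc[2] - cell[2]) == 1) ||
              (cc[2] == cell[2] && adj_mat[cc[1], cell[1]])
          }))
          in_comp <- any(comp[, 1] == cell[1] & comp[, 2] == cell[2])
          if (touches && !in_comp) {
            comp <- rbind(comp, cell)
            grew <- TRUE
          }
        }
        if (!grew) break
      }
      for (i in seq_len(nrow(comp))) assigned[comp[i, 1], comp[i, 2]] <- TRUE
      masses <- c(masses, sum(stat[comp]))
      supra <- which(s * stat > threshold & !assigned, arr.ind = TRUE)
    }
  }
  sort(masses)
}

# balanced one-way repeated-measures sums of squares, written out longhand
rm_oneway_oracle <- function(values, subjects, conditions) {
  subj <- unique(subjects)
  cond <- unique(conditions)
  n <- length(subj)
  k <- length(cond)
  g <- mean(values)
  ss_subj <- 0
  for (s in subj) ss_subj <- ss_subj + k * (mean(values[subjects == s]) - g)^2
  ss_cond <- 0
  for (cc in cond) ss_cond <- ss_cond + n * (mean(values[conditions == cc]) - g)^2
  ss_tot <- sum((values - g)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  Fv <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = Fv, df = c(k - 1, (k - 1) * (n - 1)),
       ss = c(cond = ss_cond, subj = ss_subj, err = ss_err))
}

# small helper: ROI indices for a montage
roi_idx <- function(montage) match(montage$roi, montage$names)
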