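#' Default 30-channel scalp montage
#'
#' The 10-20/10-10 subset of a 32-channel active cap after dropping the two
#' mastoid references (TP9/TP10): 30 scalp channels with 2-D positions from
#' an azimuthal projection (vertex at the origin, nasion towards +y, right
#' towards +x, outer ring inside the unit disc). The frontocentral region of
#' interest is F3, Fz, F4, FC1, FC2. Data are taken to be referenced to
#' averaged mastoids already.
#'
#' @return an object of class `montage`: list with `names`, `pos`
#'   (30 x 2 matrix), `roi`.
#' @export
default_montage <- function() {
  # name, polar angle from vertex (deg), azimuth from front midline (deg,
  # positive right); radius on the disc = angle / 95
  tab <- matrix(c(
    "Fp1", 72, -18,  "Fp2", 72,  18,
    "F7",  72, -54,  "F3",  50, -39,  "Fz", 45,   0,  "F4", 50,  39,  "F8", 72, 54,
    "FC5", 55, -69,  "FC1", 25, -45,  "FC2", 25, 45,  "FC6", 55, 69,
    "T7",  72, -90,  "C3",  45, -90,  "Cz",  0,   0,  "C4", 45,  90,  "T8", 72, 90,
    "CP5", 55, -111, "CP1", 25, -135, "CP2", 25, 135, "CP6", 55, 111,
    "P7",  72, -126, "P3",  50, -141, "Pz",  45, 180, "P4", 50, 141,  "P8", 72, 126,
    "PO9", 81, -144, "O1",  72, -162, "Oz",  72, 180, "O2", 72, 162,  "PO10", 81, 144
  ), ncol = 3, byrow = TRUE)
  nm <- tab[, 1]
  theta <- as.numeric(tab[, 2])
  phi <- as.numeric(tab[, 3]) * pi / 180
  r <- theta / 95
  pos <- cbind(x = r * sin(phi), y = r * cos(phi))
  rownames(pos) <- nm
  structure(
    list(names = nm, pos = pos, roi = c("F3", "Fz", "F4", "FC1", "FC2"),
         reference = "averaged mastoids"),
    class = "montage"
  )
}

#' Small frontocentral montage for reduced-scale simulations
#'
#' Six frontocentral channels of the default montage, used for fast
#' calibration studies (e.g. permutation-test false-positive rates).
#'
#' @return a `montage` with 6 channels.
#' @export
mini_montage <- function() {
  m <- default_montage()
  keep <- c("F3", "Fz", "F4", "FC1", "FC2", "Cz")
  structure(
    list(names = keep, pos = m$pos[keep, , drop = FALSE], roi = keep[1:5],
         reference = m$reference),
    class = "montage"
  )
}

#' Channel adjacency graph from montage positions
#'
#' Channels are neighbors when their 2-D Euclidean distance is below
#' `radius`. The default radius gives a median degree of about 4-6 on the
#' default montage and a connected graph.
#'
#' @param montage a [default_montage()]-style montage.
#' @param radius neighborhood radius (same units as the positions, `> 0`).
#' @return an object of class `adjacency`: list with `names`, `matrix`
#'   (logical, symmetric, empty diagonal), `neighbors` (list of integer
#'   vectors).
#' @export
channel_adjacency <- function(montage, radius = 0.45) {
  if (radius <= 0) stop("radius must be positive")
  n <- length(montage$names)
  if (n < 2) stop("need at least 2 channels")
  d <- as.matrix(stats::dist(montage$pos))
  adj <- d < radius
  diag(adj) <- FALSE
  structure(
    list(names = montage$names, matrix = adj,
         neighbors = lapply(seq_len(n), function(i) which(adj[i, ]))),
    class = "adjacency"
  )
}

adjacency_connected <- function(adj) {
  n <- length(adj$names)
  seen <- logical(n)
  stack <- 1L
  while (length(stack)) {
    i <- stack[[1]]
    stack <- stack[-1]
    if (seen[i]) next
    seen[i] <- TRUE
    stack <- c(stack, adj$neighbors[[i]][!seen[adj$neighbors[[i]]]])
  }
  all(seen)
}
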