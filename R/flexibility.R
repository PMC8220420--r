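#' Superpose trajectory frames onto a reference
#'
#' Removes global rigid-body motion by least-squares fitting each frame
#' onto a reference structure over a selection of atoms (Kabsch fit via
#' \pkg{bio3d}; proper rotations only, so chirality is preserved). All
#' atoms are moved by the transformation determined on the selection.
#'
#' @param trajectory A `trajectory`.
#' @param selection Integer atom indices used for the fit (default: all
#'   CA atoms; all atoms when none are named CA). At least 3 atoms.
#' @param reference `"first"` (fit to the first frame) or `"mean"`
#'   (iterated mean structure: fit to first, then refit to the mean).
#' @return A `trajectory` with superposed coordinates.
#' @export
superpose <- function(trajectory, selection = NULL,
                      reference = c("first", "mean")) {
  stopifnot(inherits(trajectory, "trajectory"))
  reference <- match.arg(reference)
  if (is.null(selection)) selection <- ca_selection(trajectory$topology)
  if (length(selection) < 3L) stop("need at least 3 selected atoms for superposition")
  n_f <- dim(trajectory$coords)[1]
  n_a <- dim(trajectory$coords)[2]
  xyz <- matrix(NA_real_, n_f, 3L * n_a)
  for (f in seq_len(n_f)) xyz[f, ] <- t(trajectory$coords[f, , ])
  fixed_inds <- bio3d::atom2xyz(selection)
  fit_once <- function(ref_xyz) {
    bio3d::fit.xyz(fixed = ref_xyz, mobile = xyz,
                   fixed.inds = fixed_inds, mobile.inds = fixed_inds)
  }
  fitted <- fit_once(xyz[1, ])
  if (reference == "mean") {
    fitted <- fit_once(colMeans(fitted))
  }
  frames <- lapply(seq_len(n_f), function(f) {
    matrix(fitted[f, ], ncol = 3L, byrow = TRUE)
  })
  new_trajectory(trajectory$topology, frames, times = trajectory$times,
                 window = trajectory$window)
}

# Default analysis selection: CA atoms, else all atoms.
ca_selection <- function(topology) {
  ca <- which(topology$atoms$name == "CA")
  if (length(ca)) ca else seq_len(nrow(topology$atoms))
}

# Split the window frames into n contiguous blocks of (near-)equal size.
block_split <- function(frames, n_blocks) {
  if (n_blocks > length(frames))
    stop(sprintf("n_blocks (%d) exceeds the %d frames in the window",
                 n_blocks, length(frames)))
  ids <- ceiling(seq_along(frames) * n_blocks / length(frames))
  split(frames, ids)
}

#' Root-mean-square fluctuation with block-averaged errors
#'
#' Per-atom RMSF over the analysis window:
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` with the 3D deviation from
#' the mean position. The window is partitioned into `n_blocks` contiguous
#' blocks; the profile reports the mean RMSF over blocks and the standard
#' error of that mean. By default each block uses its own mean structure as
#' the fluctuation reference (so the between-block SEM measures sampling
#' error of a stationary process); `reference = "global"` uses the
#' whole-window mean instead. The trajectory should be superposed first.
#'
#' @param trajectory A (superposed) `trajectory`.
#' @param selection Integer atom indices (default CA atoms).
#' @param n_blocks Number of blocks (default 5).
#' @param reference `"block"` or `"global"` fluctuation reference.
#' @return A data frame of class `flexibility_profile`: `atom`, `residue`,
#'   `rmsf_mean_A`, `rmsf_sem_A` (SEM is `NA` for `n_blocks = 1`).
#' @export
rmsf <- function(trajectory, selection = NULL, n_blocks = 5,
                 reference = c("block", "global")) {
  stopifnot(inherits(trajectory, "trajectory"))
  reference <- match.arg(reference)
  if (is.null(selection)) selection <- ca_selection(trajectory$topology)
  frames <- window_frames(trajectory)
  blocks <- block_split(frames, n_blocks)
  co <- trajectory$coords
  global_mean <- if (reference == "global") {
    apply(co[frames, selection, , drop = FALSE], c(2, 3), mean)
  } else NULL
  block_rmsf <- vapply(blocks, function(fr) {
    sub <- co[fr, selection, , drop = FALSE]
    mu <- if (is.null(global_mean)) apply(sub, c(2, 3), mean) else global_mean
    dev2 <- sweep(sub, c(2, 3), mu)^2
    sqrt(apply(dev2, 2, mean) * 3)   # mean over frames and xyz, times 3 dims
  }, numeric(length(selection)))
  block_rmsf <- matrix(block_rmsf, nrow = length(selection))
  res_id <- paste(trajectory$topology$atoms$chain[selection],
                  trajectory$topology$atoms$resno[selection], sep = ":")
  out <- data.frame(atom = selection, residue = res_id,
                    rmsf_mean_A = rowMeans(block_rmsf),
                    rmsf_sem_A = if (n_blocks >= 2L) {
                      apply(block_rmsf, 1, stats::sd) / sqrt(n_blocks)
                    } else NA_real_)
  attr(out, "n_blocks") <- n_blocks
  attr(out, "reference") <- reference
  class(out) <- c("flexibility_profile", "data.frame")
  out
}

#' Dynamic cross-correlation of positional fluctuations
#'
#' Normalized covariance of the 3D positional fluctuations of the selected
#' atoms: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with `dr`
#' the deviation from the time-mean position over the analysis window.
#' Values near +1 indicate in-phase motion, near -1 anti-phase motion.
#' Atoms with zero positional variance yield `NA` rows/columns and are
#' reported in the `undefined` attribute.
#'
#' @param trajectory A (superposed) `trajectory` with >= 2 window frames.
#' @param selection Integer atom indices (default CA atoms).
#' @return A symmetric matrix of class `correlation_matrix` with unit
#'   diagonal, dimnames = residue ids.
#' @export
cross_correlation <- function(trajectory, selection = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (is.null(selection)) selection <- ca_selection(trajectory$topology)
  frames <- window_frames(trajectory)
  if (length(frames) < 2L) stop("need at least 2 frames in the window")
  X <- trajectory$coords[frames, selection, 1, drop = TRUE]
  Y <- trajectory$coords[frames, selection, 2, drop = TRUE]
  Z <- trajectory$coords[frames, selection, 3, drop = TRUE]
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  Z <- scale(Z, scale = FALSE)
  num <- (crossprod(X) + crossprod(Y) + crossprod(Z)) / length(frames)
  v <- diag(num)
  zerovar <- v <= .Machine$double.eps
  denom <- sqrt(outer(v, v))
  C <- num / denom
  C[zerovar, ] <- NA_real_; C[, zerovar] <- NA_real_
  diag(C)[!zerovar] <- 1
  res_id <- paste(trajectory$topology$atoms$chain[selection],
                  trajectory$topology$atoms$resno[selection], sep = ":")
  dimnames(C) <- list(res_id, res_id)
  attr(C, "undefined") <- res_id[zerovar]
  class(C) <- c("correlation_matrix", class(C))
  C
}

#' Nucleotide-pocket width time series
#'
#' Per-frame distance between the reference atoms (default CA) of two
#' residues flanking a nucleotide-binding pocket -- e.g. G506-G854 for the
#' NC pocket and G1353-G1689 for the CC pocket in Brr2 author numbering --
#' with the mean and block-averaged SEM over the analysis window.
#'
#' @param trajectory A `trajectory`.
#' @param pair Length-2 character vector of residue ids (`"chain:resno"`).
#' @param atom Reference atom name (default `"CA"`).
#' @param n_blocks Number of blocks for the SEM (default 5).
#' @return A list of class `pocket_width`: `pair`, `distance` (per window
#'   frame, Angstrom), `mean`, `sem`, `times`.
#' @export
pocket_width <- function(trajectory, pair, atom = "CA", n_blocks = 5) {
  stopifnot(inherits(trajectory, "trajectory"), length(pair) == 2L)
  topo <- trajectory$topology
  res_id <- paste(topo$atoms$chain, topo$atoms$resno, sep = ":")
  ix <- vapply(pair, function(r) {
    hit <- which(res_id == r & topo$atoms$name == atom)
    if (!length(hit))
      stop(sprintf("residue %s has no '%s' reference atom", r, atom))
    hit[1]
  }, integer(1))
  frames <- window_frames(trajectory)
  d <- sqrt(rowSums((trajectory$coords[frames, ix[1], , drop = TRUE] -
                     trajectory$coords[frames, ix[2], , drop = TRUE])^2))
  if (any(d <= 0)) stop("degenerate zero pocket width encountered")
  blocks <- block_split(seq_along(d), n_blocks)
  bm <- vapply(blocks, function(b) mean(d[b]), numeric(1))
  structure(list(pair = pair, distance = d,
                 mean = mean(bm),
                 sem = if (n_blocks >= 2L) stats::sd(bm) / sqrt(n_blocks)
                       else NA_real_,
                 block_means = bm,
                 times = trajectory$times[frames]),
            class = "pocket_width")
}

#' @export
print.pocket_width <- function(x, ...) {
  cat(sprintf("<pocket_width> %s - %s: %.2f +/- %.3f A (%d frames)\n",
              x$pair[1], x$pair[2], x$mean,
              if (is.na(x$sem)) NA else x$sem, length(x$distance)))
  invisible(x)
}
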