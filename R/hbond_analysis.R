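#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triplet counts as a hydrogen bond when the
#' heavy-atom donor-acceptor distance is at most `d_max` and the deviation
#' of the D-H...A angle from linearity is at most `theta_max`. Deviation
#' from linearity is `180 - angle(D-H...A)` in degrees, where the angle is
#' measured at the hydrogen -- a perfectly linear bond has deviation 0.
#' Both cutoffs are inclusive.
#'
#' @param d_max Donor-acceptor distance cutoff in Angstrom (default 3.2).
#' @param theta_max Maximum deviation from linearity in degrees
#'   (default 42).
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 3.2, theta_max = 42) {
  if (d_max <= 0) stop("'d_max' must be > 0")
  if (theta_max <= 0 || theta_max >= 90)
    stop("'theta_max' must be in (0, 90) degrees")
  structure(list(d_max = d_max, theta_max = theta_max),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in a single frame
#'
#' Applies the geometric criterion to every donor (D, H) pair against every
#' acceptor A in a different residue. Intra-residue D/A combinations are
#' excluded (they cannot bridge graph nodes).
#'
#' @param coords N x 3 coordinate matrix (Angstrom) matching the topology
#'   atom order.
#' @param topology A `topology` (supplies donors/acceptors and residue
#'   identities), or pass `donors`/`acceptors` explicitly.
#' @param criterion An [hbond_criterion()].
#' @param donors Optional data frame of (D, H) atom-index pairs.
#' @param acceptors Optional integer vector of acceptor atom indices.
#' @return A data frame with columns `D`, `H`, `A` (atom indices), `res_D`,
#'   `res_A` (residue ids), `dist`, `deviation`.
#' @export
detect_hbonds_frame <- function(coords, topology, criterion = hbond_criterion(),
                                donors = NULL, acceptors = NULL) {
  stopifnot(inherits(criterion, "hbond_criterion"))
  if (is.null(donors)) donors <- topology$donors
  if (is.null(acceptors)) acceptors <- topology$acceptors
  empty <- data.frame(D = integer(0), H = integer(0), A = integer(0),
                      res_D = character(0), res_A = character(0),
                      dist = numeric(0), deviation = numeric(0))
  if (nrow(donors) == 0L || length(acceptors) == 0L) return(empty)
  res_id <- paste(topology$atoms$chain, topology$atoms$resno, sep = ":")

  bad_h <- donors$H > nrow(coords) | donors$D > nrow(coords)
  if (any(bad_h)) {
    warning("skipping ", sum(bad_h), " donor(s) with missing coordinates")
    donors <- donors[!bad_h, , drop = FALSE]
    if (nrow(donors) == 0L) return(empty)
  }

  nd <- nrow(donors); na <- length(acceptors)
  Dxyz <- coords[donors$D, , drop = FALSE]
  Hxyz <- coords[donors$H, , drop = FALSE]
  Axyz <- coords[acceptors, , drop = FALSE]

  # donor-acceptor distances (nd x na); 1e-9 guard keeps the inclusive
  # boundary robust to floating-point rounding
  d2 <- outer(rowSums(Dxyz^2), rep(1, na)) +
    outer(rep(1, nd), rowSums(Axyz^2)) - 2 * Dxyz %*% t(Axyz)
  d2[d2 < 0] <- 0
  cand <- which(d2 <= (criterion$d_max + 1e-9)^2, arr.ind = TRUE,
                useNames = FALSE)
  if (nrow(cand) == 0L) return(empty)

  di <- cand[, 1]; ai <- cand[, 2]
  same_res <- res_id[donors$D[di]] == res_id[acceptors[ai]]
  self <- donors$D[di] == acceptors[ai]
  cand <- cand[!(same_res | self), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  di <- cand[, 1]; ai <- cand[, 2]

  # angle at H between H->D and H->A
  v1 <- Dxyz[di, , drop = FALSE] - Hxyz[di, , drop = FALSE]
  v2 <- Axyz[ai, , drop = FALSE] - Hxyz[di, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  deviation <- 180 - ang
  ok <- deviation <= criterion$theta_max + 1e-9
  if (!any(ok)) return(empty)
  di <- di[ok]; ai <- ai[ok]
  data.frame(D = donors$D[di], H = donors$H[di], A = acceptors[ai],
             res_D = res_id[donors$D[di]], res_A = res_id[acceptors[ai]],
             dist = sqrt(d2[cbind(di, ai)]), deviation = deviation[ok],
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond occurrence probabilities over a trajectory window
#'
#' Aggregates per-frame hydrogen bonds into a symmetric residue-pair
#' probability matrix over the analysis window. Two aggregation modes:
#' `"frame-union"` (default) counts a frame for pair (i, j) when at least
#' one hydrogen bond bridges the residues in that frame, so `HB_ij` is the
#' fraction of window frames with any bridging bond; `"max-single-bond"`
#' tracks each distinct (D, H, A) triplet separately and reports the
#' maximum per-triplet occupancy. Union-mode probabilities are always >=
#' max-mode ones.
#'
#' @param trajectory A `trajectory`.
#' @param criterion An [hbond_criterion()].
#' @param aggregation `"frame-union"` or `"max-single-bond"`.
#' @return An object of class `hbond_matrix`: `residues` (ids), `P`
#'   (symmetric probability matrix with empty diagonal), `n_frames`,
#'   `aggregation`.
#' @export
occupancy_matrix <- function(trajectory, criterion = hbond_criterion(),
                             aggregation = c("frame-union", "max-single-bond")) {
  stopifnot(inherits(trajectory, "trajectory"))
  aggregation <- match.arg(aggregation)
  frames <- window_frames(trajectory)
  if (length(frames) == 0L) stop("analysis window contains no frames")
  topo <- trajectory$topology
  res_ids <- topo$residues$id
  nres <- length(res_ids)
  idx <- stats::setNames(seq_len(nres), res_ids)

  pair_counts <- new.env(parent = emptyenv())
  for (f in frames) {
    hb <- detect_hbonds_frame(trajectory$coords[f, , ], topo, criterion)
    if (nrow(hb) == 0L) next
    if (aggregation == "frame-union") {
      keys <- unique(paste(pmin(hb$res_D, hb$res_A),
                           pmax(hb$res_D, hb$res_A), sep = "|"))
    } else {
      keys <- unique(paste(pmin(hb$res_D, hb$res_A),
                           pmax(hb$res_D, hb$res_A),
                           hb$D, hb$H, hb$A, sep = "|"))
    }
    for (k in keys) {
      pair_counts[[k]] <- (pair_counts[[k]] %||% 0L) + 1L
    }
  }
  P <- matrix(0, nres, nres, dimnames = list(res_ids, res_ids))
  for (k in ls(pair_counts)) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    i <- idx[[parts[1]]]; j <- idx[[parts[2]]]
    p <- pair_counts[[k]] / length(frames)
    if (aggregation == "max-single-bond") {
      P[i, j] <- max(P[i, j], p)
    } else {
      P[i, j] <- p
    }
    P[j, i] <- P[i, j]
  }
  new_hbond_matrix(res_ids, P, length(frames), aggregation)
}

new_hbond_matrix <- function(residues, P, n_frames, aggregation = "frame-union") {
  stopifnot(is.matrix(P), nrow(P) == length(residues),
            ncol(P) == length(residues))
  if (any(P < 0 | P > 1)) stop("probabilities must lie in [0, 1]")
  if (any(diag(P) != 0)) stop("diagonal must be empty")
  if (any(abs(P - t(P)) > 1e-12)) stop("probability matrix must be symmetric")
  dimnames(P) <- list(residues, residues)
  structure(list(residues = residues, P = P, n_frames = n_frames,
                 aggregation = aggregation),
            class = "hbond_matrix")
}

#' Construct an occupancy matrix directly from probabilities
#'
#' Builds an `hbond_matrix` from a residue list and a set of pair
#' probabilities, allowing graph analysis without trajectories (e.g. from a
#' saved triplet table or a synthetic network design).
#'
#' @param residues Character vector of residue ids (`"chain:resno"`).
#' @param pairs Data frame with columns `res_i`, `res_j`, `probability`.
#' @param n_frames Number of frames the probabilities refer to (metadata).
#' @return An `hbond_matrix`.
#' @export
hbond_matrix_from_pairs <- function(residues, pairs, n_frames = NA_integer_) {
  nres <- length(residues)
  P <- matrix(0, nres, nres, dimnames = list(residues, residues))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$res_i[r], residues)
    j <- match(pairs$res_j[r], residues)
    if (is.na(i) || is.na(j))
      stop("pair residue not in residue list: ",
           pairs$res_i[r], " / ", pairs$res_j[r])
    P[i, j] <- P[j, i] <- pairs$probability[r]
  }
  new_hbond_matrix(residues, P, n_frames)
}

#' @export
print.hbond_matrix <- function(x, ...) {
  nz <- sum(x$P[upper.tri(x$P)] > 0)
  cat(sprintf("<hbond_matrix> %d residues, %d nonzero pairs, %s frames, mode '%s'\n",
              length(x$residues), nz, format(x$n_frames), x$aggregation))
  invisible(x)
}

#' Write an occupancy matrix as a sparse triplet table
#'
#' Tab-delimited columns `res_i`, `res_j`, `probability`, one row per
#' nonzero unordered pair; readable back with [read_hbond_matrix()].
#'
#' @param matrix An `hbond_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hbond_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "hbond_matrix"))
  ut <- which(upper.tri(matrix$P) & matrix$P > 0, arr.ind = TRUE)
  df <- data.frame(res_i = matrix$residues[ut[, 1]],
                   res_j = matrix$residues[ut[, 2]],
                   probability = matrix$P[ut])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_frames=%s", format(matrix$n_frames)), con)
  writeLines(sprintf("# aggregation=%s", matrix$aggregation), con)
  writeLines(sprintf("# residues=%s", paste(matrix$residues, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an occupancy matrix triplet table
#'
#' @param path Path written by [write_hbond_matrix()].
#' @return An `hbond_matrix`.
#' @export
read_hbond_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    h <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(h)) return(NULL)
    sub(paste0("^#\\s*", key, "="), "", h[1])
  }
  residues <- strsplit(get("residues"), ",", fixed = TRUE)[[1]]
  n_frames <- suppressWarnings(as.integer(get("n_frames")))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  hbond_matrix_from_pairs(residues, df, n_frames = n_frames)
}
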