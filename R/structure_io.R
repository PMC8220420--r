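#' Read a PDB structure into a topology
#'
#' Parses a PDB-format file (via \pkg{bio3d}) into the internal topology
#' model: atoms with elements, residues identified by (chain, author
#' residue number) -- author numbering is preserved throughout, so
#' residues like G506 or G1353 resolve exactly as published -- covalent
#' bonds inferred from interatomic distances, and hydrogen-bond
#' donor/acceptor roles. When alternate-location conformers are present the
#' highest-occupancy conformer is kept.
#'
#' @param path Path to a PDB file.
#' @return A list of class `topology`: `atoms` (data frame: `index`,
#'   `name`, `element`, `chain`, `resno`, `resid`), `residues` (data
#'   frame: `chain`, `resno`, `resid`, `id`), `bonds` (two-column matrix
#'   of atom indices), `donors` (data frame of (D, H) atom-index pairs),
#'   `acceptors` (integer atom indices), and `coords` (N x 3 matrix of the
#'   first model, Angstrom).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  # alternate locations: keep the highest-occupancy conformer per atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  element <- at$elesy
  miss <- is.na(element) | element == ""
  if (any(miss)) {
    warning("element records missing for ", sum(miss),
            " atoms; inferred from atom names")
    element[miss] <- infer_element(at$elety[miss])
  }
  element <- toupper(trimws(element))
  atoms <- data.frame(index = seq_len(nrow(at)),
                      name = trimws(at$elety),
                      element = element,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      resid = at$resid,
                      stringsAsFactors = FALSE)
  coords <- cbind(at$x, at$y, at$z)
  topo <- build_topology(atoms, coords)
  topo
}

infer_element <- function(name) {
  name <- trimws(name)
  first <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

# Assemble topology tables, infer covalent bonds by distance and identify
# donor/acceptor roles.
build_topology <- function(atoms, coords) {
  stopifnot(nrow(atoms) == nrow(coords))
  rkey <- paste(atoms$chain, atoms$resno, sep = ":")
  ukey <- !duplicated(rkey)
  residues <- data.frame(chain = atoms$chain[ukey], resno = atoms$resno[ukey],
                         resid = atoms$resid[ukey], id = rkey[ukey],
                         stringsAsFactors = FALSE)
  if (anyDuplicated(residues$id))
    stop("residue numbering not unique within chain")
  bonds <- infer_bonds(atoms, coords)
  hb <- hbond_roles(atoms, bonds)
  structure(list(atoms = atoms, residues = residues, bonds = bonds,
                 donors = hb$donors, acceptors = hb$acceptors,
                 coords = coords),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, %d chains, %d bonds, %d donors, %d acceptors\n",
              nrow(x$atoms), nrow(x$residues), length(unique(x$atoms$chain)),
              nrow(x$bonds), nrow(x$donors), length(x$acceptors)))
  invisible(x)
}

# Distance-based covalent bond inference. Cutoffs: X-H 1.2 A, otherwise
# 1.9 A (2.1 A when sulfur is involved). Adequate for fixtures and
# standard protein geometry; CONECT records are not required.
infer_bonds <- function(atoms, coords) {
  n <- nrow(atoms)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  dmat2 <- as.matrix(stats::dist(coords))^2
  is_h <- atoms$element == "H"
  is_s <- atoms$element == "S"
  lim2 <- matrix(1.9^2, n, n)
  lim2[is_s, ] <- 2.1^2; lim2[, is_s] <- 2.1^2
  lim2[is_h, ] <- 1.2^2; lim2[, is_h] <- 1.2^2
  hit <- dmat2 <= lim2 & upper.tri(dmat2)
  which(hit, arr.ind = TRUE, useNames = FALSE)
}

# Donors: N/O heavy atoms with a covalently bonded hydrogen, as (D, H)
# pairs. Acceptors: all N/O heavy atoms. Sulfur is optional and off by
# default.
hbond_roles <- function(atoms, bonds, include_sulfur = FALSE) {
  polar <- atoms$element %in% c("N", "O", if (include_sulfur) "S")
  acceptors <- atoms$index[polar]
  donors <- list()
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      if (atoms$element[i] == "H" && polar[j])
        donors[[length(donors) + 1L]] <- c(D = j, H = i)
      else if (atoms$element[j] == "H" && polar[i])
        donors[[length(donors) + 1L]] <- c(D = i, H = j)
    }
  }
  donors <- if (length(donors)) {
    as.data.frame(do.call(rbind, donors))
  } else data.frame(D = integer(0), H = integer(0))
  list(donors = donors, acceptors = acceptors)
}

#' Identify hydrogen-bond donors and acceptors
#'
#' Donors are N/O heavy atoms carrying at least one covalently bonded
#' hydrogen, returned as (D, H) pairs (an atom with several hydrogens
#' yields one pair per hydrogen). Acceptors are all N/O heavy atoms.
#' Sulfur participation is optional and disabled by default.
#'
#' @param topology A `topology` from [read_structure()].
#' @param include_sulfur Also treat S atoms as donors/acceptors.
#' @return A list with `donors` (data frame of atom-index pairs `D`, `H`)
#'   and `acceptors` (integer atom indices). Warns when the structure has
#'   no hydrogens (empty donor list).
#' @export
infer_hbond_participants <- function(topology, include_sulfur = FALSE) {
  stopifnot(inherits(topology, "topology"))
  if (!any(topology$atoms$element == "H"))
    warning("no hydrogen atoms in topology: donor list is empty")
  hbond_roles(topology$atoms, topology$bonds, include_sulfur)
}

#' Residue covalent adjacency
#'
#' Consecutive residues within each chain, i.e. pairs (i, i+1) in author
#' numbering. A numbering gap is treated as a chain break unless an
#' inter-residue covalent bond connects the two residues. The result is the
#' zero-cost edge set of the communication graph.
#'
#' @param topology A `topology`.
#' @return A data frame with columns `res_i`, `res_j` (residue ids
#'   `"chain:resno"`), each unordered pair listed once.
#' @export
covalent_adjacency <- function(topology) {
  stopifnot(inherits(topology, "topology"))
  res <- topology$residues
  atoms <- topology$atoms
  bonds <- topology$bonds
  # inter-residue bonded pairs by residue id
  bonded_pairs <- character(0)
  if (nrow(bonds)) {
    ri <- paste(atoms$chain[bonds[, 1]], atoms$resno[bonds[, 1]], sep = ":")
    rj <- paste(atoms$chain[bonds[, 2]], atoms$resno[bonds[, 2]], sep = ":")
    inter <- ri != rj
    bonded_pairs <- unique(paste(pmin(ri[inter], rj[inter]),
                                 pmax(ri[inter], rj[inter]), sep = "|"))
  }
  out <- list()
  for (ch in unique(res$chain)) {
    rn <- sort(res$resno[res$chain == ch])
    if (length(rn) < 2L) next
    for (k in seq_len(length(rn) - 1L)) {
      a <- rn[k]; b <- rn[k + 1L]
      ida <- paste(ch, a, sep = ":"); idb <- paste(ch, b, sep = ":")
      if (b - a == 1L) {
        out[[length(out) + 1L]] <- c(ida, idb)
      } else {
        key <- paste(pmin(ida, idb), pmax(ida, idb), sep = "|")
        if (key %in% bonded_pairs) out[[length(out) + 1L]] <- c(ida, idb)
      }
    }
  }
  if (!length(out)) return(data.frame(res_i = character(0),
                                      res_j = character(0)))
  m <- do.call(rbind, out)
  data.frame(res_i = m[, 1], res_j = m[, 2], stringsAsFactors = FALSE)
}

#' Read a multi-frame trajectory
#'
#' Reads one or more multi-model PDB files (the package's fixture format;
#' standard single-file trajectories written by [write_multimodel_pdb()])
#' and concatenates their frames in file order. Frame times, if not
#' encoded in the files, are assigned from a uniform frame spacing. The
#' analysis window defaults to the final half of the total time.
#'
#' @param topology A `topology` whose atom count each frame must match.
#' @param paths Character vector of PDB file paths.
#' @param dt Frame spacing in ns (default 0.1).
#' @param window Optional `(start_ns, end_ns)` analysis window.
#' @return A list of class `trajectory`: `topology`, `coords`
#'   (frames x atoms x 3 array), `times` (ns), `window` (ns).
#' @export
read_trajectory <- function(topology, paths, dt = 0.1, window = NULL) {
  stopifnot(inherits(topology, "topology"))
  n_atoms <- nrow(topology$atoms)
  frames <- list()
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * n_atoms)
      stop(sprintf("atom-count mismatch in '%s': trajectory has %d atoms, topology has %d",
                   p, ncol(xyz) / 3L, n_atoms))
    for (f in seq_len(nrow(xyz))) {
      frames[[length(frames) + 1L]] <-
        matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    }
  }
  new_trajectory(topology, frames, dt = dt, window = window)
}

# Internal trajectory constructor from a list of N x 3 frames.
new_trajectory <- function(topology, frames, dt = 0.1, window = NULL,
                           times = NULL) {
  n_f <- length(frames)
  if (n_f < 1L) stop("trajectory needs at least one frame")
  coords <- array(NA_real_, dim = c(n_f, nrow(frames[[1]]), 3L))
  for (f in seq_len(n_f)) coords[f, , ] <- frames[[f]]
  if (is.null(times)) times <- seq_len(n_f) * dt
  if (is.unsorted(times, strictly = TRUE)) stop("frame times must be strictly increasing")
  total <- max(times)
  if (is.null(window)) window <- c(total / 2, total)
  if (window[1] > window[2] || window[2] > total + 1e-9 || window[1] < 0)
    stop(sprintf("window [%g, %g] ns outside trajectory time range [0, %g] ns",
                 window[1], window[2], total))
  structure(list(topology = topology, coords = coords, times = times,
                 window = window),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = [%g, %g] ns, window [%g, %g] ns\n",
              dim(x$coords)[1], dim(x$coords)[2], min(x$times), max(x$times),
              x$window[1], x$window[2]))
  invisible(x)
}

# Frames inside the analysis window.
window_frames <- function(traj) {
  which(traj$times >= traj$window[1] - 1e-9 &
        traj$times <= traj$window[2] + 1e-9)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Plain-text multi-model PDB (MODEL/ENDMDL blocks), the package's
#' dependency-free fixture format; files round-trip through
#' [read_trajectory()].
#'
#' @param trajectory A `trajectory` (or a `topology`, written as one model).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(trajectory, path) {
  if (inherits(trajectory, "topology")) {
    topo <- trajectory
    coords <- array(topo$coords, dim = c(1L, nrow(topo$atoms), 3L))
  } else {
    stopifnot(inherits(trajectory, "trajectory"))
    topo <- trajectory$topology
    coords <- trajectory$coords
  }
  at <- topo$atoms
  con <- file(path, "w")
  on.exit(close(con))
  n_f <- dim(coords)[1]
  for (f in seq_len(n_f)) {
    writeLines(sprintf("MODEL %8d", f), con)
    recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    at$index,
                    ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name),
                    substr(at$resid, 1, 3), at$chain, at$resno,
                    coords[f, , 1], coords[f, , 2], coords[f, , 3],
                    1.0, 0.0, at$element)
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
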