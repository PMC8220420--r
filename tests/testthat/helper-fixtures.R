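# Shared fixtures and independent oracles, built in code at test time.

# Linear CA-only chain topology (one atom per residue).
make_chain_topology <- function(n_res, chain = "A", resno = seq_len(n_res),
                                spacing = 4) {
  atoms <- data.frame(index = seq_len(n_res), name = "CA", element = "C",
                      chain = chain, resno = resno, resid = "ALA",
                      stringsAsFactors = FALSE)
  # zig-zag (non-collinear) so rigid-body fits are well conditioned
  i <- seq_len(n_res)
  coords <- cbind(i * spacing, (i %% 2) * 1.5, (i %% 3) * 1.1)
  allokin:::build_topology(atoms, coords)
}

# Trajectory from a list of N x 3 frames.
make_trajectory <- function(topology, frames, window = NULL) {
  allokin:::new_trajectory(topology, frames, dt = 0.1, window = window)
}

# Composite path comparator mirroring the documented ordering contract
# (cost, then residue count, then lexicographic node-rank sequence);
# written independently of the package internals.
oracle_less <- function(a, b, tol = 1e-12) {
  if (a$cost < b$cost - tol) return(TRUE)
  if (a$cost > b$cost + tol) return(FALSE)
  if (length(a$seq) != length(b$seq)) return(length(a$seq) < length(b$seq))
  for (i in seq_along(a$seq)) {
    if (a$seq[i] != b$seq[i]) return(a$seq[i] < b$seq[i])
  }
  FALSE
}

# Exhaustive enumeration of all simple paths between two nodes of a
# comm_graph, sorted by the composite order. Brute-force DFS: the
# independent oracle for the k-shortest search.
oracle_all_simple_paths <- function(graph, source, target) {
  nodes <- graph$nodes
  rank <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  cost_m <- matrix(Inf, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- rank[[graph$edges$res_i[r]]]
    j <- rank[[graph$edges$res_j[r]]]
    w <- graph$edges$cost[r]
    cost_m[i, j] <- min(cost_m[i, j], w)
    cost_m[j, i] <- cost_m[i, j]
  }
  src <- rank[[source]]; dst <- rank[[target]]
  out <- list()
  dfs <- function(path, cost) {
    v <- path[length(path)]
    if (v == dst) {
      out[[length(out) + 1L]] <<- list(seq = path, cost = cost)
      return()
    }
    for (u in which(is.finite(cost_m[v, ]))) {
      if (u %in% path) next
      dfs(c(path, u), cost + cost_m[v, u])
    }
  }
  dfs(src, 0)
  if (!length(out)) return(out)
  # insertion sort with the composite comparator (n is tiny)
  for (i in seq_along(out)[-1]) {
    key <- out[[i]]
    j <- i - 1L
    while (j >= 1L && oracle_less(key, out[[j]])) {
      out[[j + 1L]] <- out[[j]]
      j <- j - 1L
    }
    out[[j + 1L]] <- key
  }
  lapply(out, function(p) list(residues = nodes[p$seq], cost = p$cost))
}

# Random communication graph on <= 8 nodes: random H-bond probabilities,
# optionally a zero-cost covalent backbone (stresses cost ties).
random_comm_graph <- function(n_nodes, seed, p_edge = 0.4,
                              with_backbone = NA) {
  set.seed(seed)
  if (is.na(with_backbone)) with_backbone <- stats::runif(1) < 0.5
  residues <- sprintf("A:%d", seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  pr <- data.frame(res_i = residues[pairs[1, keep]],
                   res_j = residues[pairs[2, keep]],
                   probability = stats::runif(sum(keep), 0.05, 1),
                   stringsAsFactors = FALSE)
  adjacency <- if (with_backbone) {
    data.frame(res_i = residues[-n_nodes], res_j = residues[-1],
               stringsAsFactors = FALSE)
  } else {
    data.frame(res_i = character(0), res_j = character(0))
  }
  mat <- hbond_matrix_from_pairs(residues, pr)
  build_graph(mat, adjacency)
}

# A minimal hand-written PDB fixture: two alanine-like residues with
# backbone N/H/CA/C/O atoms, hydrogen-bond capable.
two_residue_pdb <- function(path, with_hydrogens = TRUE) {
  atom <- function(serial, name, resno, x, y, z, elem, alt = " ", occ = 1.0) {
    sprintf("ATOM  %5d %-4s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, "ALA", "A", resno, x, y, z, occ, 0.0, elem)
  }
  lines <- c(
    atom(1, "N",  1, 0.0, 0.0, 0.0, "N"),
    if (with_hydrogens) atom(2, "H", 1, 0.0, 0.0, 1.0, "H"),
    atom(3, "CA", 1, 1.5, 0.0, 0.0, "C"),
    atom(4, "C",  1, 3.0, 0.0, 0.0, "C"),
    atom(5, "O",  1, 3.4, 1.1, 0.0, "O"),
    atom(6, "N",  2, 4.3, -0.7, 0.0, "N"),
    if (with_hydrogens) atom(7, "H", 2, 4.3, -0.7, 1.0, "H"),
    atom(8, "CA", 2, 5.8, -0.7, 0.0, "C"),
    atom(9, "C",  2, 7.3, -0.7, 0.0, "C"),
    atom(10, "O", 2, 7.7, 0.4, 0.0, "O"),
    "END")
  writeLines(lines, path)
  path
}

# Geometry fixture: donor N-H and acceptor O at a requested donor-acceptor
# distance and deviation-from-linearity angle (degrees), in two residues.
hbond_geometry_fixture <- function(dist, deviation_deg) {
  # donor residue: N at origin, H at (0,0,1); acceptor O on the N-H axis
  # rotated by the deviation angle about the H position
  dev <- deviation_deg * pi / 180
  # place O such that |N - O| = dist and angle(D-H...A) = 180 - deviation.
  # Solve in the x-z plane: H = (0,0,1); O = H + r*(sin a, 0, cos a) where
  # a is the angle of H->O from the N->H axis (+z); deviation = a.
  # Find r from |N-O| = dist.
  a <- dev
  # |N - O|^2 = (r sin a)^2 + (1 + r cos a)^2 = dist^2
  # r^2 + 2 r cos a + 1 - dist^2 = 0
  r <- (-2 * cos(a) + sqrt(4 * cos(a)^2 - 4 * (1 - dist^2))) / 2
  O <- c(r * sin(a), 0, 1 + r * cos(a))
  atoms <- data.frame(index = 1:3,
                      name = c("N", "H", "O"),
                      element = c("N", "H", "O"),
                      chain = "A", resno = c(1, 1, 2),
                      resid = "ALA", stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(0, 0, 1), O)
  allokin:::build_topology(atoms, coords)
}
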