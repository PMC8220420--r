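#' Build the residue communication graph
#'
#' Protein residues form the nodes. Hydrogen-bond edges carry cost
#' `C_ij = -ln(HB_ij)`, so highly probable bonds are cheap to traverse;
#' a pair with `HB_ij = 0` gets no edge. Covalently consecutive residues
#' are connected with cost zero. When a pair has both an H-bond and a
#' covalent edge the minimum cost (zero, covalent) is kept.
#'
#' @param matrix An `hbond_matrix`.
#' @param adjacency Data frame of covalent residue pairs from
#'   [covalent_adjacency()] (columns `res_i`, `res_j`), sharing the
#'   residue universe of `matrix`.
#' @return An object of class `comm_graph`: `nodes` (residue ids, ordered
#'   by chain then residue number), `edges` (data frame `res_i`, `res_j`,
#'   `probability`, `cost`, `provenance`).
#' @export
build_graph <- function(matrix, adjacency) {
  stopifnot(inherits(matrix, "hbond_matrix"))
  P <- matrix$P
  if (any(P < 0 | P > 1)) stop("probabilities must lie in [0, 1]")
  nodes <- order_residue_ids(matrix$residues)
  if (nrow(adjacency)) {
    unknown <- setdiff(c(adjacency$res_i, adjacency$res_j), nodes)
    if (length(unknown))
      stop("adjacency references residues outside the matrix universe: ",
           paste(utils::head(unknown, 3), collapse = ", "))
  }
  cov_key <- if (nrow(adjacency)) {
    paste(pmin(adjacency$res_i, adjacency$res_j),
          pmax(adjacency$res_i, adjacency$res_j), sep = "|")
  } else character(0)

  ut <- which(upper.tri(P) & P > 0, arr.ind = TRUE)
  hb <- if (nrow(ut)) {
    data.frame(res_i = matrix$residues[ut[, 1]],
               res_j = matrix$residues[ut[, 2]],
               probability = P[ut],
               cost = -log(P[ut]),
               provenance = "hbond", stringsAsFactors = FALSE)
  } else {
    data.frame(res_i = character(0), res_j = character(0),
               probability = numeric(0), cost = numeric(0),
               provenance = character(0), stringsAsFactors = FALSE)
  }
  hb_key <- paste(pmin(hb$res_i, hb$res_j), pmax(hb$res_i, hb$res_j), sep = "|")
  # covalent edges win (cost 0) when both exist
  hb <- hb[!(hb_key %in% cov_key), , drop = FALSE]
  cov <- if (nrow(adjacency)) {
    data.frame(res_i = adjacency$res_i, res_j = adjacency$res_j,
               probability = NA_real_, cost = 0,
               provenance = "covalent", stringsAsFactors = FALSE)
  } else hb[0, ]
  edges <- rbind(cov, hb)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "comm_graph")
}

# Residue ids ordered by (chain, residue number); this order defines the
# lexicographic tie-break used by the path search.
order_residue_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  chain <- vapply(parts, `[[`, character(1), 1)
  resno <- as.numeric(vapply(parts, `[[`, character(1), 2))
  ids[order(chain, resno)]
}

#' @export
print.comm_graph <- function(x, ...) {
  tab <- table(x$edges$provenance)
  cat(sprintf("<comm_graph> %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

# Adjacency list representation: per node, integer neighbor ids and edge
# costs. Node ids are ranks in the canonical (chain, resno) order.
graph_adjlist <- function(graph) {
  nodes <- graph$nodes
  rank <- stats::setNames(seq_along(nodes), nodes)
  nbr <- vector("list", length(nodes))
  wts <- vector("list", length(nodes))
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    i <- rank[[e$res_i[k]]]; j <- rank[[e$res_j[k]]]
    nbr[[i]] <- c(nbr[[i]], j); wts[[i]] <- c(wts[[i]], e$cost[k])
    nbr[[j]] <- c(nbr[[j]], i); wts[[j]] <- c(wts[[j]], e$cost[k])
  }
  list(nodes = nodes, rank = rank, nbr = nbr, wts = wts)
}

# Composite path order: total cost, then number of residues, then
# lexicographic on the rank sequence. Returns TRUE when a < b.
path_less <- function(cost_a, seq_a, cost_b, seq_b, tol = 1e-12) {
  if (cost_a < cost_b - tol) return(TRUE)
  if (cost_a > cost_b + tol) return(FALSE)
  la <- length(seq_a); lb <- length(seq_b)
  if (la != lb) return(la < lb)
  for (i in seq_len(la)) {
    if (seq_a[i] != seq_b[i]) return(seq_a[i] < seq_b[i])
  }
  FALSE
}

# Dijkstra with the composite tie-break; the comparator is
# extension-invariant (cost and length are additive, the sequence order is
# prefix-stable), so label-setting search remains exact. `banned_nodes` /
# `banned_edges` support the deviation search. O(V^2) selection.
dijkstra_path <- function(adj, src, dst, banned_nodes = integer(0),
                          banned_edges = NULL) {
  n <- length(adj$nodes)
  dist <- rep(Inf, n)
  seqs <- vector("list", n)
  done <- rep(FALSE, n)
  done[banned_nodes] <- TRUE
  if (done[src] || done[dst]) return(NULL)
  dist[src] <- 0
  seqs[[src]] <- src
  repeat {
    # pick the unfinished node with the smallest label
    best <- 0L
    for (v in which(!done & is.finite(dist))) {
      if (best == 0L ||
          path_less(dist[v], seqs[[v]], dist[best], seqs[[best]])) best <- v
    }
    if (best == 0L) return(NULL)
    if (best == dst) {
      return(list(cost = dist[dst], seq = seqs[[dst]]))
    }
    done[best] <- TRUE
    nbrs <- adj$nbr[[best]]
    wts <- adj$wts[[best]]
    for (k in seq_along(nbrs)) {
      v <- nbrs[k]
      if (done[v]) next
      if (!is.null(banned_edges) &&
          !is.na(banned_edges[best, v]) && banned_edges[best, v]) next
      nd <- dist[best] + wts[k]
      nseq <- c(seqs[[best]], v)
      if (!is.finite(dist[v]) || path_less(nd, nseq, dist[v], seqs[[v]])) {
        dist[v] <- nd
        seqs[[v]] <- nseq
      }
    }
  }
}

new_residue_path <- function(graph, node_seq, cost) {
  structure(list(residues = graph$nodes[node_seq],
                 cost = cost,
                 length = length(node_seq)),
            class = "residue_path")
}

#' @export
print.residue_path <- function(x, ...) {
  cat(sprintf("<residue_path> %s (cost %.4g, %d residues)\n",
              paste(x$residues, collapse = " - "), x$cost, x$length))
  invisible(x)
}

#' Minimum-cost path between two residues
#'
#' Dijkstra search on the communication graph with a deterministic
#' tie-break: among equal-cost paths the one with fewer residues wins, and
#' remaining ties are broken lexicographically on the residue sequence
#' (residues ordered by chain, then number). Disconnected pairs yield an
#' explicit no-path result rather than an error.
#'
#' @param graph A `comm_graph`.
#' @param source,target Residue ids (`"chain:resno"`), distinct.
#' @return A `residue_path` (fields `residues`, `cost`, `length`), or
#'   `NULL` when no path exists.
#' @export
shortest_path <- function(graph, source, target) {
  stopifnot(inherits(graph, "comm_graph"))
  if (source == target) stop("source and target must differ")
  if (!source %in% graph$nodes) stop("source residue not in graph: ", source)
  if (!target %in% graph$nodes) stop("target residue not in graph: ", target)
  adj <- graph_adjlist(graph)
  res <- dijkstra_path(adj, adj$rank[[source]], adj$rank[[target]])
  if (is.null(res)) return(NULL)
  new_residue_path(graph, res$seq, res$cost)
}

#' k shortest loopless paths
#'
#' Yen-style deviation search returning up to `k` distinct simple paths in
#' nondecreasing composite order (cost, then residue count, then
#' lexicographic residue sequence). The first path always equals
#' [shortest_path()]. When fewer than `k` simple paths exist, all of them
#' are returned.
#'
#' @inheritParams shortest_path
#' @param k Maximum number of paths (>= 1; default 10).
#' @return A list of `residue_path` objects (possibly shorter than `k`,
#'   possibly empty when the pair is disconnected).
#' @export
k_shortest_paths <- function(graph, source, target, k = 10) {
  stopifnot(inherits(graph, "comm_graph"), k >= 1)
  if (source == target) stop("source and target must differ")
  if (!source %in% graph$nodes) stop("source residue not in graph: ", source)
  if (!target %in% graph$nodes) stop("target residue not in graph: ", target)
  adj <- graph_adjlist(graph)
  n <- length(adj$nodes)
  src <- adj$rank[[source]]; dst <- adj$rank[[target]]

  first <- dijkstra_path(adj, src, dst)
  if (is.null(first)) return(list())
  A <- list(first)
  A_keys <- paste(first$seq, collapse = ",")
  B <- list()
  B_keys <- character(0)

  while (length(A) < k) {
    prev <- A[[length(A)]]$seq
    for (i in seq_len(length(prev) - 1L)) {
      spur_node <- prev[i]
      root <- prev[seq_len(i)]
      root_cost <- path_cost_ranks(adj, root)
      banned_edges <- matrix(NA, n, n)
      for (p in A) {
        if (length(p$seq) > i && identical(p$seq[seq_len(i)], root)) {
          banned_edges[p$seq[i], p$seq[i + 1L]] <- TRUE
          banned_edges[p$seq[i + 1L], p$seq[i]] <- TRUE
        }
      }
      banned_nodes <- setdiff(root, spur_node)
      spur <- dijkstra_path(adj, spur_node, dst,
                            banned_nodes = banned_nodes,
                            banned_edges = banned_edges)
      if (is.null(spur)) next
      total_seq <- c(root[-length(root)], spur$seq)
      if (anyDuplicated(total_seq)) next
      key <- paste(total_seq, collapse = ",")
      if (key %in% A_keys || key %in% B_keys) next
      B[[length(B) + 1L]] <- list(cost = root_cost + spur$cost,
                                  seq = total_seq)
      B_keys <- c(B_keys, key)
    }
    if (!length(B)) break
    # pop the best candidate
    best <- 1L
    for (b in seq_along(B)) {
      if (path_less(B[[b]]$cost, B[[b]]$seq, B[[best]]$cost, B[[best]]$seq))
        best <- b
    }
    A[[length(A) + 1L]] <- B[[best]]
    A_keys <- c(A_keys, B_keys[best])
    B <- B[-best]; B_keys <- B_keys[-best]
  }
  lapply(A, function(p) new_residue_path(graph, p$seq, p$cost))
}

# Sum of edge costs along a rank sequence.
path_cost_ranks <- function(adj, ranks) {
  if (length(ranks) < 2L) return(0)
  total <- 0
  for (i in seq_len(length(ranks) - 1L)) {
    u <- ranks[i]; v <- ranks[i + 1L]
    hit <- which(adj$nbr[[u]] == v)
    if (!length(hit)) stop("sequence is not a path in the graph")
    total <- total + min(adj$wts[[u]][hit])
  }
  total
}

#' Recompute the cost of a residue path on a graph
#'
#' @param graph A `comm_graph`.
#' @param path A `residue_path` or character vector of residue ids.
#' @return Sum of edge costs along the path.
#' @export
path_cost <- function(graph, path) {
  ids <- if (inherits(path, "residue_path")) path$residues else path
  adj <- graph_adjlist(graph)
  path_cost_ranks(adj, unname(adj$rank[ids]))
}

#' Residue participation frequency in a path set
#'
#' Fraction of paths that contain each residue (endpoints included); the
#' quantity colour-mapped onto structures when visualising which residues
#' carry the k-shortest communication pathways.
#'
#' @param paths Nonempty list of `residue_path` objects.
#' @return Named numeric vector (residue id -> frequency between 0 and 1),
#'   sorted decreasing.
#' @export
participation_frequency <- function(paths) {
  if (!length(paths)) stop("need at least one path")
  all_res <- unlist(lapply(paths, function(p) unique(p$residues)))
  freq <- table(all_res) / length(paths)
  sort(stats::setNames(as.numeric(freq), names(freq)), decreasing = TRUE)
}

#' Block-wise path-length statistics
#'
#' Given path sets computed from temporally blocked occupancy matrices
#' (e.g. five 20-ns blocks of a 100-ns window), reports the mean and SEM
#' over blocks of the average path length (number of connected residues)
#' per block. Blocks with no path are excluded and reported.
#'
#' @param block_paths List (one element per block) of lists of
#'   `residue_path` objects.
#' @return A list: `mean`, `sem` (`NA` when fewer than 2 usable blocks),
#'   `block_means`, `n_blocks_used`, `excluded_blocks`.
#' @export
path_length_statistics <- function(block_paths) {
  stopifnot(is.list(block_paths), length(block_paths) >= 1L)
  block_means <- vapply(block_paths, function(paths) {
    if (!length(paths)) return(NA_real_)
    mean(vapply(paths, `[[`, numeric(1), "length"))
  }, numeric(1))
  excluded <- which(is.na(block_means))
  used <- block_means[!is.na(block_means)]
  list(mean = if (length(used)) mean(used) else NA_real_,
       sem = if (length(used) >= 2L) stats::sd(used) / sqrt(length(used))
             else NA_real_,
       block_means = block_means,
       n_blocks_used = length(used),
       excluded_blocks = excluded)
}

#' Cassette partition of residues
#'
#' Assigns each residue to the N-terminal (NC) or C-terminal (CC) cassette.
#' By default the split follows the construct boundary in Brr2 author
#' numbering: residues with number < 1282 belong to the NC, >= 1282 to the
#' CC. Alternatively, chains can be mapped explicitly.
#'
#' @param residues Character vector of residue ids (`"chain:resno"`).
#' @param boundary Residue number at which the CC starts (default 1282).
#' @param by_chain Optional named character vector mapping chain ->
#'   `"NC"`/`"CC"`; overrides the numeric boundary.
#' @return Named character vector residue id -> `"NC"`/`"CC"`.
#' @export
cassette_partition <- function(residues, boundary = 1282, by_chain = NULL) {
  parts <- strsplit(residues, ":", fixed = TRUE)
  chain <- vapply(parts, `[[`, character(1), 1)
  resno <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (!is.null(by_chain)) {
    miss <- setdiff(unique(chain), names(by_chain))
    if (length(miss)) stop("no cassette assignment for chain(s): ",
                           paste(miss, collapse = ", "))
    out <- unname(by_chain[chain])
  } else {
    out <- ifelse(resno < boundary, "NC", "CC")
  }
  stats::setNames(out, residues)
}

#' Interface crossings of communication paths
#'
#' For each path, finds the edges whose endpoints lie in different
#' cassettes, and tallies the crossing residue pairs over the whole path
#' set. The dominant pairs are the hydrogen bonds that carry intercassette
#' communication.
#'
#' @param paths List of `residue_path` objects.
#' @param partition Named character vector residue -> `"NC"`/`"CC"` from
#'   [cassette_partition()]; every path residue must be assigned.
#' @return A list: `per_path` (list of data frames with `res_i`, `res_j`
#'   per crossing edge), `tally` (data frame `res_i`, `res_j`, `count`
#'   sorted decreasing), `n_crossings` (integer per path).
#' @export
interface_crossings <- function(paths, partition) {
  stopifnot(is.list(paths))
  per_path <- lapply(paths, function(p) {
    res <- p$residues
    un <- setdiff(res, names(partition))
    if (length(un)) stop("unpartitioned residue(s): ",
                         paste(un, collapse = ", "))
    side <- partition[res]
    cross <- which(side[-length(side)] != side[-1])
    data.frame(res_i = res[cross], res_j = res[cross + 1L],
               stringsAsFactors = FALSE)
  })
  all_cross <- do.call(rbind, per_path)
  tally <- if (nrow(all_cross)) {
    key <- paste(pmin(all_cross$res_i, all_cross$res_j),
                 pmax(all_cross$res_i, all_cross$res_j), sep = "|")
    tab <- sort(table(key), decreasing = TRUE)
    parts <- strsplit(names(tab), "|", fixed = TRUE)
    data.frame(res_i = vapply(parts, `[[`, character(1), 1),
               res_j = vapply(parts, `[[`, character(1), 2),
               count = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    data.frame(res_i = character(0), res_j = character(0),
               count = integer(0))
  }
  list(per_path = per_path, tally = tally,
       n_crossings = vapply(per_path, nrow, integer(1)))
}

#' Write a communication graph as an edge list
#'
#' Tab-delimited columns `res_i`, `res_j`, `probability`, `cost`,
#' `provenance`.
#'
#' @param graph A `comm_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comm_graph <- function(graph, path) {
  stopifnot(inherits(graph, "comm_graph"))
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
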