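test_that("edge costs are -ln(probability), zero for covalent, absent for zero probability", {
  residues <- sprintf("A:%d", 1:4)
  pairs <- data.frame(res_i = c("A:1", "A:2", "A:1"),
                      res_j = c("A:3", "A:4", "A:4"),
                      probability = c(1.0, 0.5, 0))
  mat <- hbond_matrix_from_pairs(residues, pairs)
  adj <- data.frame(res_i = c("A:1", "A:2", "A:3"),
                    res_j = c("A:2", "A:3", "A:4"))
  g <- build_graph(mat, adj)
  e <- g$edges
  expect_equal(e$cost[e$res_i == "A:1" & e$res_j == "A:3"], 0)
  expect_equal(e$cost[e$res_i == "A:2" & e$res_j == "A:4"], log(2),
               tolerance = 1e-12)
  # zero-probability pair contributes no edge
  expect_false(any(e$res_i == "A:1" & e$res_j == "A:4"))
  # covalent edges exactly the adjacency set, cost 0
  cov <- e[e$provenance == "covalent", ]
  expect_equal(nrow(cov), 3)
  expect_true(all(cov$cost == 0))
  # covalent wins when both edge types connect a pair
  pairs2 <- data.frame(res_i = "A:1", res_j = "A:2", probability = 0.5)
  g2 <- build_graph(hbond_matrix_from_pairs(residues, pairs2), adj)
  e12 <- g2$edges[g2$edges$res_i == "A:1" & g2$edges$res_j == "A:2", ]
  expect_equal(nrow(e12), 1)
  expect_equal(e12$cost, 0)
  expect_equal(e12$provenance, "covalent")
})

test_that("shortest path matches exhaustive enumeration on a known 4-node graph", {
  residues <- sprintf("A:%d", 1:4)
  pairs <- data.frame(res_i = c("A:1", "A:1", "A:2", "A:3"),
                      res_j = c("A:2", "A:3", "A:4", "A:4"),
                      probability = c(0.9, 0.4, 0.8, 0.9))
  mat <- hbond_matrix_from_pairs(residues, pairs)
  g <- build_graph(mat, data.frame(res_i = character(0), res_j = character(0)))
  sp <- shortest_path(g, "A:1", "A:4")
  oracle <- oracle_all_simple_paths(g, "A:1", "A:4")
  expect_identical(sp$residues, oracle[[1]]$residues)
  expect_equal(sp$cost, oracle[[1]]$cost, tolerance = 1e-12)
  # A:1 -> A:2 -> A:4 has cost -ln(.9) - ln(.8) < -ln(.4) - ln(.9)
  expect_identical(sp$residues, c("A:1", "A:2", "A:4"))
  # cost additivity against independent recomputation
  expect_equal(sp$cost, path_cost(g, sp), tolerance = 1e-12)
})

test_that("covalent chains give zero-cost paths along the backbone", {
  topo <- make_chain_topology(6)
  mat <- hbond_matrix_from_pairs(topo$residues$id,
                                 data.frame(res_i = character(0),
                                            res_j = character(0),
                                            probability = numeric(0)))
  g <- build_graph(mat, covalent_adjacency(topo))
  sp <- shortest_path(g, "A:1", "A:6")
  expect_equal(sp$cost, 0)
  expect_identical(sp$residues, sprintf("A:%d", 1:6))
  # adjacent pair: single zero-cost hop
  sp2 <- shortest_path(g, "A:2", "A:3")
  expect_equal(sp2$cost, 0)
  expect_equal(sp2$length, 2)
})

test_that("disconnected pairs yield an explicit no-path result", {
  residues <- c("A:1", "A:2", "B:1", "B:2")
  mat <- hbond_matrix_from_pairs(residues,
                                 data.frame(res_i = "A:1", res_j = "A:2",
                                            probability = 0.5))
  g <- build_graph(mat, data.frame(res_i = character(0), res_j = character(0)))
  expect_null(shortest_path(g, "A:1", "B:1"))
  expect_equal(length(k_shortest_paths(g, "A:1", "B:1")), 0)
  expect_error(shortest_path(g, "A:1", "A:1"), "must differ")
  expect_error(shortest_path(g, "A:1", "C:9"), "not in graph")
})

test_that("k-shortest paths equal exhaustive enumeration on random graphs", {
  # property suite over 100 seeded random graphs with <= 8 nodes, with and
  # without zero-cost backbones (cost ties)
  for (s in 1:100) {
    n <- 4 + (s %% 5)
    g <- random_comm_graph(n, seed = s)
    src <- "A:1"; dst <- sprintf("A:%d", n)
    oracle <- oracle_all_simple_paths(g, src, dst)
    got <- k_shortest_paths(g, src, dst, k = 10)
    k_expect <- min(10, length(oracle))
    expect_equal(length(got), k_expect,
                 info = sprintf("seed %d: path count", s))
    for (i in seq_len(k_expect)) {
      expect_identical(got[[i]]$residues, oracle[[i]]$residues,
                       info = sprintf("seed %d rank %d", s, i))
      expect_equal(got[[i]]$cost, oracle[[i]]$cost, tolerance = 1e-9,
                   info = sprintf("seed %d rank %d cost", s, i))
    }
    if (length(got)) {
      expect_identical(got[[1]]$residues,
                       shortest_path(g, src, dst)$residues)
    }
  }
})

test_that("shortest-path costs agree with an independent graph library", {
  skip_if_not_installed("igraph")
  for (s in 1:25) {
    g <- random_comm_graph(6, seed = 4000 + s)
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("res_i", "res_j")], directed = FALSE,
      vertices = g$nodes)
    d <- igraph::distances(ig, v = "A:1", to = "A:6",
                           weights = g$edges$cost)[1, 1]
    sp <- shortest_path(g, "A:1", "A:6")
    if (is.infinite(d)) {
      expect_null(sp)
    } else {
      expect_equal(sp$cost, d, tolerance = 1e-9)
    }
  }
})

test_that("a parallel ladder with exactly three simple routes returns all of them", {
  residues <- c("A:1", "A:2", "A:3", "A:4", "A:5")
  # three disjoint routes 1->5: direct, via 2, via 3-4
  pairs <- data.frame(res_i = c("A:1", "A:1", "A:2", "A:1", "A:3", "A:4"),
                      res_j = c("A:5", "A:2", "A:5", "A:3", "A:4", "A:5"),
                      probability = c(0.3, 0.9, 0.9, 0.8, 0.8, 0.8))
  g <- build_graph(hbond_matrix_from_pairs(residues, pairs),
                   data.frame(res_i = character(0), res_j = character(0)))
  got <- k_shortest_paths(g, "A:1", "A:5", k = 10)
  expect_equal(length(got), 3)
  expect_true(all(diff(vapply(got, `[[`, numeric(1), "cost")) >= -1e-12))
  expect_identical(k_shortest_paths(g, "A:1", "A:5", k = 1)[[1]]$residues,
                   got[[1]]$residues)
})

test_that("raising an edge probability never increases the shortest-path cost", {
  for (s in 1:20) {
    g <- random_comm_graph(6, seed = 900 + s, with_backbone = FALSE)
    sp0 <- shortest_path(g, "A:1", "A:6")
    if (is.null(sp0)) next
    hb_rows <- which(g$edges$provenance == "hbond")
    if (!length(hb_rows)) next
    r <- hb_rows[1 + (s %% length(hb_rows))]
    g2 <- g
    p_new <- sqrt(g2$edges$probability[r])  # raise towards 1
    g2$edges$probability[r] <- p_new
    g2$edges$cost[r] <- -log(p_new)
    sp1 <- shortest_path(g2, "A:1", "A:6")
    expect_lte(sp1$cost, sp0$cost + 1e-12)
  }
})

test_that("participation frequency counts paths per residue, endpoints included", {
  p1 <- structure(list(residues = c("A:1", "A:2", "A:4"), cost = 1, length = 3),
                  class = "residue_path")
  p2 <- structure(list(residues = c("A:1", "A:3", "A:2", "A:4"), cost = 2,
                       length = 4), class = "residue_path")
  f1 <- participation_frequency(list(p1))
  expect_true(all(f1 == 1))
  f <- participation_frequency(list(p1, p2))
  expect_equal(unname(f["A:2"]), 1.0)
  expect_equal(unname(f["A:3"]), 0.5)
  expect_equal(unname(f["A:1"]), 1.0)
  expect_error(participation_frequency(list()), "at least one")
})

test_that("block path-length statistics give mean and SEM over blocks", {
  mk <- function(len) structure(list(residues = sprintf("A:%d", 1:len),
                                     cost = 0, length = len),
                                class = "residue_path")
  # identical blocks: SEM 0
  same <- replicate(5, list(mk(6)), simplify = FALSE)
  st <- path_length_statistics(same)
  expect_equal(st$mean, 6)
  expect_equal(st$sem, 0)
  # alternation between 5- and 7-residue paths: mean 6
  alt <- list(list(mk(5)), list(mk(7)))
  st2 <- path_length_statistics(alt)
  expect_equal(st2$mean, 6)
  expect_equal(st2$sem, sd(c(5, 7)) / sqrt(2))
  # single block: mean defined, SEM absent
  st3 <- path_length_statistics(list(list(mk(4))))
  expect_equal(st3$mean, 4)
  expect_true(is.na(st3$sem))
  # a block with no path is excluded and reported
  st4 <- path_length_statistics(list(list(mk(5)), list(), list(mk(7))))
  expect_equal(st4$n_blocks_used, 2)
  expect_equal(st4$excluded_blocks, 2)
  expect_equal(st4$mean, 6)
})

test_that("interface crossings are tallied per partition-spanning edge", {
  part <- cassette_partition(c(sprintf("A:%d", 1:5), sprintf("B:%d", 6:10)),
                             by_chain = c(A = "NC", B = "CC"))
  mk <- function(res) structure(list(residues = res, cost = 0,
                                     length = length(res)),
                                class = "residue_path")
  # entirely within the NC: no crossings
  cr0 <- interface_crossings(list(mk(c("A:1", "A:2", "A:3"))), part)
  expect_equal(cr0$n_crossings, 0)
  # one crossing at the designated pair
  cr1 <- interface_crossings(list(mk(c("A:1", "A:4", "B:7", "B:8"))), part)
  expect_equal(cr1$n_crossings, 1)
  expect_equal(cr1$tally$count, 1L)
  expect_setequal(c(cr1$tally$res_i, cr1$tally$res_j), c("A:4", "B:7"))
  # zig-zag path crossing three times
  zig <- mk(c("A:1", "B:6", "A:2", "B:7"))
  expect_equal(interface_crossings(list(zig), part)$n_crossings, 3)
  # unpartitioned residue errors
  expect_error(interface_crossings(list(mk(c("A:1", "C:99"))), part),
               "unpartitioned")
  # Brr2 numbering default boundary: 1281 is NC, 1282 is CC
  p <- cassette_partition(c("A:1281", "A:1282"))
  expect_equal(unname(p), c("NC", "CC"))
})

test_that("planted communication routes are recovered as the rank-1 path", {
  hits_route <- 0L; hits_dom <- 0L
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    net <- generate_occupancy_network(network_design(seed = 2000 + s))
    g <- build_graph(net$matrix, net$adjacency)
    ps <- k_shortest_paths(g, net$truth$endpoints[1],
                           net$truth$endpoints[2], k = 10)
    if (identical(ps[[1]]$residues, net$truth$route))
      hits_route <- hits_route + 1L
    cr <- interface_crossings(ps, net$partition)
    key <- paste(sort(net$truth$interface_pair), collapse = "|")
    tal_key <- paste(cr$tally$res_i, cr$tally$res_j, sep = "|")
    planted_count <- cr$tally$count[match(key, tal_key)]
    if (!is.na(planted_count) &&
        planted_count >= max(cr$tally$count))
      hits_dom <- hits_dom + 1L
  }
  expect_gte(hits_route / n_seeds, 0.95)
  expect_gte(hits_dom / n_seeds, 0.95)
})

test_that("graphs serialize as edge lists", {
  net <- generate_occupancy_network(network_design(seed = 3))
  g <- build_graph(net$matrix, net$adjacency)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_comm_graph(g, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(g$edges))
  expect_true(all(back$cost >= 0))
})
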