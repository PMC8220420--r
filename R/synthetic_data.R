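# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Stopped-flow experimental design for synthetic kinetics data
#'
#' Captures the published experimental design: a concentration series of
#' association experiments plus a chase experiment, each with replicate
#' traces of 1000 log-sampled points carrying additive Gaussian noise.
#' Generating rate constants default to the published values for the
#' chosen construct/nucleotide ([brr2_rate_constants()]).
#'
#' @param construct Construct label (e.g. `"hBrr2T1"`).
#' @param nucleotide `"mant-ADP"` or `"mant-ATPgS"`.
#' @param rates Optional data frame in [brr2_rate_constants()] format
#'   overriding the published generating constants.
#' @param protein_conc Protein concentration, uM (default 0.2; the
#'   published experiments used 0.2-0.5 uM against >= 1 uM nucleotide).
#' @param conc_series Association nucleotide concentrations, uM.
#' @param chase_nucleotide_conc Labelled-nucleotide concentration used to
#'   preform the chase complex, uM (default 5).
#' @param chase_conc Unlabelled competitor concentration, uM (default 100).
#' @param replicates Traces per condition (default 7; >= 3).
#' @param noise Noise SD as a fraction of the total amplitude
#'   (default 0.01).
#' @param n_points Points per trace (default 1000).
#' @param amplitudes Named amplitudes per cassette (default 1 each).
#' @param seed Base seed (default 0).
#' @return A list of class `kinetics_design`.
#' @export
kinetics_design <- function(construct = "hBrr2T1", nucleotide = "mant-ATPgS",
                            rates = NULL, protein_conc = 0.2,
                            conc_series = c(1, 2.5, 5, 10, 20),
                            chase_nucleotide_conc = 5, chase_conc = 100,
                            replicates = 7, noise = 0.01, n_points = 1000L,
                            amplitudes = c(NC = 1, CC = 1), seed = 0L) {
  if (is.null(rates)) {
    rates <- brr2_rate_constants(construct = construct,
                                 nucleotide = nucleotide)
    if (!nrow(rates))
      stop("no published rate constants for ", construct, " / ", nucleotide)
  }
  if (any(conc_series <= 0)) stop("concentrations must be > 0")
  if (replicates < 3L) stop("need >= 3 replicates")
  sites <- lapply(seq_len(nrow(rates)), function(i) {
    cas <- rates$cassette[i]
    amp <- if (cas %in% names(amplitudes)) unname(amplitudes[[cas]]) else 1
    binding_site(cas, k_on = rates$k1[i], k_off = rates$k_minus1[i],
                 amplitude = amp)
  })
  structure(list(construct = construct, nucleotide = nucleotide,
                 rates = rates, sites = sites, protein_conc = protein_conc,
                 conc_series = conc_series,
                 chase_nucleotide_conc = chase_nucleotide_conc,
                 chase_conc = chase_conc, replicates = as.integer(replicates),
                 noise = noise, n_points = as.integer(n_points),
                 seed = as.integer(seed)),
            class = "kinetics_design")
}

#' Generate a synthetic stopped-flow dataset
#'
#' Simulates the full experimental design of a construct/nucleotide pair:
#' association traces at every concentration of the series (one noiseless
#' model curve per concentration plus i.i.d. Gaussian noise per replicate)
#' and chase traces. Time windows adapt to the generating rates (five
#' half-lives of the slowest phase), matching how an experimenter chooses
#' acquisition spans; the slow CC chase therefore runs to thousands of
#' seconds. The generator is a pure function of (design, seed).
#'
#' @param design A [kinetics_design()].
#' @param dir Optional directory; when given, every trace is written via
#'   [write_kinetic_trace()] along with a `manifest.tsv` and a
#'   `truth.json` recording the generating constants.
#' @return A list of class `kinetics_dataset`: `association` (list per
#'   concentration of replicate [kinetic_trace()]s), `chase` (list of
#'   replicates), `design`, `truth`.
#' @export
generate_kinetics_dataset <- function(design, dir = NULL) {
  stopifnot(inherits(design, "kinetics_design"))
  with_seed(design$seed, {
    sites <- design$sites
    scheme <- binding_scheme(sites, protein_conc = design$protein_conc)
    total_amp <- sum(vapply(sites, `[[`, numeric(1), "amplitude"))
    sigma <- design$noise * total_amp

    association <- lapply(design$conc_series, function(conc) {
      slowest <- min(vapply(sites, apparent_rate, numeric(1),
                            nucleotide_conc = conc))
      spec <- experiment_spec("association", nucleotide_conc = conc,
                              time_span = c(1e-4, 5 / slowest),
                              n_points = design$n_points)
      clean <- model_association(scheme, spec)
      lapply(seq_len(design$replicates), function(r) {
        md <- trace_metadata(clean)
        md$replicate <- r
        md$construct <- design$construct
        md$nucleotide <- design$nucleotide
        md$seed <- design$seed
        kinetic_trace(clean$time,
                      clean$signal + stats::rnorm(length(clean$signal),
                                                  0, sigma),
                      metadata = md)
      })
    })
    names(association) <- as.character(design$conc_series)

    slowest_off <- min(vapply(sites, `[[`, numeric(1), "k_off"))
    chase_span <- c(1e-4, max(10, 5 / max(slowest_off, 1e-6)))
    chase_spec <- experiment_spec("chase",
                                  nucleotide_conc = design$chase_nucleotide_conc,
                                  chase_conc = design$chase_conc,
                                  time_span = chase_span,
                                  n_points = design$n_points)
    chase_clean <- model_chase(scheme, chase_spec)
    chase <- lapply(seq_len(design$replicates), function(r) {
      md <- trace_metadata(chase_clean)
      md$replicate <- r
      md$construct <- design$construct
      md$nucleotide <- design$nucleotide
      md$seed <- design$seed
      kinetic_trace(chase_clean$time,
                    chase_clean$signal + stats::rnorm(length(chase_clean$signal),
                                                      0, sigma),
                    metadata = md)
    })

    truth <- design$rates
    out <- structure(list(association = association, chase = chase,
                          design = design, truth = truth),
                     class = "kinetics_dataset")
    if (!is.null(dir)) write_kinetics_dataset(out, dir)
    out
  })
}

write_kinetics_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- dataset$design
  manifest <- list()
  for (conc in names(dataset$association)) {
    for (r in seq_along(dataset$association[[conc]])) {
      fn <- sprintf("assoc_c%s_r%d.tsv", gsub("[.]", "p", conc), r)
      write_kinetic_trace(dataset$association[[conc]][[r]],
                          file.path(dir, fn))
      manifest[[length(manifest) + 1L]] <-
        data.frame(construct = design$construct,
                   nucleotide = design$nucleotide, mode = "association",
                   conc_uM = as.numeric(conc), replicate = r,
                   trace_path = fn)
    }
  }
  for (r in seq_along(dataset$chase)) {
    fn <- sprintf("chase_r%d.tsv", r)
    write_kinetic_trace(dataset$chase[[r]], file.path(dir, fn))
    manifest[[length(manifest) + 1L]] <-
      data.frame(construct = design$construct,
                 nucleotide = design$nucleotide, mode = "chase",
                 conc_uM = design$chase_nucleotide_conc, replicate = r,
                 trace_path = fn)
  }
  utils::write.table(do.call(rbind, manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rates = dataset$truth, seed = design$seed,
                            noise = design$noise),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Synthetic communication-network design
#'
#' Describes a two-cassette toy system: two chains of `n_residues` each
#' (chain A = NC, chain B = CC), a planted communication route between two
#' pocket endpoint residues, and random background hydrogen bonds. Because
#' consecutive residues communicate at zero cost, the planted route
#' consists of the backbone runs from each endpoint to a designated
#' interface residue pair, joined by one high-occupancy interface hydrogen
#' bond at `p_path`; background edges have occupancy at most `p_bg`.
#'
#' @param n_residues Residues per cassette (default 30).
#' @param endpoints Length-2 residue ids, one per cassette (default the
#'   chain midpoints).
#' @param interface_pair Length-2 residue ids of the planted interface
#'   hydrogen bond (default `A:20` and `B:10` style positions).
#' @param p_path Planted interface-bond occupancy (default 0.95).
#' @param p_bg Background occupancy ceiling (default 0.3; must be <
#'   `p_path`).
#' @param n_background Number of random background bonds (default 40).
#' @param f_interface Fraction of background bonds allowed to cross the
#'   cassette interface (default 0.15): in a folded two-cassette enzyme
#'   the contact area between cassettes is small, so intercassette
#'   hydrogen bonds are far rarer than intra-cassette ones.
#' @param n_frames Frames for trajectory realisations (default 200).
#' @param jitter Positional noise SD in Angstrom (default 0.05).
#' @param seed Base seed (default 0).
#' @return A list of class `network_design`.
#' @export
network_design <- function(n_residues = 30, endpoints = NULL,
                           interface_pair = NULL, p_path = 0.95,
                           p_bg = 0.3, n_background = 40,
                           f_interface = 0.15,
                           n_frames = 200, jitter = 0.05, seed = 0L) {
  if (p_path <= p_bg)
    warning("p_path <= p_bg: the planted route is not distinguishable ",
            "from background (negative-control setting)")
  n <- as.integer(n_residues)
  if (is.null(endpoints))
    endpoints <- c(sprintf("A:%d", ceiling(n / 2)),
                   sprintf("B:%d", n + ceiling(n / 2)))
  if (is.null(interface_pair))
    interface_pair <- c(sprintf("A:%d", ceiling(3 * n / 4)),
                        sprintf("B:%d", n + ceiling(n / 4)))
  structure(list(n_residues = n, endpoints = endpoints,
                 interface_pair = interface_pair, p_path = p_path,
                 p_bg = p_bg, n_background = as.integer(n_background),
                 f_interface = f_interface,
                 n_frames = as.integer(n_frames), jitter = jitter,
                 seed = as.integer(seed)),
            class = "network_design")
}

# Residue universe of a network design: chain A numbered 1..n, chain B
# numbered n+1..2n (so the two cassettes also split by residue number).
network_residues <- function(design) {
  n <- design$n_residues
  c(sprintf("A:%d", seq_len(n)), sprintf("B:%d", n + seq_len(n)))
}

# Backbone adjacency of the design's two chains.
network_adjacency <- function(design) {
  n <- design$n_residues
  data.frame(
    res_i = c(sprintf("A:%d", seq_len(n - 1)), sprintf("B:%d", n + seq_len(n - 1))),
    res_j = c(sprintf("A:%d", 1 + seq_len(n - 1)), sprintf("B:%d", n + 1 + seq_len(n - 1))),
    stringsAsFactors = FALSE)
}

# The planted route: backbone run from each endpoint to its interface
# residue, joined by the interface H-bond.
planted_route <- function(design) {
  n <- design$n_residues
  parse_no <- function(id) as.integer(strsplit(id, ":")[[1]][2])
  a0 <- parse_no(design$endpoints[1]); a1 <- parse_no(design$interface_pair[1])
  b0 <- parse_no(design$interface_pair[2]); b1 <- parse_no(design$endpoints[2])
  c(sprintf("A:%d", seq(a0, a1)), sprintf("B:%d", seq(b0, b1)))
}

#' Generate a synthetic occupancy network
#'
#' Fast path that skips trajectory geometry: directly emits the
#' hydrogen-bond probability matrix of a [network_design()] -- the planted
#' interface bond at `p_path` plus `n_background` random residue pairs
#' with occupancies drawn uniformly from `(0.05, p_bg]` -- together with
#' the backbone adjacency and a ground-truth record. When
#' `p_path <= p_bg` (the negative-control setting) the planted bond is
#' drawn from the background occupancy distribution instead of being
#' fixed, making the planted route statistically indistinguishable from
#' background; route recovery then falls to chance.
#'
#' @param design A [network_design()].
#' @return A list: `matrix` (an `hbond_matrix`), `adjacency`, `partition`
#'   (residue -> NC/CC), `truth` (list with `route`, `interface_pair`,
#'   `endpoints`, `p_path`, `p_bg`, `seed`).
#' @export
generate_occupancy_network <- function(design) {
  stopifnot(inherits(design, "network_design"))
  with_seed(design$seed, {
    residues <- network_residues(design)
    adjacency <- network_adjacency(design)
    p_planted <- if (design$p_path > design$p_bg) design$p_path
                 else stats::runif(1, 0.05, design$p_bg)
    pairs <- data.frame(res_i = design$interface_pair[1],
                        res_j = design$interface_pair[2],
                        probability = p_planted,
                        stringsAsFactors = FALSE)
    if (design$n_background > 0) {
      taken <- paste(pairs$res_i, pairs$res_j, sep = "|")
      adj_key <- paste(pmin(adjacency$res_i, adjacency$res_j),
                       pmax(adjacency$res_i, adjacency$res_j), sep = "|")
      n_inter <- round(design$f_interface * design$n_background)
      chain_of <- sub(":.*", "", residues)
      added <- 0L
      while (added < design$n_background) {
        want_inter <- added < n_inter
        ij <- sample(residues, 2L)
        is_inter <- chain_of[match(ij[1], residues)] !=
          chain_of[match(ij[2], residues)]
        if (is_inter != want_inter) next
        key <- paste(pmin(ij[1], ij[2]), pmax(ij[1], ij[2]), sep = "|")
        if (key %in% taken || key %in% adj_key) next
        pairs <- rbind(pairs, data.frame(
          res_i = ij[1], res_j = ij[2],
          probability = stats::runif(1, 0.05, design$p_bg),
          stringsAsFactors = FALSE))
        taken <- c(taken, key)
        added <- added + 1L
      }
    }
    mat <- hbond_matrix_from_pairs(residues, pairs,
                                   n_frames = design$n_frames)
    partition <- cassette_partition(residues,
                                    by_chain = c(A = "NC", B = "CC"))
    list(matrix = mat, adjacency = adjacency, partition = partition,
         truth = list(route = planted_route(design),
                      interface_pair = design$interface_pair,
                      endpoints = design$endpoints,
                      p_path = design$p_path, p_bg = design$p_bg,
                      seed = design$seed))
  })
}

#' Generate a synthetic trajectory with planted hydrogen bonds
#'
#' Builds a geometric toy protein realising a [network_design()]: each
#' residue contributes backbone-like atoms N, H (bonded to N, the donor),
#' CA, C and O (the acceptor) on a rigid lattice; the two chains sit on
#' parallel rails. In each frame, every planted or background bond is
#' switched on with its Bernoulli probability by placing the acceptor
#' oxygen 1.9 A beyond the donor hydrogen along the N-H axis (D-A distance
#' 2.9 A, deviation 0 degrees -- inside the criterion), or parked at its
#' lattice home otherwise (far outside). Small Gaussian jitter is added to
#' every atom. Each residue takes part in at most one switchable bond; a
#' design that would require more is rejected as geometrically infeasible.
#'
#' @param design A [network_design()].
#' @return A list: `trajectory` (class `trajectory`, window = full span),
#'   `truth` (as in [generate_occupancy_network()] plus per-bond planted
#'   probabilities).
#' @export
generate_synthetic_trajectory <- function(design) {
  stopifnot(inherits(design, "network_design"))
  with_seed(design$seed, {
    residues <- network_residues(design)
    n <- design$n_residues

    # switchable bonds: the planted interface bond + random background;
    # in the negative-control setting (p_path <= p_bg) the planted bond
    # occupancy is itself a background draw
    p_planted <- if (design$p_path > design$p_bg) design$p_path
                 else stats::runif(1, 0.05, design$p_bg)
    bonds <- data.frame(donor = design$interface_pair[1],
                        acceptor = design$interface_pair[2],
                        p = p_planted, stringsAsFactors = FALSE)
    used <- c(design$interface_pair)
    if (design$n_background > 0) {
      avail <- setdiff(residues, used)
      if (length(avail) < 2L * design$n_background)
        stop("infeasible geometry: not enough free residues for ",
             design$n_background, " background bonds (each residue may ",
             "take part in at most one switchable bond)")
      picks <- sample(avail, 2L * design$n_background)
      for (b in seq_len(design$n_background)) {
        bonds <- rbind(bonds, data.frame(
          donor = picks[2 * b - 1L], acceptor = picks[2 * b],
          p = stats::runif(1, 0.05, design$p_bg), stringsAsFactors = FALSE))
      }
    }

    # lattice: chain A along x at y=0, chain B along x at y=40
    spacing <- 8
    base <- matrix(NA_real_, length(residues), 3)
    for (i in seq_len(n)) base[i, ] <- c(i * spacing, 0, 0)
    for (i in seq_len(n)) base[n + i, ] <- c(i * spacing, 40, 0)

    # per-residue template: N, H, CA, C, O offsets (N-H along +z)
    offs <- rbind(N  = c(0, 0, 0),
                  H  = c(0, 0, 1.0),
                  CA = c(1.5, 0, 0),
                  C  = c(3.0, 0, 0),
                  O  = c(3.4, 1.1, 0))
    atom_names <- rownames(offs)
    n_res <- length(residues)
    atoms <- data.frame(
      index = seq_len(5L * n_res),
      name = rep(atom_names, n_res),
      element = rep(c("N", "H", "C", "C", "O"), n_res),
      chain = rep(sub(":.*", "", residues), each = 5L),
      resno = rep(as.integer(sub(".*:", "", residues)), each = 5L),
      resid = "ALA", stringsAsFactors = FALSE)
    home <- base[rep(seq_len(n_res), each = 5L), ] +
      offs[rep(seq_len(5L), n_res), ]

    atom_of <- function(res, name) {
      which(paste(atoms$chain, atoms$resno, sep = ":") == res &
              atoms$name == name)
    }
    don_H <- vapply(bonds$donor, atom_of, integer(1), name = "H")
    don_N <- vapply(bonds$donor, atom_of, integer(1), name = "N")
    acc_O <- vapply(bonds$acceptor, atom_of, integer(1), name = "O")

    frames <- vector("list", design$n_frames)
    bond_states <- matrix(FALSE, design$n_frames, nrow(bonds))
    for (f in seq_len(design$n_frames)) {
      co <- home
      on <- stats::runif(nrow(bonds)) < bonds$p
      bond_states[f, ] <- on
      for (b in which(on)) {
        u <- co[don_H[b], ] - co[don_N[b], ]
        u <- u / sqrt(sum(u^2))
        co[acc_O[b], ] <- co[don_H[b], ] + 1.9 * u
      }
      co <- co + matrix(stats::rnorm(length(co), 0, design$jitter),
                        ncol = 3)
      frames[[f]] <- co
    }
    topo <- build_topology(atoms, frames[[1]])
    traj <- new_trajectory(topo, frames, dt = 0.1,
                           window = c(0, design$n_frames * 0.1))
    list(trajectory = traj,
         truth = list(route = planted_route(design),
                      interface_pair = design$interface_pair,
                      endpoints = design$endpoints,
                      bonds = cbind(bonds,
                                    occupancy = colMeans(bond_states)),
                      p_path = design$p_path, p_bg = design$p_bg,
                      seed = design$seed))
  })
}
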