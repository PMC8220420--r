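#' Published rate constants for adenine nucleotide binding to hBrr2 variants
#'
#' Elementary rate constants of mant-ADP / mant-ATPgS binding to the
#' nucleotide-binding cassettes of human Brr2 constructs, as determined by
#' stopped-flow measurements: `k1` (association, per uM per s, from the
#' slope of the k_app titration) and `k_minus1` (dissociation, per s, from
#' chase experiments). Isolated-cassette constructs (`hBrr2NC`, `hBrr2CC`)
#' were fit with single exponentials; double-cassette constructs with
#' double exponentials, one phase per cassette. These values parameterise
#' the synthetic-data generators and serve as the reference truth for
#' parameter-recovery experiments.
#'
#' @param construct Optional construct filter (e.g. `"hBrr2T1"`).
#' @param nucleotide Optional nucleotide filter (`"mant-ADP"` or
#'   `"mant-ATPgS"`).
#' @param cassette Optional cassette filter (`"NC"` or `"CC"`).
#' @return A data frame with columns `construct`, `nucleotide`, `cassette`,
#'   `k1`, `k1_se` (per uM per s), `k_minus1`, `k_minus1_se` (per s) and
#'   `fitting` (`"SE"`/`"DE"` for single-/double-exponential).
#' @export
brr2_rate_constants <- function(construct = NULL, nucleotide = NULL,
                                cassette = NULL) {
  r <- function(con, nuc, cas, k1, k1se, km1, km1se, fit)
    data.frame(construct = con, nucleotide = nuc, cassette = cas,
               k1 = k1, k1_se = k1se, k_minus1 = km1, k_minus1_se = km1se,
               fitting = fit, stringsAsFactors = FALSE)
  tab <- rbind(
    r("hBrr2NC", "mant-ADP",   "NC", 1.0,  0.1,   1.9,    0.1,     "SE"),
    r("hBrr2NC", "mant-ATPgS", "NC", 0.3,  0.02,  1.6,    0.02,    "SE"),
    r("hBrr2CC", "mant-ADP",   "CC", 0.5,  0.01,  2.0e-3, 0.2e-3,  "SE"),
    r("hBrr2CC", "mant-ATPgS", "CC", 0.1,  0.001, 2.0e-3, 0.2e-3,  "SE"),
    r("hBrr2FL", "mant-ADP",   "NC", 2.8,  0.03,  1.5,    0.02,    "DE"),
    r("hBrr2FL", "mant-ADP",   "CC", 0.4,  0.01,  1.0e-3, 0.1e-3,  "DE"),
    r("hBrr2FL", "mant-ATPgS", "NC", 1.0,  0.02,  1.5,    0.04,    "DE"),
    r("hBrr2FL", "mant-ATPgS", "CC", 0.1,  0.01,  1.0e-3, 0.1e-3,  "DE"),
    r("hBrr2T1", "mant-ADP",   "NC", 2.5,  0.1,   1.3,    0.02,    "DE"),
    r("hBrr2T1", "mant-ADP",   "CC", 0.4,  0.02,  1.0e-3, 0.1e-3,  "DE"),
    r("hBrr2T1", "mant-ATPgS", "NC", 2.5,  0.03,  1.2,    0.04,    "DE"),
    r("hBrr2T1", "mant-ATPgS", "CC", 0.1,  0.01,  0.9e-3, 0.01e-3, "DE"),
    r("R603A",   "mant-ADP",   "NC", 0.2,  0.03,  1.4,    0.04,    "DE"),
    r("R603A",   "mant-ADP",   "CC", 0.02, 0.001, 1.0e-3, 0.1e-3,  "DE"),
    r("R603A",   "mant-ATPgS", "NC", 0.3,  0.03,  1.0,    0.04,    "DE"),
    r("R603A",   "mant-ATPgS", "CC", 0.02, 0.001, 1.0e-3, 0.2e-3,  "DE"),
    r("R637A",   "mant-ADP",   "NC", 3.4,  0.2,   1.2,    0.03,    "DE"),
    r("R637A",   "mant-ADP",   "CC", 0.5,  0.01,  1.0e-3, 0.1e-3,  "DE"),
    r("R637A",   "mant-ATPgS", "NC", 0.4,  0.04,  1.0,    0.1,     "DE"),
    r("R637A",   "mant-ATPgS", "CC", 0.02, 0.001, 1.0e-3, 0.04e-3, "DE"),
    r("S1087L",  "mant-ADP",   "NC", 2.7,  0.1,   1.4,    0.04,    "DE"),
    r("S1087L",  "mant-ADP",   "CC", 0.5,  0.01,  1.0e-3, 0.03e-3, "DE"),
    r("S1087L",  "mant-ATPgS", "NC", 2.2,  0.21,  1.4,    0.04,    "DE"),
    r("S1087L",  "mant-ATPgS", "CC", 0.1,  0.004, 1.0e-3, 0.4e-3,  "DE"),
    r("PPP1296-8AAA", "mant-ADP",   "NC", 2.9,  0.1,   2.2,    0.1,    "DE"),
    r("PPP1296-8AAA", "mant-ADP",   "CC", 0.52, 0.003, 2.0e-3, 0.04e-3, "DE"),
    r("PPP1296-8AAA", "mant-ATPgS", "NC", 0.5,  0.03,  2.2,    0.1,    "DE"),
    r("PPP1296-8AAA", "mant-ATPgS", "CC", 0.03, 0.002, 2.0e-3, 0.4e-3, "DE"),
    r("GK1355-6QE", "mant-ADP",   "NC", 1.3, 0.1,  1.5, 0.02, "SE"),
    r("GK1355-6QE", "mant-ATPgS", "NC", 0.4, 0.02, 1.7, 0.1,  "SE"),
    r("H1548A",  "mant-ADP",   "NC", 3.3,  0.3,   1.2,    0.1,     "DE"),
    r("H1548A",  "mant-ADP",   "CC", 0.5,  0.01,  1.0e-3, 0.3e-3,  "DE"),
    r("H1548A",  "mant-ATPgS", "NC", 0.2,  0.02,  1.3,    0.1,     "DE"),
    r("H1548A",  "mant-ATPgS", "CC", 0.02, 0.001, 1.0e-3, 0.03e-3, "DE")
  )
  if (!is.null(construct)) tab <- tab[tab$construct %in% construct, ]
  if (!is.null(nucleotide)) tab <- tab[tab$nucleotide %in% nucleotide, ]
  if (!is.null(cassette)) tab <- tab[tab$cassette %in% cassette, ]
  rownames(tab) <- NULL
  tab
}

#' Published equilibrium affinities of hBrr2 variants
#'
#' Printed equilibrium dissociation constants `Kd = k_minus1 / k1` for
#' mant-ADP and mant-ATPgS binding to the NC and CC pockets of hBrr2
#' constructs. All values are returned in uM (the CC pockets bind in the
#' low-nanomolar range). Note the printed Kds were computed from unrounded
#' rate constants, so recomputing them from the rounded published rates can
#' differ in the last digit for some entries.
#'
#' @inheritParams brr2_rate_constants
#' @return A data frame with columns `construct`, `nucleotide`, `cassette`,
#'   `kd_uM` and `kd_se_uM`.
#' @export
brr2_affinities <- function(construct = NULL, nucleotide = NULL,
                            cassette = NULL) {
  a <- function(con, nuc, cas, kd, se)
    data.frame(construct = con, nucleotide = nuc, cassette = cas,
               kd_uM = kd, kd_se_uM = se, stringsAsFactors = FALSE)
  nM <- 1e-3
  tab <- rbind(
    a("hBrr2NC", "mant-ADP",   "NC", 2.0, 0.2),
    a("hBrr2NC", "mant-ATPgS", "NC", 5.8, 0.4),
    a("hBrr2CC", "mant-ADP",   "CC", 4 * nM, 0.4 * nM),
    a("hBrr2CC", "mant-ATPgS", "CC", 30 * nM, 3 * nM),
    a("hBrr2FL", "mant-ADP",   "NC", 0.5, 0.01),
    a("hBrr2FL", "mant-ADP",   "CC", 2 * nM, 0.2 * nM),
    a("hBrr2FL", "mant-ATPgS", "NC", 1.6, 0.1),
    a("hBrr2FL", "mant-ATPgS", "CC", 10 * nM, 1 * nM),
    a("hBrr2T1", "mant-ADP",   "NC", 0.5, 0.02),
    a("hBrr2T1", "mant-ADP",   "CC", 2 * nM, 0.3 * nM),
    a("hBrr2T1", "mant-ATPgS", "NC", 0.5, 0.02),
    a("hBrr2T1", "mant-ATPgS", "CC", 10 * nM, 1 * nM),
    a("R603A",   "mant-ADP",   "NC", 6.3, 0.8),
    a("R603A",   "mant-ADP",   "CC", 50 * nM, 4 * nM),
    a("R603A",   "mant-ATPgS", "NC", 4.1, 0.5),
    a("R603A",   "mant-ATPgS", "CC", 50 * nM, 10 * nM),
    a("R637A",   "mant-ADP",   "NC", 0.4, 0.2),
    a("R637A",   "mant-ADP",   "CC", 2 * nM, 0.1 * nM),
    a("R637A",   "mant-ATPgS", "NC", 2.6, 0.03),
    a("R637A",   "mant-ATPgS", "CC", 40 * nM, 2 * nM),
    a("S1087L",  "mant-ADP",   "NC", 0.5, 0.02),
    a("S1087L",  "mant-ADP",   "CC", 2 * nM, 0.1 * nM),
    a("S1087L",  "mant-ATPgS", "NC", 0.6, 0.1),
    a("S1087L",  "mant-ATPgS", "CC", 10 * nM, 4 * nM),
    a("PPP1296-8AAA", "mant-ADP",   "NC", 0.8, 0.05),
    a("PPP1296-8AAA", "mant-ADP",   "CC", 4 * nM, 0.1 * nM),
    a("PPP1296-8AAA", "mant-ATPgS", "NC", 4.3, 0.4),
    a("PPP1296-8AAA", "mant-ATPgS", "CC", 60 * nM, 10 * nM),
    a("GK1355-6QE", "mant-ADP",   "NC", 1.2, 0.05),
    a("GK1355-6QE", "mant-ATPgS", "NC", 4.4, 0.3),
    a("H1548A",  "mant-ADP",   "NC", 0.4, 0.04),
    a("H1548A",  "mant-ADP",   "CC", 2 * nM, 0.6 * nM),
    a("H1548A",  "mant-ATPgS", "NC", 5.9, 0.6),
    a("H1548A",  "mant-ATPgS", "CC", 40 * nM, 2 * nM)
  )
  if (!is.null(construct)) tab <- tab[tab$construct %in% construct, ]
  if (!is.null(nucleotide)) tab <- tab[tab$nucleotide %in% nucleotide, ]
  if (!is.null(cassette)) tab <- tab[tab$cassette %in% cassette, ]
  rownames(tab) <- NULL
  tab
}
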