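#' One-site reversible binding parameters
#'
#' A binding site groups the elementary rate constants of a one-step
#' reversible binding scheme P + N <-> PN for one nucleotide-binding
#' cassette, together with the relative fluorescence amplitude that binding
#' at this site contributes to the observed FRET signal.
#'
#' @param label Cassette identifier, `"NC"` or `"CC"`.
#' @param k_on Association rate constant, per uM per s (> 0).
#' @param k_off Dissociation rate constant, per s (>= 0).
#' @param amplitude Relative fluorescence amplitude, dimensionless (> 0).
#'
#' @return An object of class `binding_site`.
#' @examples
#' nc <- binding_site("NC", k_on = 1.0, k_off = 1.9)
#' apparent_rate(nc, 5)
#' equilibrium_kd(nc)
#' @export
binding_site <- function(label = c("NC", "CC"), k_on, k_off, amplitude = 1) {
  label <- match.arg(label)
  stopifnot(is.numeric(k_on), length(k_on) == 1L,
            is.numeric(k_off), length(k_off) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L)
  if (k_on <= 0) stop("'k_on' must be > 0 (per-uM per-s)")
  if (k_off < 0) stop("'k_off' must be >= 0 (per-s)")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(label = label, k_on = k_on, k_off = k_off,
                 amplitude = amplitude),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site %s>  k_on = %g /uM/s, k_off = %g /s, Kd = %g uM, amplitude = %g\n",
              x$label, x$k_on, x$k_off, x$k_off / x$k_on, x$amplitude))
  invisible(x)
}

#' Binding scheme of one or two independent sites
#'
#' Combines one or two [binding_site()] objects with the protein
#' concentration and the final-signal plateau `F_inf`. Two sites are treated
#' as fully independent: the model signal is a sum of independent
#' exponential phases, one per site.
#'
#' @param sites A `binding_site` or list of one or two `binding_site`
#'   objects with distinct labels.
#' @param protein_conc Protein concentration in uM.
#' @param baseline Final signal `F_inf` in arbitrary units. For association
#'   traces the signal rises towards `baseline`; for chase traces it decays
#'   towards it.
#'
#' @return An object of class `binding_scheme`.
#' @export
binding_scheme <- function(sites, protein_conc = 0.2, baseline = NULL) {
  if (inherits(sites, "binding_site")) sites <- list(sites)
  stopifnot(is.list(sites), length(sites) >= 1L, length(sites) <= 2L)
  for (s in sites) {
    if (!inherits(s, "binding_site")) stop("'sites' must contain binding_site objects")
  }
  labels <- vapply(sites, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("site labels must be unique")
  if (protein_conc <= 0) stop("'protein_conc' must be > 0 uM")
  total_amp <- sum(vapply(sites, `[[`, numeric(1), "amplitude"))
  # default plateau chosen so association traces start at signal 1 (the F_0
  # every experimental point is later normalised to)
  if (is.null(baseline)) baseline <- 1 + total_amp
  structure(list(sites = sites, protein_conc = protein_conc,
                 baseline = baseline),
            class = "binding_scheme")
}

#' @export
print.binding_scheme <- function(x, ...) {
  cat(sprintf("<binding_scheme> %d site(s), protein %g uM, F_inf = %g\n",
              length(x$sites), x$protein_conc, x$baseline))
  for (s in x$sites) print(s)
  invisible(x)
}

#' Stopped-flow experiment specification
#'
#' Describes one mixing experiment: an association experiment (apo protein
#' rapidly mixed with labelled nucleotide under pseudo-first-order excess)
#' or a chase experiment (preformed labelled complex mixed with an excess of
#' unlabelled competitor, so the observed decay rate equals the dissociation
#' rate constant).
#'
#' @param mode `"association"` or `"chase"`.
#' @param nucleotide_conc Labelled-nucleotide concentration in uM (for
#'   chase, the concentration used to preform the complex).
#' @param chase_conc Unlabelled competitor concentration in uM (chase only).
#'   A warning is raised when it is below 10x `nucleotide_conc`, where the
#'   no-rebinding approximation degrades.
#' @param time_span Length-2 numeric `(t_min, t_max)` in seconds; `t_min`
#'   must be > 0 for logarithmic sampling.
#' @param n_points Number of acquisition points (instrument default 1000).
#' @param sampling `"logarithmic"` (instrument default) or `"linear"`.
#'
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(mode = c("association", "chase"),
                            nucleotide_conc = 5,
                            chase_conc = NULL,
                            time_span = c(1e-4, 10),
                            n_points = 1000L,
                            sampling = c("logarithmic", "linear")) {
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  stopifnot(length(time_span) == 2L, is.numeric(time_span))
  if (nucleotide_conc < 0) stop("'nucleotide_conc' must be >= 0 uM")
  if (n_points < 2L) stop("'n_points' must be >= 2")
  if (time_span[1] >= time_span[2]) stop("'time_span' must be increasing")
  if (sampling == "logarithmic" && time_span[1] <= 0)
    stop("logarithmic sampling requires t_min > 0")
  if (mode == "chase") {
    if (is.null(chase_conc)) chase_conc <- 100
    if (chase_conc < 10 * nucleotide_conc)
      warning("chase competitor below 10x the labelled-nucleotide concentration; ",
              "rebinding of the labelled nucleotide may not be negligible")
  }
  structure(list(mode = mode, nucleotide_conc = nucleotide_conc,
                 chase_conc = chase_conc, time_span = time_span,
                 n_points = as.integer(n_points), sampling = sampling),
            class = "experiment_spec")
}

# Time grid for an experiment spec (log-spaced by default, as acquired by
# the stopped-flow instrument).
time_grid <- function(spec) {
  with(spec, {
    if (sampling == "logarithmic") {
      exp(seq(log(time_span[1]), log(time_span[2]), length.out = n_points))
    } else {
      seq(time_span[1], time_span[2], length.out = n_points)
    }
  })
}

#' Kinetic trace container
#'
#' A single stopped-flow time course: a strictly increasing time grid
#' (seconds) with the observed or modelled fluorescence signal (arbitrary
#' units), plus free-form metadata.
#'
#' @param time Numeric vector of times in seconds, strictly increasing.
#' @param signal Numeric vector, same length as `time`.
#' @param metadata Named list of metadata (mode, concentrations, seed, ...).
#'
#' @return A data frame of class `kinetic_trace` with columns `time` and
#'   `signal` and a `"metadata"` attribute.
#' @export
kinetic_trace <- function(time, signal, metadata = list()) {
  stopifnot(is.numeric(time), is.numeric(signal), length(time) == length(signal))
  if (is.unsorted(time, strictly = TRUE)) stop("'time' must be strictly increasing")
  out <- data.frame(time = time, signal = signal)
  attr(out, "metadata") <- metadata
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' @export
print.kinetic_trace <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<kinetic_trace> %d points, t = [%g, %g] s\n",
              nrow(x), min(x$time), max(x$time)))
  if (length(md)) {
    keys <- names(md)
    cat("  metadata:", paste(keys, unlist(lapply(md, format)), sep = "=",
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Metadata of a kinetic trace
#' @param trace A `kinetic_trace`.
#' @return Named list.
#' @export
trace_metadata <- function(trace) attr(trace, "metadata") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apparent pseudo-first-order rate of one binding phase
#'
#' Under pseudo-first-order conditions (nucleotide in large excess over
#' protein) each binding phase relaxes with apparent rate
#' `k_app = k_on * [nucleotide] + k_off`, so a titration of `k_app` against
#' concentration is a line whose slope is `k_on` and whose intercept is
#' `k_off`.
#'
#' @param site A [binding_site()].
#' @param nucleotide_conc Nucleotide concentration(s) in uM, >= 0.
#' @return Apparent rate(s) in per-s.
#' @export
apparent_rate <- function(site, nucleotide_conc) {
  stopifnot(inherits(site, "binding_site"), is.numeric(nucleotide_conc))
  if (any(nucleotide_conc < 0)) stop("'nucleotide_conc' must be >= 0 uM")
  site$k_on * nucleotide_conc + site$k_off
}

#' Equilibrium dissociation constant of a site
#'
#' `Kd = k_off / k_on`, in uM. Lower values mean tighter binding.
#'
#' @param site A [binding_site()].
#' @return Kd in uM.
#' @export
equilibrium_kd <- function(site) {
  stopifnot(inherits(site, "binding_site"))
  if (site$k_on == 0) stop("Kd undefined: k_on is zero")
  site$k_off / site$k_on
}

#' Noiseless association trace (pseudo-first-order closed form)
#'
#' The modelled FRET signal of an association experiment is
#' `F(t) = F_inf + sum_i F_i * exp(-k_app_i * t)` with one exponential term
#' per site and `F_i = -amplitude_i` (the signal rises towards `F_inf`).
#'
#' @param scheme A [binding_scheme()].
#' @param spec An [experiment_spec()] with `mode = "association"`.
#' @return A [kinetic_trace()].
#' @export
model_association <- function(scheme, spec) {
  stopifnot(inherits(scheme, "binding_scheme"), inherits(spec, "experiment_spec"))
  if (spec$mode != "association") stop("spec mode must be 'association'")
  tt <- time_grid(spec)
  sig <- rep(scheme$baseline, length(tt))
  for (s in scheme$sites) {
    kapp <- apparent_rate(s, spec$nucleotide_conc)
    sig <- sig - s$amplitude * exp(-kapp * tt)
  }
  kinetic_trace(tt, sig, metadata = list(
    mode = "association", nucleotide_conc = spec$nucleotide_conc,
    protein_conc = scheme$protein_conc,
    n_sites = length(scheme$sites), model = "closed-form"))
}

#' Noiseless chase trace
#'
#' In a chase experiment the decay rate of each phase equals the
#' dissociation rate constant of its site:
#' `F(t) = F_inf + sum_i F_i * exp(-k_off_i * t)` with `F_i = amplitude_i`
#' (the signal decays towards `F_inf`).
#'
#' @inheritParams model_association
#' @param spec An [experiment_spec()] with `mode = "chase"`.
#' @return A [kinetic_trace()].
#' @export
model_chase <- function(scheme, spec) {
  stopifnot(inherits(scheme, "binding_scheme"), inherits(spec, "experiment_spec"))
  if (spec$mode != "chase") stop("spec mode must be 'chase'")
  tt <- time_grid(spec)
  f_inf <- scheme$baseline - sum(vapply(scheme$sites, `[[`, numeric(1), "amplitude"))
  sig <- rep(f_inf, length(tt))
  for (s in scheme$sites) {
    sig <- sig + s$amplitude * exp(-s$k_off * tt)
  }
  kinetic_trace(tt, sig, metadata = list(
    mode = "chase", nucleotide_conc = spec$nucleotide_conc,
    chase_conc = spec$chase_conc, protein_conc = scheme$protein_conc,
    n_sites = length(scheme$sites), model = "closed-form"))
}

#' Association trace by full mass-action integration
#'
#' Integrates `d[PN]/dt = k_on * [P] * [N] - k_off * [PN]` per independent
#' site without the excess-nucleotide approximation, as a fidelity check of
#' the pseudo-first-order closed form. Site occupancies are mapped to the
#' same signal scale as [model_association()] (each site's amplitude is
#' reached at its pseudo-first-order equilibrium occupancy), so the two
#' traces converge as `nucleotide_conc / protein_conc` grows.
#'
#' @inheritParams model_association
#' @param ... Passed to [deSolve::lsoda()] (e.g. `rtol`, `atol`).
#' @return A [kinetic_trace()].
#' @export
model_association_ode <- function(scheme, spec, ...) {
  stopifnot(inherits(scheme, "binding_scheme"), inherits(spec, "experiment_spec"))
  if (spec$mode != "association") stop("spec mode must be 'association'")
  tt <- time_grid(spec)
  n0 <- spec$nucleotide_conc
  p0 <- scheme$protein_conc
  sig <- rep(scheme$baseline, length(tt))
  for (s in scheme$sites) {
    rhs <- function(t, y, parms) {
      pn <- y[1]
      list(s$k_on * (p0 - pn) * (n0 - pn) - s$k_off * pn)
    }
    sol <- try(deSolve::lsoda(c(pn = 0), times = c(0, tt), func = rhs,
                              parms = NULL, rtol = 1e-8,
                              atol = 1e-10 * p0, ...), silent = TRUE)
    if (inherits(sol, "try-error") || any(!is.finite(sol[, "pn"])))
      stop("mass-action integration failed: ", attr(sol, "condition")$message %||%
             "non-finite occupancy")
    pn <- sol[-1, "pn"]
    # pseudo-first-order equilibrium occupancy used as the amplitude anchor
    kd <- s$k_off / s$k_on
    theta_pfo <- p0 * n0 / (n0 + kd)
    sig <- sig - s$amplitude * (1 - pn / theta_pfo)
  }
  kinetic_trace(tt, sig, metadata = list(
    mode = "association", nucleotide_conc = n0, protein_conc = p0,
    n_sites = length(scheme$sites), model = "mass-action"))
}

#' Write a kinetic trace to delimited text
#'
#' Two-column (time_s, signal) tab-delimited text with a header block of
#' `# key=value` metadata lines.
#'
#' @param trace A [kinetic_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinetic_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  md <- trace_metadata(trace)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(md)) {
    writeLines(sprintf("# %s=%s", k, format(md[[k]], digits = 15)), con)
  }
  writeLines("time_s\tsignal", con)
  utils::write.table(data.frame(time_s = trace$time, signal = trace$signal),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a kinetic trace written by [write_kinetic_trace()]
#'
#' @param path File path.
#' @return A [kinetic_trace()].
#' @export
read_kinetic_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  md <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      md[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (grepl("^time", body[1])) body <- body[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  time <- as.numeric(vapply(parts, `[[`, character(1), 1))
  signal <- as.numeric(vapply(parts, `[[`, character(1), 2))
  kinetic_trace(time, signal, metadata = md)
}
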