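#' Normalize and average replicate traces
#'
#' Mirrors the instrument work-up: each replicate is divided by its initial
#' signal `F_0` (its first acquired point) and the normalized replicates
#' are averaged pointwise. Traces on different grids are first resampled
#' onto the grid of the first trace by linear interpolation.
#'
#' @param traces List of at least two [kinetic_trace()] objects.
#' @return A [kinetic_trace()]; metadata records `n_averaged`.
#' @export
normalize_and_average <- function(traces) {
  if (!is.list(traces) || length(traces) < 2L)
    stop("need at least 2 traces to average")
  for (tr in traces) stopifnot(inherits(tr, "kinetic_trace"))
  grid <- traces[[1]]$time
  mat <- vapply(traces, function(tr) {
    f0 <- tr$signal[1]
    if (!is.finite(f0) || f0 <= 0)
      stop("cannot normalize: initial signal F_0 <= 0")
    y <- if (length(tr$time) == length(grid) && all(tr$time == grid)) {
      tr$signal
    } else {
      stats::approx(tr$time, tr$signal, xout = grid, rule = 2)$y
    }
    y / f0
  }, numeric(length(grid)))
  md <- trace_metadata(traces[[1]])
  md$n_averaged <- length(traces)
  md$normalized <- TRUE
  kinetic_trace(grid, rowMeans(mat), metadata = md)
}

#' Optimizer settings for exponential fitting
#'
#' @param ftol Convergence tolerance on the sum of squares.
#' @param maxit Maximum number of function evaluations.
#' @return A list of control settings.
#' @export
fit_control <- function(ftol = 1e-10, maxit = 10000L) {
  list(ftol = ftol, maxit = as.integer(maxit))
}

# Starting values: F_inf from the last 5% of points; k from a log-linear
# regression of |signal - F_inf| on time; two-phase seeds split the
# single-phase estimate by x10 / /10.
start_values <- function(time, signal, n_phases) {
  n <- length(time)
  tail_n <- max(2L, ceiling(0.05 * n))
  f_inf0 <- mean(signal[(n - tail_n + 1L):n])
  dev <- signal - f_inf0
  a0 <- dev[1]
  absdev <- abs(dev)
  thr <- max(absdev) * 1e-3
  use <- which(absdev > thr)
  # drop the settled tail so the log-linear slope reflects the decay
  use <- use[seq_len(max(2L, floor(0.9 * length(use))))]
  k0 <- if (length(use) >= 2L) {
    sl <- stats::coef(stats::lm(log(absdev[use]) ~ time[use]))[2]
    if (is.finite(sl) && sl < 0) -sl else 1 / stats::median(time)
  } else 1 / stats::median(time)
  if (n_phases == 1L) {
    list(f_inf = f_inf0, F1 = a0, k1 = k0)
  } else {
    list(f_inf = f_inf0, F1 = a0 / 2, F2 = a0 / 2, k1 = k0 * 10, k2 = k0 / 10)
  }
}

#' Fit a kinetic trace to a sum of exponentials
#'
#' Nonlinear least-squares fit of
#' `F(t) = F_inf + F_1 exp(-k_app1 t)` (one phase) or
#' `F(t) = F_inf + F_1 exp(-k_app1 t) + F_2 exp(-k_app2 t)` (two phases)
#' by Levenberg-Marquardt. Rates are constrained positive; amplitudes may
#' take either sign, so rising (association) and decaying (chase) traces
#' are handled uniformly. Two-phase results are reported sorted fast to
#' slow. Starting values are derived deterministically from the trace
#' (plateau from the last 5% of points, rate from a log-linear regression
#' of the deviation from plateau), so the fit is reproducible.
#'
#' @param trace A [kinetic_trace()] with at least 10 points on a monotone
#'   time grid.
#' @param n_phases 1 or 2 exponential phases.
#' @param control Optimizer settings from [fit_control()].
#' @return An object of class `exp_fit` with elements `n_phases`, `k_app`
#'   (per s, fast to slow), `amplitudes`, `f_inf`, `param_se`,
#'   `residual_ss`, `converged`, `flags`, `fitted`, `trace`.
#' @seealso [select_phase_count()], [regress_kapp()]
#' @examples
#' site <- binding_site("NC", k_on = 1, k_off = 1.9)
#' tr <- model_association(binding_scheme(site),
#'                         experiment_spec("association", 5))
#' fit <- fit_exponentials(tr, 1)
#' coef(fit)
#' @export
fit_exponentials <- function(trace, n_phases = 1L, control = fit_control()) {
  stopifnot(inherits(trace, "kinetic_trace"))
  n_phases <- as.integer(n_phases)
  if (!n_phases %in% 1:2) stop("'n_phases' must be 1 or 2")
  if (nrow(trace) < 10L) stop("need at least 10 points")
  tt <- trace$time
  yy <- trace$signal
  flags <- character(0)

  if (stats::sd(yy) < .Machine$double.eps^0.5 * max(1, abs(mean(yy)))) {
    return(new_exp_fit(n_phases, k_app = rep(NA_real_, n_phases),
                       amplitudes = rep(NA_real_, n_phases),
                       f_inf = mean(yy), param_se = NULL,
                       residual_ss = 0, converged = FALSE,
                       flags = "non-identifiable: constant signal",
                       fitted = yy, trace = trace))
  }

  st <- start_values(tt, yy, n_phases)
  kmin <- 1e-12
  if (n_phases == 1L) {
    form <- signal ~ f_inf + F1 * exp(-k1 * time)
    lower <- c(f_inf = -Inf, F1 = -Inf, k1 = kmin)
  } else {
    form <- signal ~ f_inf + F1 * exp(-k1 * time) + F2 * exp(-k2 * time)
    lower <- c(f_inf = -Inf, F1 = -Inf, F2 = -Inf, k1 = kmin, k2 = kmin)
  }
  dat <- data.frame(time = tt, signal = yy)
  fit <- try(minpack.lm::nlsLM(
    form, data = dat, start = st, lower = lower,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, maxiter = min(1024L, control$maxit))),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(new_exp_fit(n_phases, k_app = rep(NA_real_, n_phases),
                       amplitudes = rep(NA_real_, n_phases),
                       f_inf = NA_real_, param_se = NULL,
                       residual_ss = NA_real_, converged = FALSE,
                       flags = paste("fit failed:", conditionMessage(attr(fit, "condition"))),
                       fitted = rep(NA_real_, length(yy)), trace = trace))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  conv <- isTRUE(fit$convInfo$isConv) || is.null(fit$convInfo)
  ks <- cf[grep("^k", names(cf))]
  amps <- cf[grep("^F[12]$", names(cf))]
  kse <- se[grep("^k", names(cf))]
  ase <- se[grep("^F[12]$", names(cf))]
  ord <- order(ks, decreasing = TRUE)    # fast phase first
  ks <- ks[ord]; amps <- amps[ord]; kse <- kse[ord]; ase <- ase[ord]
  if (any(ks <= kmin * 10)) {
    flags <- c(flags, "rate at lower parameter bound")
    conv <- FALSE
  }
  if (n_phases == 2L && ks[1] / ks[2] < 1.0001)
    flags <- c(flags, "degenerate two-phase fit: equal rates")
  new_exp_fit(n_phases,
              k_app = unname(ks), amplitudes = unname(amps),
              f_inf = unname(cf[["f_inf"]]),
              param_se = list(k_app = unname(kse), amplitudes = unname(ase),
                              f_inf = unname(se[[which(names(cf) == "f_inf")]])),
              residual_ss = sum(stats::resid(fit)^2),
              converged = conv, flags = flags,
              fitted = as.vector(stats::fitted(fit)), trace = trace)
}

new_exp_fit <- function(n_phases, k_app, amplitudes, f_inf, param_se,
                        residual_ss, converged, flags, fitted, trace) {
  structure(list(n_phases = n_phases, k_app = k_app, amplitudes = amplitudes,
                 f_inf = f_inf, param_se = param_se,
                 residual_ss = residual_ss, converged = converged,
                 flags = flags, fitted = fitted, trace = trace,
                 n_obs = nrow(trace)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d-phase exponential fit (%d points)%s\n",
              x$n_phases, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (i in seq_len(x$n_phases)) {
    cat(sprintf("  phase %d: k_app = %g /s, amplitude = %g\n",
                i, x$k_app[i], x$amplitudes[i]))
  }
  cat(sprintf("  F_inf = %g, residual SS = %g\n", x$f_inf, x$residual_ss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  k <- object$k_app
  a <- object$amplitudes
  out <- c(object$f_inf, rbind(a, k))
  names(out) <- c("f_inf",
                  as.vector(rbind(paste0("F", seq_along(a)),
                                  paste0("k_app", seq_along(k)))))
  out
}

#' @export
fitted.exp_fit <- function(object, ...) object$fitted

#' @export
residuals.exp_fit <- function(object, ...) object$trace$signal - object$fitted

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$trace$time else newdata$time %||% newdata
  y <- rep(object$f_inf, length(tt))
  for (i in seq_len(object$n_phases)) {
    y <- y + object$amplitudes[i] * exp(-object$k_app[i] * tt)
  }
  y
}

#' @export
summary.exp_fit <- function(object, ...) {
  df <- object$n_obs - (2 * object$n_phases + 1)
  out <- list(fit = object,
              sigma = sqrt(object$residual_ss / max(df, 1L)),
              df = df,
              durbin_watson = durbin_watson(residuals(object)))
  class(out) <- "summary.exp_fit"
  out
}

#' @export
print.summary.exp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sigma = %g on %d df; Durbin-Watson = %.3f\n",
              x$sigma, x$df, x$durbin_watson))
  if (!is.null(x$fit$param_se)) {
    se <- x$fit$param_se
    for (i in seq_len(x$fit$n_phases)) {
      cat(sprintf("  phase %d: k_app = %g +/- %g /s\n",
                  i, x$fit$k_app[i], se$k_app[i]))
    }
  }
  invisible(x)
}

#' @export
plot.exp_fit <- function(x, log_time = TRUE, ...) {
  tr <- x$trace
  graphics::plot(tr$time, tr$signal, pch = 16, cex = 0.3,
                 log = if (log_time) "x" else "",
                 xlab = "time (s)", ylab = "signal (a.u.)", ...)
  graphics::lines(tr$time, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

# Durbin-Watson statistic of a residual series (values near 2 indicate
# uncorrelated residuals).
durbin_watson <- function(res) {
  res <- res[is.finite(res)]
  sum(diff(res)^2) / sum(res^2)
}

#' Select the number of exponential phases
#'
#' Fits one- and two-phase models and prefers the two-phase model only when
#' the extra-sum-of-squares F-test rejects the one-phase model at `alpha`
#' AND the two fitted rates are separated by at least `min_fold`. Both fits
#' and the test statistics are retained so the decision is auditable.
#'
#' @param trace A [kinetic_trace()].
#' @param alpha Significance level of the F-test (default 0.01).
#' @param min_fold Required fast/slow rate separation (default 3).
#' @param control Optimizer settings.
#' @return A list of class `phase_selection`: `n_phases`, `f_statistic`,
#'   `p_value`, `rate_fold`, `fit1`, `fit2`.
#' @export
select_phase_count <- function(trace, alpha = 0.01, min_fold = 3,
                               control = fit_control()) {
  fit1 <- fit_exponentials(trace, 1L, control)
  fit2 <- fit_exponentials(trace, 2L, control)
  if (!fit1$converged && !fit2$converged)
    stop("phase selection failed: neither fit converged (",
         paste(c(fit1$flags, fit2$flags), collapse = "; "), ")")
  n <- fit1$n_obs
  p1 <- 3; p2 <- 5
  fstat <- p <- fold <- NA_real_
  n_phases <- 1L
  if (fit1$converged && fit2$converged && fit2$residual_ss > 0) {
    fstat <- ((fit1$residual_ss - fit2$residual_ss) / (p2 - p1)) /
      (fit2$residual_ss / (n - p2))
    p <- stats::pf(fstat, p2 - p1, n - p2, lower.tail = FALSE)
    fold <- fit2$k_app[1] / fit2$k_app[2]
    if (is.finite(p) && p < alpha && is.finite(fold) && fold >= min_fold)
      n_phases <- 2L
  } else if (!fit1$converged && fit2$converged) {
    n_phases <- 2L
    fold <- fit2$k_app[1] / fit2$k_app[2]
  }
  structure(list(n_phases = n_phases, f_statistic = unname(fstat),
                 p_value = unname(p), rate_fold = unname(fold),
                 alpha = alpha, min_fold = min_fold,
                 fit1 = fit1, fit2 = fit2),
            class = "phase_selection")
}

#' @export
print.phase_selection <- function(x, ...) {
  cat(sprintf("<phase_selection> chose %d phase(s): F = %.3g, p = %.3g, rate fold = %.3g\n",
              x$n_phases, x$f_statistic, x$p_value, x$rate_fold))
  invisible(x)
}

#' Titration series of apparent rates
#'
#' @param conc Nucleotide concentrations in uM (>= 3 distinct values).
#' @param k_app Mean apparent rates, per s.
#' @param k_app_sd Optional SDs of `k_app` (>= 0).
#' @param n_replicates Optional replicate counts.
#' @param phase_label Optional cassette label (`"NC"`/`"CC"`).
#' @return A data frame of class `titration_series`.
#' @export
titration_series <- function(conc, k_app, k_app_sd = NULL,
                             n_replicates = NULL, phase_label = NULL) {
  stopifnot(length(conc) == length(k_app))
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct concentrations for the k_app regression")
  if (!is.null(k_app_sd) && any(k_app_sd < 0)) stop("SDs must be >= 0")
  out <- data.frame(conc = conc, k_app = k_app,
                    k_app_sd = if (is.null(k_app_sd)) NA_real_ else k_app_sd,
                    n_replicates = if (is.null(n_replicates)) NA_integer_
                                   else n_replicates)
  attr(out, "phase_label") <- phase_label
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Linear regression of apparent rates against concentration
#'
#' Fits `k_app = k1 * [nucleotide] + k_minus1`: the slope estimates the
#' association rate constant `k1` and the intercept the dissociation rate
#' constant `k_minus1`. When SDs are available, weighting by `1/SD^2` is
#' optional. A negative fitted intercept is retained but flagged (the
#' chase-derived dissociation rate is the authoritative estimate).
#'
#' @param series A [titration_series()].
#' @param weighted Use `1/SD^2` weights when SDs are present.
#' @return A list of class `kapp_regression`: `k1`, `k1_se`, `k_minus1`,
#'   `k_minus1_se`, `flags`, `model` (the underlying `lm`).
#' @export
regress_kapp <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  w <- NULL
  if (weighted && all(is.finite(series$k_app_sd)) && all(series$k_app_sd > 0))
    w <- 1 / series$k_app_sd^2
  m <- stats::lm(k_app ~ conc, data = series, weights = w)
  cf <- summary(m)$coefficients
  flags <- character(0)
  if (cf["(Intercept)", "Estimate"] < 0)
    flags <- "negative fitted intercept; prefer chase-derived k_off"
  structure(list(k1 = unname(cf["conc", "Estimate"]),
                 k1_se = unname(cf["conc", "Std. Error"]),
                 k_minus1 = unname(cf["(Intercept)", "Estimate"]),
                 k_minus1_se = unname(cf["(Intercept)", "Std. Error"]),
                 phase_label = attr(series, "phase_label"),
                 flags = flags, model = m),
            class = "kapp_regression")
}

#' @export
print.kapp_regression <- function(x, ...) {
  cat(sprintf("<kapp_regression>%s k1 = %g +/- %g /uM/s, k_minus1 = %g +/- %g /s\n",
              if (is.null(x$phase_label)) "" else paste0(" [", x$phase_label, "]"),
              x$k1, x$k1_se, x$k_minus1, x$k_minus1_se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Assign exponential phases to cassettes
#'
#' For double-cassette constructs the faster phase is assigned to the NC
#' (rapid nucleotide turnover) and the slower to the CC (slow release),
#' following the isolated-cassette calibration. If a calibration table of
#' isolated-cassette rate constants is supplied and the trace metadata
#' carries the nucleotide concentration, the assignment is validated by
#' checking that each observed rate lies within a 10-fold window of the
#' apparent rate predicted for its cassette.
#'
#' @param fit A two-phase `exp_fit`.
#' @param calibration Optional data frame in the format of
#'   [brr2_rate_constants()] restricted to isolated-cassette rows.
#' @param ambiguity_fold Rates closer than this fold trigger an
#'   ambiguous-assignment warning (default 3).
#' @return A data frame with columns `phase`, `k_app`, `amplitude`,
#'   `cassette`, `validated`.
#' @export
assign_phases <- function(fit, calibration = NULL, ambiguity_fold = 3) {
  stopifnot(inherits(fit, "exp_fit"))
  if (fit$n_phases != 2L) stop("phase assignment requires a two-phase fit")
  ks <- fit$k_app   # already fast -> slow
  if (is.finite(ks[1]) && is.finite(ks[2]) && ks[1] / ks[2] < ambiguity_fold)
    warning(sprintf("ambiguous assignment: rates within %.3g-fold", ks[1] / ks[2]))
  cassette <- c("NC", "CC")
  validated <- rep(NA, 2L)
  conc <- trace_metadata(fit$trace)$nucleotide_conc
  if (!is.null(calibration) && !is.null(conc)) {
    for (i in 1:2) {
      row <- calibration[calibration$cassette == cassette[i], , drop = FALSE]
      if (nrow(row)) {
        pred <- row$k1[1] * conc + row$k_minus1[1]
        validated[i] <- ks[i] > pred / 10 && ks[i] < pred * 10
      }
    }
  }
  data.frame(phase = 1:2, k_app = ks, amplitude = fit$amplitudes,
             cassette = cassette, validated = validated)
}

#' Build a rate-constant set
#'
#' Assembles per-(construct, nucleotide, cassette) elementary rate
#' constants with uncertainties into the canonical long format used by the
#' affinity derivation. `provenance` records where each estimate came from
#' (`"chase"`, `"regression"`, `"association"` or `"table"`).
#'
#' @param construct,nucleotide,cassette Character vectors.
#' @param k1,k1_se Association rate constants, per uM per s.
#' @param k_minus1,k_minus1_se Dissociation rate constants, per s.
#' @param provenance Character vector.
#' @return A data frame of class `rate_constant_set`.
#' @export
rate_constant_set <- function(construct, nucleotide, cassette,
                              k1, k1_se = NA_real_,
                              k_minus1, k_minus1_se = NA_real_,
                              provenance = "table") {
  out <- data.frame(construct = construct, nucleotide = nucleotide,
                    cassette = cassette, k1 = k1, k1_se = k1_se,
                    k_minus1 = k_minus1, k_minus1_se = k_minus1_se,
                    provenance = provenance, stringsAsFactors = FALSE)
  class(out) <- c("rate_constant_set", "data.frame")
  out
}

#' Fold ratios from an equilibrium-affinity table
#'
#' Computes the cassette and nucleotide preference folds directly from
#' tabulated Kd values (e.g. the published affinity table,
#' [brr2_affinities()]), without re-deriving Kd from rate constants: per
#' (group, nucleotide) the CC-vs-NC affinity fold `Kd_NC / Kd_CC`, and per
#' (group, cassette) the ADP-vs-ATPgS preference fold
#' `Kd_ATPgS / Kd_ADP`. The isolated-cassette constructs are paired as one
#' group.
#'
#' @param kd_table Data frame with columns `construct`, `nucleotide`,
#'   `cassette`, `kd_uM`.
#' @return A data frame with columns `group`, `comparison`, `label`,
#'   `value`.
#' @export
affinity_folds <- function(kd_table) {
  stopifnot(all(c("construct", "nucleotide", "cassette", "kd_uM") %in%
                  names(kd_table)))
  kd_table$group <- ifelse(kd_table$construct %in% c("hBrr2NC", "hBrr2CC"),
                           "isolated", kd_table$construct)
  rows <- list()
  add <- function(group, comparison, label, value)
    data.frame(group = group, comparison = comparison, label = label,
               value = value, stringsAsFactors = FALSE)
  for (g in unique(kd_table$group)) {
    sub <- kd_table[kd_table$group == g, ]
    for (nuc in unique(sub$nucleotide)) {
      nc <- sub[sub$nucleotide == nuc & sub$cassette == "NC", ]
      cc <- sub[sub$nucleotide == nuc & sub$cassette == "CC", ]
      if (nrow(nc) == 1L && nrow(cc) == 1L)
        rows[[length(rows) + 1L]] <-
          add(g, nuc, "CC_vs_NC_affinity_fold", nc$kd_uM / cc$kd_uM)
    }
    for (cas in unique(sub$cassette)) {
      adp <- sub[sub$cassette == cas & sub$nucleotide == "mant-ADP", ]
      atp <- sub[sub$cassette == cas & sub$nucleotide == "mant-ATPgS", ]
      if (nrow(adp) == 1L && nrow(atp) == 1L)
        rows[[length(rows) + 1L]] <-
          add(g, cas, "ADP_vs_ATPgS_preference_fold", atp$kd_uM / adp$kd_uM)
    }
  }
  do.call(rbind, rows)
}

#' Derive affinities and fold ratios from rate constants
#'
#' Computes `Kd = k_minus1 / k1` for every entry with both constants,
#' propagating uncertainties in quadrature
#' (`se(Kd)/Kd = sqrt((se(k1)/k1)^2 + (se(k-1)/k-1)^2)`), and the named
#' fold ratios used to compare the cassettes: per (construct, nucleotide)
#' the CC-vs-NC affinity fold `Kd_NC / Kd_CC` and the NC-vs-CC
#' dissociation-rate fold `k_minus1_NC / k_minus1_CC`; per (construct,
#' cassette) the ADP-vs-ATPgS preference fold `Kd_ATPgS / Kd_ADP`.
#' The isolated-cassette constructs `hBrr2NC` and `hBrr2CC` are paired as
#' one group for the cross-cassette folds.
#'
#' @param rates A [rate_constant_set()] or compatible data frame (e.g.
#'   [brr2_rate_constants()]).
#' @return A list with `affinities` (data frame with `kd_uM`, `kd_se_uM`)
#'   and `folds` (data frame with `group`, `nucleotide_or_cassette`,
#'   `ratio`, `value`). Entries missing a pair member are skipped and
#'   recorded in `skipped`.
#' @export
derive_affinity_table <- function(rates) {
  stopifnot(is.data.frame(rates))
  need <- c("construct", "nucleotide", "cassette", "k1", "k_minus1")
  if (!all(need %in% names(rates)))
    stop("rates must have columns ", paste(need, collapse = ", "))
  if (!"k1_se" %in% names(rates)) rates$k1_se <- NA_real_
  if (!"k_minus1_se" %in% names(rates)) rates$k_minus1_se <- NA_real_

  aff <- rates
  aff$kd_uM <- aff$k_minus1 / aff$k1
  rel <- sqrt((aff$k1_se / aff$k1)^2 + (aff$k_minus1_se / aff$k_minus1)^2)
  aff$kd_se_uM <- aff$kd_uM * rel

  # isolated-cassette constructs act as one paired group
  group_of <- function(con) ifelse(con %in% c("hBrr2NC", "hBrr2CC"),
                                   "isolated", con)
  aff$group <- group_of(aff$construct)

  folds <- list(); skipped <- list()
  add <- function(group, comparison, label, value)
    data.frame(group = group, comparison = comparison, label = label,
               value = value, stringsAsFactors = FALSE)
  for (g in unique(aff$group)) {
    sub <- aff[aff$group == g, ]
    for (nuc in unique(sub$nucleotide)) {
      nc <- sub[sub$nucleotide == nuc & sub$cassette == "NC", ]
      cc <- sub[sub$nucleotide == nuc & sub$cassette == "CC", ]
      if (nrow(nc) == 1L && nrow(cc) == 1L) {
        folds[[length(folds) + 1L]] <-
          rbind(add(g, nuc, "CC_vs_NC_affinity_fold", nc$kd_uM / cc$kd_uM),
                add(g, nuc, "NC_vs_CC_dissociation_fold",
                    nc$k_minus1 / cc$k_minus1))
      } else {
        skipped[[length(skipped) + 1L]] <-
          sprintf("group %s / %s: missing %s entry", g, nuc,
                  if (nrow(nc) == 0L) "NC" else "CC")
      }
    }
    for (cas in unique(sub$cassette)) {
      adp <- sub[sub$cassette == cas & sub$nucleotide == "mant-ADP", ]
      atp <- sub[sub$cassette == cas & sub$nucleotide == "mant-ATPgS", ]
      if (nrow(adp) == 1L && nrow(atp) == 1L) {
        folds[[length(folds) + 1L]] <-
          add(g, cas, "ADP_vs_ATPgS_preference_fold", atp$kd_uM / adp$kd_uM)
      }
    }
  }
  list(affinities = aff[, c("construct", "nucleotide", "cassette",
                            "k1", "k1_se", "k_minus1", "k_minus1_se",
                            "kd_uM", "kd_se_uM")],
       folds = if (length(folds)) do.call(rbind, folds) else
         data.frame(group = character(0), comparison = character(0),
                    label = character(0), value = numeric(0)),
       skipped = unlist(skipped))
}
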