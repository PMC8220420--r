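make_noisy_trace <- function(scheme, spec, sigma, seed,
                             mode = c("association", "chase")) {
  mode <- match.arg(mode)
  clean <- if (mode == "association") model_association(scheme, spec)
           else model_chase(scheme, spec)
  set.seed(seed)
  kinetic_trace(clean$time,
                clean$signal + rnorm(length(clean$signal), 0, sigma),
                metadata = trace_metadata(clean))
}

test_that("normalization divides by F_0 and averaging shrinks noise like 1/sqrt(n)", {
  sch <- binding_scheme(binding_site("NC", 1, 1.9))
  spec <- experiment_spec("association", 5, time_span = c(1e-4, 2),
                          n_points = 200)
  clean <- model_association(sch, spec)
  # identical replicates: output equals input / F_0
  avg <- normalize_and_average(list(clean, clean, clean))
  expect_equal(avg$signal, clean$signal / clean$signal[1], tolerance = 1e-12)
  expect_equal(trace_metadata(avg)$n_averaged, 3)
  expect_error(normalize_and_average(list(clean)), "at least 2")
  neg <- kinetic_trace(clean$time, clean$signal - 10)
  expect_error(normalize_and_average(list(neg, neg)), "F_0")

  # Monte-Carlo: residual noise of a 7-replicate average ~ sigma / sqrt(7)
  sigma <- 0.05
  set.seed(42)
  sds <- replicate(300, {
    reps <- lapply(1:7, function(r)
      kinetic_trace(clean$time,
                    clean$signal + rnorm(nrow(clean), 0, sigma)))
    a <- normalize_and_average(reps)
    sd(a$signal - clean$signal / clean$signal[1])
  })
  expect_equal(mean(sds), sigma / sqrt(7), tolerance = 0.05)
})

test_that("resampling puts replicates on a common grid before averaging", {
  sch <- binding_scheme(binding_site("NC", 1, 1.9))
  t1 <- model_association(sch, experiment_spec("association", 5,
                                               time_span = c(1e-3, 2),
                                               n_points = 150))
  t2 <- model_association(sch, experiment_spec("association", 5,
                                               time_span = c(1e-3, 2),
                                               n_points = 333))
  avg <- normalize_and_average(list(t1, t2))
  expect_equal(nrow(avg), 150)
  expect_equal(avg$signal, t1$signal / t1$signal[1], tolerance = 1e-4)
})

test_that("noiseless single-exponential traces are recovered to machine-level accuracy", {
  sch <- binding_scheme(binding_site("NC", 1.0, 1.9))
  tr <- model_association(sch, experiment_spec("association", 5,
                                               time_span = c(1e-4, 2)))
  fit <- fit_exponentials(tr, 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$k_app - 6.9) / 6.9, 1e-6)
  expect_lt(abs(fit$f_inf - sch$baseline), 1e-8)
  expect_lt(abs(fit$amplitudes + 1), 1e-6)
  # methods on the fitted object
  expect_equal(unname(coef(fit)["k_app1"]), fit$k_app)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("two-phase fits recover well-separated rates from noisy log-grid traces", {
  # published T1/mant-ADP style pair at 5 uM: k_app 13.8 and ~2 per s is
  # only 7-fold apart; use the NC/CC pair (13.8, 0.55) with 1% noise
  sch <- binding_scheme(list(binding_site("NC", 2.5, 1.3, amplitude = 1),
                             binding_site("CC", 0.1, 0.05, amplitude = 1)))
  spec <- experiment_spec("association", 5, time_span = c(1e-4, 10))
  hits <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    tr <- make_noisy_trace(sch, spec, sigma = 0.02, seed = s)
    fit <- fit_exponentials(tr, 2)
    if (!fit$converged) next
    ok1 <- abs(fit$k_app[1] - 13.8) <= 3 * fit$param_se$k_app[1]
    ok2 <- abs(fit$k_app[2] - 0.55) <= 3 * fit$param_se$k_app[2]
    if (ok1 && ok2) hits <- hits + 1L
  }
  # 3 SE covers ~99.7%; allow a small miss rate over 100 seeds
  expect_gte(hits, 90)
})

test_that("constant traces are flagged non-identifiable rather than fitted", {
  tr <- kinetic_trace(seq(0.01, 1, length.out = 50), rep(2, 50))
  fit <- fit_exponentials(tr, 1)
  expect_false(fit$converged)
  expect_match(fit$flags, "non-identifiable")
})

test_that("phase-count selection follows the F-test plus rate-separation rule", {
  # isolated-cassette style single-phase trace -> 1 phase
  sch1 <- binding_scheme(binding_site("NC", 1.0, 1.9))
  spec <- experiment_spec("association", 5, time_span = c(1e-4, 5))
  tr1 <- make_noisy_trace(sch1, spec, sigma = 0.01, seed = 1)
  sel1 <- select_phase_count(tr1)
  expect_equal(sel1$n_phases, 1L)

  # double-cassette trace with ~1000-fold separated rates -> 2 phases
  sch2 <- binding_scheme(list(binding_site("NC", 2.5, 1.2),
                              binding_site("CC", 0.1, 9e-4)))
  spec2 <- experiment_spec("association", 5, time_span = c(1e-4, 50))
  tr2 <- make_noisy_trace(sch2, spec2, sigma = 0.02, seed = 2)
  sel2 <- select_phase_count(tr2)
  expect_equal(sel2$n_phases, 2L)
  expect_lt(sel2$p_value, 0.01)
  expect_gt(sel2$rate_fold, 3)

  # pure-noise traces must not spuriously gain a second phase
  overcalls <- 0L
  for (s in 1:200) {
    set.seed(1000 + s)
    tt <- exp(seq(log(1e-3), log(10), length.out = 150))
    tr <- kinetic_trace(tt, 1 + rnorm(150, 0, 0.02))
    sel <- tryCatch(select_phase_count(tr), error = function(e) NULL)
    if (!is.null(sel) && sel$n_phases == 2L) overcalls <- overcalls + 1L
  }
  expect_lte(overcalls, 10)  # 1-phase retained in >= 95% of null seeds
})

test_that("k_app regression recovers slope and intercept", {
  # exact points on a line: exact recovery
  ser <- titration_series(c(1, 2.5, 5, 10, 20), 2.5 * c(1, 2.5, 5, 10, 20) + 1.3)
  # exact fixtures trigger lm's perfect-fit note on the SE summary
  reg <- suppressWarnings(regress_kapp(ser))
  expect_equal(reg$k1, 2.5, tolerance = 1e-12)
  expect_equal(reg$k_minus1, 1.3, tolerance = 1e-12)
  # constant k_app: zero slope, intercept = common value
  ser0 <- titration_series(c(1, 5, 10), rep(4.4, 3))
  reg0 <- suppressWarnings(regress_kapp(ser0))
  expect_equal(reg0$k1, 0, tolerance = 1e-12)
  expect_equal(reg0$k_minus1, 4.4, tolerance = 1e-12)
  # negative intercept flagged but retained
  sern <- titration_series(c(1, 5, 10), c(0.5, 4.2, 9.1) - 1)
  expect_match(regress_kapp(sern)$flags, "negative")
  expect_error(titration_series(c(1, 1, 1), c(1, 2, 3)), "3 distinct")
})

test_that("simulated titrations recover the generating association constant within 10%", {
  # isolated-NC mant-ADP design: full concentration series, 7 replicates
  slopes <- sapply(1:30, function(s) {
    d <- kinetics_design("hBrr2NC", "mant-ADP", seed = s)
    ds <- generate_kinetics_dataset(d)
    allokin:::analyze_association_only(ds)$NC$k1
  })
  expect_lt(abs(median(slopes) - 1.0) / 1.0, 0.1)
})

test_that("phase assignment labels fast as NC and slow as CC, order-invariantly", {
  sch <- binding_scheme(list(binding_site("CC", 0.1, 0.05),
                             binding_site("NC", 2.5, 1.3)))
  spec <- experiment_spec("association", 5, time_span = c(1e-4, 10))
  tr <- model_association(sch, spec)
  fit <- fit_exponentials(tr, 2)
  asg <- assign_phases(fit)
  expect_equal(asg$cassette, c("NC", "CC"))
  expect_gt(asg$k_app[1], asg$k_app[2])
  # calibration validation against isolated-cassette ranges
  cal <- brr2_rate_constants(construct = c("hBrr2NC", "hBrr2CC"),
                             nucleotide = "mant-ADP")
  asg2 <- assign_phases(fit, calibration = cal)
  expect_true(all(asg2$validated))
  # near-equal rates warn
  sch_tie <- binding_scheme(list(binding_site("NC", 1, 1, amplitude = 2),
                                 binding_site("CC", 0.5, 0.5)))
  tr_tie <- model_association(sch_tie, spec)
  fit_tie <- fit_exponentials(tr_tie, 2)
  expect_warning(assign_phases(fit_tie), "ambiguous")
  expect_error(assign_phases(fit), NA)
})

test_that("affinity table reproduces published Kd folds and is scale-consistent", {
  rates <- brr2_rate_constants(construct = c("hBrr2NC", "hBrr2CC"))
  out <- derive_affinity_table(rates)
  folds <- out$folds
  dis_atp <- folds$value[folds$comparison == "mant-ATPgS" &
                           folds$label == "NC_vs_CC_dissociation_fold"]
  expect_equal(dis_atp, 1.6 / 0.002)  # = 800
  # identical Kds give fold 1
  same <- rate_constant_set(c("X", "X"), "mant-ADP", c("NC", "CC"),
                            k1 = c(1, 2), k_minus1 = c(0.5, 1))
  f1 <- derive_affinity_table(same)$folds
  expect_equal(f1$value[f1$label == "CC_vs_NC_affinity_fold"], 1)
  # scaling all rates by c leaves every fold unchanged
  scaled <- rates
  scaled$k1 <- scaled$k1 * 7.3
  scaled$k_minus1 <- scaled$k_minus1 * 7.3
  f_orig <- derive_affinity_table(rates)$folds
  f_scaled <- derive_affinity_table(scaled)$folds
  expect_equal(f_scaled$value, f_orig$value, tolerance = 1e-12)
  # missing pair members are skipped with a record
  lone <- rate_constant_set("Y", "mant-ADP", "NC", k1 = 1, k_minus1 = 0.5)
  expect_match(derive_affinity_table(lone)$skipped, "missing CC")
  # uncertainty propagation in quadrature
  one <- rate_constant_set("Z", "mant-ADP", "CC", k1 = 0.5, k1_se = 0.01,
                           k_minus1 = 0.002, k_minus1_se = 0.0002)
  aff <- derive_affinity_table(one)$affinities
  expect_equal(aff$kd_se_uM,
               0.004 * sqrt((0.01 / 0.5)^2 + (0.0002 / 0.002)^2))
})

test_that("printed affinity table yields the published preference folds", {
  folds <- affinity_folds(brr2_affinities())
  iso_adp <- folds$value[folds$group == "isolated" &
                           folds$comparison == "mant-ADP" &
                           folds$label == "CC_vs_NC_affinity_fold"]
  expect_equal(iso_adp, 500)       # 2.0 uM / 4 nM
  fl_cc <- folds$value[folds$group == "hBrr2FL" & folds$comparison == "CC" &
                         folds$label == "ADP_vs_ATPgS_preference_fold"]
  expect_equal(fl_cc, 5)           # 10 nM / 2 nM
})

test_that("fit residuals on correctly specified synthetic data are uncorrelated", {
  sch <- binding_scheme(binding_site("NC", 1.0, 1.9))
  spec <- experiment_spec("association", 5, time_span = c(1e-4, 2))
  dws <- sapply(1:20, function(s) {
    tr <- make_noisy_trace(sch, spec, sigma = 0.01, seed = 300 + s)
    summary(fit_exponentials(tr, 1))$durbin_watson
  })
  expect_true(all(dws > 1.5 & dws < 2.5))
})

test_that("chase-derived k_off and titration intercept agree within joint 95% CI", {
  agree <- sapply(1:20, function(s) {
    d <- kinetics_design("hBrr2NC", "mant-ADP", seed = 700 + s)
    ds <- generate_kinetics_dataset(d)
    reg <- allokin:::analyze_association_only(ds)$NC
    chase_avg <- normalize_and_average(ds$chase)
    cf <- fit_exponentials(chase_avg, 1)
    # intercept SE has only 3 regression df: use the t quantile
    half <- qt(0.975, df = 3) * sqrt(reg$k_minus1_se^2 +
                                       cf$param_se$k_app[1]^2)
    abs(reg$k_minus1 - cf$k_app[1]) <= half
  })
  expect_gte(mean(agree), 0.9)
})
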