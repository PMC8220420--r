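test_that("apparent rate is affine in concentration with slope k_on and intercept k_off", {
  expect_equal(apparent_rate(binding_site("NC", 1.0, 1.9), 0), 1.9)
  expect_equal(apparent_rate(binding_site("NC", 2.5, 1.3), 5), 13.8)
  expect_equal(apparent_rate(binding_site("CC", 0.5, 0.002), 10), 5.002)
  expect_error(apparent_rate(binding_site("NC", 1, 1), -1), "must be >= 0")
  # exact recovery of (k_on, k_off) from any two distinct concentrations
  s <- binding_site("NC", 0.73, 0.21)
  for (cs in list(c(0, 1), c(2, 17), c(0.5, 3.25))) {
    k <- apparent_rate(s, cs)
    slope <- diff(k) / diff(cs)
    expect_equal(slope, s$k_on)
    expect_equal(k[1] - slope * cs[1], s$k_off)
  }
})

test_that("equilibrium Kd is k_off / k_on and satisfies Kd * k_on = k_off", {
  expect_equal(equilibrium_kd(binding_site("CC", 0.5, 0.002)), 0.004)
  expect_equal(equilibrium_kd(binding_site("NC", 3, 0)), 0)
  expect_equal(equilibrium_kd(binding_site("CC", 0.4, 0.001)), 0.0025)
  s <- binding_site("NC", 2.8, 1.5)
  expect_equal(equilibrium_kd(s) * s$k_on, s$k_off, tolerance = 1e-15)
  s0 <- binding_site("NC", 1, 1); s0$k_on <- 0
  expect_error(equilibrium_kd(s0), "k_on is zero")
})

test_that("association model has the closed-form shape, asymptote and half-time", {
  site <- binding_site("NC", 1.0, 1.9)
  sch <- binding_scheme(site)
  spec <- experiment_spec("association", 5, time_span = c(1e-5, 20))
  tr <- model_association(sch, spec)
  # rises monotonically to F_inf (plateau points may tie in floating point)
  expect_true(all(diff(tr$signal) >= 0))
  expect_true(all(diff(tr$signal[tr$time < 1 / 6.9]) > 0))
  expect_equal(tr$signal[nrow(tr)], sch$baseline, tolerance = 1e-6)
  # half-change time ln 2 / k_app with k_app = 1*5 + 1.9 = 6.9
  f0 <- sch$baseline - site$amplitude
  rising <- tr$time < 2 / 6.9   # interpolate on the strictly rising part
  half <- stats::approx(tr$signal[rising], tr$time[rising],
                        xout = f0 + site$amplitude / 2)$y
  expect_equal(half, log(2) / 6.9, tolerance = 1e-3)
  # two sites: initial value F_inf + F_1 + F_2 (amplitudes negative)
  sch2 <- binding_scheme(list(binding_site("NC", 2.5, 1.2),
                              binding_site("CC", 0.1, 9e-4)))
  spec2 <- experiment_spec("association", 5, time_span = c(1e-6, 1e4))
  tr2 <- model_association(sch2, spec2)
  expect_equal(tr2$signal[1], sch2$baseline - 2, tolerance = 1e-4)
  expect_equal(tr2$signal[nrow(tr2)], sch2$baseline, tolerance = 1e-6)
  expect_error(model_association(sch, experiment_spec("chase", 5)),
               "must be 'association'")
})

test_that("chase model decays at k_off per phase; k_off = 0 gives a constant trace", {
  site <- binding_site("NC", 1.0, 1.9)
  sch <- binding_scheme(site)
  spec <- experiment_spec("chase", 5, time_span = c(1e-4, 10))
  tr <- model_chase(sch, spec)
  fit <- fit_exponentials(tr, 1)
  expect_equal(fit$k_app, 1.9, tolerance = 1e-6)
  # irreversible site: flat line
  s0 <- binding_site("NC", 1.0, 0)
  tr0 <- model_chase(binding_scheme(s0), spec)
  expect_true(all(tr0$signal == tr0$signal[1]))
  # biphasic: fast phase half-life ln2 / 1.3
  sch2 <- binding_scheme(list(binding_site("NC", 2.5, 1.3),
                              binding_site("CC", 0.4, 0.001)))
  tr2 <- model_chase(sch2, experiment_spec("chase", 5, time_span = c(1e-4, 5000)))
  fit2 <- fit_exponentials(tr2, 2)
  expect_equal(log(2) / fit2$k_app[1], log(2) / 1.3, tolerance = 1e-5)
  expect_equal(fit2$k_app[2], 0.001, tolerance = 1e-5)
})

test_that("signals stay bounded between plateau and initial value per phase", {
  sch <- binding_scheme(list(binding_site("NC", 2.8, 1.5),
                             binding_site("CC", 0.4, 0.001)))
  a <- model_association(sch, experiment_spec("association", 10,
                                              time_span = c(1e-5, 1e4)))
  expect_true(all(a$signal <= sch$baseline + 1e-12))
  expect_true(all(a$signal >= sch$baseline - 2 - 1e-12))
  c <- model_chase(sch, experiment_spec("chase", 5, time_span = c(1e-5, 1e4)))
  expect_true(all(diff(c$signal) < 0))
})

test_that("mass-action ODE matches the pseudo-first-order closed form under excess", {
  site <- binding_site("NC", 1.0, 1.9)   # published isolated-NC mant-ADP rates
  spec <- experiment_spec("association", 5, time_span = c(1e-4, 2))
  # 25:1 nucleotide excess: closed form within 2% of amplitude
  cf <- model_association(binding_scheme(site, protein_conc = 0.2), spec)
  od <- model_association_ode(binding_scheme(site, protein_conc = 0.2), spec)
  expect_lt(max(abs(od$signal - cf$signal)), 0.02)
  # equimolar: the approximation visibly breaks down
  cf1 <- model_association(binding_scheme(site, protein_conc = 5), spec)
  od1 <- model_association_ode(binding_scheme(site, protein_conc = 5), spec)
  expect_gt(max(abs(od1$signal - cf1$signal)), 0.02)
  # vanishing protein: pseudo-first-order becomes exact
  cf2 <- model_association(binding_scheme(site, protein_conc = 1e-6), spec)
  od2 <- model_association_ode(binding_scheme(site, protein_conc = 1e-6), spec)
  expect_lt(max(abs(od2$signal - cf2$signal)), 1e-5)
})

test_that("ODE/closed-form agreement holds across published parameter ranges at 20x excess", {
  rates <- brr2_rate_constants(construct = c("hBrr2NC", "hBrr2CC",
                                             "hBrr2FL", "hBrr2T1"))
  for (i in seq_len(nrow(rates))) {
    site <- binding_site(rates$cassette[i], rates$k1[i], rates$k_minus1[i])
    kapp <- apparent_rate(site, 5)
    spec <- experiment_spec("association", 5,
                            time_span = c(1e-4, 5 / kapp))
    cf <- model_association(binding_scheme(site, protein_conc = 0.25), spec)
    od <- model_association_ode(binding_scheme(site, protein_conc = 0.25), spec)
    expect_lt(max(abs(od$signal - cf$signal)), 0.02)
  }
})

test_that("experiment specs validate their grids and chase excess", {
  expect_error(experiment_spec("association", 5, time_span = c(0, 10)),
               "t_min > 0")
  expect_error(experiment_spec("association", 5, n_points = 1), ">= 2")
  expect_warning(experiment_spec("chase", 5, chase_conc = 20),
                 "below 10x")
  expect_silent(experiment_spec("chase", 5, chase_conc = 100))
})

test_that("trace files round-trip through the delimited text format", {
  tr <- model_association(binding_scheme(binding_site("NC", 1, 1.9)),
                          experiment_spec("association", 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kinetic_trace(tr, f)
  back <- read_kinetic_trace(f)
  expect_equal(back$time, tr$time, tolerance = 1e-12)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_equal(trace_metadata(back)$nucleotide_conc, 5)
  expect_equal(trace_metadata(back)$mode, "association")
})
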