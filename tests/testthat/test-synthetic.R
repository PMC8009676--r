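test_that("every generator is deterministic given the seed", {
  expect_identical(gen_cohort_table(10, seed = 3), gen_cohort_table(10, seed = 3))
  r1 <- gen_perfusion_record(3.5, flow_noise_cv = 0.05, seed = 4)
  r2 <- gen_perfusion_record(3.5, flow_noise_cv = 0.05, seed = 4)
  expect_identical(r1$steps, r2$steps)
  expect_identical(gen_force_curves(2, noise_sd = 0.1, n_curves = 3, seed = 5),
                   gen_force_curves(2, noise_sd = 0.1, n_curves = 3, seed = 5))
  expect_identical(gen_mouse_iop_series(4, seed = 6),
                   gen_mouse_iop_series(4, seed = 6))
  t1 <- gen_wall_trace(seed = 7)
  t2 <- gen_wall_trace(seed = 7)
  expect_identical(t1, t2)
})

test_that("cohort generator matches its configured moments", {
  tab <- gen_cohort_table(21, 24.3, 6.6, 7.9, 4.5, seed = 1)
  # sample mean within 3 sd/sqrt(n) of the configured mean
  expect_lt(abs(mean(tab$iop_before) - 24.3), 3 * 6.6 / sqrt(21) + 0.5)

  none <- gen_cohort_table(12, 24.3, 6.6, mean_drop = 0, sd_drop = 0, seed = 2)
  expect_equal(none$iop_after, none$iop_before)

  # the 5 mmHg floor truncates large drops; an independent Monte-Carlo
  # oracle for E[before - max(before - drop, 5)] gives the expected drop
  big <- gen_cohort_table(10000, 24.3, 6.6, 7.9, 4.5, seed = 3)
  set.seed(99)
  bf <- round(stats::rnorm(2e5, 24.3, 6.6))
  dr <- stats::rnorm(2e5, 7.9, 4.5)
  oracle_drop <- mean(bf - round(pmax(bf - dr, 5)))
  expect_equal(mean(big$iop_before - big$iop_after), oracle_drop,
               tolerance = 0.2 / oracle_drop)
  expect_equal(mean(big$iop_before), 24.3, tolerance = 0.2 / 24.3)

  # when the floor never binds, the configured drop is recovered
  high <- gen_cohort_table(10000, 45, 3, 7.9, 2, seed = 4)
  expect_equal(mean(high$iop_before - high$iop_after), 7.9,
               tolerance = 0.2 / 7.9)

  expect_error(gen_cohort_table(10, sd_before = 0), "positive")
})

test_that("perfusion generator evaluates the power-law flow model", {
  rec <- gen_perfusion_record(3.5, beta = 0, flow_noise_cv = 0, seed = 1)
  q9 <- rec$steps[[which(rec$targets == 9)]]$flow_nl_min
  expect_true(all(q9 == 31.5))

  rec2 <- gen_perfusion_record(3.5, beta = 0.3, flow_noise_cv = 0,
                               steps = c(6, 8, 10), seed = 1)
  q8 <- rec2$steps[[which(rec2$targets == 8)]]$flow_nl_min
  expect_true(all(q8 == 28.0)) # beta nulled at the reference pressure

  expect_error(gen_perfusion_record(3.5, steps = numeric(0)), "non-empty")
  expect_error(gen_perfusion_record(-1), "facility")
})

test_that("force-curve generator follows the Hertz law and the force cap", {
  cv <- gen_force_curves(2, contact_offset = 0, noise_sd = 0, n_curves = 1,
                         delta_max = 1.2, n_samples = 121,
                         force_cap = 10, seed = 1)[[1]]
  at1 <- cv$force_nN[abs(cv$delta_um - 1) < 1e-9]
  expect_equal(round(at1, 2), 7.95)
  expect_equal(cv$force_nN[cv$delta_um == 0], 0)

  capped <- gen_force_curves(2, noise_sd = 0, n_curves = 1, seed = 1)[[1]]
  expect_lte(max(capped$force_nN), 7)

  expect_error(gen_force_curves(2, R = 0), "radius")
})

test_that("noiseless force curves round-trip through the Hertz fit", {
  for (E in c(0.8, 1.54, 2.0)) {
    cv <- gen_force_curves(E, contact_offset = 0.07, noise_sd = 0,
                           n_curves = 1, seed = 2)[[1]]
    ft <- fit_hertz(cv$delta_um, cv$force_nN)
    expect_equal(ft$E, E, tolerance = 1e-6)
    expect_equal(ft$contact_point, 0.07, tolerance = 1e-5)
  }
})

test_that("area-curve generator wraps the forward model faithfully", {
  clean <- gen_area_curve(61, noise_cv = 0, seed = 1)
  fwd <- solve_forward(tissue_model(E_tm = 61))
  expect_equal(clean$area, fwd$area)
  expect_equal(clean$area_norm, fwd$area_norm)

  soft <- gen_area_curve(22, noise_cv = 0, seed = 1)
  expect_lt(soft$area_norm[soft$iop_mmHg == 20],
            clean$area_norm[clean$iop_mmHg == 20])

  noisy <- gen_area_curve(61, noise_cv = 0.05, seed = 2)
  expect_false(isTRUE(all.equal(noisy$area, fwd$area)))
  expect_error(gen_area_curve(61, iop_levels = c(12, 15, 20)), "10 mmHg")
  expect_error(gen_area_curve(2), ">= 5")
})

test_that("mouse IOP series has the configured elevation structure", {
  s <- gen_mouse_iop_series(40, measurement_sd = 0.5, seed = 11)
  expect_equal(sort(unique(s$day)), c(0, 1, 3, 7, 10, 14, 17, 21, 24, 28))
  d <- window_delta_iop(s, c(3, 28))
  m_pl <- mean(d$delta_iop[d$group == "PL"])
  m_nt <- mean(d$delta_iop[d$group == "NT"])
  expect_equal(m_pl, 5.94, tolerance = 3 * 0.6 / sqrt(40) / 5.94 + 0.02)
  expect_lt(abs(m_nt - 0.23), 0.4)
})

test_that("wall-trace generator hits its configured coverage exactly", {
  for (cov in c(0, 0.2, 0.55, 1)) {
    tr <- gen_wall_trace(coverage = cov, offset_coverage = 0, seed = 3)
    expect_equal(bmm_ratio(tr), cov, tolerance = 1e-9)
  }
  tr2 <- gen_wall_trace(coverage = 0.3, offset_coverage = 0.2, seed = 4)
  expect_equal(bmm_ratio(tr2), 0.3, tolerance = 1e-9)
  expect_true(all(tr2$start_um >= 0))
  expect_true(all(tr2$end_um <= 100))
})
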