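test_that("step averaging uses only the final stable window", {
  st <- make_step(9, 10)
  av <- average_step(st)
  expect_true(av$usable)
  expect_equal(av$Q_mean, 10)
  expect_equal(av$Q_cv, 0)

  # 6-minute step whose first 2 minutes are contaminated: only the final
  # 4 minutes contribute
  st2 <- make_step(9, 10)
  st2$flow_nl_min[st2$t_s < 120] <- 100
  av2 <- average_step(st2)
  expect_equal(av2$Q_mean, 10)

  # alternating 8/12 flow over a balanced window: mean 10, CV ~ 0.2
  st3 <- make_step(9, c(8, 12), duration_s = 478)
  av3 <- average_step(st3, window_s = 238) # window holds 120 samples
  expect_equal(av3$Q_mean, 10)
  expect_equal(av3$Q_cv, 0.2, tolerance = 0.01)

  short <- make_step(9, 10, duration_s = 100)
  expect_false(average_step(short)$usable)
})

test_that("a poor step invalidates itself and everything after it", {
  rec <- make_linear_record()
  qc <- qc_steps(rec)
  expect_equal(nrow(qc$steps), 9)
  expect_null(qc$dropped)

  noisy_at <- function(i) {
    steps <- default_pressure_steps()
    t0 <- 0
    tabs <- lapply(seq_along(steps), function(k) {
      fl <- if (k == i) 3.5 * steps[k] * c(0.5, 1.5) else 3.5 * steps[k]
      s <- make_step(steps[k], fl, t0 = t0)
      t0 <<- t0 + 362
      s
    })
    perfusion_record(do.call(rbind, tabs))
  }
  qc6 <- qc_steps(noisy_at(6))
  expect_equal(nrow(qc6$steps), 5)
  expect_equal(qc6$dropped$targets, default_pressure_steps()[6:9])
  expect_match(qc6$dropped$reason, "CV")

  expect_error(qc_steps(noisy_at(2)), "rejected")
})

test_that("QC is monotone: making a step noisier never keeps more steps", {
  base <- gen_perfusion_record(3.5, flow_noise_cv = 0.03, seed = 2)
  n_base <- nrow(qc_steps(base)$steps)
  for (cv in c(0.2, 0.5, 1.0)) {
    worse <- base
    w <- worse$steps[[5]]
    w$flow_nl_min <- w$flow_nl_min * (1 + rep(c(-cv, cv), length.out = nrow(w)))
    worse$steps[[5]] <- w
    n_worse <- tryCatch(nrow(qc_steps(worse)$steps), error = function(e) 0)
    expect_lte(n_worse, n_base)
  }
})

test_that("facility fit recovers exact and power-law synthetic records", {
  est <- fit_facility(qc_steps(make_linear_record(C = 3.5)))
  expect_equal(est$C_r, 3.5, tolerance = 1e-6)
  expect_equal(est$beta, 0, tolerance = 1e-6)
  expect_equal(exp(est$log_C), est$C_r)
  expect_equal(est$n_steps_used, 9)

  rec <- gen_perfusion_record(4.2, beta = 0.3, flow_noise_cv = 0, seed = 7)
  est2 <- fit_facility(qc_steps(rec))
  expect_equal(est2$C_r, 4.2, tolerance = 1e-4)
  expect_equal(est2$beta, 0.3, tolerance = 1e-4)

  lin <- fit_facility(qc_steps(rec), model = "linear")
  expect_equal(lin$beta, 0)
})

test_that("facility estimator is scale-equivariant in flow", {
  rec <- gen_perfusion_record(3.1, beta = 0.2, flow_noise_cv = 0.04, seed = 5)
  est1 <- fit_facility(qc_steps(rec))
  scaled <- rec
  scaled$steps <- lapply(rec$steps, function(s) {
    s$flow_nl_min <- 2.5 * s$flow_nl_min
    s
  })
  est2 <- fit_facility(qc_steps(scaled))
  expect_equal(est2$C_r, 2.5 * est1$C_r, tolerance = 1e-6)
  expect_equal(est2$beta, est1$beta, tolerance = 1e-6)
})

test_that("equal-weight facility comparison equals the plain t-test on logs", {
  mk <- function(C) {
    structure(list(C_r = C, beta = 0, log_C = log(C), se_log_C = 0.1,
                   n_steps_used = 9), class = "facility_estimate")
  }
  a <- lapply(c(4.2, 5.6, 4.9, 5.1), mk)
  b <- lapply(c(3.1, 2.6, 3.4, 2.9), mk)
  cmp <- compare_facilities(a, b)
  ref <- stats::t.test(log(c(4.2, 5.6, 4.9, 5.1)),
                       log(c(3.1, 2.6, 3.4, 2.9)))
  expect_equal(cmp$t, unname(ref$statistic))
  expect_equal(cmp$p, ref$p.value)

  ident <- compare_facilities(a, a)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  paired <- compare_facilities(a, b, paired = TRUE)
  ref_p <- stats::t.test(log(c(4.2, 5.6, 4.9, 5.1)),
                         log(c(3.1, 2.6, 3.4, 2.9)), paired = TRUE)
  expect_equal(paired$t, unname(ref_p$statistic))
  expect_equal(paired$p, ref_p$p.value)
})

test_that("group facility contrasts reproduce the published percent differences", {
  cmp_vals <- percent_difference(4.87, 2.64, "ratio_minus_one")
  expect_equal(round(cmp_vals), 84)

  # synthetic populations at the reversal-study means give ~33% (treated-
  # referenced) within Monte-Carlo error
  set.seed(9)
  gen_fits <- function(mean_C, n, seed0) {
    lapply(seq_len(n), function(i) {
      C <- stats::rlnorm(1, log(mean_C) - 0.5 * 0.1^2, 0.1)
      fit_facility(qc_steps(gen_perfusion_record(
        C, beta = 0.1, flow_noise_cv = 0.05, seed = seed0 + i)))
    })
  }
  nt <- gen_fits(5.18, 10, 100)
  pl <- gen_fits(3.48, 10, 200)
  cmp <- compare_facilities(nt, pl)
  expect_equal(cmp$percent_a_referenced, 32.8, tolerance = 0.25)
  expect_true(cmp$weighted)
})
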