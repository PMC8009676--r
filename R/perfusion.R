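#' Build a stepped perfusion record
#'
#' Wraps a long-format table of pressure/flow samples into a perfusion
#' record: one eye perfused at a sequence of target pressures, each step
#' holding a stream of timestamped pressure (mmHg) and flow (nl/min)
#' samples.
#'
#' @param samples Data frame with columns `step_target_mmHg`, `t_s`,
#'   `pressure_mmHg`, `flow_nl_min`; rows time-ordered within step.
#' @param eye_id,treatment Labels carried through to reports.
#' @return Object of class `perfusion_record` (list of per-step data frames
#'   plus metadata).
#' @export
perfusion_record <- function(samples, eye_id = "eye", treatment = NA) {
  need <- c("step_target_mmHg", "t_s", "pressure_mmHg", "flow_nl_min")
  stopifnot(is.data.frame(samples), all(need %in% names(samples)))
  stopifnot(all(samples$pressure_mmHg > 0))
  targets <- unique(samples$step_target_mmHg)
  if (is.unsorted(targets)) stop("step target pressures must be non-decreasing")
  steps <- lapply(targets, function(tg) {
    s <- samples[samples$step_target_mmHg == tg, ]
    if (is.unsorted(s$t_s)) stop("samples must be time-ordered within a step")
    s
  })
  structure(list(eye_id = eye_id, treatment = treatment,
                 targets = targets, steps = steps),
            class = "perfusion_record")
}

#' Average a pressure step over its final stable window
#'
#' Flow and pressure need time to stabilise after a step change, so the step
#' mean is taken over only the final `window_s` seconds (default 240 s, i.e.
#' 4 min). The flow coefficient of variation over the same window is the
#' step's quality metric.
#'
#' @param step One step data frame (columns `t_s`, `pressure_mmHg`,
#'   `flow_nl_min`, `step_target_mmHg`).
#' @param window_s Averaging window (s).
#' @return List with `target`, `P_mean`, `Q_mean`, `Q_cv`, `usable`. A step
#'   shorter than the window is flagged `usable = FALSE` rather than erroring.
#' @export
average_step <- function(step, window_s = 240) {
  dur <- max(step$t_s) - min(step$t_s)
  if (dur < window_s) {
    return(list(target = step$step_target_mmHg[1], P_mean = NA_real_,
                Q_mean = NA_real_, Q_cv = NA_real_, usable = FALSE))
  }
  inw <- step$t_s >= max(step$t_s) - window_s
  q <- step$flow_nl_min[inw]
  list(target = step$step_target_mmHg[1],
       P_mean = mean(step$pressure_mmHg[inw]),
       Q_mean = mean(q),
       Q_cv = if (mean(q) == 0) Inf else stats::sd(q) / mean(q),
       usable = TRUE)
}

#' Quality-control the steps of a perfusion record
#'
#' Applies the rule that a poor-quality step invalidates everything after
#' it: at the first step whose flow CV exceeds `cv_max`, whose mean pressure
#' misses its target by more than `p_tol`, or which is too short to average,
#' that step and all subsequent steps are dropped. A record keeping fewer
#' than `min_steps` steps is rejected.
#'
#' @param record A [perfusion_record()].
#' @param cv_max Maximum acceptable flow CV within the averaging window.
#' @param p_tol Maximum |mean pressure - target| (mmHg).
#' @param window_s Averaging window passed to [average_step()].
#' @param min_steps Minimum surviving steps (>= 3 needed for a facility fit).
#' @return List with `steps` (data frame of surviving `target`, `P_mean`,
#'   `Q_mean`, `Q_cv`), `dropped` (targets dropped and the reason for the
#'   first failure), `eye_id`, `treatment`. Rejection raises an error
#'   carrying the diagnostic.
#' @export
qc_steps <- function(record, cv_max = 0.10, p_tol = 0.5, window_s = 240,
                     min_steps = 3) {
  stopifnot(inherits(record, "perfusion_record"))
  avg <- lapply(record$steps, average_step, window_s = window_s)
  df <- do.call(rbind, lapply(avg, function(a) {
    data.frame(target = a$target, P_mean = a$P_mean, Q_mean = a$Q_mean,
               Q_cv = a$Q_cv, usable = a$usable)
  }))
  bad <- !df$usable | df$Q_cv > cv_max | abs(df$P_mean - df$target) > p_tol
  first_bad <- if (any(bad)) which(bad)[1] else nrow(df) + 1L
  keep <- seq_len(first_bad - 1L)
  reason <- if (any(bad)) {
    i <- first_bad
    if (!df$usable[i]) "step shorter than averaging window"
    else if (is.finite(df$Q_cv[i]) && df$Q_cv[i] > cv_max) "flow CV above threshold"
    else "mean pressure off target"
  } else NA_character_
  if (length(keep) < min_steps) {
    stop(sprintf(
      "record %s rejected: %d usable steps (need >= %d); first failure at target %g mmHg (%s)",
      record$eye_id, length(keep), min_steps, df$target[first_bad], reason))
  }
  list(steps = df[keep, c("target", "P_mean", "Q_mean", "Q_cv")],
       dropped = if (any(bad)) {
         list(targets = df$target[first_bad:nrow(df)], reason = reason)
       } else NULL,
       eye_id = record$eye_id, treatment = record$treatment)
}

#' Fit outflow facility to QC-passing pressure steps
#'
#' Nonlinear least squares of the power-law pressure-flow model
#' `Q = C_r * (P / P_r)^beta * P` with reference pressure `P_r = 8` mmHg:
#' `C_r` is the outflow facility at the reference pressure and `beta`
#' captures any mild pressure dependence of facility (clamped to
#' `[-1, 1]`). The fit is parameterised in `log(C_r)` because facility is
#' log-normally distributed across eyes, so the standard error of the log
#' facility comes straight from the fit covariance. If the nonlinear fit
#' fails, a linear (`beta = 0`) model is fitted with a warning.
#'
#' @param qc Output of [qc_steps()], or a data frame with `P_mean`, `Q_mean`.
#' @param P_r Reference pressure (mmHg).
#' @param model `"powerlaw"` (default) or `"linear"` (forces `beta = 0`).
#' @return Object of class `facility_estimate`: list with `C_r`, `beta`,
#'   `log_C`, `se_log_C`, `n_steps_used`, `eye_id`, `treatment`, `model`.
#' @export
fit_facility <- function(qc, P_r = 8, model = c("powerlaw", "linear")) {
  model <- match.arg(model)
  steps <- if (is.data.frame(qc)) qc else qc$steps
  stopifnot(all(c("P_mean", "Q_mean") %in% names(steps)))
  if (nrow(steps) < 3) stop("need >= 3 QC-passing steps to fit facility")
  P <- steps$P_mean; Q <- steps$Q_mean
  stopifnot(all(P > 0))

  lin_logC <- log(max(sum(P * Q) / sum(P^2), 1e-9))
  fit_linear <- function() {
    r <- Q - exp(lin_logC) * P
    n <- length(P)
    # delta method on least-squares slope through the origin
    se_C <- sqrt(sum(r^2) / max(n - 1, 1) / sum(P^2))
    list(logC = lin_logC, beta = 0, se = se_C / exp(lin_logC), model = "linear")
  }

  res <- if (model == "linear") fit_linear() else {
    fit <- tryCatch(
      minpack.lm::nlsLM(Q ~ exp(logC) * (P / P_r)^beta * P,
                        start = list(logC = lin_logC, beta = 0),
                        lower = c(logC = -Inf, beta = -1),
                        upper = c(logC = Inf, beta = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("power-law fit did not converge; falling back to linear model")
      fit_linear()
    } else {
      cf <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["logC"]],
                     error = function(e) NA_real_)
      list(logC = cf[["logC"]], beta = cf[["beta"]], se = se,
           model = "powerlaw")
    }
  }
  structure(list(C_r = exp(res$logC), beta = unname(res$beta),
                 log_C = unname(res$logC), se_log_C = unname(res$se),
                 n_steps_used = nrow(steps), P_r = P_r,
                 eye_id = if (is.data.frame(qc)) NA else qc$eye_id,
                 treatment = if (is.data.frame(qc)) NA else qc$treatment,
                 model = res$model),
            class = "facility_estimate")
}

#' Compare facility estimates between groups in the log domain
#'
#' Weighted t-test on log facility with inverse-variance weights
#' `1 / se_log_C^2` (equal weights reduce it to the ordinary t-test on log
#' values). Because facility is log-normal, testing in the log domain is the
#' natural scale; percent differences between the group arithmetic means of
#' `C_r` are reported in both published conventions, explicitly labeled:
#' `ratio_minus_one` (`(mean_a/mean_b - 1) * 100`) and `a_referenced`
#' (`(mean_a - mean_b)/mean_a * 100`).
#'
#' @param group_a,group_b Lists of `facility_estimate` objects (group a is
#'   the treated/reference group for the `a_referenced` convention).
#' @param paired Paired design? Requires equal lengths with aligned order.
#' @return List with `t`, `df`, `p` (two-sided), `mean_log_a`, `mean_log_b`,
#'   `mean_C_a`, `mean_C_b`, `percent_ratio_minus_one`,
#'   `percent_a_referenced`, `weighted` (FALSE when any SE is missing and
#'   equal weights were used).
#' @export
compare_facilities <- function(group_a, group_b, paired = FALSE) {
  get <- function(g, f) vapply(g, function(e) e[[f]], numeric(1))
  la <- get(group_a, "log_C"); lb <- get(group_b, "log_C")
  if (length(la) < 2 || length(lb) < 2) stop("need >= 2 estimates per group")
  sa <- get(group_a, "se_log_C"); sb <- get(group_b, "se_log_C")
  weighted <- all(is.finite(c(sa, sb))) && all(c(sa, sb) > 0)

  wmean <- function(x, w) sum(w * x) / sum(w)
  wvar <- function(x, w) { # unbiased under normalised weights
    n <- length(x); w <- w * n / sum(w)
    sum(w * (x - wmean(x, w))^2) / (n - 1)
  }

  if (paired) {
    if (length(la) != length(lb)) stop("paired groups must have equal length")
    d <- la - lb
    w <- if (weighted) 1 / (sa^2 + sb^2) else rep(1, length(d))
    n <- length(d)
    m <- wmean(d, w); v <- wvar(d, w)
    if (v == 0) stop("zero variance of paired log differences")
    t <- m / sqrt(v / n); df <- n - 1
  } else {
    wa <- if (weighted) 1 / sa^2 else rep(1, length(la))
    wb <- if (weighted) 1 / sb^2 else rep(1, length(lb))
    ma <- wmean(la, wa); mb <- wmean(lb, wb)
    va <- wvar(la, wa); vb <- wvar(lb, wb)
    na <- length(la); nb <- length(lb)
    se2 <- va / na + vb / nb
    if (se2 == 0) stop("zero variance in both groups")
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  Ca <- get(group_a, "C_r"); Cb <- get(group_b, "C_r")
  list(t = t, df = df, p = p,
       mean_log_a = mean(la), mean_log_b = mean(lb),
       mean_C_a = mean(Ca), mean_C_b = mean(Cb),
       percent_ratio_minus_one = percent_difference(mean(Ca), mean(Cb),
                                                    "ratio_minus_one"),
       percent_a_referenced = percent_difference(mean(Ca), mean(Cb),
                                                 "a_referenced"),
       weighted = weighted, paired = paired)
}
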