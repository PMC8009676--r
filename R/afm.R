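#' Hertzian force for a spherical indenter on an elastic half-space
#'
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`. With E in kPa and
#' R, delta in micrometres the result is in nN without further conversion
#' (1 kPa * um^2 = 1 nN).
#'
#' @param delta Indentation depth (um), >= 0; vectorised.
#' @param E Young's modulus (kPa), > 0.
#' @param R Probe radius (um), > 0; default 5 (a 10 um diameter sphere).
#' @param nu Poisson ratio, in (0, 0.5]; 0.5 for incompressible soft tissue.
#' @return Force in nN.
#' @export
hertz_force <- function(delta, E, R = 5, nu = 0.5) {
  stopifnot(E > 0, R > 0, nu > 0, nu < 1)
  if (nu > 0.5) stop("nu must be <= 0.5 for an elastic solid")
  if (any(delta < 0)) stop("indentation depth must be non-negative")
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * delta^1.5
}

#' Fit the Hertz model to a force-indentation curve
#'
#' Joint least squares over Young's modulus and the contact point: the model
#' is `F = hertz_force(max(delta - delta0, 0), E)` fitted on the approach
#' segment with forces below a cap (default 7 nN, a typical maximum applied
#' force for soft tissue). Fitting the contact offset jointly rather than
#' thresholding is robust for soft samples where the contact point is not
#' sharp.
#'
#' @param delta,force Numeric vectors (um, nN) of the approach segment.
#' @param R Probe radius (um). @param nu Poisson ratio.
#' @param force_cap Samples with force above this (nN) are excluded.
#' @param min_points Minimum usable samples; fewer flags the curve invalid.
#' @return List with `E` (kPa), `contact_point` (um), `rss`, `n_used` and
#'   `valid`. An unfittable curve returns `valid = FALSE` (never an error)
#'   so batch processing can drop it from aggregation.
#' @export
fit_hertz <- function(delta, force, R = 5, nu = 0.5, force_cap = 7,
                      min_points = 10) {
  stopifnot(length(delta) == length(force))
  keep <- is.finite(delta) & is.finite(force) & force <= force_cap
  d <- delta[keep]; f <- force[keep]
  invalid <- list(E = NA_real_, contact_point = NA_real_, rss = NA_real_,
                  n_used = sum(keep), valid = FALSE)
  if (sum(keep) < min_points) return(invalid)

  # starting values: contact where force first exceeds a small fraction of
  # its range; E from the linearised F^(2/3) ~ delta slope past that point
  f_rng <- diff(range(f))
  if (f_rng <= 0) return(invalid)
  i0 <- which(f > min(f) + 0.02 * f_rng)[1]
  d0_start <- if (is.na(i0)) min(d) else d[i0]
  past <- d > d0_start & f > 0
  if (sum(past) >= 3) {
    sl <- stats::coef(stats::lm(I(f[past]^(2 / 3)) ~ I(d[past] - d0_start)))[2]
    E_start <- max(unname(sl)^1.5 * (1 - nu^2) * 3 / (4 * sqrt(R)), 1e-3)
  } else {
    E_start <- 1
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * pmax(d - d0, 0)^1.5,
      start = list(E = E_start, d0 = d0_start),
      lower = c(E = 1e-6, d0 = min(d) - diff(range(d))),
      upper = c(E = Inf, d0 = max(d)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(invalid)
  cf <- stats::coef(fit)
  if (!is.finite(cf[["E"]]) || cf[["E"]] <= 0) return(invalid)
  list(E = unname(cf[["E"]]), contact_point = unname(cf[["d0"]]),
       rss = sum(stats::resid(fit)^2), n_used = sum(keep), valid = TRUE)
}

#' Fit every curve in a long-format AFM table
#'
#' @param curves Data frame with columns `eye`, `quadrant`, `section`,
#'   `location`, `rep`, `delta_um`, `force_nN` and optionally `on_tm`
#'   (logical mask; curves with `on_tm = FALSE` are excluded post hoc, e.g.
#'   locations later judged to lie off the trabecular meshwork).
#' @inheritParams fit_hertz
#' @return Data frame with one row per curve: grouping labels, `E`,
#'   `contact_point`, `valid`.
#' @export
fit_hertz_batch <- function(curves, R = 5, nu = 0.5, force_cap = 7) {
  need <- c("eye", "quadrant", "section", "location", "rep",
            "delta_um", "force_nN")
  stopifnot(is.data.frame(curves), all(need %in% names(curves)))
  if (!"on_tm" %in% names(curves)) curves$on_tm <- TRUE
  key <- interaction(curves$eye, curves$quadrant, curves$section,
                     curves$location, curves$rep, drop = TRUE)
  rows <- lapply(split(curves, key), function(s) {
    ft <- fit_hertz(s$delta_um, s$force_nN, R = R, nu = nu,
                    force_cap = force_cap)
    data.frame(eye = s$eye[1], quadrant = s$quadrant[1],
               section = s$section[1], location = s$location[1],
               rep = s$rep[1], on_tm = all(s$on_tm),
               E = ft$E, contact_point = ft$contact_point,
               valid = ft$valid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hierarchical per-eye trabecular meshwork stiffness
#'
#' Unweighted nested averaging of per-curve moduli: repeats are averaged to a
#' location value, locations to a cryosection, cryosections to a quadrant,
#' and quadrants to the eye. For unbalanced designs this differs from the
#' grand mean of all curves, by construction: each quadrant contributes
#' equally regardless of how many curves it holds.
#'
#' @param samples Data frame with columns `eye`, `quadrant`, `section`,
#'   `location`, `E` (kPa) and optionally `valid` / `on_tm` (rows with
#'   either `FALSE` are dropped first).
#' @return List with `eye_table` (one row per eye: `eye`, `E_eye`,
#'   `n_curves`) and `levels`, the intermediate per-quadrant / per-section /
#'   per-location tables.
#' @export
aggregate_eye_stiffness <- function(samples) {
  need <- c("eye", "quadrant", "section", "location", "E")
  stopifnot(is.data.frame(samples), all(need %in% names(samples)))
  if ("valid" %in% names(samples)) samples <- samples[samples$valid, ]
  if ("on_tm" %in% names(samples)) samples <- samples[samples$on_tm, ]
  samples <- samples[is.finite(samples$E), ]
  if (nrow(samples) == 0) stop("no usable stiffness samples")
  stopifnot(all(samples$E > 0))

  mean_over <- function(df, keys, val = "E") {
    agg <- stats::aggregate(df[[val]], df[keys], mean)
    names(agg)[length(agg)] <- val
    agg
  }
  n_curves <- stats::aggregate(samples$E, samples["eye"], length)
  loc <- mean_over(samples, c("eye", "quadrant", "section", "location"))
  sec <- mean_over(loc, c("eye", "quadrant", "section"))
  quad <- mean_over(sec, c("eye", "quadrant"))
  eye <- mean_over(quad, "eye")
  names(eye)[2] <- "E_eye"
  eye$n_curves <- n_curves$x[match(eye$eye, n_curves$eye)]
  list(eye_table = eye,
       levels = list(location = loc, section = sec, quadrant = quad))
}

#' Percent difference between two group means, by stated convention
#'
#' Published group contrasts use (at least) two conventions; this makes the
#' choice explicit. `ratio_minus_one` is `100 * (a/b - 1)` (how much larger
#' a is than b); `a_referenced` is `100 * (a - b) / a` (the difference as a
#' share of a, e.g. treatment-referenced reduction).
#'
#' @param a,b Group means (scalars), `b` is the comparator.
#' @param convention `"ratio_minus_one"` or `"a_referenced"`.
#' @return Percent difference (scalar).
#' @export
percent_difference <- function(a, b,
                               convention = c("ratio_minus_one",
                                              "a_referenced")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(a), is.finite(b), b != 0, a != 0)
  switch(convention,
         ratio_minus_one = 100 * (a / b - 1),
         a_referenced = 100 * (a - b) / a)
}
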