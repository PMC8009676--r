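# Synthetic inputs for every pipeline stage. Each generator takes an explicit
# seed and is deterministic given it; noise scales of zero give exact model
# output so estimator round-trips can be tested against the truth.

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic before/after clinical IOP cohort
#'
#' Pre-treatment IOP is Normal(`mean_before`, `sd_before`), the treatment
#' drop is Normal(`mean_drop`, `sd_drop`), and the post-treatment IOP is
#' `before - drop`, floored at 5 mmHg (clinically implausible lower values
#' are truncated). IOPs are rounded to integers, matching how applanation
#' tonometry readings are recorded in clinical tables.
#'
#' @param n_eyes Number of eyes (>= 2).
#' @param mean_before,sd_before Pre-treatment IOP distribution (mmHg).
#' @param mean_drop,sd_drop Treatment-induced drop distribution (mmHg).
#' @param seed Integer seed.
#' @return Data frame with columns `patient`, `eye`, `iop_before`,
#'   `iop_after` (integer mmHg).
#' @export
gen_cohort_table <- function(n_eyes, mean_before = 24.3, sd_before = 6.6,
                             mean_drop = 7.9, sd_drop = 4.5, seed = 1) {
  stopifnot(n_eyes >= 2)
  if (sd_before <= 0 || sd_drop < 0) {
    stop("sd_before must be positive and sd_drop non-negative")
  }
  with_seed(seed, {
    before <- round(stats::rnorm(n_eyes, mean_before, sd_before))
    drop <- stats::rnorm(n_eyes, mean_drop, sd_drop)
    after <- round(pmax(before - drop, 5))
    data.frame(patient = seq_len(n_eyes),
               eye = rep_len(c("OD", "OS"), n_eyes),
               iop_before = before, iop_after = after)
  })
}

#' Default perfusion step schedule (mmHg)
#' @export
default_pressure_steps <- function() c(4.5, 6, 7.5, 9, 10.5, 12, 15, 18, 21)

#' Generate a stepped perfusion record with known facility
#'
#' Per-step flow samples follow the power-law facility model
#' `Q(P) = C * (P / P_r)^beta * P` (reference pressure `P_r = 8` mmHg) with
#' multiplicative Gaussian noise of coefficient of variation
#' `flow_noise_cv`; noise is multiplicative because perfusion flow scales
#' with pressure. Recorded pressure gets additive jitter of SD
#' `pressure_noise_sd`.
#'
#' @param true_facility Facility `C` at the reference pressure (nl/min/mmHg).
#' @param beta Pressure-nonlinearity exponent (0 = strictly linear).
#' @param flow_noise_cv Fractional flow noise (>= 0).
#' @param steps Target pressures (mmHg), strictly increasing.
#' @param step_duration_s,sample_dt_s Step length and sampling interval (s).
#' @param pressure_noise_sd Additive pressure noise SD (mmHg).
#' @param seed Integer seed.
#' @param eye_id,treatment Labels.
#' @param P_r Reference pressure (mmHg).
#' @return A [perfusion_record()].
#' @export
gen_perfusion_record <- function(true_facility, beta = 0, flow_noise_cv = 0.05,
                                 steps = default_pressure_steps(),
                                 step_duration_s = 360, sample_dt_s = 2,
                                 pressure_noise_sd = 0, seed = 1,
                                 eye_id = "synthetic", treatment = NA,
                                 P_r = 8) {
  stopifnot(true_facility > 0, flow_noise_cv >= 0, pressure_noise_sd >= 0)
  if (length(steps) == 0) stop("step list must be non-empty")
  if (any(diff(steps) <= 0)) stop("steps must be strictly increasing")
  with_seed(seed, {
    t0 <- 0
    tabs <- lapply(steps, function(P) {
      t_s <- seq(0, step_duration_s, by = sample_dt_s)
      q <- true_facility * (P / P_r)^beta * P
      flow <- q * (1 + stats::rnorm(length(t_s), 0, flow_noise_cv))
      p <- P + stats::rnorm(length(t_s), 0, pressure_noise_sd)
      df <- data.frame(step_target_mmHg = P, t_s = t0 + t_s,
                       pressure_mmHg = p, flow_nl_min = flow)
      t0 <<- t0 + step_duration_s + sample_dt_s
      df
    })
    perfusion_record(do.call(rbind, tabs), eye_id = eye_id,
                     treatment = treatment)
  })
}

#' Generate Hertzian AFM force curves with known modulus
#'
#' Indentation is sampled on a uniform grid; force follows the Hertz sphere
#' law with the contact point shifted by `contact_offset` (zero force before
#' contact), additive Gaussian force noise, and truncation at the force cap
#' (default 7 nN, a typical maximum applied force).
#'
#' @param E_true Young's modulus (kPa), > 0.
#' @param R Probe radius (um), > 0.
#' @param nu Poisson ratio (0, 0.5].
#' @param contact_offset Contact-point shift (um).
#' @param noise_sd Additive force noise SD (nN).
#' @param n_curves Number of curves.
#' @param delta_max Maximum commanded indentation (um).
#' @param n_samples Samples per curve.
#' @param force_cap Truncation force (nN).
#' @param seed Integer seed.
#' @return List of `n_curves` data frames with columns `delta_um`,
#'   `force_nN`.
#' @export
gen_force_curves <- function(E_true, R = 5, nu = 0.5, contact_offset = 0,
                             noise_sd = 0, n_curves = 1, delta_max = 1.2,
                             n_samples = 120, force_cap = 7, seed = 1) {
  stopifnot(E_true > 0, noise_sd >= 0, n_curves >= 1)
  if (R <= 0) stop("probe radius must be positive")
  with_seed(seed, {
    lapply(seq_len(n_curves), function(i) {
      delta <- seq(0, delta_max, length.out = n_samples)
      f <- hertz_force(pmax(delta - contact_offset, 0), E_true, R, nu)
      f <- f + stats::rnorm(n_samples, 0, noise_sd)
      keep <- f <= force_cap
      data.frame(delta_um = delta[keep], force_nN = f[keep])
    })
  })
}

#' Generate a Schlemm's canal pressure-area collapse curve
#'
#' Runs the biomechanical forward model (see [solve_forward()]) at the given
#' trabecular meshwork stiffness and multiplies the areas by log-normal
#' noise of the stated CV. The 10 mmHg level must be present so
#' normalisation is defined.
#'
#' @param E_tm Trabecular meshwork small-strain modulus (kPa), within the
#'   forward-model validity range 5-500 kPa.
#' @param iop_levels Clamped IOP levels (mmHg); must include 10.
#' @param noise_cv Multiplicative (log-normal) area noise CV (>= 0).
#' @param seed Integer seed.
#' @param model Optional [tissue_model()]; default geometry otherwise.
#' @return A `pressure_area_curve` (see [pressure_area_curve()]).
#' @export
gen_area_curve <- function(E_tm, iop_levels = c(10, 12, 15, 17, 20),
                           noise_cv = 0, seed = 1, model = NULL) {
  stopifnot(E_tm >= 5, E_tm <= 500, noise_cv >= 0)
  if (!any(iop_levels == 10)) stop("iop_levels must include the 10 mmHg level")
  if (is.null(model)) model <- tissue_model(E_tm = E_tm)
  else model$E_tm <- E_tm
  curve <- solve_forward(model, iop_levels)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(curve$area), -sdlog^2 / 2, sdlog)
    pressure_area_curve(curve$iop_mmHg, curve$area * noise)
  })
}

#' Generate longitudinal mouse IOP series for two treatment groups
#'
#' Emulates twice-weekly rebound tonometry in a steroid ocular-hypertension
#' experiment: eyes start at a common baseline (about 19 mmHg in untreated
#' mice), steroid exposure elevates IOP by a group-specific mean from
#' `elevation_start_day`, and (optionally) treatment from
#' `treatment_start_day` changes the elevation to `post_treatment_elevation`.
#' Day-to-day measurement scatter is additive Gaussian.
#'
#' @param n_eyes Eyes per group.
#' @param groups Named list, one element per group, each a list with
#'   `elevation_mean`, `elevation_sd` (between-eye SD of the sustained
#'   elevation, mmHg) and optionally `post_treatment_elevation` (mmHg).
#' @param baseline_mean,baseline_sd Baseline IOP distribution (mmHg).
#' @param days Measurement day grid; default `c(0,1,3,7,10,14,17,21,24,28)`
#'   mirrors twice-weekly tonometry over four weeks.
#' @param elevation_start_day First day the steroid elevation applies.
#' @param treatment_start_day Day the treatment effect applies (NA = never).
#' @param measurement_sd Within-eye measurement noise SD (mmHg).
#' @param seed Integer seed.
#' @return Data frame with columns `eye`, `group`, `day`, `iop_mmHg`,
#'   `baseline`.
#' @export
gen_mouse_iop_series <- function(n_eyes,
                                 groups = list(
                                   PL = list(elevation_mean = 5.94,
                                             elevation_sd = 0.57),
                                   NT = list(elevation_mean = 0.23,
                                             elevation_sd = 0.45)),
                                 baseline_mean = 19.4, baseline_sd = 1.0,
                                 days = c(0, 1, 3, 7, 10, 14, 17, 21, 24, 28),
                                 elevation_start_day = 3,
                                 treatment_start_day = NA,
                                 measurement_sd = 1.0, seed = 1) {
  stopifnot(n_eyes >= 1, baseline_sd >= 0, measurement_sd >= 0)
  with_seed(seed, {
    out <- lapply(names(groups), function(g) {
      spec <- groups[[g]]
      do.call(rbind, lapply(seq_len(n_eyes), function(i) {
        base <- stats::rnorm(1, baseline_mean, baseline_sd)
        elev <- stats::rnorm(1, spec$elevation_mean, spec$elevation_sd)
        post <- if (!is.null(spec$post_treatment_elevation)) {
          stats::rnorm(1, spec$post_treatment_elevation, spec$elevation_sd)
        } else NULL
        mu <- vapply(days, function(d) {
          if (!is.na(treatment_start_day) && !is.null(post) &&
              d >= treatment_start_day) base + post
          else if (d >= elevation_start_day) base + elev
          else base
        }, numeric(1))
        data.frame(eye = sprintf("%s_%02d", g, i), group = g, day = days,
                   iop_mmHg = mu + stats::rnorm(length(days), 0,
                                                measurement_sd),
                   baseline = base, stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}

#' Generate an inner-wall trace with known basement-membrane coverage
#'
#' Lays non-overlapping segments of basement membrane material (BMM) along
#' an inner wall of length `wall_length_um` until the requested coverage of
#' attached (non-offset) material is reached, then adds offset segments
#' (membrane optically separated from the wall, which morphometry must
#' exclude) covering `offset_coverage` of the wall.
#'
#' @param wall_length_um Total inner-wall length (um).
#' @param coverage Target attached-BMM coverage fraction in `[0, 1]`.
#' @param offset_coverage Coverage fraction of offset segments.
#' @param n_segments Number of attached segments to split the coverage into.
#' @param seed Integer seed.
#' @return A `wall_trace` (see [wall_trace()]) whose attached coverage is
#'   exactly `coverage`.
#' @export
gen_wall_trace <- function(wall_length_um = 100, coverage = 0.4,
                           offset_coverage = 0, n_segments = 3, seed = 1) {
  stopifnot(wall_length_um > 0, coverage >= 0,
            coverage + offset_coverage <= 1, n_segments >= 1)
  with_seed(seed, {
    total_seg <- coverage * wall_length_um
    total_off <- offset_coverage * wall_length_um
    # split covered length into n_segments pieces and place them in the
    # gaps of a random partition of the uncovered length
    piece <- function(total, n) {
      if (n == 0) return(numeric(0))
      if (total == 0) return(rep(0, n))
      w <- stats::runif(n); total * w / sum(w)
    }
    segs <- piece(total_seg, n_segments)
    offs <- piece(total_off, if (total_off > 0) max(1, n_segments %/% 2) else 0)
    lens <- c(segs, offs)
    flags <- c(rep(FALSE, length(segs)), rep(TRUE, length(offs)))
    keep <- lens > 0
    lens <- lens[keep]; flags <- flags[keep]
    if (length(lens) == 0) {
      return(wall_trace(numeric(0), numeric(0), logical(0),
                        wall_length_um = wall_length_um))
    }
    ord <- sample(length(lens))
    lens <- lens[ord]; flags <- flags[ord]
    gap_total <- wall_length_um - sum(lens)
    gaps <- piece(gap_total, length(lens) + 1)
    n <- length(lens)
    starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(lens))[seq_len(n)]
    ends <- pmin(starts + lens, wall_length_um) # guard accumulated round-off
    wall_trace(start_um = ends - lens, end_um = ends,
               offset = flags, wall_length_um = wall_length_um)
  })
}
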