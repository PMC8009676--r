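# Table schemas shared by the CSV readers and the synthetic writers.
# Units are fixed by convention: lengths um, pressures mmHg, flows nl/min,
# moduli kPa, forces nN; conversion happens only at this boundary.
table_schemas <- list(
  cohort = c(iop_before = "numeric", iop_after = "numeric"),
  perfusion = c(step_target_mmHg = "numeric", t_s = "numeric",
                pressure_mmHg = "numeric", flow_nl_min = "numeric"),
  afm = c(eye = "character", quadrant = "character", section = "character",
          location = "character", rep = "character",
          delta_um = "numeric", force_nN = "numeric"),
  area = c(iop_mmHg = "numeric", area = "numeric"),
  wall_trace = c(eye = "character", image = "character",
                 start_um = "numeric", end_um = "numeric",
                 offset_flag = "logical", wall_length_um = "numeric"),
  grades = c(eye = "character", group = "character", grade = "numeric"),
  iop_series = c(eye = "character", day = "numeric", iop_mmHg = "numeric",
                 baseline = "numeric")
)

#' Read and validate a CSV table against a named schema
#'
#' Checks that every schema column is present (extra columns are kept), then
#' coerces column types row-safely: rows with unparseable or missing values
#' in schema columns are dropped and reported, the rest are returned.
#'
#' @param path CSV file path.
#' @param schema_name One of `"cohort"`, `"perfusion"`, `"afm"`, `"area"`,
#'   `"wall_trace"`, `"grades"`, `"iop_series"`.
#' @return Validated data frame with attribute `rejected_rows` (integer
#'   vector of 1-based data row numbers dropped, with a warning naming
#'   them).
#' @export
load_table <- function(path, schema_name) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  schema <- table_schemas[[schema_name]]
  if (is.null(schema)) {
    stop(sprintf("unknown schema '%s'; known: %s", schema_name,
                 paste(names(table_schemas), collapse = ", ")))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(names(schema), names(raw))
  if (length(missing) > 0) {
    stop(sprintf("schema '%s': missing column(s): %s", schema_name,
                 paste(missing, collapse = ", ")))
  }
  bad <- rep(FALSE, nrow(raw))
  for (col in names(schema)) {
    v <- trimws(raw[[col]])
    conv <- switch(schema[[col]],
                   numeric = suppressWarnings(as.numeric(v)),
                   logical = as.logical(toupper(v)),
                   character = ifelse(v == "", NA_character_, v))
    bad <- bad | is.na(conv)
    raw[[col]] <- conv
  }
  if (any(bad)) {
    warning(sprintf("schema '%s': dropped %d invalid row(s): %s",
                    schema_name, sum(bad),
                    paste(utils::head(which(bad), 10), collapse = ", ")))
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_rows") <- which(bad)
  out
}

#' Path to the bundled clinical IOP cohort table
#'
#' Before/after IOP (mmHg) for two published cohorts of steroid-induced
#' ocular hypertension patients treated with a rho-kinase inhibitor after
#' standard medications failed to control pressure.
#' @return File path.
#' @export
clinical_cohorts_path <- function() {
  system.file("extdata", "clinical_iop_cohorts.csv", package = "outflowr",
              mustWork = TRUE)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Generates synthetic inputs for every stage (clinical cohort, perfusion
#' records for two treatment groups, AFM curves, mouse IOP series), runs the
#' corresponding estimators and group tests, analyses the bundled clinical
#' table, and evaluates the Goldmann accounting at the supplied group means.
#' Deterministic given `seed`. The biomechanical inverse stage is optional
#' because it dominates runtime.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_eyes_perfusion Eyes per treatment group in the perfusion stage.
#' @param facility_means Named vector `c(NT = , PL = )` of true facilities
#'   (nl/min/mmHg) used by the generator; defaults are the published
#'   reversal-study group means.
#' @param afm_means Named vector `c(NT = , CON = )` of true moduli (kPa);
#'   defaults are the published treated/contralateral means.
#' @param run_biomech Run the inverse-FEM stage (slow)?
#' @param out_dir If non-NULL, write `summary.json` (and the generated
#'   tables as CSV) there.
#' @return Nested list of results; see names of the returned list.
#' @export
run_pipeline <- function(seed = 1, n_eyes_perfusion = 8,
                         facility_means = c(NT = 5.18, PL = 3.48),
                         afm_means = c(NT = 1.54, CON = 2.00),
                         run_biomech = FALSE, out_dir = NULL) {
  seeds <- derive_seeds(seed, 6)

  # clinical table bundled with the package
  clin <- load_table(clinical_cohorts_path(), "cohort")
  cohort1 <- cohort_summary(clin[clin$cohort == 1, ], exclude_flagged = FALSE)
  cohort2 <- cohort_summary(clin[clin$cohort == 2, ], exclude_flagged = TRUE)

  # perfusion: two groups of synthetic eyes, log-normal facilities
  gen_group <- function(mean_C, n, seed0) {
    lapply(seq_len(n), function(i) {
      C <- stats::rlnorm(1, log(mean_C) - 0.5 * 0.25^2, 0.25)
      rec <- gen_perfusion_record(C, beta = 0.1, flow_noise_cv = 0.05,
                                  seed = seed0 + i, eye_id = paste0("eye", i))
      fit_facility(qc_steps(rec))
    })
  }
  fits_nt <- with_seed(seeds[1], gen_group(facility_means[["NT"]],
                                           n_eyes_perfusion, seeds[2]))
  fits_pl <- with_seed(seeds[1] + 1, gen_group(facility_means[["PL"]],
                                               n_eyes_perfusion,
                                               seeds[2] + 1000))
  perf_cmp <- compare_facilities(fits_nt, fits_pl)

  # AFM: fit synthetic curves and aggregate per eye
  afm_fit_eye <- function(E, seed0) {
    curves <- gen_force_curves(E, contact_offset = 0.05, noise_sd = 0.1,
                               n_curves = 27, seed = seed0)
    E_hat <- vapply(curves, function(cv) {
      fit_hertz(cv$delta_um, cv$force_nN)$E
    }, numeric(1))
    samples <- data.frame(eye = "e", quadrant = rep(1:3, each = 9),
                          section = rep(1:3, times = 9),
                          location = rep(1:3, each = 3), E = E_hat)
    aggregate_eye_stiffness(samples)$eye_table$E_eye
  }
  afm_nt <- afm_fit_eye(afm_means[["NT"]], seeds[3])
  afm_con <- afm_fit_eye(afm_means[["CON"]], seeds[3] + 1)

  # derived percentages at the published group means
  derived <- list(
    facility_prevention_pct = percent_difference(4.87, 2.64,
                                                 "ratio_minus_one"),
    facility_reversal_vs_pl_pct = percent_difference(5.18, 3.48,
                                                     "a_referenced"),
    facility_reversal_vs_contra_pct = percent_difference(5.18, 3.27,
                                                         "a_referenced"),
    afm_reduction_pct = percent_difference(2.00, 1.54, "a_referenced")
  )

  # Goldmann accounting at the reversal and prevention study means
  goldmann <- list(
    reversal = goldmann_sweep(goldmann_inputs(28.4, 21.0, 3.48, 5.18)),
    prevention = goldmann_sweep(goldmann_inputs(25.0, 17.4, 2.64, 4.87))
  )

  # mouse IOP series and window deltas
  series <- gen_mouse_iop_series(8, seed = seeds[4])
  deltas <- window_delta_iop(series, c(3, 28))
  mw <- mann_whitney(deltas$delta_iop[deltas$group == "PL"],
                     deltas$delta_iop[deltas$group == "NT"])

  biomech <- NULL
  if (run_biomech) {
    obs <- gen_area_curve(61, noise_cv = 0.05, seed = seeds[5])
    biomech <- invert_stiffness(obs)
  }

  out <- list(
    clinical = list(cohort1 = cohort1, cohort2 = cohort2),
    perfusion = perf_cmp,
    afm = list(E_nt = afm_nt, E_contra = afm_con,
               reduction_pct = percent_difference(afm_con, afm_nt,
                                                  "a_referenced")),
    derived = derived,
    goldmann = goldmann,
    mouse = list(deltas = deltas, mann_whitney = mw),
    biomech = biomech,
    seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summarize_pipeline(out),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2^30, n))
}

# flatten the pipeline result into the machine-readable summary
summarize_pipeline <- function(res) {
  list(
    seed = res$seed,
    cohort1_mean_before = res$clinical$cohort1$mean_before,
    cohort1_mean_after = res$clinical$cohort1$mean_after,
    cohort1_mean_drop = res$clinical$cohort1$mean_drop,
    cohort2_mean_before = res$clinical$cohort2$mean_before,
    cohort2_mean_drop = res$clinical$cohort2$mean_drop,
    facility_prevention_pct = res$derived$facility_prevention_pct,
    facility_reversal_vs_pl_pct = res$derived$facility_reversal_vs_pl_pct,
    facility_reversal_vs_contra_pct =
      res$derived$facility_reversal_vs_contra_pct,
    afm_reduction_pct = res$derived$afm_reduction_pct,
    perfusion_percent_a_referenced = res$perfusion$percent_a_referenced,
    perfusion_p = res$perfusion$p,
    mouse_mann_whitney_p = res$mouse$mann_whitney$p,
    biomech_E_tm = if (!is.null(res$biomech)) res$biomech$E_tm else NULL
  )
}
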