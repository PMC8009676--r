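#' Flag high outliers by the Tukey upper fence
#'
#' Flags values lying above `Q3 + k * IQR`, the rule routinely used to screen
#' clinical IOP tables before summarising a cohort. Quartiles use linear
#' interpolation (`stats::quantile()` type 7). The lower fence
#' (`Q1 - k * IQR`) is off by default because IOP screening is one-sided:
#' only implausibly high pressures are suspect.
#'
#' @param values Numeric vector (e.g. IOP in mmHg).
#' @param k Fence multiplier, conventionally 1.5.
#' @param lower Also flag values below the lower fence? Default `FALSE`.
#' @return Logical vector, `TRUE` where a value is flagged. If fewer than 4
#'   values are supplied no flags are raised and a warning is issued.
#' @examples
#' tukey_flags(c(1, 2, 3, 4, 100))  # flags the 100
#' @export
tukey_flags <- function(values, k = 1.5, lower = FALSE) {
  stopifnot(is.numeric(values))
  if (length(values) < 4) {
    warning("fewer than 4 values: no outlier flags raised")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7,
                       na.rm = TRUE)
  iqr <- q[2] - q[1]
  flags <- values > q[2] + k * iqr
  if (lower) flags <- flags | values < q[1] - k * iqr
  flags & !is.na(values)
}

#' Summarise a before/after IOP cohort table
#'
#' Computes arithmetic means and standard deviations of IOP before treatment,
#' after treatment, and of the per-eye drop. Outlier exclusion uses
#' [tukey_flags()] on the pre-treatment IOPs and is always explicit: printed
#' clinical summaries sometimes include an eye that is separately flagged as
#' an outlier, so inclusion is a caller decision, never silent.
#'
#' @param table Data frame with numeric columns `iop_before` and `iop_after`
#'   (mmHg); other columns are carried along untouched.
#' @param exclude_flagged If `TRUE`, rows whose `iop_before` is flagged by the
#'   Tukey upper fence are dropped before summarising.
#' @param digits Decimal places used for the `rounded` element (reporting
#'   convention: one decimal). Unrounded values are always returned too.
#' @return List with `n`, `mean_before`, `mean_after`, `mean_drop`,
#'   `sd_before`, `sd_after`, `sd_drop`, `excluded` (row indices dropped) and
#'   `rounded` (named numeric vector at `digits` decimals).
#' @export
cohort_summary <- function(table, exclude_flagged = FALSE, digits = 1) {
  stopifnot(is.data.frame(table),
            all(c("iop_before", "iop_after") %in% names(table)))
  before <- table$iop_before
  after <- table$iop_after
  keep <- !is.na(before) & !is.na(after)
  excluded <- integer(0)
  if (exclude_flagged) {
    flags <- tukey_flags(before[keep])
    excluded <- which(keep)[flags]
    keep[excluded] <- FALSE
  }
  if (sum(keep) < 2) stop("fewer than 2 usable rows after exclusion")
  b <- before[keep]; a <- after[keep]; d <- b - a
  out <- list(
    n = sum(keep),
    mean_before = mean(b), mean_after = mean(a), mean_drop = mean(d),
    sd_before = stats::sd(b), sd_after = stats::sd(a), sd_drop = stats::sd(d),
    excluded = excluded
  )
  out$rounded <- round(unlist(out[c("mean_before", "mean_after", "mean_drop",
                                    "sd_before", "sd_after", "sd_drop")]),
                       digits)
  out
}

#' One-tailed paired t-test for an expected IOP decrease
#'
#' Paired t-test on `before - after` with the upper-tailed alternative
#' (treatment lowers pressure, so the expected difference is positive).
#'
#' @param before,after Paired numeric vectors (mmHg), same length, n >= 3.
#' @return List with `t`, `df`, `p` (one-tailed), `mean_diff`.
#' @export
paired_t_one_tailed <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 3)
  d <- before - after
  if (stats::sd(d) == 0) {
    stop("differences have zero variance; paired t-test undefined")
  }
  tt <- stats::t.test(before, after, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' Window-averaged IOP change from baseline, per eye
#'
#' For longitudinal tonometry series, averages all measurements whose day
#' falls inside a closed window and subtracts the eye's baseline, yielding a
#' single delta-IOP per eye suitable for group testing. Eyes with no
#' measurement inside the window are dropped with a warning.
#'
#' @param series Data frame with columns `eye`, `day`, `iop_mmHg`,
#'   `baseline` (mmHg; constant within eye) and optionally `group`.
#' @param window_days Length-2 numeric `(start, end)`, inclusive at both ends.
#' @return Data frame with one row per surviving eye: `eye`, `group` (if
#'   present), `n_obs`, `delta_iop`.
#' @export
window_delta_iop <- function(series, window_days) {
  stopifnot(is.data.frame(series),
            all(c("eye", "day", "iop_mmHg", "baseline") %in% names(series)),
            length(window_days) == 2, window_days[1] <= window_days[2])
  eyes <- unique(series$eye)
  rows <- lapply(eyes, function(e) {
    s <- series[series$eye == e, ]
    inw <- s$day >= window_days[1] & s$day <= window_days[2]
    if (!any(inw)) {
      warning(sprintf("eye %s: no measurements in window [%g, %g]; dropped",
                      e, window_days[1], window_days[2]))
      return(NULL)
    }
    base <- s$baseline[1]
    data.frame(eye = e,
               group = if ("group" %in% names(s)) s$group[1] else NA,
               n_obs = sum(inw),
               delta_iop = mean(s$iop_mmHg[inw]) - base,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Mann-Whitney U-test with exact small-sample enumeration
#'
#' Two-sided rank-sum test. For groups of at most 8 observations each and no
#' ties, the exact permutation distribution is used; otherwise the normal
#' approximation with tie correction and continuity correction. The U
#' statistic counts pairs in which a group-a value exceeds a group-b value
#' (ties count one half).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3.
#' @param exact_max Per-group size up to which the exact branch is used.
#' @return List with `U`, `p` (two-sided) and `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 8) {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- !ties && length(group_a) <= exact_max &&
    length(group_b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}
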