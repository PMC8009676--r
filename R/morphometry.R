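#' Inner-wall trace with basement membrane material segments
#'
#' Records, for one electron-micrograph image, the total length of the inner
#' wall of Schlemm's canal and the intervals along it covered by basement
#' membrane material (BMM). Segments carry an `offset` flag: material that
#' shows an optically clear offset from the wall (i.e. not in contact) is
#' recorded but excluded from the coverage ratio.
#'
#' @param start_um,end_um Segment endpoints (um), within
#'   `[0, wall_length_um]`, `start < end` elementwise.
#' @param offset Logical per segment; `TRUE` = membrane offset from wall.
#' @param wall_length_um Total inner-wall length (um), > 0.
#' @return Object of class `wall_trace`.
#' @export
wall_trace <- function(start_um, end_um, offset = rep(FALSE, length(start_um)),
                       wall_length_um) {
  stopifnot(length(start_um) == length(end_um),
            length(offset) == length(start_um),
            wall_length_um > 0)
  if (length(start_um) > 0) {
    stopifnot(all(start_um >= 0), all(end_um <= wall_length_um),
              all(end_um > start_um))
  }
  structure(list(start_um = as.numeric(start_um),
                 end_um = as.numeric(end_um),
                 offset = as.logical(offset),
                 wall_length_um = wall_length_um),
            class = "wall_trace")
}

merge_intervals <- function(start, end) {
  if (length(start) == 0) return(list(start = start, end = end, merged = FALSE))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c(); merged <- FALSE
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      merged <- merged || start[i] < me - 1e-9 # contiguity is not overlap
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me), merged = merged)
}

#' Basement membrane coverage ratio of the inner wall
#'
#' Sum of the lengths of attached (non-offset) BMM segments divided by the
#' total inner-wall length. Offset segments contribute zero. Overlapping
#' segments are merged first (with a warning), so the ratio never exceeds 1.
#'
#' @param trace A [wall_trace()].
#' @return Coverage fraction in `[0, 1]`.
#' @export
bmm_ratio <- function(trace) {
  stopifnot(inherits(trace, "wall_trace"))
  keep <- !trace$offset
  m <- merge_intervals(trace$start_um[keep], trace$end_um[keep])
  if (m$merged) warning("overlapping BMM segments merged")
  sum(m$end - m$start) / trace$wall_length_um
}

#' Mean BMM coverage per eye over multiple images
#'
#' @param traces List of [wall_trace()] objects.
#' @param eye Character/factor vector assigning each trace to an eye.
#' @return Data frame `eye`, `n_images`, `bmm_ratio` (per-eye mean).
#' @export
bmm_ratio_by_eye <- function(traces, eye) {
  stopifnot(length(traces) == length(eye))
  r <- vapply(traces, bmm_ratio, numeric(1))
  agg <- stats::aggregate(r, list(eye = eye),
                          function(x) c(n = length(x), mean = mean(x)))
  data.frame(eye = agg$eye, n_images = agg$x[, "n"],
             bmm_ratio = agg$x[, "mean"])
}

#' Aggregate semi-quantitative extracellular matrix grades
#'
#' Grades score ECM density/extent in the juxtacanalicular region on a 0-2
#' scale (0 = normal basal lamina, 2 = continuous extensive basement
#' membrane material). When two graders disagree on an image their scores
#' are averaged, so half grades are permitted. Per-eye values are image
#' means; groups are compared by both a parametric route (one-way ANOVA F
#' plus pairwise Welch t-tests) and a non-parametric route (Kruskal-Wallis
#' plus pairwise Wilcoxon rank-sum).
#'
#' @param grades Data frame with columns `eye`, `group`, `grade` and
#'   optionally `image`: with an `image` column, rows are per grader and
#'   grader scores are averaged within each image first; grades must lie in
#'   `[0, 2]` in steps of 0.5.
#' @return List with `eye_means` (data frame `eye`, `group`, `grade`),
#'   `anova_p`, `kruskal_p`, `pairwise_t`, `pairwise_wilcox` (data frames of
#'   group pairs and p-values).
#' @export
aggregate_grades <- function(grades) {
  stopifnot(is.data.frame(grades),
            all(c("eye", "group", "grade") %in% names(grades)))
  g <- grades$grade
  if (any(g < 0 | g > 2) || any(abs(g * 2 - round(g * 2)) > 1e-9)) {
    stop("grades must lie in {0, 0.5, 1, 1.5, 2}")
  }
  if ("image" %in% names(grades)) { # average graders within each image
    grades <- stats::aggregate(grade ~ eye + group + image, grades, mean)
  }
  eye_means <- stats::aggregate(grade ~ eye + group, grades, mean)
  groups <- unique(eye_means$group)
  x <- eye_means$grade
  gf <- factor(eye_means$group)

  within_var <- stats::ave(x, gf, FUN = function(v) {
    if (length(v) > 1) stats::var(v) else 0
  })
  anova_p <- if (length(groups) < 2 || stats::var(x) == 0) {
    NA_real_
  } else if (all(within_var == 0)) {
    0 # groups internally constant but different: perfect separation
  } else {
    stats::anova(stats::lm(x ~ gf))[["Pr(>F)"]][1]
  }
  kruskal_p <- if (length(groups) >= 2) {
    if (stats::var(x) == 0) 1 else stats::kruskal.test(x, gf)$p.value
  } else NA_real_

  pairs <- if (length(groups) >= 2) utils::combn(as.character(groups), 2) else NULL
  pair_test <- function(fun) {
    if (is.null(pairs)) return(NULL)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- x[gf == pairs[1, i]]; b <- x[gf == pairs[2, i]]
      p <- tryCatch(fun(a, b), error = function(e) NA_real_)
      data.frame(group_a = pairs[1, i], group_b = pairs[2, i], p = p)
    }))
  }
  list(eye_means = eye_means,
       anova_p = anova_p, kruskal_p = kruskal_p,
       pairwise_t = pair_test(function(a, b) stats::t.test(a, b)$p.value),
       pairwise_wilcox = pair_test(function(a, b) {
         suppressWarnings(stats::wilcox.test(a, b))$p.value
       }))
}

#' Cluster-bootstrap comparison of per-image readouts between two groups
#'
#' Multiple images per eye are not independent. Rather than an
#' estimating-equations correction, the group contrast is assessed by a
#' cluster bootstrap: eyes (clusters) are resampled with replacement within
#' each group, each resampled eye contributing its eye-mean readout, and the
#' difference of group means is recomputed per resample. Reported inference
#' is bootstrap-based and labeled as such.
#'
#' @param data Data frame with columns `eye`, `group` (exactly two levels)
#'   and `value` (one row per image).
#' @param n_boot Number of bootstrap resamples (default 1999).
#' @param seed Integer seed for the resampling.
#' @return List with `diff` (observed difference of group means of eye
#'   means, first level minus second), `ci` (percentile 95% interval),
#'   `p` (two-sided, from the shifted bootstrap distribution), `n_boot`,
#'   and `method = "cluster bootstrap over eyes"`.
#' @export
roi_group_test <- function(data, n_boot = 1999, seed = 1) {
  stopifnot(is.data.frame(data),
            all(c("eye", "group", "value") %in% names(data)))
  eye_means <- stats::aggregate(value ~ eye + group, data, mean)
  lev <- unique(as.character(eye_means$group))
  if (length(lev) != 2) stop("exactly two groups required")
  va <- eye_means$value[eye_means$group == lev[1]]
  vb <- eye_means$value[eye_means$group == lev[2]]
  if (length(va) < 2 || length(vb) < 2) stop("need >= 2 eyes per group")
  d_obs <- mean(va) - mean(vb)
  boot <- with_seed(seed, replicate(n_boot, {
    mean(sample(va, replace = TRUE)) - mean(sample(vb, replace = TRUE))
  }))
  centred <- boot - d_obs # bootstrap distribution shifted to the null
  p <- (sum(abs(centred) >= abs(d_obs)) + 1) / (n_boot + 1)
  list(diff = d_obs,
       ci = unname(stats::quantile(boot, c(0.025, 0.975), type = 7)),
       p = p, n_boot = n_boot,
       groups = lev, method = "cluster bootstrap over eyes")
}

#' Mean fluorescence intensity within a region of interest
#'
#' Arithmetic mean of the image values under a binary mask. A confocal
#' z-stack supplied as a 3-D array is mean-projected across slices first,
#' then averaged under the mask, so the result is the mean grayscale value
#' of the projected region of interest.
#'
#' @param image Numeric matrix, or 3-D array (rows x cols x slices).
#' @param roi_mask Logical or 0/1 matrix matching the image plane.
#' @return Mean intensity (scalar).
#' @export
roi_mean_intensity <- function(image, roi_mask) {
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  stopifnot(is.matrix(image))
  if (!all(dim(roi_mask) == dim(image))) {
    stop("ROI mask dimensions must match the image")
  }
  m <- roi_mask != 0
  if (!any(m)) stop("ROI mask is empty")
  mean(image[m])
}
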