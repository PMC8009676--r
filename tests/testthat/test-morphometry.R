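test_that("BMM coverage ratio follows the attached-segment rule", {
  full <- wall_trace(0, 100, FALSE, wall_length_um = 100)
  expect_equal(bmm_ratio(full), 1)

  two <- wall_trace(c(0, 20), c(10, 30), c(FALSE, FALSE),
                    wall_length_um = 100)
  expect_equal(bmm_ratio(two), 0.20)

  # a segment optically offset from the wall contributes nothing
  off <- wall_trace(c(0, 20), c(10, 30), c(FALSE, TRUE),
                    wall_length_um = 100)
  expect_equal(bmm_ratio(off), 0.10)

  expect_warning(r <- bmm_ratio(wall_trace(c(0, 5), c(10, 15),
                                           wall_length_um = 100)),
                 "merged")
  expect_equal(r, 0.15)
})

test_that("BMM ratio is bounded, additive over disjoint segments and order-invariant", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    bounds <- sort(stats::runif(2 * n, 0, 100))
    starts <- bounds[seq(1, 2 * n, 2)]
    ends <- bounds[seq(2, 2 * n, 2)]
    ord <- sample(n)
    tr <- wall_trace(starts, ends, rep(FALSE, n), wall_length_um = 100)
    tr_perm <- wall_trace(starts[ord], ends[ord], rep(FALSE, n),
                          wall_length_um = 100)
    r <- bmm_ratio(tr)
    expect_gte(r, 0); expect_lte(r, 1)
    expect_equal(r, sum(ends - starts) / 100)
    expect_equal(bmm_ratio(tr_perm), r)
  }
})

test_that("per-eye BMM means average over images", {
  traces <- list(wall_trace(0, 40, FALSE, 100),
                 wall_trace(0, 20, FALSE, 100),
                 wall_trace(0, 10, FALSE, 100))
  tab <- bmm_ratio_by_eye(traces, c("e1", "e1", "e2"))
  expect_equal(tab$bmm_ratio[tab$eye == "e1"], 0.3)
  expect_equal(tab$bmm_ratio[tab$eye == "e2"], 0.1)
})

test_that("grade aggregation averages graders and compares groups both ways", {
  # two graders disagreeing 0 vs 1 on one image average to 0.5
  g <- data.frame(eye = "e1", group = "A", image = "i1", grade = c(0, 1))
  expect_equal(aggregate_grades(g)$eye_means$grade, 0.5)

  ext <- data.frame(eye = rep(c("a1", "a2", "a3", "b1", "b2", "b3"),
                              each = 2),
                    group = rep(c("PL", "NT"), each = 6),
                    grade = rep(c(2, 0), each = 6))
  res <- aggregate_grades(ext)
  expect_equal(sort(unique(res$eye_means$grade)), c(0, 2))
  expect_lt(res$kruskal_p, 0.05)
  expect_lt(res$pairwise_wilcox$p, 0.1)

  same <- data.frame(eye = paste0("e", 1:6),
                     group = rep(c("A", "B"), 3),
                     grade = rep(1, 6))
  expect_equal(aggregate_grades(same)$kruskal_p, 1)

  bad <- data.frame(eye = "e", group = "A", grade = 2.3)
  expect_error(aggregate_grades(bad), "grades")
})

test_that("parametric and rank-based group tests agree with permutation references", {
  set.seed(15)
  g <- data.frame(eye = paste0("e", 1:8), group = rep(c("A", "B"), each = 4),
                  grade = c(0, 0.5, 1, 1.5, 1, 1.5, 2, 2))
  res <- aggregate_grades(g)
  # permutation reference for the rank-sum comparison
  x <- res$eye_means$grade[res$eye_means$group == "A"]
  y <- res$eye_means$grade[res$eye_means$group == "B"]
  p_perm <- mw_exact_brute(x, y)
  expect_equal(res$pairwise_wilcox$p, p_perm, tolerance = 0.25)

  # Kruskal-Wallis vs Monte-Carlo label permutation
  vals <- res$eye_means$grade
  grp <- factor(res$eye_means$group)
  kw_obs <- stats::kruskal.test(vals, grp)$statistic
  perm <- replicate(4000, {
    stats::kruskal.test(vals, sample(grp))$statistic
  })
  p_mc <- mean(perm >= kw_obs - 1e-12)
  expect_equal(res$kruskal_p, p_mc, tolerance = 0.35)
})

test_that("ROI mean intensity averages the masked region of the projection", {
  img <- matrix(100, 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  expect_equal(roi_mean_intensity(img, mask), 100)

  half <- matrix(c(rep(0, 32), rep(200, 32)), 8, 8)
  expect_equal(roi_mean_intensity(half, matrix(TRUE, 8, 8)), 100)

  # values outside the mask are irrelevant
  img2 <- img; img2[!mask] <- 1e6
  expect_equal(roi_mean_intensity(img2, mask), 100)

  # z-stacks are mean-projected before averaging
  zs <- array(0, c(4, 4, 9)); zs[, , 5] <- 9 * 50
  expect_equal(roi_mean_intensity(zs, matrix(TRUE, 4, 4)), 50)

  expect_error(roi_mean_intensity(img, matrix(TRUE, 4, 4)), "dimensions")
  expect_error(roi_mean_intensity(img, matrix(FALSE, 8, 8)), "empty")
})

test_that("cluster bootstrap respects eye-level clustering of images", {
  set.seed(16)
  mk <- function(group, shift, n_eyes = 5, n_img = 4) {
    do.call(rbind, lapply(seq_len(n_eyes), function(i) {
      eye_mu <- shift + stats::rnorm(1, 0, 2)
      data.frame(eye = sprintf("%s%d", group, i), group = group,
                 value = eye_mu + stats::rnorm(n_img, 0, 0.2))
    }))
  }
  dat <- rbind(mk("PL", 110), mk("NT", 100))
  res <- roi_group_test(dat, n_boot = 999, seed = 5)
  expect_lt(abs(abs(res$diff) - 10), 3)
  expect_true(res$ci[1] < res$diff && res$diff < res$ci[2])
  expect_identical(roi_group_test(dat, n_boot = 999, seed = 5)$p, res$p)

  # identical groups: difference near zero, p large
  same <- rbind(mk("PL", 100), mk("NT", 100))
  res0 <- roi_group_test(same, n_boot = 999, seed = 6)
  expect_gt(res0$p, 0.05)

  expect_error(roi_group_test(dat[dat$group == "PL", ]), "two groups")
})
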