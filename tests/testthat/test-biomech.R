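test_that("SC luminal pressure follows the series-resistance divider", {
  expect_equal(sc_pressure(20, evp = 7, r = 1), 7)
  expect_equal(sc_pressure(20, evp = 7, r = 0), 20)
  expect_equal(sc_pressure(20, evp = 7, r = 0.7), 10.9)
  expect_error(sc_pressure(20, r = 1.2), "\\[0, 1\\]")
  expect_error(sc_pressure(5, evp = 7))
})

test_that("pressure-area normalisation is exact and idempotent", {
  cv <- pressure_area_curve(c(10, 15, 20), c(100, 80, 50))
  n1 <- normalize_area(cv)
  expect_equal(n1$area, c(1.0, 0.8, 0.5))
  expect_equal(normalize_area(n1)$area, n1$area)

  const <- normalize_area(pressure_area_curve(c(10, 20), c(70, 70)))
  expect_equal(const$area_norm, c(1, 1))

  expect_error(normalize_area(pressure_area_curve(c(12, 20), c(1, 1))),
               "10 mmHg")
  expect_error(normalize_area(pressure_area_curve(c(10, 20), c(0, 1))),
               "zero area")
})

test_that("mask areas are foreground counts times pitch squared", {
  expect_equal(area_from_mask(matrix(0, 5, 5)), 0)
  m <- matrix(0, 20, 20); m[1:10, 1:10] <- 1
  expect_equal(area_from_mask(m, 1), 100)
  checker <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)
  expect_equal(area_from_mask(checker, 2), 50 * 4)
  expect_error(area_from_mask(matrix(0.5, 3, 3)), "binary")

  tmp <- tempfile(fileext = ".png")
  png::writePNG(m, tmp)
  expect_equal(area_from_mask(tmp, 1.5), 100 * 1.5^2)
  unlink(tmp)
})

test_that("forward solver matches the thick-wall (Lame) solution in the linear limit", {
  a <- 40; b <- 140; E <- 60; p <- 0.05
  # the package's incompressible-convention constants: mu = E/3
  mu <- E / 3

  # clamped outer ring, compressible
  nu <- 0.3
  lam <- 2 * mu * nu / (1 - 2 * nu)
  A <- -p / (2 * lam + 2 * mu * (1 + b^2 / a^2))
  u_fixed <- A * (a^2 - b^2) / a
  mod <- tissue_model(E_tm = E, E_shell = E, nu = nu, lumen_a_um = a,
                      lumen_b_um = a, shell_radius_um = b,
                      tm_thickness_um = 50, n_theta = 48, n_rho = 10)
  ctx <- outflowr:::fem_context(mod, outer_bc = "fixed")
  sol <- outflowr:::fem_solve(ctx, p)
  u_fem <- sol$u[2 * ctx$mesh$inner_ring[1] - 1]
  expect_lt(abs(u_fem / u_fixed - 1), 0.02)

  # traction-free outer ring, nearly incompressible
  nu2 <- 0.4995
  lam2 <- 2 * mu * nu2 / (1 - 2 * nu2)
  u_free <- p * a^2 / (2 * (lam2 + mu) * (b^2 - a^2)) * a +
    p * a^2 * b^2 / (2 * mu * (b^2 - a^2)) / a
  mod2 <- tissue_model(E_tm = E, E_shell = E, nu = nu2, lumen_a_um = a,
                       lumen_b_um = a, shell_radius_um = b,
                       tm_thickness_um = 50, n_theta = 48, n_rho = 10)
  ctx2 <- outflowr:::fem_context(mod2, outer_bc = "rigid3")
  sol2 <- outflowr:::fem_solve(ctx2, p)
  u_fem2 <- sol2$u[2 * ctx2$mesh$inner_ring[1] - 1]
  expect_lt(abs(u_fem2 / u_free - 1), 0.02)
})

test_that("zero transmural load leaves the section undeformed", {
  mod <- tissue_model()
  cv <- solve_forward(mod, 7) # IOP equal to EVP: no pressure drop
  expect_equal(cv$area, attr(cv, "undeformed_area"), tolerance = 1e-9)
})

test_that("strain energy is non-negative and increases with load", {
  cv <- solve_forward(tissue_model(E_tm = 61))
  en <- attr(cv, "energy")
  expect_true(all(en >= 0))
  expect_true(all(diff(en[order(cv$iop_mmHg)]) > 0))
})

test_that("collapse is monotone in IOP and in TM stiffness", {
  soft <- solve_forward(tissue_model(E_tm = 22))
  stiff <- solve_forward(tissue_model(E_tm = 61))
  expect_true(all(diff(soft$area_norm) < 0))
  expect_true(all(diff(stiff$area_norm) < 0))
  expect_true(all(stiff$area_norm[-1] > soft$area_norm[-1]))
})

test_that("mesh refinement changes predicted areas by less than 1 percent", {
  m <- tissue_model(E_tm = 100)
  coarse <- solve_forward(m)
  m2 <- tissue_model(E_tm = 100, n_theta = 96, n_rho = 16)
  fine <- solve_forward(m2)
  expect_lt(max(abs(fine$area_norm / coarse$area_norm - 1)), 0.01)
})

test_that("inverse fit is self-consistent at a grid point", {
  truth <- solve_forward(tissue_model(E_tm = 60))
  fit <- invert_stiffness(truth)
  expect_equal(fit$E_tm, 60)
  expect_equal(fit$grid[which.min(fit$sse)], 60)
  expect_equal(min(fit$sse), 0, tolerance = 1e-12)
  expect_equal(length(fit$grid), 23)

  expect_error(invert_stiffness(truth, grid = numeric(0)))
  shifted <- pressure_area_curve(c(22, 25), c(1, 0.9))
  expect_error(invert_stiffness(shifted), "10 mmHg")
})
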