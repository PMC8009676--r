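# Plane-strain total-Lagrangian finite-element solver for a pseudo-2D
# section of the irideocorneal angle: an elliptical Schlemm's canal lumen
# surrounded by a soft trabecular meshwork band inside a stiff outer shell.
#
# Constitutive model: Mooney-Rivlin extended to near-incompressibility.
# In plane strain the 3-D invariants reduce to functions of the in-plane
# deformation gradient F (2x2) only: I1_3D = tr(F'F) + 1, I2_3D = tr(F'F) +
# J^2 with J = det F, so
#   W = c1 (I1 - 2) + c2 (I1 + J^2 - 3) - 2 (c1 + 2 c2) ln J
#       + lambda/2 (ln J)^2
# which is stress-free at F = I with small-strain shear modulus
# mu = 2 (c1 + c2) and Lame parameter lambda + 4 c2. Volumetric locking of
# bilinear quads at near-incompressibility is avoided by selective reduced
# integration: the lambda (ln J)^2 term is integrated at the element
# centroid only, the rest at 2x2 Gauss points.

# shape-function derivatives of the 4-node quad at (xi, eta)
q4_dshape <- function(xi, eta) {
  cbind(dxi = 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
        deta = 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)))
}

# structured quad mesh between an inner ellipse and an outer circle.
# radial coordinate is graded toward the lumen (power `grading`) so the
# trabecular band is better resolved than the shell.
fem_mesh <- function(a, b, r_out, n_theta = 48, n_rho = 8, grading = 1.5) {
  stopifnot(a > 0, b > 0, r_out > max(a, b), n_theta %% 4 == 0, n_rho >= 2)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rho <- (seq(0, n_rho) / n_rho)^grading
  inner <- cbind(a * cos(theta), b * sin(theta))
  outer <- cbind(r_out * cos(theta), r_out * sin(theta))
  nid <- function(i, j) (j * n_theta) + ((i - 1) %% n_theta) + 1
  nodes <- matrix(0, n_theta * (n_rho + 1), 2)
  for (j in 0:n_rho) {
    nodes[nid(seq_len(n_theta), j), ] <-
      (1 - rho[j + 1]) * inner + rho[j + 1] * outer
  }
  elems <- matrix(0L, n_theta * n_rho, 4)
  ray_frac <- numeric(n_theta * n_rho) # centroid distance from lumen / ray
  e <- 0L
  for (j in seq_len(n_rho)) {
    for (i in seq_len(n_theta)) {
      e <- e + 1L
      elems[e, ] <- c(nid(i, j - 1), nid(i, j),
                      nid(i + 1, j), nid(i + 1, j - 1))
      ray_frac[e] <- (rho[j] + rho[j + 1]) / 2
    }
  }
  ray_len <- sqrt(rowSums((outer - inner)^2))
  elem_theta_i <- rep(seq_len(n_theta), times = n_rho)
  dist_from_lumen <- ray_frac * ray_len[elem_theta_i]
  centroid <- cbind(rowMeans(matrix(nodes[elems, 1], nrow(elems), 4)),
                    rowMeans(matrix(nodes[elems, 2], nrow(elems), 4)))
  list(nodes = nodes, elems = elems, n_theta = n_theta, n_rho = n_rho,
       inner_ring = nid(seq_len(n_theta), 0),
       outer_ring = nid(seq_len(n_theta), n_rho),
       dist_from_lumen = dist_from_lumen, centroid = centroid,
       nnode = nrow(nodes), nel = nrow(elems))
}

# reference-configuration quantities per Gauss point, plus sparse indexing
fem_precompute <- function(mesh) {
  gp <- rbind(expand.grid(xi = c(-1, 1) / sqrt(3), eta = c(-1, 1) / sqrt(3)),
              c(0, 0))
  wgp <- c(1, 1, 1, 1, 4)
  Xn <- matrix(mesh$nodes[mesh$elems, 1], mesh$nel, 4)
  Yn <- matrix(mesh$nodes[mesh$elems, 2], mesh$nel, 4)
  gps <- lapply(seq_len(nrow(gp)), function(g) {
    ds <- q4_dshape(gp$xi[g], gp$eta[g])
    dxdxi <- Xn %*% ds[, 1]; dxdeta <- Xn %*% ds[, 2]
    dydxi <- Yn %*% ds[, 1]; dydeta <- Yn %*% ds[, 2]
    detJ <- as.numeric(dxdxi * dydeta - dxdeta * dydxi)
    if (any(detJ <= 0)) stop("mesh has inverted elements")
    dNdX <- array(0, c(mesh$nel, 4, 2))
    for (aa in 1:4) {
      dNdX[, aa, 1] <- (ds[aa, 1] * dydeta - ds[aa, 2] * dydxi) / detJ
      dNdX[, aa, 2] <- (-ds[aa, 1] * dxdeta + ds[aa, 2] * dxdxi) / detJ
    }
    list(dNdX = dNdX, wdetJ = wgp[g] * detJ)
  })
  edof <- matrix(0L, mesh$nel, 8)
  edof[, seq(1, 8, 2)] <- 2L * mesh$elems - 1L
  edof[, seq(2, 8, 2)] <- 2L * mesh$elems
  iK <- edof[, rep(1:8, times = 8)]
  jK <- edof[, rep(1:8, each = 8)]
  list(gps = gps, edof = edof, iK = as.vector(iK), jK = as.vector(jK))
}

# consistent nodal loads on the inner (lumen) boundary for unit inflating
# pressure, dead (reference-configuration) formulation
fem_pressure_load <- function(mesh) {
  ring <- mesh$inner_ring
  nxt <- c(ring[-1], ring[1])
  dx <- mesh$nodes[nxt, 1] - mesh$nodes[ring, 1]
  dy <- mesh$nodes[nxt, 2] - mesh$nodes[ring, 2]
  n <- 2 * mesh$nnode
  # each edge contributes p/2 * (dy, -dx) to both of its end nodes
  accum_dof(c(2 * ring - 1L, 2 * nxt - 1L), c(0.5 * dy, 0.5 * dy), n) +
    accum_dof(c(2 * ring, 2 * nxt), c(-0.5 * dx, -0.5 * dx), n)
}

# internal force, tangent stiffness and strain energy at displacement u.
# mat: list of per-element vectors c1, c2, lam.
fem_assemble <- function(mesh, pre, mat, u, need_K = TRUE) {
  nel <- mesh$nel
  ux <- matrix(u[2 * mesh$elems - 1], nel, 4)
  uy <- matrix(u[2 * mesh$elems], nel, 4)
  fint <- numeric(2 * mesh$nnode)
  Kblock <- if (need_K) matrix(0, nel, 64) else NULL
  energy <- 0
  minJ <- Inf
  c1 <- mat$c1; c2 <- mat$c2; lam <- mat$lam
  mu_t <- 2 * (c1 + c2)

  for (g in seq_along(pre$gps)) {
    gpd <- pre$gps[[g]]
    dNdX <- gpd$dNdX; wdetJ <- gpd$wdetJ
    volumetric <- (g == 5) # centroid point carries the lambda term only
    F11 <- 1 + rowSums(ux * dNdX[, , 1]); F12 <- rowSums(ux * dNdX[, , 2])
    F21 <- rowSums(uy * dNdX[, , 1]); F22 <- 1 + rowSums(uy * dNdX[, , 2])
    Jd <- F11 * F22 - F12 * F21
    minJ <- min(minJ, min(Jd))
    if (min(Jd) <= 0) return(list(ok = FALSE, minJ = min(Jd)))
    iJ <- 1 / Jd
    Fi11 <- F22 * iJ; Fi12 <- -F12 * iJ; Fi21 <- -F21 * iJ; Fi22 <- F11 * iJ
    # F^{-T} components
    FiT11 <- Fi11; FiT12 <- Fi21; FiT21 <- Fi12; FiT22 <- Fi22
    lnJ <- log(Jd)

    if (!volumetric) {
      aP <- mu_t                    # coefficient of F
      bP <- 2 * c2 * Jd^2 - 2 * (c1 + 2 * c2) # coefficient of F^{-T}
      coefB <- 4 * c2 * Jd^2        # rank-one tangent coefficient
      gT <- 2 * c2 * Jd^2 - 2 * (c1 + 2 * c2)
      I1 <- F11^2 + F12^2 + F21^2 + F22^2
      energy <- energy + sum(wdetJ * (c1 * (I1 - 2) +
                                        c2 * (I1 + Jd^2 - 3) -
                                        2 * (c1 + 2 * c2) * lnJ))
    } else {
      aP <- 0
      bP <- lam * lnJ
      coefB <- lam
      gT <- lam * lnJ
      energy <- energy + sum(wdetJ * lam / 2 * lnJ^2)
    }
    P11 <- aP * F11 + bP * FiT11; P12 <- aP * F12 + bP * FiT12
    P21 <- aP * F21 + bP * FiT21; P22 <- aP * F22 + bP * FiT22

    # nodal internal forces
    for (aa in 1:4) {
      fx <- wdetJ * (P11 * dNdX[, aa, 1] + P12 * dNdX[, aa, 2])
      fy <- wdetJ * (P21 * dNdX[, aa, 1] + P22 * dNdX[, aa, 2])
      idx <- 2 * mesh$elems[, aa] - 1L
      fint <- fint + accum_dof(idx, fx, 2 * mesh$nnode) +
        accum_dof(idx + 1L, fy, 2 * mesh$nnode)
    }

    if (need_K) {
      # B_a,i = sum_m dNa/dX_m Finv_mi (spatial gradient)
      B1 <- array(0, c(nel, 4)); B2 <- array(0, c(nel, 4))
      for (aa in 1:4) {
        B1[, aa] <- dNdX[, aa, 1] * Fi11 + dNdX[, aa, 2] * Fi21
        B2[, aa] <- dNdX[, aa, 1] * Fi12 + dNdX[, aa, 2] * Fi22
      }
      for (aa in 1:4) for (bb in 1:4) {
        dNdN <- dNdX[, aa, 1] * dNdX[, bb, 1] + dNdX[, aa, 2] * dNdX[, bb, 2]
        Ba <- list(B1[, aa], B2[, aa]); Bb <- list(B1[, bb], B2[, bb])
        for (ii in 1:2) for (jj in 1:2) {
          val <- coefB * Ba[[ii]] * Bb[[jj]] - gT * Ba[[jj]] * Bb[[ii]]
          if (ii == jj) val <- val + aP * dNdN
          col64 <- (2 * (bb - 1) + jj - 1) * 8 + (2 * (aa - 1) + ii)
          Kblock[, col64] <- Kblock[, col64] + wdetJ * val
        }
      }
    }
  }
  list(ok = TRUE, fint = fint,
       vK = if (need_K) as.vector(Kblock) else NULL,
       energy = energy, minJ = minJ)
}

# scatter-add element values into a global dof vector
accum_dof <- function(idx, val, n) {
  out <- numeric(n)
  acc <- rowsum(val, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

#' Low-level hyperelastic solve of the lumen section under cavity pressure
#'
#' Newton iteration with automatic load-step halving. Positive pressure
#' inflates the lumen; negative pressure (the physiological transmural load
#' on a collapsing Schlemm's canal) compresses it.
#'
#' @param ctx Solver context from [fem_context()].
#' @param pressure_kPa Cavity pressure (kPa), dead load.
#' @param u0 Warm-start displacement (optional).
#' @param n_steps Initial number of load increments.
#' @param tol Relative residual tolerance.
#' @param max_newton Newton iterations per increment.
#' @param max_halvings Load-step halvings before giving up.
#' @return List with `u`, `area` (deformed lumen area), `energy`,
#'   `converged`.
#' @keywords internal
fem_solve <- function(ctx, pressure_kPa, u0 = NULL, p0 = 0, n_steps = 2,
                      tol = 1e-8, max_newton = 30, max_halvings = 8) {
  ndof <- 2 * ctx$mesh$nnode
  free <- ctx$free
  u <- if (is.null(u0)) numeric(ndof) else u0
  fbase <- ctx$f_unit * p0
  finc <- ctx$f_unit * (pressure_kPa - p0)
  fscale <- max(sqrt(sum((ctx$f_unit * pressure_kPa)^2)), 1e-12)

  lam <- 0; dlam <- 1 / n_steps; halvings <- 0
  while (lam < 1 - 1e-12) {
    target <- min(1, lam + dlam)
    u_try <- u
    ok <- FALSE
    for (it in seq_len(max_newton)) {
      asm <- fem_assemble(ctx$mesh, ctx$pre, ctx$mat, u_try, need_K = TRUE)
      if (!asm$ok) break
      fext <- fbase + target * finc
      res <- asm$fint - fext
      rnorm <- sqrt(sum(res[free]^2))
      if (rnorm <= tol * fscale && it > 1) { ok <- TRUE; break }
      K <- Matrix::sparseMatrix(i = ctx$pre$iK, j = ctx$pre$jK, x = asm$vK,
                                dims = c(ndof, ndof))
      du <- tryCatch(
        as.numeric(Matrix::solve(K[free, free], -res[free])),
        error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) break
      u_try[free] <- u_try[free] + du
      if (sqrt(sum(du^2)) <= 1e-12 * max(1, sqrt(sum(u_try^2)))) {
        asm2 <- fem_assemble(ctx$mesh, ctx$pre, ctx$mat, u_try, need_K = FALSE)
        if (asm2$ok &&
            sqrt(sum((asm2$fint - fext)[free]^2)) <= tol * fscale) {
          ok <- TRUE
        }
        break
      }
    }
    if (ok) {
      u <- u_try; lam <- target
    } else {
      dlam <- dlam / 2; halvings <- halvings + 1
      if (halvings > max_halvings) {
        stop(sprintf(
          "hyperelastic solve failed to converge at load fraction %.3f of %.4g kPa",
          lam + dlam * 2, pressure_kPa))
      }
    }
  }
  asm <- fem_assemble(ctx$mesh, ctx$pre, ctx$mat, u, need_K = FALSE)
  list(u = u, area = lumen_area(ctx$mesh, u), energy = asm$energy,
       converged = TRUE)
}

# deformed lumen area by the shoelace formula over the inner ring
lumen_area <- function(mesh, u = NULL) {
  ring <- mesh$inner_ring
  x <- mesh$nodes[ring, 1]; y <- mesh$nodes[ring, 2]
  if (!is.null(u)) {
    x <- x + u[2 * ring - 1]; y <- y + u[2 * ring]
  }
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * abs(sum(x * yn - xn * y))
}
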