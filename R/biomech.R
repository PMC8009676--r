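# mmHg to kPa
MMHG_KPA <- 0.1333224

#' Idealised irideocorneal-angle tissue model
#'
#' Parameterises the pseudo-2D section used by the forward collapse model:
#' an elliptical Schlemm's canal (SC) lumen surrounded by a trabecular
#' meshwork (TM) band of given thickness, embedded in a stiff outer shell
#' (sclera/cornea/uvea lumped together). Materials are Mooney-Rivlin with
#' small-strain Young's modulus `E = 6 (c1 + c2)`; by default `c2 = 0` (the
#' neo-Hookean special case) so `c1 = E / 6`. Incompressibility is handled
#' as nearly-incompressible with a bulk-to-shear ratio of at least 1000
#' (Poisson ratio 0.4995).
#'
#' @param E_tm TM small-strain modulus (kPa).
#' @param E_shell Shell modulus (kPa); default 3000 (3 MPa, scleral order).
#' @param c2_frac Fraction of each region's `c1 + c2` carried by `c2`
#'   (0 = neo-Hookean).
#' @param nu Poisson ratio for the near-incompressibility penalty.
#' @param lumen_a_um,lumen_b_um SC lumen semi-axes (um): a wide, flat,
#'   slit-like lumen, as seen in cross-sections of the canal.
#' @param tm_thickness_um Thickness of the TM band around the lumen (um).
#' @param shell_radius_um Outer radius of the section (um).
#' @param n_theta,n_rho Mesh resolution (circumferential x radial).
#' @param evp Episcleral venous pressure (mmHg) for the SC pressure divider.
#' @param tm_resistance_fraction Fraction of total outflow resistance
#'   residing in the TM (sets SC luminal pressure, see [sc_pressure()]).
#' @return Object of class `tissue_model`.
#' @export
tissue_model <- function(E_tm = 60, E_shell = 3000, c2_frac = 0, nu = 0.4995,
                         lumen_a_um = 90, lumen_b_um = 5,
                         tm_thickness_um = 30, shell_radius_um = 200,
                         n_theta = 48, n_rho = 8,
                         evp = 7, tm_resistance_fraction = 0.7) {
  stopifnot(E_tm > 0, E_shell > 0, c2_frac >= 0, c2_frac < 1,
            nu > 0, nu < 0.5,
            lumen_a_um > 0, lumen_b_um > 0, tm_thickness_um > 0,
            shell_radius_um > max(lumen_a_um, lumen_b_um) + tm_thickness_um)
  structure(list(E_tm = E_tm, E_shell = E_shell, c2_frac = c2_frac, nu = nu,
                 lumen_a_um = lumen_a_um, lumen_b_um = lumen_b_um,
                 tm_thickness_um = tm_thickness_um,
                 shell_radius_um = shell_radius_um,
                 n_theta = n_theta, n_rho = n_rho,
                 evp = evp, tm_resistance_fraction = tm_resistance_fraction),
            class = "tissue_model")
}

# Mooney-Rivlin constants and penalty Lame parameter for a region modulus.
# Small-strain checks: mu = 2 (c1 + c2) = E / 3 (incompressible convention
# E = 6 (c1 + c2)); the effective Lame parameter of the discretised model is
# lambda + 4 c2, so the input lambda is shifted accordingly.
region_material <- function(E, c2_frac, nu) {
  csum <- E / 6
  c2 <- c2_frac * csum
  c1 <- csum - c2
  mu <- 2 * csum
  lam <- 2 * mu * nu / (1 - 2 * nu) - 4 * c2
  list(c1 = c1, c2 = c2, lam = lam)
}

# Build the solver context (mesh, reference quantities, materials, BCs).
#
# Region layout mirrors the anatomy of the section: the lumen sits between
# the sclera above and the anterior chamber below. Elements within the TM
# band around the lumen, and everything on the chamber (lower) side, are
# soft outflow tissue (TM/uvea, modulus E_tm); the remaining upper material
# is the stiff shell. Boundary conditions by mode:
#   "shell"  - outer nodes on the scleral (upper) half clamped, the chamber
#              (lower) arc free so tissue can displace toward the chamber;
#              this is the physiological mode. A fully clamped ring would
#              make the nearly incompressible section's lumen area almost
#              independent of TM stiffness, since any lumen change would
#              have to shear the much stiffer shell.
#   "fixed"  - whole outer ring clamped (thick-wall benchmark).
#   "rigid3" - only rigid-body modes removed, via tangential constraints at
#              three outer nodes compatible with an axisymmetric solution
#              (free-outer benchmark).
fem_context <- function(model, outer_bc = c("shell", "fixed", "rigid3")) {
  outer_bc <- match.arg(outer_bc)
  mesh <- fem_mesh(model$lumen_a_um, model$lumen_b_um,
                   model$shell_radius_um, model$n_theta, model$n_rho)
  pre <- fem_precompute(mesh)
  is_tm <- mesh$dist_from_lumen <= model$tm_thickness_um |
    mesh$centroid[, 2] < 0
  m_tm <- region_material(model$E_tm, model$c2_frac, model$nu)
  m_sh <- region_material(model$E_shell, model$c2_frac, model$nu)
  mat <- list(c1 = ifelse(is_tm, m_tm$c1, m_sh$c1),
              c2 = ifelse(is_tm, m_tm$c2, m_sh$c2),
              lam = ifelse(is_tm, m_tm$lam, m_sh$lam))
  ndof <- 2 * mesh$nnode
  fixed <- switch(outer_bc,
    fixed = c(2 * mesh$outer_ring - 1, 2 * mesh$outer_ring),
    shell = {
      up <- mesh$outer_ring[mesh$nodes[mesh$outer_ring, 2] >= -1e-9]
      c(2 * up - 1, 2 * up)
    },
    rigid3 = {
      nt <- mesh$n_theta
      n_0 <- mesh$outer_ring[1]            # theta = 0
      n_90 <- mesh$outer_ring[nt / 4 + 1]  # theta = pi/2
      n_180 <- mesh$outer_ring[nt / 2 + 1] # theta = pi
      c(2 * n_0, 2 * n_180, 2 * n_90 - 1)  # uy, uy, ux
    })
  list(mesh = mesh, pre = pre, mat = mat,
       free = setdiff(seq_len(ndof), fixed),
       f_unit = fem_pressure_load(mesh),
       is_tm = is_tm, outer_bc = outer_bc)
}

#' Schlemm's canal luminal pressure from a series-resistance divider
#'
#' Treats the outflow pathway as TM resistance in series with distal
#' resistance: a fraction `r` of the total pressure drop from IOP to EVP
#' occurs across the TM, so `P_SC = IOP - r * (IOP - EVP)`.
#'
#' @param iop Intraocular pressure (mmHg), >= `evp`.
#' @param evp Episcleral venous pressure (mmHg).
#' @param r Fraction of total resistance in the TM, in `[0, 1]`.
#' @return SC luminal pressure (mmHg).
#' @export
sc_pressure <- function(iop, evp = 7, r = 0.7) {
  if (r < 0 || r > 1) stop("tm_resistance_fraction must lie in [0, 1]")
  stopifnot(all(iop >= evp))
  iop - r * (iop - evp)
}

#' Pressure-area curve of the Schlemm's canal lumen
#'
#' @param iop_mmHg Clamped IOP levels (mmHg).
#' @param area Lumen cross-sectional area at each level (um^2, or any
#'   consistent unit; normalisation removes it).
#' @return Object of class `pressure_area_curve` (data frame `iop_mmHg`,
#'   `area`, `area_norm` where `area_norm` is relative to the 10 mmHg
#'   level if present, else NA).
#' @export
pressure_area_curve <- function(iop_mmHg, area) {
  stopifnot(length(iop_mmHg) == length(area), all(area >= 0))
  df <- data.frame(iop_mmHg = iop_mmHg, area = area,
                   area_norm = NA_real_)
  base <- which(iop_mmHg == 10)
  if (length(base) == 1 && area[base] > 0) {
    df$area_norm <- area / area[base]
  }
  class(df) <- c("pressure_area_curve", "data.frame")
  df
}

#' Normalise a pressure-area curve to its 10 mmHg level
#'
#' Relative SC area, i.e. each area divided by the area at the 10 mmHg
#' reference level. Idempotent.
#'
#' @param curve A [pressure_area_curve()] containing the 10 mmHg level.
#' @return The curve with `area` and `area_norm` both normalised.
#' @export
normalize_area <- function(curve) {
  stopifnot(inherits(curve, "pressure_area_curve"))
  base <- which(curve$iop_mmHg == 10)
  if (length(base) != 1) stop("curve must contain the 10 mmHg level")
  if (curve$area[base] <= 0) stop("zero area at the 10 mmHg baseline")
  pressure_area_curve(curve$iop_mmHg, curve$area / curve$area[base])
}

forward_cache_env <- new.env(parent = emptyenv())

forward_cache_key <- function(model, iop_levels) {
  paste(format(c(model$E_tm, model$E_shell, model$c2_frac, model$nu,
                 model$lumen_a_um, model$lumen_b_um, model$tm_thickness_um,
                 model$shell_radius_um, model$n_theta, model$n_rho,
                 model$evp, model$tm_resistance_fraction,
                 sort(iop_levels)), digits = 12),
        collapse = "|")
}

#' Forward simulation of Schlemm's canal collapse with IOP
#'
#' Solves the plane-strain nearly-incompressible hyperelastic section at
#' each clamped IOP level. The load is the transmural pressure
#' `IOP - P_SC = r * (IOP - EVP)` compressing the lumen, applied on the
#' inner-wall boundary and ramped with Newton increments (warm-started from
#' the previous level). Solutions are cached on the model parameters, so
#' repeated calls during an inverse sweep cost one solve per grid point.
#'
#' @param model A [tissue_model()].
#' @param iop_levels Clamped IOP levels (mmHg) within 5-30.
#' @param use_cache Reuse cached solutions for identical inputs?
#' @return A [pressure_area_curve()] with attributes `E_tm`, `energy`
#'   (strain energy per level, in kPa um^2 per unit depth) and
#'   `undeformed_area`.
#' @export
solve_forward <- function(model, iop_levels = c(10, 12, 15, 17, 20),
                          use_cache = TRUE) {
  stopifnot(inherits(model, "tissue_model"), length(iop_levels) >= 1,
            all(iop_levels >= 5), all(iop_levels <= 30))
  key <- forward_cache_key(model, iop_levels)
  if (use_cache && !is.null(forward_cache_env[[key]])) {
    return(forward_cache_env[[key]])
  }
  ctx <- fem_context(model, outer_bc = "shell")
  ord <- order(iop_levels)
  levels_sorted <- iop_levels[ord]
  p_trans <- -(levels_sorted - sc_pressure(levels_sorted, model$evp,
                                           model$tm_resistance_fraction)) *
    MMHG_KPA # negative: compresses the lumen
  areas <- numeric(length(levels_sorted))
  energies <- numeric(length(levels_sorted))
  u <- NULL; p_prev <- 0
  for (k in seq_along(levels_sorted)) {
    sol <- fem_solve(ctx, p_trans[k], u0 = u, p0 = p_prev)
    areas[k] <- sol$area
    energies[k] <- sol$energy
    u <- sol$u; p_prev <- p_trans[k]
  }
  out <- pressure_area_curve(iop_levels,
                             areas[match(iop_levels, levels_sorted)])
  attr(out, "E_tm") <- model$E_tm
  attr(out, "energy") <- energies[match(iop_levels, levels_sorted)]
  attr(out, "undeformed_area") <- lumen_area(ctx$mesh)
  if (use_cache) forward_cache_env[[key]] <- out
  out
}

#' Clear the forward-model solution cache
#' @export
clear_forward_cache <- function() {
  rm(list = ls(forward_cache_env), envir = forward_cache_env)
  invisible(NULL)
}

#' Inverse estimation of trabecular meshwork stiffness
#'
#' Sweeps TM stiffness over a grid, runs the forward collapse model once per
#' grid value, and returns the stiffness minimising the sum of squared
#' differences between model and observed normalised SC areas over the IOP
#' range (default 10-20 mmHg). Multiple observed curves (eyes) are pooled
#' into one objective.
#'
#' @param observed A [pressure_area_curve()] or list of them; each must
#'   cover IOP levels within the range and include the 10 mmHg level.
#' @param grid Stiffness grid (kPa); default 20 to 240 by 10.
#' @param model Template [tissue_model()] whose `E_tm` is swept.
#' @param iop_range Closed IOP interval used in the objective (mmHg).
#' @param refine Golden-section refinement of the minimum between the
#'   neighbouring grid points (extra forward solves)?
#' @return Object of class `stiffness_fit`: list with `E_tm` (best), `grid`,
#'   `sse` (per grid point), `refined` (logical), `n_curves`.
#' @export
invert_stiffness <- function(observed, grid = seq(20, 240, by = 10),
                             model = tissue_model(), iop_range = c(10, 20),
                             refine = FALSE) {
  if (inherits(observed, "pressure_area_curve")) observed <- list(observed)
  stopifnot(length(observed) >= 1, length(grid) >= 1)
  obs <- lapply(observed, function(cv) {
    cv <- normalize_area(cv)
    keep <- cv$iop_mmHg >= iop_range[1] & cv$iop_mmHg <= iop_range[2]
    if (!any(keep)) stop("observed curve has no levels inside iop_range")
    cv[keep, ]
  })
  levels <- sort(unique(unlist(lapply(obs, function(cv) cv$iop_mmHg))))

  sse_at <- function(E) {
    m <- model
    m$E_tm <- E
    fwd <- normalize_area(solve_forward(m, levels))
    sum(vapply(obs, function(cv) {
      pred <- fwd$area_norm[match(cv$iop_mmHg, fwd$iop_mmHg)]
      sum((pred - cv$area_norm)^2)
    }, numeric(1)))
  }
  sse <- vapply(grid, sse_at, numeric(1))
  i_best <- which.min(sse)
  best <- grid[i_best]
  refined <- FALSE
  if (refine && length(grid) >= 3 && i_best > 1 && i_best < length(grid)) {
    opt <- stats::optimize(sse_at, c(grid[i_best - 1], grid[i_best + 1]),
                           tol = 0.5)
    if (opt$objective < sse[i_best]) {
      best <- opt$minimum
      refined <- TRUE
    }
  }
  structure(list(E_tm = best, grid = grid, sse = sse, refined = refined,
                 n_curves = length(obs)),
            class = "stiffness_fit")
}

#' Lumen area from a binary segmentation mask
#'
#' @param mask Binary matrix (0/1 or logical), or path to a PNG mask.
#' @param pixel_pitch_um Physical pixel pitch (um/pixel), > 0.
#' @return Area in um^2 (foreground pixel count times pitch squared).
#' @export
area_from_mask <- function(mask, pixel_pitch_um = 1) {
  stopifnot(pixel_pitch_um > 0)
  if (is.character(mask)) {
    mask <- png::readPNG(mask)
    if (length(dim(mask)) == 3) mask <- mask[, , 1]
  }
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) stop("mask is not binary (values other than 0/1)")
  sum(mask == 1) * pixel_pitch_um^2
}
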