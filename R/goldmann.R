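#' Goldmann-equation inputs for treated-vs-control IOP accounting
#'
#' Bundles the quantities entering the steady-state aqueous humor balance
#' `Q = C * (IOP - EVP) + FU`: measured IOP and outflow facility in the
#' placebo (PL) and treated (NT) groups, an assumed episcleral venous
#' pressure, the unconventional (pressure-independent) outflow rate, and the
#' fractional suppression of aqueous inflow attributed to treatment.
#'
#' @param iop_pl,iop_nt Measured IOP (mmHg) in PL- and NT-treated eyes.
#' @param c_pl,c_nt Outflow facility (nl/min/mmHg) in each group; positive.
#' @param evp Episcleral venous pressure (mmHg), assumed equal across groups.
#' @param fu Unconventional outflow rate (nl/min), assumed treatment-invariant.
#' @param x Fractional reduction of aqueous inflow due to treatment, in
#'   `[0, 1)`; 0 means inflow is unaffected.
#' @return Object of class `goldmann_inputs`.
#' @export
goldmann_inputs <- function(iop_pl, iop_nt, c_pl, c_nt, evp = 7, fu = 0,
                            x = 0) {
  stopifnot(c_pl > 0, c_nt > 0, x >= 0, x < 1, fu >= 0)
  if (iop_pl <= evp) stop("IOP_PL must exceed EVP")
  structure(list(iop_pl = iop_pl, iop_nt = iop_nt, c_pl = c_pl, c_nt = c_nt,
                 evp = evp, fu = fu, x = x),
            class = "goldmann_inputs")
}

#' Aqueous inflow rate implied by the placebo group
#'
#' `Q_PL = C_PL * (IOP_PL - EVP) + FU`, the steady-state inflow consistent
#' with the measured placebo IOP and facility at the assumed EVP.
#'
#' @param inputs A [goldmann_inputs()] object.
#' @return Inflow rate in nl/min.
#' @export
inflow_rate <- function(inputs) {
  stopifnot(inherits(inputs, "goldmann_inputs"))
  with(inputs, c_pl * (iop_pl - evp) + fu)
}

#' Predicted IOP in treated eyes from facility changes alone
#'
#' Rearranging the aqueous balance for the treated group, assuming EVP and
#' unconventional outflow are unchanged by treatment and inflow is reduced by
#' the fraction `x`:
#' `IOP_pred = -x * Q_PL / C_NT + (C_PL / C_NT) * (IOP_PL - EVP) + EVP`.
#' With `x = 0` and `C_NT = C_PL` this returns `IOP_PL` identically.
#'
#' @inheritParams inflow_rate
#' @return Predicted treated-eye IOP in mmHg.
#' @export
predict_iop <- function(inputs) {
  stopifnot(inherits(inputs, "goldmann_inputs"))
  q_pl <- inflow_rate(inputs)
  with(inputs, -x * q_pl / c_nt + (c_pl / c_nt) * (iop_pl - evp) + evp)
}

#' Fraction of the observed IOP change accounted for by facility
#'
#' Two conventions are computed, because published accountings do not always
#' state which is used:
#' * `diff_ratio`: predicted IOP drop over observed drop,
#'   `100 * (IOP_PL - IOP_pred) / (IOP_PL - IOP_NT)`;
#' * `level_ratio`: predicted over measured treated-eye IOP,
#'   `100 * IOP_pred / IOP_NT`.
#' Both are percentages; 100 means facility changes exactly account for the
#' observed IOP.
#'
#' @inheritParams inflow_rate
#' @return List with `iop_pred`, `diff_ratio`, `level_ratio` (percent).
#' @export
percent_accounted <- function(inputs) {
  stopifnot(inherits(inputs, "goldmann_inputs"))
  if (inputs$iop_pl == inputs$iop_nt) {
    stop("IOP_PL equals IOP_NT: observed difference is zero")
  }
  pred <- predict_iop(inputs)
  list(iop_pred = pred,
       diff_ratio = 100 * (inputs$iop_pl - pred) /
         (inputs$iop_pl - inputs$iop_nt),
       level_ratio = 100 * pred / inputs$iop_nt)
}

#' Sweep the IOP accounting over assumed EVP and inflow-suppression grids
#'
#' EVP and the inflow effect of treatment are rarely measured alongside
#' facility; this evaluates [percent_accounted()] on the Cartesian product of
#' assumed values so the accounting can be reported as an envelope rather
#' than a point. The predicted IOP rises with EVP whenever `C_NT > C_PL`
#' (`d IOP_pred / d EVP = 1 - (1 - x) C_PL / C_NT > 0`), so at fixed `x`
#' `diff_ratio` decreases and `level_ratio` increases monotonically in EVP;
#' the monotonicity diagnostic records whether that holds numerically.
#'
#' @param inputs_base A [goldmann_inputs()] object providing measured IOPs
#'   and facilities; its `evp` and `x` are overridden by the grids.
#' @param evp_grid Numeric vector of EVP values (mmHg), default 4 to 10 by
#'   0.5.
#' @param x_grid Numeric vector of inflow-suppression fractions, default
#'   `c(0, 0.10, 0.15)`.
#' @return Data frame with one row per (EVP, x) pair: `evp`, `x`,
#'   `iop_pred`, `diff_ratio`, `level_ratio`, plus logical attribute
#'   `monotone_in_evp` (`diff_ratio` non-increasing and `level_ratio`
#'   non-decreasing within every `x`).
#' @export
goldmann_sweep <- function(inputs_base, evp_grid = seq(4, 10, by = 0.5),
                           x_grid = c(0, 0.10, 0.15)) {
  stopifnot(inherits(inputs_base, "goldmann_inputs"),
            length(evp_grid) >= 1, length(x_grid) >= 1)
  grid <- expand.grid(evp = evp_grid, x = x_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- mapply(function(evp, x) {
    inp <- goldmann_inputs(inputs_base$iop_pl, inputs_base$iop_nt,
                           inputs_base$c_pl, inputs_base$c_nt,
                           evp = evp, fu = inputs_base$fu, x = x)
    pa <- percent_accounted(inp)
    c(iop_pred = pa$iop_pred, diff_ratio = pa$diff_ratio,
      level_ratio = pa$level_ratio)
  }, grid$evp, grid$x)
  out <- cbind(grid, t(rows))
  mono <- vapply(split(out, out$x), function(s) {
    s <- s[order(s$evp), ]
    c(diff = all(diff(s$diff_ratio) <= 0),
      level = all(diff(s$level_ratio) >= 0))
  }, logical(2))
  attr(out, "monotone_in_evp") <- all(mono)
  out
}
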