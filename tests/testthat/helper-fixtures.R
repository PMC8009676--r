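# shared fixture builders

# one pressure step as a raw sample table
make_step <- function(target, flow, duration_s = 360, dt = 2,
                      pressure = target, t0 = 0) {
  t_s <- seq(0, duration_s, by = dt)
  data.frame(step_target_mmHg = target, t_s = t0 + t_s,
             pressure_mmHg = rep_len(pressure, length(t_s)),
             flow_nl_min = rep_len(flow, length(t_s)))
}

# exact-linear perfusion record Q = C * P over the standard step schedule
make_linear_record <- function(C = 3.5, steps = default_pressure_steps()) {
  t0 <- 0
  tabs <- lapply(steps, function(p) {
    s <- make_step(p, C * p, t0 = t0)
    t0 <<- t0 + 362
    s
  })
  perfusion_record(do.call(rbind, tabs))
}

# independent linear-interpolation quantile (same definition as type 7),
# written from the textbook formula for use as a brute-force oracle
quantile_lin <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force exact two-sided Mann-Whitney p by full enumeration
mw_exact_brute <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(xa, xb) sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  u_obs <- u_of(a, b)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# the published group means used throughout (facility nl/min/mmHg, IOP mmHg,
# AFM moduli kPa)
study_means <- list(
  prevention = list(iop_pl = 25.0, iop_nt = 17.4, c_pl = 2.64, c_nt = 4.87),
  reversal = list(iop_pl = 28.4, iop_nt = 21.0, c_pl = 3.48, c_nt = 5.18,
                  c_contra = 3.27),
  afm = list(nt = 1.54, contra = 2.00)
)
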