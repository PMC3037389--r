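# Independent numerical oracles used to cross-check the analytic
# machinery.  These deliberately avoid the code paths they verify:
# the ODE oracle integrates numerically, the root oracles use plain
# bisection / dense grids rather than the package's closed forms.

# Numerical integration of dC/dt = ks - kd*C with a stiff-capable
# integrator at tight tolerance.
ode_cyclin <- function(c0, ks, kd, dt) {
  if (dt == 0) return(c0)
  out <- deSolve::lsoda(
    y = c(C = c0), times = c(0, dt),
    func = function(t, y, p) list(p["ks"] - p["kd"] * y),
    parms = c(ks = ks, kd = kd),
    rtol = 1e-12, atol = 1e-12
  )
  unname(out[2, "C"])
}

# Plain bisection to tolerance `tol`; f(lo) and f(hi) must bracket.
bisect_root <- function(f, lo, hi, tol = 1e-9) {
  flo <- f(lo)
  stopifnot(flo * f(hi) <= 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (flo * f(mid) <= 0) hi <- mid else {
      lo <- mid
      flo <- f(mid)
    }
  }
  (lo + hi) / 2
}

# First grid point (resolution `by`) at which f changes sign, refined
# by bisection on the bracketing cell.
grid_first_crossing <- function(f, t_max, by = 1e-3, tol = 1e-9) {
  ts <- seq(0, t_max, by = by)
  vals <- vapply(ts, f, numeric(1))
  i <- which(vals[-1] * vals[-length(vals)] <= 0)[1]
  if (is.na(i)) return(Inf)
  bisect_root(f, ts[i], ts[i + 1], tol)
}

# A fully deterministic configuration and its single golden cycle,
# shared by several test files.
hc_det_config <- function() deterministic_config(model_config())

hc_det_history <- function(n = 1) {
  simulate_lineage(n, 0, hc_det_config())
}
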