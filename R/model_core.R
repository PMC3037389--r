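# Analytic machinery of the hybrid model: effective rate constants per
# Boolean state, the closed-form solution of the piecewise-linear cyclin
# kinetics, exponential growth, and the threshold-crossing solvers.

#' Effective synthesis and degradation rates of one cyclin
#'
#' Within a Boolean state, each cyclin X obeys
#' `d[CycX]/dt = ks - kd * [CycX]` with effective rate "constants"
#' assembled from a basal term plus the increments whose regulator flag
#' is active: TFE and TFB drive synthesis (TFE for cyclins E and A,
#' TFB for cyclins B and A); SCF, Cdc20A, Cdc20B and Cdh1 drive
#' degradation (SCF for E, Cdc20A for A, Cdc20B for B, Cdh1 for A
#' and B).
#'
#' @param cyclin `"A"`, `"B"` or `"E"`.
#' @param regs A [boolean_regulators()] vector.
#' @param params Named list of rate constants (see
#'   [hc_default_config_path()] for the key names).
#' @return Named numeric `c(ks = , kd = )`; errors if the effective
#'   degradation rate is not positive (the analytic solution divides
#'   by `kd`).
#' @export
effective_rates <- function(cyclin, regs, params) {
  cyclin <- match.arg(toupper(cyclin), c("A", "B", "E"))
  r <- function(k) as.numeric(params[[k]])
  if (cyclin == "A") {
    ks <- r("ksa_basal") + r("ksa_tfe") * regs[["tfe"]] +
      r("ksa_tfb") * regs[["tfb"]]
    kd <- r("kda_basal") + r("kda_cdc20a") * regs[["cdc20a"]] +
      r("kda_cdh1") * regs[["cdh1"]]
  } else if (cyclin == "B") {
    ks <- r("ksb_basal") + r("ksb_tfb") * regs[["tfb"]]
    kd <- r("kdb_basal") + r("kdb_cdc20b") * regs[["cdc20b"]] +
      r("kdb_cdh1") * regs[["cdh1"]]
  } else {
    ks <- r("kse_basal") + r("kse_tfe") * regs[["tfe"]]
    kd <- r("kde_basal") + r("kde_scf") * regs[["scf"]]
  }
  if (!is.finite(kd) || kd <= 0)
    stop("effective degradation rate for cyclin ", cyclin,
         " is not positive; the analytic solution requires kd > 0",
         call. = FALSE)
  c(ks = ks, kd = kd)
}

#' Cyclin concentration after a time interval (closed form)
#'
#' Exact solution of `dC/dt = ks - kd * C`:
#' `C(dt) = ks/kd + (C0 - ks/kd) * exp(-kd * dt)`.
#' No numerical integration is involved.
#'
#' @param c0 Initial concentration.
#' @param ks Synthesis rate (concentration/h).
#' @param kd Degradation rate (1/h), must be > 0.
#' @param dt Elapsed time (h), >= 0; vectorised.
#' @return Concentration(s) at `dt`.
#' @export
cyclin_at <- function(c0, ks, kd, dt) {
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(dt < 0)) stop("dt must be >= 0", call. = FALSE)
  ks / kd + (c0 - ks / kd) * exp(-kd * dt)
}

#' Cell mass after a time interval
#'
#' Exponential growth `M0 * exp(gamma * dt)` by default.  In linear
#' mode the cell adds mass at the constant rate `gamma * M0` set at the
#' reference time, i.e. `M0 * (1 + gamma * dt)`.
#'
#' @param m0 Mass at the reference time.
#' @param gamma Specific growth rate (1/h).
#' @param dt Elapsed time (h), >= 0; vectorised.
#' @param growth `"exponential"` (default) or `"linear"`.
#' @return Mass at `dt`.
#' @export
mass_at <- function(m0, gamma, dt, growth = c("exponential", "linear")) {
  growth <- match.arg(growth)
  if (any(dt < 0)) stop("dt must be >= 0", call. = FALSE)
  if (growth == "exponential") m0 * exp(gamma * dt) else m0 * (1 + gamma * dt)
}

#' Time for a cyclin concentration to cross a threshold
#'
#' Inverts the closed-form trajectory: the smallest `t >= 0` with
#' `C(t) = theta` is `log((c0 - ks/kd) / (theta - ks/kd)) / kd` when
#' the monotone trajectory actually reaches `theta`.  If the starting
#' value is already past the threshold in the crossing direction the
#' crossing time is 0 (the state machine treats the condition as
#' already satisfied).  If `theta` lies beyond the asymptote `ks/kd`
#' the threshold is unreachable and `Inf` is returned.
#'
#' @param c0 Starting concentration.
#' @param ks,kd Effective rates; `kd > 0`.
#' @param theta Threshold concentration.
#' @param direction `"up"` (rising crossing) or `"down"`.
#' @return Crossing time in hours, `0` if already past, `Inf` if
#'   unreachable.
#' @export
concentration_crossing_time <- function(c0, ks, kd, theta,
                                        direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  a <- ks / kd
  if (direction == "up") {
    if (c0 >= theta) return(0)
    if (a <= theta) return(Inf)
  } else {
    if (c0 <= theta) return(0)
    if (a >= theta) return(Inf)
  }
  log((c0 - a) / (theta - a)) / kd
}

#' Time for a cyclin *amount* to cross a threshold
#'
#' Solves `C(t) * M(t) = theta` for the product of the analytic cyclin
#' concentration and the growing cell mass.  The equation is
#' transcendental, so the root is bracketed and refined numerically
#' (`stats::uniroot`, interval tolerance `tol`).  With `gamma = 0`
#' this reduces exactly to [concentration_crossing_time()] with
#' threshold `theta / m0`.
#'
#' @param c0 Starting concentration.
#' @param ks,kd Effective rates; `kd > 0`.
#' @param m0 Mass at the start of the interval (> 0).
#' @param gamma Specific growth rate (1/h), >= 0.
#' @param theta Threshold amount (concentration x mass).
#' @param direction `"up"` or `"down"`.
#' @param tol Root tolerance in hours.
#' @param t_max Horizon beyond which the threshold is declared
#'   unreachable.
#' @return Crossing time in hours, `0` if already past, `Inf` if
#'   unreachable within `t_max`.
#' @export
amount_crossing_time <- function(c0, ks, kd, m0, gamma, theta,
                                 direction = c("up", "down"),
                                 tol = 1e-10, t_max = 1e4) {
  direction <- match.arg(direction)
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (m0 <= 0) stop("m0 must be > 0", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (gamma == 0)
    return(concentration_crossing_time(c0, ks, kd, theta / m0, direction))
  sgn <- if (direction == "up") 1 else -1
  f <- function(t) sgn * (cyclin_at(c0, ks, kd, t) * m0 * exp(gamma * t) - theta)
  if (f(0) >= 0) return(0)  # already past the threshold at state entry
  hi <- 1
  while (hi < t_max && f(hi) < 0) hi <- hi * 2
  if (f(min(hi, t_max)) < 0) return(Inf)
  stats::uniroot(f, c(0, min(hi, t_max)), tol = tol)$root
}
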