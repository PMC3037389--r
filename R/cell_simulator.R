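# Single-cell life histories: per-state residence times, analytic
# cyclin/mass updates, division, and lineage iteration with burn-in.

#' Stochastic waiting time from a uniform deviate
#'
#' Inversion formula for the exponential stochastic component of a
#' state transition: `-lambda * log(r)` for `r` uniform on (0, 1].
#' Deterministic given `r`; [sample_stochastic_delay()] draws `r`.
#'
#' @param lambda Mean waiting time (h), >= 0.
#' @param r Uniform deviate(s) in (0, 1].
#' @return Waiting time(s) in hours; 0 when `lambda = 0`.
#' @export
stochastic_delay_from_uniform <- function(lambda, r) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  if (any(r <= 0) || any(r > 1)) stop("r must lie in (0, 1]", call. = FALSE)
  out <- -lambda * log(r)
  out[rep(lambda == 0, length.out = length(out))] <- 0
  out
}

#' Draw exponential stochastic waiting times
#'
#' @param lambda Mean waiting time (h), >= 0.
#' @param n Number of draws.
#' @return `n` non-negative waiting times; all 0 when `lambda = 0`.
#' @export
sample_stochastic_delay <- function(lambda, n = 1) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (lambda == 0) return(rep(0, n))
  stochastic_delay_from_uniform(lambda, stats::runif(n))
}

#' Residence time in one Boolean state
#'
#' The time a cell spends in state `n` is the sum of a deterministic
#' execution time and an exponential stochastic wait with mean
#' `lambda_n`.  The deterministic part is 0 for states 1, 6, 7 and 8,
#' the S-phase timer for state 4, and the threshold-crossing time of
#' the state's cyclin condition for states 2, 3, 5 and 9 (computed
#' with the closed-form/root solvers of the analytic core).
#'
#' @param state State index 1..9.
#' @param conc Named concentrations `c(cyca, cycb, cyce)` at state
#'   entry.
#' @param mass Cell mass at state entry (for amount-based thresholds).
#' @param config A `hybrid_config`.
#' @param theta_factors Length-4 multiplicative noise factors for
#'   `(theta_e, theta_a, theta_b1, theta_b2)`; default no noise.
#' @param mass_fun Optional function `(dt) -> mass` giving the mass
#'   trajectory from state entry (used internally for linear growth);
#'   defaults to exponential growth from `mass`.
#' @return List with `total`, `t_det` and `t_stoch` (hours).  An
#'   unreachable threshold aborts with a diagnostic naming the state.
#' @export
residence_time <- function(state, conc, mass, config,
                           theta_factors = rep(1, 4), mass_fun = NULL) {
  st <- config$states
  stopifnot(state %in% 1:9)
  rts <- config$rates
  th <- config$thresholds * theta_factors
  t_det <- switch(as.character(state),
    "2" = {
      if (is.null(mass_fun)) {
        amount_crossing_time(conc[["cyce"]], rts[2, "kse"], rts[2, "kde"],
                             mass, config$gamma, th[["theta_e"]], "up")
      } else {
        # generic mass trajectory (linear growth): bracketed root find
        f <- function(t) cyclin_at(conc[["cyce"]], rts[2, "kse"],
                                   rts[2, "kde"], t) * mass_fun(t) -
          th[["theta_e"]]
        if (f(0) >= 0) 0 else {
          hi <- 1
          while (hi < 1e4 && f(hi) < 0) hi <- hi * 2
          if (f(min(hi, 1e4)) < 0) Inf
          else stats::uniroot(f, c(0, min(hi, 1e4)), tol = 1e-10)$root
        }
      }
    },
    "3" = concentration_crossing_time(conc[["cyca"]], rts[3, "ksa"],
                                      rts[3, "kda"], th[["theta_a"]], "up"),
    "5" = concentration_crossing_time(conc[["cycb"]], rts[5, "ksb"],
                                      rts[5, "kdb"], th[["theta_b1"]], "up"),
    "9" = concentration_crossing_time(conc[["cycb"]], rts[9, "ksb"],
                                      rts[9, "kdb"], th[["theta_b2"]], "down"),
    st$t_det[state]
  )
  t_det <- unname(t_det)
  if (!is.finite(t_det))
    stop("threshold unreachable in state ", state, " (", st$phase[state],
         "): entry conc [", paste(signif(conc, 4), collapse = ", "),
         "], mass ", signif(mass, 4), call. = FALSE)
  t_stoch <- sample_stochastic_delay(st$lambda[state], 1)
  list(total = t_det + t_stoch, t_det = t_det, t_stoch = t_stoch)
}

# Core single-cycle engine.  Inlined arithmetic (no per-call argument
# checking) because simulate_lineage and the population simulator call
# this tens of thousands of times; residence_time() is the documented
# general form of the per-state logic.  If `w1` is supplied it is used
# as the full state-1 residence time (the population simulator draws it
# from the density-dependent rate before calling).
.hc_cycle_core <- function(m0, conc, config, w1 = NULL) {
  rts <- config$rates
  lam <- config$states$lambda
  t_det4 <- config$states$t_det[4]
  g <- if (config$threshold_noise_sd > 0)
    stats::rnorm(4, 1, config$threshold_noise_sd) else c(1, 1, 1, 1)
  th_e <- config$thresholds[[1]] * g[1]
  th_a <- config$thresholds[[2]] * g[2]
  th_b1 <- config$thresholds[[3]] * g[3]
  th_b2 <- config$thresholds[[4]] * g[4]
  gam <- config$gamma
  lin <- config$growth == "linear"
  a <- 0
  ages <- numeric(9); tdet <- numeric(9); tstoch <- numeric(9)
  cm <- matrix(NA_real_, 10, 3)
  cm[1, ] <- conc
  ca <- conc[1]; cb <- conc[2]; ce <- conc[3]
  for (n in 1:9) {
    ksa <- rts[[n, 1]]; kda <- rts[[n, 2]]
    ksb <- rts[[n, 3]]; kdb <- rts[[n, 4]]
    kse <- rts[[n, 5]]; kde <- rts[[n, 6]]
    td <- 0
    if (n == 2L) {
      asy <- kse / kde
      f <- if (lin)
        function(t) (asy + (ce - asy) * exp(-kde * t)) *
          m0 * (1 + gam * (a + t)) - th_e
      else
        function(t) (asy + (ce - asy) * exp(-kde * t)) *
          m0 * exp(gam * (a + t)) - th_e
      if (f(0) < 0) {
        hi <- 1
        while (hi < 1e4 && f(hi) < 0) hi <- hi * 2
        td <- if (f(min(hi, 1e4)) < 0) Inf
        else stats::uniroot(f, c(0, min(hi, 1e4)), tol = 1e-10)$root
      }
    } else if (n == 3L) {
      asy <- ksa / kda
      td <- if (ca >= th_a) 0
      else if (asy <= th_a) Inf
      else log((ca - asy) / (th_a - asy)) / kda
    } else if (n == 4L) {
      td <- t_det4
    } else if (n == 5L) {
      asy <- ksb / kdb
      td <- if (cb >= th_b1) 0
      else if (asy <= th_b1) Inf
      else log((cb - asy) / (th_b1 - asy)) / kdb
    } else if (n == 9L) {
      asy <- ksb / kdb
      td <- if (cb <= th_b2) 0
      else if (asy >= th_b2) Inf
      else log((cb - asy) / (th_b2 - asy)) / kdb
    }
    if (!is.finite(td))
      stop("threshold unreachable in state ", n, " (",
           config$states$phase[n], "): entry conc [",
           paste(signif(c(ca, cb, ce), 4), collapse = ", "),
           "], mass ", signif(m0 * exp(gam * a), 4), call. = FALSE)
    if (n == 1L && !is.null(w1)) {
      ts <- w1
    } else {
      ts <- if (lam[n] > 0) stats::rexp(1, 1 / lam[n]) else 0
    }
    tdet[n] <- td; tstoch[n] <- ts
    dt <- td + ts
    ca <- ksa / kda + (ca - ksa / kda) * exp(-kda * dt)
    cb <- ksb / kdb + (cb - ksb / kdb) * exp(-kdb * dt)
    ce <- kse / kde + (ce - kse / kde) * exp(-kde * dt)
    a <- a + dt
    ages[n] <- a
    cm[n + 1, 1] <- ca; cm[n + 1, 2] <- cb; cm[n + 1, 3] <- ce
  }
  list(ages = ages, t_det = tdet, t_stoch = tstoch, conc = cm,
       m_div = if (lin) m0 * (1 + gam * a) else m0 * exp(gam * a),
       theta_factors = g)
}

#' Simulate one complete cell cycle
#'
#' Follows a newborn cell (state 1, G1a) through the nine-state
#' sequence until division.  Within each state the cyclin
#' concentrations evolve by the closed-form solution under that
#' state's effective rates and the mass grows exponentially (or
#' linearly); concentrations are continuous across state boundaries.
#'
#' @param config A `hybrid_config`.
#' @param birth_mass Mass at birth; defaults to the configured initial
#'   condition.
#' @param birth_conc Named concentrations `c(cyca, cycb, cyce)` at
#'   birth; defaults to the configured initial conditions.
#' @param birth_time Absolute birth time (h), recorded as `t0`.
#' @return A `cell_cycle` list: `t0`, `m0`, `a_exit` (ages at the nine
#'   state exits), `t_det`, `t_stoch`, `conc` (10 x 3 matrix of
#'   boundary concentrations, birth first), `theta_factors`, `a9`
#'   (cycle length) and `m_div` (mass at division).
#' @export
simulate_cycle <- function(config, birth_mass = config$init[["mass"]],
                           birth_conc = config$init[c("cyca", "cycb", "cyce")],
                           birth_time = 0) {
  stopifnot(inherits(config, "hybrid_config"),
            birth_mass > 0, all(birth_conc > 0))
  core <- .hc_cycle_core(birth_mass, as.numeric(birth_conc), config)
  structure(list(t0 = birth_time, m0 = birth_mass,
                 a_exit = core$ages, t_det = core$t_det,
                 t_stoch = core$t_stoch,
                 conc = `dimnames<-`(core$conc,
                                     list(c("birth", paste0("exit", 1:9)),
                                          c("cyca", "cycb", "cyce"))),
                 theta_factors = core$theta_factors,
                 a9 = core$ages[9], m_div = core$m_div),
            class = "cell_cycle")
}

#' Divide a cell
#'
#' Draws the division-asymmetry fraction `delta` from a Gaussian with
#' the configured mean and SD (clipped to
#' `(delta_clip, 1 - delta_clip)`; at the default SD of 0.0167 the
#' clip is essentially never triggered).  One daughter receives
#' `delta * M_div`, the other `(1 - delta) * M_div`; both inherit the
#' mother's boundary cyclin concentrations unchanged (concentrations,
#' not amounts, pass through division).
#'
#' @param history A `cell_cycle` from [simulate_cycle()].
#' @param config A `hybrid_config`.
#' @return List with `delta`, `daughter_mass` (`delta * M_div`),
#'   `other_mass`, and `clipped` (logical).
#' @export
divide <- function(history, config) {
  stopifnot(inherits(history, "cell_cycle"))
  d <- if (config$delta_sd > 0)
    stats::rnorm(1, config$delta_mean, config$delta_sd) else config$delta_mean
  clipped <- d <= config$delta_clip || d >= 1 - config$delta_clip
  d <- min(max(d, config$delta_clip), 1 - config$delta_clip)
  list(delta = d, daughter_mass = d * history$m_div,
       other_mass = (1 - d) * history$m_div, clipped = clipped)
}

#' Simulate a cell lineage
#'
#' Starts from the configured progenitor (concentrations 1, mass 3 by
#' default), follows the cell to division, picks one of the two
#' daughters at random (tracked mass `delta * M_div` or
#' `(1 - delta) * M_div` with probability 1/2 each), and repeats for
#' `n_total` iterations.  The first `n_burnin` cells are discarded so
#' the retained sample comes from the stationary birth-size
#' distribution enforced by the cyclin-E size control.
#'
#' @param n_total Total number of cycles simulated.
#' @param n_burnin Number of initial cycles discarded
#'   (`0 <= n_burnin < n_total`).
#' @param config A `hybrid_config`.
#' @param seed Optional integer seed.
#' @return A `cell_histories` data.frame with one row per retained
#'   cell: `cell`, `t0` (absolute birth time), `m0`, `a1..a9` (ages at
#'   state exits; `a9` is the cycle length), `m_div`,
#'   `delta` (tracked daughter fraction of the division ending the
#'   cycle), `clipped`, and boundary concentrations `cyca0..cyca9`,
#'   `cycb0..cycb9`, `cyce0..cyce9` (birth value then the nine exit
#'   values).
#' @export
simulate_lineage <- function(n_total, n_burnin = 0, config = model_config(),
                             seed = NULL) {
  stopifnot(n_total > n_burnin, n_burnin >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_keep <- n_total - n_burnin
  out <- matrix(NA_real_, n_keep, 44)
  colnames(out) <- c("t0", "m0", paste0("a", 1:9), "m_div", "delta",
                     "clipped",
                     paste0("cyca", 0:9), paste0("cycb", 0:9),
                     paste0("cyce", 0:9))
  m0 <- config$init[["mass"]]
  conc <- as.numeric(config$init[c("cyca", "cycb", "cyce")])
  t0 <- 0
  for (i in seq_len(n_total)) {
    core <- .hc_cycle_core(m0, conc, config)
    d <- if (config$delta_sd > 0)
      stats::rnorm(1, config$delta_mean, config$delta_sd) else
        config$delta_mean
    clipped <- d <= config$delta_clip || d >= 1 - config$delta_clip
    d <- min(max(d, config$delta_clip), 1 - config$delta_clip)
    if (stats::runif(1) < 0.5) d <- 1 - d
    if (i > n_burnin) {
      j <- i - n_burnin
      out[j, ] <- c(t0, m0, core$ages, core$m_div, d, clipped,
                    core$conc[, 1], core$conc[, 2], core$conc[, 3])
    }
    t0 <- t0 + core$ages[9]
    m0 <- d * core$m_div
    conc <- core$conc[10, ]
  }
  df <- as.data.frame(out)
  df <- cbind(cell = seq_len(n_keep), df)
  class(df) <- c("cell_histories", "data.frame")
  df
}

#' Export cell life histories as TSV
#'
#' One row per cell with the documented column order of
#' [simulate_lineage()]; RFC-4180-style with a tab separator and a
#' mandatory header.
#'
#' @param x A `cell_histories` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cell_histories <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
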