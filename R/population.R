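# Contact-inhibited population growth: density-dependent G1a exit,
# event-driven simulation of every cell, daily counts and phase
# fractions.

#' Contact-inhibition parameters
#'
#' `p0` is the maximal G1a exit rate; the exit probability drops
#' sigmoidally around the population size `n0` over a width `n1`.
#'
#' @param p0 Maximal exit rate from state 1 (1/h).
#' @param n0 Inhibition midpoint (cells).
#' @param n1 Transition width (cells), `0 < n1 << n0`.
#' @param n_init Number of starting cells.
#' @param days Duration of the experiment (days).
#' @param cap Hard cap on population size; exceeding it aborts the
#'   run with a diagnostic (runaway-growth guard).
#' @return A `contact_params` list.
#' @export
contact_params <- function(p0 = 0.5, n0 = 11000, n1 = 500,
                           n_init = 500, days = 10, cap = 1e6) {
  stopifnot(p0 > 0, n1 > 0, n0 > n1, n_init >= 1, days >= 1, cap > n_init)
  structure(list(p0 = p0, n0 = n0, n1 = n1, n_init = n_init,
                 days = days, cap = cap),
            class = "contact_params")
}

#' Density-dependent G1a exit probability
#'
#' Logistic form `p(N) = p0 / (1 + exp((N - n0) / n1))`: approximately
#' `p0` for small populations, `p0 / 2` at the midpoint `n0`, and
#' dropping abruptly to 0 for `N > n0` when `n1 << n0`.  Strictly
#' decreasing in `N`.
#'
#' @param n Population size(s), >= 0.
#' @param params A [contact_params()] list.
#' @return Exit rate(s) in 1/h, in `(0, p0]`.
#' @export
transition_probability <- function(n, params = contact_params()) {
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  params$p0 / (1 + exp((n - params$n0) / params$n1))
}

#' Phase fractions of a population snapshot
#'
#' Classifies cells by Boolean state (1-3 G0/G1, 4 S, 5-9 G2/M) and
#' returns percentages summing to 100.
#'
#' @param states Integer vector of state indices (1..9) of the live
#'   cells.
#' @return Named numeric `c(g0g1, s, g2m)` in percent.
#' @export
phase_fractions <- function(states) {
  if (length(states) == 0) stop("empty population", call. = FALSE)
  c(g0g1 = 100 * mean(states <= 3),
    s = 100 * mean(states == 4),
    g2m = 100 * mean(states >= 5))
}

#' Simulate contact-inhibited population growth
#'
#' Event-driven simulation tracking every cell (both daughters of each
#' division).  When a cell enters state 1 (G1a) its exponential
#' waiting-time mean is set to `1 / p(N)` with `p` evaluated at the
#' instantaneous population size `N`; the drawn wait is kept even if
#' `N` changes during it.  All other states behave exactly as in the
#' single-lineage simulator.  Starting cells are newborns with the
#' configured initial conditions.  Every 24 h the live-cell count and
#' the phase distribution are recorded.
#'
#' Cells whose G1a wait extends past the simulation horizon are left
#' arrested in state 1 (quiescence): no daughters are scheduled for
#' divisions beyond the horizon.
#'
#' @param params A [contact_params()] list.
#' @param config A `hybrid_config`.
#' @param seed Optional integer seed.
#' @return A list with `growth_curve` (a `growth_curve` data.frame:
#'   `day`, `count`, `pct_g0g1`, `pct_s`, `pct_g2m`) and `cells`
#'   (birth time `t0`, absolute state-exit times `t1..t9`, `Inf` past
#'   the horizon for arrested cells).
#' @export
simulate_contact_inhibition <- function(params = contact_params(),
                                        config = model_config(),
                                        seed = NULL) {
  stopifnot(inherits(params, "contact_params"),
            inherits(config, "hybrid_config"))
  if (!is.null(seed)) set.seed(seed)
  horizon <- params$days * 24

  # Binary min-heap on event time, kept as parallel local vectors and
  # mutated via superassignment so element writes stay in place.
  # Event payload: type (1 = G1a entry, 2 = division), mass, cyclin
  # concentrations at birth.
  hcap <- 4096L
  e_t <- numeric(hcap); e_type <- integer(hcap)
  e_m <- numeric(hcap); e_a <- numeric(hcap)
  e_b <- numeric(hcap); e_e <- numeric(hcap)
  hn <- 0L
  swap <- function(i, j) {
    tt <- e_t[i]; e_t[i] <<- e_t[j]; e_t[j] <<- tt
    tt <- e_type[i]; e_type[i] <<- e_type[j]; e_type[j] <<- tt
    tt <- e_m[i]; e_m[i] <<- e_m[j]; e_m[j] <<- tt
    tt <- e_a[i]; e_a[i] <<- e_a[j]; e_a[j] <<- tt
    tt <- e_b[i]; e_b[i] <<- e_b[j]; e_b[j] <<- tt
    tt <- e_e[i]; e_e[i] <<- e_e[j]; e_e[j] <<- tt
  }
  hpush <- function(t, type, m, ca, cb, ce) {
    if (hn + 1L > length(e_t)) {
      e_t <<- c(e_t, numeric(length(e_t)))
      e_type <<- c(e_type, integer(length(e_type)))
      e_m <<- c(e_m, numeric(length(e_m)))
      e_a <<- c(e_a, numeric(length(e_a)))
      e_b <<- c(e_b, numeric(length(e_b)))
      e_e <<- c(e_e, numeric(length(e_e)))
    }
    hn <<- hn + 1L
    e_t[hn] <<- t; e_type[hn] <<- type; e_m[hn] <<- m
    e_a[hn] <<- ca; e_b[hn] <<- cb; e_e[hn] <<- ce
    i <- hn
    while (i > 1L) {
      p <- i %/% 2L
      if (e_t[p] <= e_t[i]) break
      swap(p, i)
      i <- p
    }
  }
  hpop <- function() {
    r <- c(e_t[1], e_type[1], e_m[1], e_a[1], e_b[1], e_e[1])
    swap(1L, hn)
    hn <<- hn - 1L
    i <- 1L
    repeat {
      l <- 2L * i; rgt <- l + 1L; s <- i
      if (l <= hn && e_t[l] < e_t[s]) s <- l
      if (rgt <= hn && e_t[rgt] < e_t[s]) s <- rgt
      if (s == i) break
      swap(s, i)
      i <- s
    }
    r
  }

  for (i in seq_len(params$n_init))
    hpush(0, 1L, config$init[["mass"]], config$init[["cyca"]],
          config$init[["cycb"]], config$init[["cyce"]])
  n_alive <- params$n_init
  t0v <- numeric(4096L)
  exits <- matrix(NA_real_, 4096L, 9)
  ncell <- 0L
  divtimes <- numeric(0)
  while (hn > 0L) {
    ev <- hpop()
    t <- ev[1]
    if (ev[2] == 2) {  # division: one mother becomes two daughters
      n_alive <- n_alive + 1L
      divtimes[length(divtimes) + 1L] <- t
      if (n_alive > params$cap)
        stop("population exceeded the hard cap of ", params$cap,
             " cells (runaway growth)", call. = FALSE)
      next
    }
    # G1a entry: draw the waiting time with mean 1/p(N_now)
    p <- transition_probability(n_alive, params)
    if (ncell + 1L > nrow(exits)) {
      exits <- rbind(exits, matrix(NA_real_, nrow(exits), 9))
      t0v <- c(t0v, numeric(nrow(exits) - length(t0v)))
    }
    ncell <- ncell + 1L
    t0v[ncell] <- t
    w1 <- if (is.finite(1 / p)) sample_stochastic_delay(1 / p, 1) else Inf
    if (!is.finite(w1) || t + w1 > horizon) {
      # arrested in G1a (quiescent) for the remainder of the run
      exits[ncell, ] <- Inf
      next
    }
    core <- .hc_cycle_core(ev[3], ev[4:6], config, w1 = w1)
    exits[ncell, ] <- t + core$ages
    tdiv <- t + core$ages[9]
    if (tdiv <= horizon) {
      hpush(tdiv, 2L, 0, 0, 0, 0)
      d <- if (config$delta_sd > 0)
        stats::rnorm(1, config$delta_mean, config$delta_sd) else
          config$delta_mean
      d <- min(max(d, config$delta_clip), 1 - config$delta_clip)
      hpush(tdiv, 1L, d * core$m_div,
            core$conc[10, 1], core$conc[10, 2], core$conc[10, 3])
      hpush(tdiv, 1L, (1 - d) * core$m_div,
            core$conc[10, 1], core$conc[10, 2], core$conc[10, 3])
    }
  }
  exits <- exits[seq_len(ncell), , drop = FALSE]
  t0v <- t0v[seq_len(ncell)]
  days <- 0:params$days
  counts <- vapply(days, function(d)
    params$n_init + sum(divtimes <= d * 24), numeric(1))
  pcts <- t(vapply(days, function(d) {
    tt <- d * 24
    alive <- t0v <= tt & exits[, 9] > tt
    states <- 1L + rowSums(exits[alive, , drop = FALSE] <= tt)
    phase_fractions(states)
  }, numeric(3)))
  gc <- data.frame(day = days, count = counts,
                   pct_g0g1 = pcts[, 1], pct_s = pcts[, 2],
                   pct_g2m = pcts[, 3])
  class(gc) <- c("growth_curve", "data.frame")
  list(growth_curve = gc,
       cells = data.frame(t0 = t0v,
                          stats::setNames(as.data.frame(exits),
                                          paste0("t", 1:9))))
}

#' Export a growth curve as CSV
#'
#' @param x A `growth_curve` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_growth_curve <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
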