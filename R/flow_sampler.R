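# Simulated asynchronous flow cytometry: random cell-cycle positions,
# state lookup, DNA/cyclin/mass read-out and instrument noise.

#' Cell-cycle fraction from a uniform deviate
#'
#' In an exponentially expanding asynchronous population the density of
#' cells is twice as high at birth (`phi = 0`) as at division
#' (`phi = 1`): the ideal density is proportional to `2^-phi`.  The
#' transformation method inverts its CDF, giving
#' `phi = -log2(1 - r/2)` for `r` uniform on [0, 1).
#'
#' @param r Uniform deviate(s) in [0, 1).
#' @return Cell-cycle fraction(s) in [0, 1).
#' @export
phase_from_uniform <- function(r) {
  if (any(r < 0) || any(r >= 1)) stop("r must lie in [0, 1)", call. = FALSE)
  -log2(1 - r / 2)
}

#' Sample cell-cycle fractions for an asynchronous population
#'
#' @param n Number of draws.
#' @return `n` fractions with density proportional to `2^-phi`.
#' @export
sample_phase <- function(n) phase_from_uniform(stats::runif(n))

# Ages at state exits as an n x 9 matrix from a histories data.frame.
.hc_age_matrix <- function(histories) {
  as.matrix(histories[, paste0("a", 1:9)])
}

#' Locate the Boolean state of a cell at a given age
#'
#' Returns the unique state `n` whose half-open residence interval
#' `[a_{n-1}, a_n)` contains the age (a cell exactly at a boundary
#' belongs to the later state).
#'
#' @param histories A `cell_histories` data.frame (or a single row).
#' @param age Age(s) in hours, one per row, with `0 <= age < a9`.
#' @return Integer state indices 1..9.
#' @export
locate_state <- function(histories, age) {
  am <- .hc_age_matrix(histories)
  if (any(age < 0) || any(age >= am[, 9]))
    stop("age must satisfy 0 <= age < a9", call. = FALSE)
  as.integer(1 + rowSums(am <= age))
}

#' Cyclin concentration at an arbitrary age
#'
#' Applies the closed-form solution within the state occupied at
#' `age`, starting from the stored boundary concentration at that
#' state's entry, so values are exact and continuous across
#' boundaries.
#'
#' @param histories A `cell_histories` data.frame.
#' @param age Age(s) in hours, one per row.
#' @param cyclin `"A"`, `"B"` or `"E"`.
#' @param config The `hybrid_config` the histories were generated
#'   with.
#' @return Concentration(s) at `age`.
#' @export
cyclin_at_age <- function(histories, age, cyclin, config) {
  cyclin <- match.arg(toupper(cyclin), c("A", "B", "E"))
  n <- locate_state(histories, age)
  am <- .hc_age_matrix(histories)
  entry_age <- cbind(0, am)[cbind(seq_along(n), n)]
  col0 <- paste0("cyc", tolower(cyclin), 0:9)
  c_entry <- as.matrix(histories[, col0])[cbind(seq_along(n), n)]
  rc <- switch(cyclin, A = c("ksa", "kda"), B = c("ksb", "kdb"),
               E = c("kse", "kde"))
  ks <- unname(config$rates[n, rc[1]])
  kd <- unname(config$rates[n, rc[2]])
  cyclin_at(c_entry, ks, kd, age - entry_age)
}

#' DNA content at an arbitrary age
#'
#' 1 before S entry (exit of state 3), rising linearly to 2 across S
#' phase, and 2 from S exit (exit of state 4) to division.
#'
#' @param histories A `cell_histories` data.frame.
#' @param age Age(s) in hours, one per row.
#' @return DNA content in [1, 2].
#' @export
dna_at_age <- function(histories, age) {
  a3 <- histories$a3; a4 <- histories$a4
  dna <- ifelse(age < a3, 1,
                ifelse(age < a4, 1 + (age - a3) / (a4 - a3), 2))
  as.numeric(dna)
}

#' Apply multiplicative instrument noise to a flow sample
#'
#' Each measurable channel (DNA and the three total cyclins) is
#' multiplied by an independent Gaussian factor with mean 1 and the
#' configured per-channel SD, emulating probe, staining and
#' measurement error.  True values are retained alongside the
#' measured ones.  Negative measured values (vanishingly rare at the
#' default SDs) are left as-is; their count is recorded in the
#' `n_negative` attribute.
#'
#' @param events A `flow_events` data.frame with `*_true` columns.
#' @param config A `hybrid_config` (per-channel SDs).
#' @return The events with `dna_meas`, `cyca_meas`, `cycb_meas`,
#'   `cyce_meas` filled in.
#' @export
apply_instrument_noise <- function(events, config) {
  n <- nrow(events)
  fac <- function(sd) if (sd > 0) stats::rnorm(n, 1, sd) else rep(1, n)
  events$dna_meas <- events$dna_true * fac(config$noise_dna)
  events$cyca_meas <- events$cyca_true * fac(config$noise_cyclin)
  events$cycb_meas <- events$cycb_true * fac(config$noise_cyclin)
  events$cyce_meas <- events$cyce_true * fac(config$noise_cyclin)
  attr(events, "n_negative") <-
    sum(events$dna_meas < 0) + sum(events$cyca_meas < 0) +
    sum(events$cycb_meas < 0) + sum(events$cyce_meas < 0)
  events
}

.hc_phase_labels <- c("G0/G1", "S", "G2/M")

# state index -> coarse phase label (1-3 G0/G1, 4 S, 5-9 G2/M)
.hc_state_phase <- function(state) {
  .hc_phase_labels[ifelse(state <= 3, 1L, ifelse(state == 4, 2L, 3L))]
}

#' Simulate an asynchronous flow-cytometry sample
#'
#' Draws a cell-cycle fraction `phi` for each life history (density
#' proportional to `2^-phi`), locates the Boolean state at the
#' corresponding age, reads out the exact DNA content, mass, and total
#' cyclin amounts (`[CycX](a) * M(a)`, the flow cytometer measures
#' total fluorescence per cell), and applies instrument noise.
#'
#' @param histories A `cell_histories` data.frame from
#'   [simulate_lineage()].
#' @param config The `hybrid_config` used to generate the histories.
#' @param seed Optional integer seed.
#' @param n_events Number of events; defaults to one per history.  If
#'   larger, histories are resampled with replacement.
#' @return A `flow_events` data.frame: `cell_id`, `phi`, `age_h`,
#'   `state`, `phase`, `dna_true`, `dna_meas`, `cyca_true`,
#'   `cyca_meas`, `cycb_true`, `cycb_meas`, `cyce_true`, `cyce_meas`,
#'   `mass` (mass is exported noise-free).
#' @export
simulate_flow_sample <- function(histories, config, seed = NULL,
                                 n_events = nrow(histories)) {
  stopifnot(nrow(histories) > 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- if (n_events == nrow(histories)) seq_len(n_events)
         else sample.int(nrow(histories), n_events, replace = TRUE)
  h <- histories[idx, , drop = FALSE]
  phi <- sample_phase(n_events)
  age <- phi * h$a9
  state <- locate_state(h, age)
  mass <- mass_at(h$m0, config$gamma, age, config$growth)
  ev <- data.frame(
    cell_id = h$cell,
    phi = phi,
    age_h = age,
    state = state,
    phase = .hc_state_phase(state),
    dna_true = dna_at_age(h, age),
    dna_meas = NA_real_,
    cyca_true = cyclin_at_age(h, age, "A", config) * mass,
    cyca_meas = NA_real_,
    cycb_true = cyclin_at_age(h, age, "B", config) * mass,
    cycb_meas = NA_real_,
    cyce_true = cyclin_at_age(h, age, "E", config) * mass,
    cyce_meas = NA_real_,
    mass = mass,
    stringsAsFactors = FALSE
  )
  ev <- apply_instrument_noise(ev, config)
  class(ev) <- c("flow_events", "data.frame")
  ev
}

#' Export a flow sample as CSV
#'
#' RFC-4180 CSV with header, '.' decimal separator, one row per event
#' in the documented column order.
#'
#' @param x A `flow_events` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flow_events <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scatter plot of a simulated flow sample
#'
#' Convenience display (measured total cyclin B against cyclin A by
#' default) coloured by Boolean state, mimicking instrument scatter
#' plots.  Presentation-only; an optional display gain rescales the
#' DNA axis to instrument units.
#'
#' @param events A `flow_events` data.frame.
#' @param x,y Column names to plot.
#' @param dna_gain Multiplier applied when plotting a DNA channel
#'   (display only, never used in statistics).
#' @param ... Passed to [graphics::plot()].
#' @return The events, invisibly.
#' @export
plot_flow_scatter <- function(events, x = "cyca_meas", y = "cycb_meas",
                              dna_gain = 190, ...) {
  xv <- events[[x]]; yv <- events[[y]]
  if (grepl("^dna", x)) xv <- xv * dna_gain
  if (grepl("^dna", y)) yv <- yv * dna_gain
  pal <- grDevices::hcl.colors(9, "Dark 3")
  graphics::plot(xv, yv, col = pal[events$state], pch = ".",
                 xlab = x, ylab = y, ...)
  invisible(events)
}
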