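# Model configuration: the nine-state table, rate constants, thresholds,
# noise parameters, and the YAML config-file interface.

.hc_env <- new.env(parent = emptyenv())

#' Path to the packaged default configuration file
#'
#' The packaged YAML file is the single source of truth for all default
#' parameter values; every key carries a provenance comment
#' (`paper` or `calibrated`).
#'
#' @return Path to the installed `default-config.yaml`.
#' @export
hc_default_config_path <- function() {
  system.file("extdata", "default-config.yaml", package = "hybridcycle",
              mustWork = TRUE)
}

# Flat key set accepted in config files and as overrides.
.hc_config_keys <- c(
  "ksa_basal", "ksa_tfe", "ksa_tfb", "kda_basal", "kda_cdc20a", "kda_cdh1",
  "kse_basal", "kse_tfe", "kde_basal", "kde_scf",
  "ksb_basal", "ksb_tfb", "kdb_basal", "kdb_cdc20b", "kdb_cdh1",
  "theta_e", "theta_a", "theta_b1", "theta_b2",
  paste0("lambda_", 1:9), "t_det_4",
  "gamma", "growth",
  "delta_mean", "delta_sd", "delta_clip",
  "threshold_noise_sd", "noise_dna", "noise_cyclin",
  "init_cyca", "init_cycb", "init_cyce", "init_mass"
)

#' Boolean regulator vector
#'
#' Six binary flags for the lumped transcription factors (TFE, TFB) and
#' ubiquitination activities (SCF, Cdc20A, Cdc20B, Cdh1) that gate
#' cyclin synthesis and degradation.
#'
#' @param tfe,tfb,scf,cdc20a,cdc20b,cdh1 0 or 1.
#' @return Named integer vector of length 6.
#' @export
boolean_regulators <- function(tfe = 0, tfb = 0, scf = 0,
                               cdc20a = 0, cdc20b = 0, cdh1 = 0) {
  regs <- c(tfe = tfe, tfb = tfb, scf = scf,
            cdc20a = cdc20a, cdc20b = cdc20b, cdh1 = cdh1)
  if (!all(regs %in% c(0, 1)))
    stop("regulator flags must each be 0 or 1", call. = FALSE)
  storage.mode(regs) <- "integer"
  regs
}

#' The fixed nine-state regulatory sequence
#'
#' One row per Boolean state of the cycle, in order of traversal:
#' the regulator flags active in that state, the exit condition
#' (`timer` or `threshold`), the threshold specification where one
#' applies (which cyclin, on an amount or concentration basis, and the
#' crossing direction), the deterministic timer component `t_det`, and
#' the mean `lambda` of the exponential stochastic wait.
#'
#' States 2, 3, 5 and 9 exit on threshold crossings; states 1, 6, 7 and
#' 8 are pure stochastic waits (`t_det = 0`); state 4 (S phase) has a
#' 7 h deterministic floor.  TFE is active in states 2-4, TFB in 5-8,
#' SCF in 4-9, Cdc20A in 7-8, Cdc20B in 8, and Cdh1 in 1-2 and 9.
#'
#' @param lambda Numeric length 9, per-state stochastic means (h).
#' @param t_det_4 Deterministic S-phase duration (h).
#' @return A data.frame with 9 rows.
#' @export
default_state_table <- function(lambda = c(2, 0, 0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                                t_det_4 = 7) {
  stopifnot(length(lambda) == 9, all(lambda >= 0), t_det_4 >= 0)
  data.frame(
    index = 1:9,
    phase = c("G1a", "G1b-early", "G1b-late", "S", "G2", "prophase",
              "prometaphase-metaphase", "anaphase", "telophase"),
    tfe    = c(0, 1, 1, 1, 0, 0, 0, 0, 0),
    tfb    = c(0, 0, 0, 0, 1, 1, 1, 1, 0),
    scf    = c(0, 0, 0, 1, 1, 1, 1, 1, 1),
    cdc20a = c(0, 0, 0, 0, 0, 0, 1, 1, 0),
    cdc20b = c(0, 0, 0, 0, 0, 0, 0, 1, 0),
    cdh1   = c(1, 1, 0, 0, 0, 0, 0, 0, 1),
    exit      = c("timer", "threshold", "threshold", "timer", "threshold",
                  "timer", "timer", "timer", "threshold"),
    cyclin    = c(NA, "E", "A", NA, "B", NA, NA, NA, "B"),
    basis     = c(NA, "amount", "concentration", NA, "concentration",
                  NA, NA, NA, "concentration"),
    direction = c(NA, "up", "up", NA, "up", NA, NA, NA, "down"),
    t_det  = c(0, NA, NA, t_det_4, NA, 0, 0, 0, NA),
    lambda = lambda,
    stringsAsFactors = FALSE
  )
}

.hc_read_defaults <- function() {
  if (is.null(.hc_env$defaults)) {
    vals <- yaml::read_yaml(hc_default_config_path())
    .hc_env$defaults <- vals
  }
  .hc_env$defaults
}

.hc_build_config <- function(kv) {
  params <- kv[c("ksa_basal", "ksa_tfe", "ksa_tfb",
                 "kda_basal", "kda_cdc20a", "kda_cdh1",
                 "kse_basal", "kse_tfe", "kde_basal", "kde_scf",
                 "ksb_basal", "ksb_tfb", "kdb_basal", "kdb_cdc20b",
                 "kdb_cdh1")]
  lambda <- unlist(kv[paste0("lambda_", 1:9)], use.names = FALSE)
  cfg <- list(
    params = lapply(params, as.numeric),
    thresholds = c(theta_e = as.numeric(kv$theta_e),
                   theta_a = as.numeric(kv$theta_a),
                   theta_b1 = as.numeric(kv$theta_b1),
                   theta_b2 = as.numeric(kv$theta_b2)),
    gamma = as.numeric(kv$gamma),
    growth = as.character(kv$growth),
    delta_mean = as.numeric(kv$delta_mean),
    delta_sd = as.numeric(kv$delta_sd),
    delta_clip = as.numeric(kv$delta_clip),
    threshold_noise_sd = as.numeric(kv$threshold_noise_sd),
    noise_dna = as.numeric(kv$noise_dna),
    noise_cyclin = as.numeric(kv$noise_cyclin),
    init = c(cyca = as.numeric(kv$init_cyca),
             cycb = as.numeric(kv$init_cycb),
             cyce = as.numeric(kv$init_cyce),
             mass = as.numeric(kv$init_mass)),
    states = default_state_table(lambda = lambda,
                                 t_det_4 = as.numeric(kv$t_det_4))
  )
  class(cfg) <- "hybrid_config"
  validate_config(cfg)
  cfg$rates <- state_rates(cfg)
  cfg
}

#' Build a model configuration
#'
#' Reads the packaged default parameter file and applies any overrides
#' given as named arguments using the flat config-file keys, e.g.
#' `model_config(lambda_1 = 2, gamma = log(2) / 22)`.
#'
#' @param ... Named overrides; unknown keys are an error.
#' @return A validated `hybrid_config` object: rate parameters,
#'   thresholds, growth rate, noise parameters, initial conditions, the
#'   nine-state table, and a precomputed per-state effective-rate matrix.
#' @seealso [load_config()], [deterministic_config()]
#' @export
model_config <- function(...) {
  kv <- .hc_read_defaults()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .hc_config_keys)
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown configuration key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    kv[names(over)] <- over
  }
  .hc_build_config(kv)
}

#' Load a model configuration from a YAML file
#'
#' Missing keys are filled from the packaged defaults; unknown keys are
#' an error; invariant violations (negative rates, a state with zero
#' effective degradation, non-positive thresholds, ...) raise a
#' validation error naming the offending keys.  An empty file yields
#' the packaged defaults.
#'
#' @param path Path to a flat key-value YAML file.
#' @return A validated `hybrid_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  bad <- setdiff(names(vals), .hc_config_keys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  kv <- .hc_read_defaults()
  kv[names(vals)] <- vals
  .hc_build_config(kv)
}

#' Fully deterministic variant of a configuration
#'
#' Sets every stochastic mean `lambda_i` to zero, fixes the division
#' asymmetry at its mean, and turns off threshold and instrument noise.
#' Two runs of the resulting configuration are bit-identical regardless
#' of seed; used for golden-trajectory fixtures.
#'
#' @param base A `hybrid_config` to start from.
#' @return A `hybrid_config`.
#' @export
deterministic_config <- function(base = model_config()) {
  stopifnot(inherits(base, "hybrid_config"))
  base$states$lambda <- rep(0, 9)
  base$delta_sd <- 0
  base$threshold_noise_sd <- 0
  base$noise_dna <- 0
  base$noise_cyclin <- 0
  validate_config(base)
  base
}

#' Per-state effective rate constants for all three cyclins
#'
#' Applies [effective_rates()] to each row of the state table.
#'
#' @param config A `hybrid_config`.
#' @return A 9 x 6 matrix with columns
#'   `ksa, kda, ksb, kdb, kse, kde`.
#' @export
state_rates <- function(config) {
  st <- config$states
  out <- matrix(NA_real_, 9, 6,
                dimnames = list(NULL, c("ksa", "kda", "ksb", "kdb",
                                        "kse", "kde")))
  for (n in 1:9) {
    regs <- boolean_regulators(st$tfe[n], st$tfb[n], st$scf[n],
                               st$cdc20a[n], st$cdc20b[n], st$cdh1[n])
    out[n, 1:2] <- effective_rates("A", regs, config$params)
    out[n, 3:4] <- effective_rates("B", regs, config$params)
    out[n, 5:6] <- effective_rates("E", regs, config$params)
  }
  out
}

#' Validate a configuration
#'
#' Checks the invariants the simulator relies on: non-negative rate
#' constants, strictly positive effective degradation in every state
#' (the analytic cyclin solution divides by it), positive thresholds
#' and growth rate, non-negative noise SDs, a division-asymmetry SD
#' small enough that clipping is essentially never triggered, and the
#' structural rules of the nine-state table.
#'
#' @param config A `hybrid_config`.
#' @return The config, invisibly; errors describe offending keys.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "hybrid_config"))
  p <- unlist(config$params)
  if (any(p < 0))
    stop("negative rate constant(s): ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  th <- config$thresholds
  if (any(!is.finite(th)) || any(th <= 0))
    stop("thresholds must be finite and > 0: ",
         paste(names(th)[!(th > 0)], collapse = ", "), call. = FALSE)
  if (!is.finite(config$gamma) || config$gamma <= 0)
    stop("gamma must be > 0", call. = FALSE)
  if (!config$growth %in% c("exponential", "linear"))
    stop("growth must be 'exponential' or 'linear'", call. = FALSE)
  sds <- c(delta_sd = config$delta_sd,
           threshold_noise_sd = config$threshold_noise_sd,
           noise_dna = config$noise_dna, noise_cyclin = config$noise_cyclin)
  if (any(sds < 0))
    stop("negative SD(s): ", paste(names(sds)[sds < 0], collapse = ", "),
         call. = FALSE)
  if (config$delta_clip <= 0 || config$delta_clip >= 0.5)
    stop("delta_clip must lie in (0, 0.5)", call. = FALSE)
  # delta stays inside (clip, 1-clip) with overwhelming probability
  if (config$delta_sd > 0 &&
      (0.5 - config$delta_clip) / config$delta_sd < 6)
    stop("delta_sd too large relative to the clipping bounds", call. = FALSE)
  if (any(config$init <= 0))
    stop("initial conditions must be > 0", call. = FALSE)
  st <- config$states
  if (nrow(st) != 9 || !identical(st$index, 1:9))
    stop("state table must have indices 1..9 exactly once", call. = FALSE)
  if (!all(st$exit[c(2, 3, 5, 9)] == "threshold"))
    stop("states 2, 3, 5, 9 must exit on thresholds", call. = FALSE)
  if (!all(st$exit[c(1, 4, 6, 7, 8)] == "timer"))
    stop("states 1, 4, 6, 7, 8 must exit on timers", call. = FALSE)
  if (!all(st$t_det[c(1, 6, 7, 8)] == 0))
    stop("states 1, 6, 7, 8 must have t_det = 0", call. = FALSE)
  if (any(st$lambda < 0)) stop("lambda values must be >= 0", call. = FALSE)
  # effective degradation must be positive everywhere
  rts <- state_rates(config)
  kd <- rts[, c("kda", "kdb", "kde")]
  if (any(kd <= 0)) {
    bad <- which(kd <= 0, arr.ind = TRUE)
    stop("effective degradation rate is 0 in state(s) ",
         paste(unique(bad[, 1]), collapse = ", "),
         " (", paste(unique(colnames(kd)[bad[, 2]]), collapse = ", "),
         "): the analytic solution requires kd > 0", call. = FALSE)
  }
  invisible(config)
}

#' @export
print.hybrid_config <- function(x, ...) {
  cat("<hybrid_config> 9-state hybrid cell-cycle model\n")
  cat("  gamma:", format(x$gamma), "/h (", x$growth, "growth )\n")
  cat("  thresholds:",
      paste(names(x$thresholds), x$thresholds, sep = "=", collapse = "  "),
      "\n")
  cat("  lambda (h):", paste(x$states$lambda, collapse = ", "), "\n")
  cat("  division asymmetry: N(", x$delta_mean, ",", x$delta_sd, ")\n")
  cat("  noise: threshold", x$threshold_noise_sd,
      "| DNA", x$noise_dna, "| cyclin", x$noise_cyclin, "\n")
  invisible(x)
}

# Flatten a config back to the flat key-value representation (used by
# run manifests so a run can be reproduced from its manifest alone).
.hc_flatten_config <- function(config) {
  st <- config$states
  c(config$params,
    as.list(config$thresholds),
    stats::setNames(as.list(st$lambda), paste0("lambda_", 1:9)),
    list(t_det_4 = st$t_det[4],
         gamma = config$gamma, growth = config$growth,
         delta_mean = config$delta_mean, delta_sd = config$delta_sd,
         delta_clip = config$delta_clip,
         threshold_noise_sd = config$threshold_noise_sd,
         noise_dna = config$noise_dna, noise_cyclin = config$noise_cyclin,
         init_cyca = unname(config$init["cyca"]),
         init_cycb = unname(config$init["cycb"]),
         init_cyce = unname(config$init["cyce"]),
         init_mass = unname(config$init["mass"])))
}
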