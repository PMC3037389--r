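# Run manifests and deterministic fixtures -- the reproducibility
# plumbing around the simulator.

#' Write a run manifest
#'
#' Every CLI run emits exactly one manifest: a JSON snapshot of all
#' resolved parameter values (flat config keys), the seed, the package
#' version, the command line, and MD5 checksums of the output files.
#' Re-running with the manifest's config and seed reproduces the
#' outputs bit for bit.
#'
#' @param path Manifest destination (JSON).
#' @param config The resolved `hybrid_config` of the run.
#' @param seed The master seed (or `NULL` for deterministic runs).
#' @param command Character description of the invocation.
#' @param outputs Character vector of output file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed = NULL,
                               command = "", outputs = character()) {
  man <- list(
    package = "hybridcycle",
    version = as.character(utils::packageVersion("hybridcycle")),
    command = command,
    seed = if (is.null(seed)) NA else seed,
    config = .hc_flatten_config(config),
    outputs = if (length(outputs))
      as.list(tools::md5sum(outputs)) else list()
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Deterministic golden-trajectory fixture
#'
#' One cell cycle simulated under [deterministic_config()] (all
#' stochastic waits zero, symmetric division, no threshold or
#' instrument noise) from the configured progenitor.  The result is
#' identical across runs and seeds and serves as a regression anchor.
#'
#' @param config Base configuration; its deterministic variant is
#'   used.
#' @return A `cell_cycle` object.
#' @export
fixture_history <- function(config = model_config()) {
  simulate_cycle(deterministic_config(config))
}

#' @export
print.cell_cycle <- function(x, ...) {
  cat("<cell_cycle> born t0 =", format(x$t0), "h, mass", format(x$m0), "\n")
  cat("  cycle length a9 =", format(x$a9), "h; mass at division",
      format(x$m_div), "\n")
  cat("  state exit ages (h):",
      paste(signif(x$a_exit, 4), collapse = ", "), "\n")
  invisible(x)
}
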