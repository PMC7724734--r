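#' Pipeline defaults
#'
#' The built-in settings every stage falls back to: the length filter
#' (500 ungapped sites), 1000 bootstrap replicates, strain thresholds
#' 0.97 / 0.90, the 400-site supergroup classifiability floor, 999
#' SPS null replicates, 5000 ParaFit permutations, the event cost
#' scheme (0, 1, 2, 1, 1), 50 random tip-mapping iterations, a
#' 100-generation / 300-candidate heuristic search, and the 60%
#' sex-balance rule. The ClustalW gap penalties (15 / 6.66) are
#' recorded for provenance only -- alignment is an upstream step, not
#' performed here.
#'
#' @return Named list of defaults.
#' @export
symbio_defaults <- function() {
  list(
    min_length = 500,
    min_classifiable_length = 400,
    bootstrap_reps = 1000,
    primary_threshold = 0.97,
    secondary_threshold = 0.90,
    sps_replicates = 999,
    sps_null = "uniform",
    parafit_permutations = 5000,
    parafit_distance = "patristic",
    cost_cospeciation = 0,
    cost_duplication = 1,
    cost_host_shift = 2,
    cost_loss = 1,
    cost_failure_to_diverge = 1,
    tip_mapping_iterations = 50,
    generations = 100,
    population = 300,
    balance_ratio = 0.6,
    mcnemar = "exact",
    adjust = "none",
    clustalw_gap_penalty = 15,
    clustalw_gap_extension = 6.66
  )
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values that parse as numbers are numeric. Keys override
#' the [symbio_defaults()].
#'
#' @param path config file, or `NULL` for the defaults.
#' @return Named list of settings.
#' @export
read_config <- function(path = NULL) {
  cfg <- symbio_defaults()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) {
      sym_stop("symbio_bad_config", paste("cannot parse config line:", ln))
    }
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}
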