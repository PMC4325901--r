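## configuration defaults: the benchmark realization constants
.config_defaults <- function() {
  list(environment = "moderate", D = NULL, delta_sep = 1, step = 0.1,
       n_iter = 10000L, grid_lo = -10, grid_hi = 10, grid_step = 0.1,
       schedule_mode = "fixed", schedule_path = NULL, theta = 0,
       variant = "selection_weighted", orientation = "confidence",
       sigma_dir = "toward_trained", prior_alpha = 1, prior_beta = 1,
       seed = NULL, output_dir = ".")
}

#' Load (and validate) a run configuration
#'
#' Reads a flat key-value YAML file and fills every omitted field with the
#' benchmark defaults (10,000 iterations, thresholds -10 to 10 in steps of
#' 0.1, step size 0.1, uniform priors). Unknown keys and out-of-range
#' values are rejected with field-level messages.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated named list of class `nf_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
      cfg[names(user)] <- user
    }
  }
  .validate_config(cfg)
}

.validate_config <- function(cfg) {
  if (cfg$n_iter < 1) stop("config field 'n_iter' must be >= 1")
  if (cfg$grid_step <= 0) stop("config field 'grid_step' must be > 0")
  if (cfg$grid_lo > cfg$grid_hi)
    stop("config field 'grid_lo' must be <= 'grid_hi'")
  if (cfg$step <= 0) stop("config field 'step' must be > 0")
  if (cfg$prior_alpha <= 0 || cfg$prior_beta <= 0)
    stop("config fields 'prior_alpha'/'prior_beta' must be > 0")
  if (!cfg$variant %in% .variants)
    stop("config field 'variant' must be one of: ",
         paste(.variants, collapse = ", "))
  if (!cfg$orientation %in% .orientations)
    stop("config field 'orientation' must be one of: ",
         paste(.orientations, collapse = ", "))
  if (!cfg$sigma_dir %in% .sigma_dirs)
    stop("config field 'sigma_dir' must be one of: ",
         paste(.sigma_dirs, collapse = ", "))
  if (!cfg$schedule_mode %in% c("fixed", "adaptive_entropy",
                                "adaptive_efficiency", "custom"))
    stop("config field 'schedule_mode' is invalid")
  if (is.null(cfg$D)) {
    cfg$env <- standard_environment(cfg$environment)
  } else {
    cfg$env <- nf_env(cfg$D, cfg$delta_sep, cfg$step, name = cfg$environment)
  }
  structure(cfg, class = c("nf_config", "list"))
}

#' Save a run configuration
#'
#' @param config an `nf_config` (or plain named list of config fields).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  keep <- intersect(names(.config_defaults()), names(config))
  vals <- config[keep]
  yaml::write_yaml(vals[!vapply(vals, is.null, logical(1L))], path)
  invisible(path)
}

## full-precision numeric formatting for CSV round-trips
.fmt17 <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

.write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- .fmt17(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.sidecar <- function(paths, meta = NULL, extra = list()) {
  info <- list(
    package = "nfadapt",
    version = as.character(utils::packageVersion("nfadapt")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  if (!is.null(meta)) {
    env <- meta$env
    info$run <- list(environment = env$name, D = env$D,
                     delta_sep = env$delta_sep, step = env$step,
                     n_iter = meta$n_iter, variant = meta$variant,
                     orientation = meta$orientation,
                     sigma_dir = meta$sigma_dir,
                     schedule_mode = meta$schedule_mode, seed = meta$seed)
  }
  c(info, extra)
}

#' Write a simulation trace to CSV (with JSON sidecar)
#'
#' One row per iteration with the fixed column order of the trace
#' contract; numbers are serialized with 17 significant digits so that
#' [read_trace()] round-trips to full double precision. A JSON sidecar
#' (`<path>.json`) records the run configuration, package version and an
#' MD5 checksum of the CSV.
#'
#' @param trace an `nf_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nf_trace"))
  .write_csv17(as.data.frame(trace), path)
  jsonlite::write_json(.sidecar(list(path), attr(trace, "meta")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a simulation trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return A data.frame with the trace columns (metadata, if present, is
#'   re-attached from the sidecar as attribute `sidecar`).
#' @export
read_trace <- function(path) {
  out <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(out, "sidecar") <- jsonlite::read_json(side)
  class(out) <- c("nf_trace", "data.frame")
  out
}

#' Write sweep results to CSV
#'
#' Emits a long-format table (`theta`, `iteration`, `entropy_bits`,
#' `efficiency`) and a derived-vectors table (`iteration`,
#' `theta_entropy`, `theta_ie`), plus a JSON sidecar covering both files.
#'
#' @param sweep an `nf_sweep`.
#' @param path output path for the long table; the derived vectors go to
#'   `<path-root>_vectors.csv`.
#' @return Character vector of the two CSV paths, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "nf_sweep"))
  K <- length(sweep$grid)
  long <- data.frame(
    theta = rep(sweep$grid, each = sweep$n_iter),
    iteration = rep(seq_len(sweep$n_iter), K),
    entropy_bits = as.vector(sweep$H),
    efficiency = as.vector(sweep$IE))
  .write_csv17(long, path)
  vec_path <- paste0(sub("\\.csv$", "", path), "_vectors.csv")
  .write_csv17(data.frame(iteration = seq_len(sweep$n_iter),
                          theta_entropy = sweep$theta_entropy,
                          theta_ie = sweep$theta_ie), vec_path)
  jsonlite::write_json(.sidecar(list(path, vec_path), sweep$meta,
                                list(grid = list(lo = min(sweep$grid),
                                                 hi = max(sweep$grid),
                                                 n = K))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(path, vec_path))
}

#' Write a trace comparison to CSV
#'
#' @param comparison an `nf_compare` from [compare_traces()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "nf_compare"))
  .write_csv17(as.data.frame(comparison), path)
  jsonlite::write_json(
    .sidecar(list(path), NULL,
             list(final_crossover = attr(comparison, "final_crossover"),
                  crossings = attr(comparison, "crossings"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a Monte-Carlo ensemble summary to CSV
#'
#' @param ensemble an `nf_ensemble` from [monte_carlo()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "nf_ensemble"))
  .write_csv17(as.data.frame(ensemble), path)
  jsonlite::write_json(.sidecar(list(path), attr(ensemble, "meta"),
                                list(n_runs = attr(ensemble, "n_runs"))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
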