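CONFIG_KEYS <- c("mode", "target_g", "eccentricity", "duration", "dt",
                 "max_rate", "rpm", "radius", "frame_rate", "platter_radius",
                 "seed", "trace_csv", "density_csv", "report_json")

CONFIG_DEFAULTS <- list(
  duration = 3600, dt = 0.1, max_rate = 60, frame_rate = 60,
  platter_radius = 0.20, seed = 1
)

#' Load and validate a run configuration
#'
#' Merges a flat YAML configuration file with override values (CLI flags
#' take precedence over file values, which take precedence over defaults)
#' and validates the result for the requested mode. For `sw` mode exactly
#' one of `target_g` / `eccentricity` must be given; the other is resolved
#' via the quadrature maps and echoed back.
#'
#' @param path Path to a YAML file with a flat key set, or `NULL`.
#' @param overrides Named list of values overriding the file (e.g. parsed
#'   CLI flags).
#' @return A validated `run_config` list with defaults applied and, for sw
#'   mode, both `target_g` and `eccentricity` resolved.
#' @examples
#' load_config(overrides = list(mode = "sw", target_g = 0.38))
#' @export
load_config <- function(path = NULL, overrides = list()) {
  file_cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    file_cfg <- yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
  }
  unknown <- setdiff(union(names(file_cfg), names(overrides)), CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, file_cfg)
  cfg <- utils::modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])

  if (is.null(cfg$mode) || !cfg$mode %in% c("sw", "hw", "classic", "two_state")) {
    stop('config requires `mode`, one of "sw", "hw", "classic", "two_state"',
         call. = FALSE)
  }
  if (cfg$duration <= 0 || cfg$dt <= 0) {
    stop("`duration` and `dt` must be positive", call. = FALSE)
  }

  derived <- NULL
  if (cfg$mode == "sw") {
    has_g <- !is.null(cfg$target_g)
    has_e <- !is.null(cfg$eccentricity)
    if (has_g == has_e) {
      stop("sw mode requires exactly one of `target_g`, `eccentricity`",
           call. = FALSE)
    }
    if (has_g) {
      cfg$eccentricity <- eccentricity_for_mean_g(cfg$target_g)
      derived <- "eccentricity"
    } else {
      cfg$target_g <- mean_g_from_eccentricity(cfg$eccentricity)
      derived <- "target_g"
    }
  }
  if (cfg$mode == "hw") {
    if (is.null(cfg$target_g) || is.null(cfg$radius)) {
      stop("hw mode requires `target_g` and `radius` (metres)", call. = FALSE)
    }
    cfg$rpm <- cfg$rpm %||% solve_rpm(cfg$target_g, cfg$radius)
  }
  if (cfg$mode == "two_state" && is.null(cfg$target_g)) {
    stop("two_state mode requires `target_g`", call. = FALSE)
  }
  if (cfg$mode == "classic") {
    cfg$eccentricity <- 0
    cfg$target_g <- 0
  }
  structure(cfg, class = "run_config", derived = derived)
}

#' Serialise a run configuration back to YAML
#'
#' Fields that [load_config()] derived (e.g. the eccentricity resolved from
#' a target g) are dropped, so a dumped config reloads to an equivalent
#' configuration.
#'
#' @param cfg A `run_config`.
#' @param path Optional file path; `NULL` returns the YAML string.
#' @return The YAML text, invisibly if written to a file.
#' @export
dump_config <- function(cfg, path = NULL) {
  drop <- attr(cfg, "derived")
  cfg <- unclass(cfg)
  if (!is.null(drop)) cfg[[drop]] <- NULL
  txt <- yaml::as.yaml(cfg[order(names(cfg))])
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Write a structured JSON run report
#'
#' Reports carry a schema version, the resolved settings (including the
#' seed), and whatever result blocks the caller supplies (achieved mean g,
#' convergence error at the end of the run, density metrics, a settings
#' table). Identical inputs and seed reproduce the report bit-identically,
#' aside from the timestamp field.
#'
#' @param results Named list of result blocks (scalars, vectors, tibbles).
#' @param path Output path for the JSON file.
#' @param config Optional `run_config` (or plain list) echoed under
#'   `$config`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  report <- list(
    schema = "rpmsim-report/1",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config)) NULL else unclass(config),
    results = results
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}
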