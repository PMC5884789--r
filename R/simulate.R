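#' Run a full simulation from a configuration
#'
#' Dispatches on `config$mode`:
#' * `"sw"` — spheroid-based software partial gravity
#'   ([generate_sw_trajectory()]);
#' * `"classic"` — classic RPM randomisation (software driver with
#'   eccentricity 0, target 0 g);
#' * `"two_state"` — deterministic down/up baseline
#'   ([two_state_trajectory()]);
#' * `"hw"` — no trajectory: returns the centrifuge plan ([plan_hw()]).
#'
#' For trajectory modes the return value bundles the trace, the
#' convergence report against the target g-level, and density diagnostics
#' on the default 100-cell equal-area map.
#'
#' @param config A `run_config` from [load_config()].
#' @return An `rpm_simulation` list: `config`, `trace`, `convergence`,
#'   `density`, `metrics`, `summary` (one-row tibble); or for hw mode a
#'   list with `config` and `plan`.
#' @examples
#' cfg <- load_config(overrides = list(mode = "sw", target_g = 0.38,
#'                                     duration = 600, seed = 7))
#' sim <- run_simulation(cfg)
#' sim$summary
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must come from load_config()", call. = FALSE)
  if (config$mode == "hw") {
    return(structure(list(config = config,
                          plan = plan_hw(config$target_g, config$radius,
                                         frame_rate = config$frame_rate,
                                         platter_radius = config$platter_radius)),
                     class = "rpm_simulation"))
  }
  max_rate <- config$max_rate * pi / 180
  trace <- switch(config$mode,
    sw = ,
    classic = generate_sw_trajectory(spheroid_spec(config$eccentricity),
                                     duration = config$duration, dt = config$dt,
                                     max_rate = max_rate, seed = config$seed),
    two_state = two_state_trajectory(config$target_g, config$duration, config$dt)
  )
  conv <- convergence_report(trace, config$target_g)
  part <- equal_area_partition(10)
  dens <- residence_density(trace, part)
  metrics <- uniformity_metrics(dens)
  avg <- time_averaged_gravity(trace)
  summary <- tibble::tibble(
    mode = config$mode,
    target_g = config$target_g,
    eccentricity = config$eccentricity %||% NA_real_,
    achieved_g = avg$magnitude,
    final_error = conv$error[nrow(conv)],
    density_cv = metrics$cv,
    seed = config$seed
  )
  structure(list(config = config, trace = trace, convergence = conv,
                 density = dens, metrics = metrics, summary = summary),
            class = "rpm_simulation")
}

#' @export
print.rpm_simulation <- function(x, ...) {
  if (!is.null(x$plan)) {
    cat("<rpm_simulation> hardware plan\n")
    print(x$plan)
  } else {
    cat(sprintf("<rpm_simulation> mode %s, %d trace samples\n",
                x$config$mode, nrow(x$trace)))
    print(x$summary)
  }
  invisible(x)
}
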