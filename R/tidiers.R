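#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into its per-sample convergence table
#'
#' @param x An `rpm_simulation`.
#' @param ... Unused.
#' @return The convergence report tibble (`t`, `mean_g`, `error`), or the
#'   plan tibble for hardware-mode runs.
#' @method tidy rpm_simulation
#' @export
tidy.rpm_simulation <- function(x, ...) {
  if (!is.null(x$plan)) return(x$plan)
  tibble::as_tibble(x$convergence)
}

#' One-row summary of a simulation
#'
#' @param x An `rpm_simulation`.
#' @param ... Unused.
#' @return A one-row tibble with achieved mean g, final convergence error
#'   and density uniformity, or the plan row for hardware-mode runs.
#' @method glance rpm_simulation
#' @export
glance.rpm_simulation <- function(x, ...) {
  if (!is.null(x$plan)) return(x$plan)
  x$summary
}

#' @method tidy density_map
#' @export
tidy.density_map <- function(x, ...) tibble::as_tibble(x)

#' @method glance density_map
#' @export
glance.density_map <- function(x, ...) uniformity_metrics(x)
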