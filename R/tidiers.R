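# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a single replicate: the per-generation trajectory
#'
#' @param x A `deme_replicate` from [run_replicate()].
#' @param ... Unused.
#' @return A tibble with columns `generation`, `rho` (cooperator frequency,
#'   0 for an extinct population), `total_size`, `occupied_demes`.
#' @export
tidy.deme_replicate <- function(x, ...) {
  x$trajectory
}

#' One-row outcome summary of a replicate
#'
#' @param x A `deme_replicate`.
#' @param ... Unused.
#' @return A one-row tibble: `seed`, `outcome`, `final_rho`,
#'   `generations_run`.
#' @export
glance.deme_replicate <- function(x, ...) {
  tibble::tibble(seed = x$seed, outcome = x$outcome, final_rho = x$final_rho,
                 generations_run = x$generations_run)
}

#' Tidy an ensemble: one row per replicate
#'
#' @param x A `deme_ensemble` from [run_ensemble()].
#' @param ... Unused.
#' @return A tibble with columns `seed`, `outcome`, `final_rho`,
#'   `generations_run`.
#' @export
tidy.deme_ensemble <- function(x, ...) {
  x$outcomes
}

#' One-row ensemble summary
#'
#' @param x A `deme_ensemble`.
#' @param ... Unused.
#' @return The [summarize_outcomes()] row.
#' @export
glance.deme_ensemble <- function(x, ...) {
  x$summary
}

#' Tidy a phase diagram: one row per grid point
#'
#' @param x A `deme_phase` from [phase_diagram()].
#' @param ... Unused.
#' @return A tibble with `m`, `D`, `N0`, ensemble summaries and `regime`.
#' @export
tidy.deme_phase <- function(x, ...) {
  x$phase
}

#' One-row phase-diagram summary
#'
#' @param x A `deme_phase`.
#' @param ... Unused.
#' @return A one-row tibble: `D_c` (critical deme number), `n_points`,
#'   `eps_onset`, `eps_pure`.
#' @export
glance.deme_phase <- function(x, ...) {
  tibble::tibble(D_c = x$D_c, n_points = nrow(x$phase),
                 eps_onset = x$eps_onset, eps_pure = x$eps_pure)
}

#' Tidy a threshold sweep: one row per (E, m) point
#'
#' @param x A `deme_threshold` from [sweep_threshold()].
#' @param ... Unused.
#' @return The stacked sweep tibble with its `E` column.
#' @export
tidy.deme_threshold <- function(x, ...) {
  x$sweeps
}

#' Onset table of a threshold sweep
#'
#' @param x A `deme_threshold`.
#' @param ... Unused.
#' @return A tibble with one row per `E`: the onset migration rate `onset_m`.
#' @export
glance.deme_threshold <- function(x, ...) {
  x$onset
}
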