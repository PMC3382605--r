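# Ensemble layer: replicate batches -> fixation / coexistence probabilities
# and the conditional cooperation level.

#' Summarise replicate outcomes
#'
#' Reduces a table of replicate outcomes to the ensemble observables:
#' `p_coop`, the probability that cooperation persists (outcome `COOP_FIXED`
#' or `COEXISTENCE`); `p_coex`, the probability of coexistence; and
#' `mean_rho`, the mean cooperator frequency conditioned on persistence
#' (`COOP_FIXED` runs contribute exactly 1, `COEXISTENCE` runs their
#' stationary mean frequency).  `UNRESOLVED` runs are excluded from every
#' denominator and reported in `n_unresolved`.  Standard errors are binomial,
#' `sqrt(p (1 - p) / n)`.
#'
#' @param outcomes A data frame with columns `outcome` (one of `EXTINCT`,
#'   `COOP_FIXED`, `COEXISTENCE`, `UNRESOLVED`) and `final_rho`.
#' @return A one-row tibble with columns `n_runs`, `n_resolved`,
#'   `n_unresolved`, `p_coop`, `p_coop_se`, `p_coex`, `p_coex_se`,
#'   `mean_rho`.
#' @examples
#' summarize_outcomes(tibble::tibble(
#'   outcome = c("EXTINCT", "COOP_FIXED", "COEXISTENCE"),
#'   final_rho = c(0, 1, 0.6)))
#' @export
summarize_outcomes <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("outcome", "final_rho") %in% names(outcomes)))
  bad <- setdiff(unique(outcomes$outcome), OUTCOME_LEVELS)
  if (length(bad) > 0) stop("unknown outcome label(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  n_runs <- nrow(outcomes)
  resolved <- outcomes[outcomes$outcome != "UNRESOLVED", , drop = FALSE]
  n_res <- nrow(resolved)
  if (n_res == 0) stop("no resolved runs to summarise", call. = FALSE)
  persisting <- resolved$outcome %in% c("COOP_FIXED", "COEXISTENCE")
  coex <- resolved$outcome == "COEXISTENCE"
  p_coop <- mean(persisting)
  p_coex <- mean(coex)
  mean_rho <- if (any(persisting)) {
    mean(ifelse(resolved$outcome[persisting] == "COOP_FIXED", 1,
                resolved$final_rho[persisting]))
  } else NA_real_
  tibble::tibble(n_runs = n_runs, n_resolved = n_res,
                 n_unresolved = n_runs - n_res,
                 p_coop = p_coop,
                 p_coop_se = sqrt(p_coop * (1 - p_coop) / n_res),
                 p_coex = p_coex,
                 p_coex_se = sqrt(p_coex * (1 - p_coex) / n_res),
                 mean_rho = mean_rho)
}

#' Run an ensemble of independent replicates
#'
#' Runs `n_runs` replicates with seeds `base_seed, base_seed + 1, ...,
#' base_seed + n_runs - 1` (each replicate is a single seeded RNG stream:
#' network generation, founding population and dynamics) and summarises the
#' outcome frequencies with [summarize_outcomes()].  A warning is emitted if
#' more than 1% of runs hit the generation horizon unresolved.
#'
#' @param params A [deme_params()] object.
#' @param n_runs Number of replicates.
#' @param base_seed First replicate seed.
#' @param engine `"cpp"` or `"r"` (see [run_replicate()]).
#' @return An object of class `deme_ensemble`: a list with `outcomes` (tibble,
#'   one row per replicate), `summary` (one-row tibble) and `params`.
#' @examples
#' p <- deme_params(N = 40, D = 4, m = 0, max_generations = 400,
#'                  stationarity_window = 50)
#' glance(run_ensemble(p, n_runs = 5, base_seed = 1))
#' @export
run_ensemble <- function(params, n_runs = 100, base_seed = 1,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(n_runs >= 1)
  params <- validate_params(params)
  outcomes <- purrr::map_dfr(seq_len(n_runs) - 1L, function(r) {
    rep <- run_replicate(params, seed = base_seed + r, engine = engine)
    tibble::tibble(seed = rep$seed, outcome = rep$outcome,
                   final_rho = rep$final_rho,
                   generations_run = rep$generations_run)
  })
  summary <- summarize_outcomes(outcomes)
  if (summary$n_unresolved > 0.01 * n_runs) {
    warning(summary$n_unresolved, " of ", n_runs,
            " runs hit the generation horizon unresolved", call. = FALSE)
  }
  structure(list(outcomes = outcomes, summary = summary, params = params),
            class = "deme_ensemble")
}

#' @export
print.deme_ensemble <- function(x, ...) {
  s <- x$summary
  cat("<deme_ensemble>", s$n_runs, "runs | p_coop",
      format(round(s$p_coop, 3)), "| p_coex", format(round(s$p_coex, 3)),
      "| mean rho given persistence", format(round(s$mean_rho, 3)), "\n")
  invisible(x)
}

# one-row parameter fingerprint prepended to sweep tables
params_row <- function(params) {
  tibble::tibble(N = params$N, D = params$D, N0 = params$N0,
                 E = params$E, topology = params$topology$kind)
}

#' Sweep the migration rate
#'
#' Runs one replicate ensemble per migration rate in `m_grid` (disjoint seed
#' blocks) and stacks the summaries: the probability-of-fixation and
#' probability-of-coexistence curves as functions of the migration rate,
#' plus the conditional cooperation level.
#'
#' @param params A [deme_params()] object (its `m` is overridden).
#' @param m_grid Numeric vector of migration rates.
#' @param n_runs Replicates per grid point.
#' @param base_seed Seed of the first replicate of the first grid point;
#'   grid point `i` uses the block `base_seed + (i - 1) n_runs + (0 ... n_runs - 1)`.
#' @param engine `"cpp"` or `"r"`.
#' @return A tibble of class `deme_sweep`, one row per `m`, with the
#'   [summarize_outcomes()] columns plus `m` and parameter fingerprint
#'   columns.
#' @export
sweep_migration <- function(params, m_grid, n_runs = 100, base_seed = 1,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(length(m_grid) >= 1, all(m_grid >= 0), all(m_grid <= 1))
  rows <- purrr::imap_dfr(as.numeric(m_grid), function(mi, i) {
    pi <- update_params(params, m = mi)
    ens <- run_ensemble(pi, n_runs = n_runs,
                        base_seed = base_seed + (i - 1L) * n_runs,
                        engine = engine)
    dplyr::bind_cols(tibble::tibble(m = mi), params_row(pi), ens$summary)
  })
  class(rows) <- c("deme_sweep", class(rows))
  rows
}
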