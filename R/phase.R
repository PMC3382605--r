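# Regime classification, phase diagram over (m, D), topology comparison and
# elimination-threshold sweeps.

REGIME_LEVELS <- c("EXTINCTION", "COOP_LIKELY", "PURE_COOP", "COEXISTENCE")

#' Classify the dynamical regime of an ensemble
#'
#' Maps ensemble probabilities to one of the four regimes of the phase
#' diagram, in decreasing precedence:
#'
#' * `EXTINCTION` — the fixation probability of cooperation is below the
#'   onset cutoff (`p_coop < eps_onset`);
#' * `COEXISTENCE` — coexistence itself clears the onset cutoff
#'   (`p_coex > eps_onset`); checked before the pure regime so that a band
#'   with certain persistence but frequent coexistence is labelled
#'   coexistence;
#' * `PURE_COOP` — fixation is essentially certain (`p_coop >= 1 - eps_pure`)
#'   with negligible coexistence;
#' * `COOP_LIKELY` — cooperation fixates with a probability that is
#'   non-negligible but short of certainty.
#'
#' The cutoffs must be resolvable by the ensemble size: the function errors
#' when `n_resolved < 1 / eps_onset`.
#'
#' @param summary A data frame with columns `p_coop`, `p_coex`, `n_resolved`
#'   (one or more rows, e.g. a [sweep_migration()] table).
#' @param eps_onset Onset cutoff: the smallest fixation probability counted
#'   as "cooperation is likely".
#' @param eps_pure Tolerance to certainty for the pure-cooperation regime.
#' @return The input as a tibble with a `regime` factor column appended.
#' @examples
#' classify_regime(tibble::tibble(p_coop = c(0, 1, 0.4),
#'                                p_coex = c(0, 0, 0),
#'                                n_resolved = 100))
#' @export
classify_regime <- function(summary, eps_onset = 0.01, eps_pure = 0.02) {
  stopifnot(is.data.frame(summary),
            all(c("p_coop", "p_coex", "n_resolved") %in% names(summary)))
  if (any(summary$n_resolved < 1 / eps_onset)) {
    stop("insufficient runs to resolve eps_onset = ", eps_onset,
         ": need at least ", ceiling(1 / eps_onset), " resolved runs",
         call. = FALSE)
  }
  regime <- dplyr::case_when(
    summary$p_coop < eps_onset ~ "EXTINCTION",
    summary$p_coex > eps_onset ~ "COEXISTENCE",
    summary$p_coop >= 1 - eps_pure ~ "PURE_COOP",
    TRUE ~ "COOP_LIKELY")
  out <- tibble::as_tibble(summary)
  out$regime <- factor(regime, levels = REGIME_LEVELS)
  out
}

#' Phase diagram in the (migration rate, number of demes) plane
#'
#' For every combination of `m` in `m_grid` and `D` in `D_grid`, runs a
#' replicate ensemble — holding the total population `N` fixed, so the deme
#' capacity is `N0 = N / D` at each point — and classifies its regime with
#' [classify_regime()].  Also reports the critical deme number `D_c`: the
#' smallest `D` whose regime at the smallest simulated migration rate is not
#' `EXTINCTION`, i.e. the level of structuring above which cooperation has a
#' non-negligible chance even at minimal migration.
#'
#' @param params A [deme_params()] object supplying `N` and everything not on
#'   the grid.
#' @param m_grid Migration rates (sorted internally).
#' @param D_grid Deme counts; values not dividing `N` are skipped with a
#'   warning.
#' @param n_runs Replicates per grid point.
#' @param base_seed Seed origin; grid points use disjoint seed blocks.
#' @param eps_onset,eps_pure Regime cutoffs, see [classify_regime()].
#' @param engine `"cpp"` or `"r"`.
#' @return An object of class `deme_phase`: a list with `phase` (tibble with
#'   one row per grid point: `m`, `D`, `N0`, ensemble summary columns and
#'   `regime`), `D_c` (integer or `NA` if no scanned `D` escapes extinction at
#'   minimal `m`), `eps_onset`, `eps_pure`, and `params`.
#' @export
phase_diagram <- function(params, m_grid, D_grid, n_runs = 100, base_seed = 1,
                          eps_onset = 0.01, eps_pure = 0.02,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  m_grid <- sort(as.numeric(m_grid))
  D_grid <- sort(as.integer(D_grid))
  ok <- params$N %% D_grid == 0L
  if (any(!ok)) {
    warning("skipping D not dividing N = ", params$N, ": ",
            paste(D_grid[!ok], collapse = ", "), call. = FALSE)
    D_grid <- D_grid[ok]
  }
  grid <- tidyr::expand_grid(D = D_grid, m = m_grid)
  rows <- purrr::pmap_dfr(
    list(grid$D, grid$m, seq_len(nrow(grid))),
    function(Di, mi, i) {
      pi <- update_params(params, D = Di, m = mi)
      ens <- run_ensemble(pi, n_runs = n_runs,
                          base_seed = base_seed + (i - 1L) * n_runs,
                          engine = engine)
      dplyr::bind_cols(tibble::tibble(m = mi, D = Di, N0 = pi$N0),
                       ens$summary)
    })
  phase <- classify_regime(rows, eps_onset = eps_onset, eps_pure = eps_pure)
  at_min_m <- phase[phase$m == min(m_grid), , drop = FALSE]
  escaped <- at_min_m$D[at_min_m$regime != "EXTINCTION"]
  D_c <- if (length(escaped) > 0) min(escaped) else NA_integer_
  structure(list(phase = phase, D_c = D_c,
                 eps_onset = eps_onset, eps_pure = eps_pure,
                 params = params),
            class = "deme_phase")
}

#' @export
print.deme_phase <- function(x, ...) {
  cat("<deme_phase>", nrow(x$phase), "grid points | D_c =",
      if (is.na(x$D_c)) "not found" else x$D_c, "\n")
  print(dplyr::count(x$phase, .data$regime))
  invisible(x)
}

#' Compare migration topologies at matched mean degree
#'
#' Runs a migration sweep ([sweep_migration()]) once per topology, all at the
#' mean degree of `params$topology`, and stacks the results.  The fixation
#' and coexistence probability curves are expected to be nearly
#' indistinguishable across topologies, while in the coexistence range the
#' sustained cooperation level orders with network heterogeneity:
#' scale-free >= random graph >= island model.
#'
#' @param params A [deme_params()] object (`mean_degree` taken from its
#'   topology).
#' @param topologies Character vector among `"er"`, `"island"`, `"ba"`.
#' @param m_grid Migration rates.
#' @param n_runs Replicates per (topology, m) point.
#' @param base_seed Seed origin; topologies use disjoint seed blocks.
#' @param engine `"cpp"` or `"r"`.
#' @return A tibble of class `deme_topology`, the [sweep_migration()] columns
#'   plus `topology`.
#' @export
compare_topologies <- function(params, topologies = c("er", "island", "ba"),
                               m_grid, n_runs = 100, base_seed = 1,
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  z <- params$topology$mean_degree
  block <- length(m_grid) * n_runs
  rows <- purrr::imap_dfr(topologies, function(kind, i) {
    pi <- update_params(params, topology = topology_spec(kind, mean_degree = z))
    sw <- sweep_migration(pi, m_grid, n_runs = n_runs,
                          base_seed = base_seed + (i - 1L) * block,
                          engine = engine)
    sw$topology <- kind
    sw
  })
  class(rows) <- c("deme_topology", setdiff(class(rows), "deme_sweep"))
  rows
}

#' Sweep the elimination threshold
#'
#' Runs a migration sweep per elimination threshold `E` and locates, for each
#' `E`, the onset of cooperation: the smallest migration rate in the grid at
#' which the fixation probability reaches `eps_onset`.  Raising the threshold
#' is expected to shift the onset (and the coexistence window) towards larger
#' migration rates.
#'
#' @param params A [deme_params()] object.
#' @param E_values Elimination thresholds, each below the reward payoff.
#' @param m_grid Migration rates.
#' @param n_runs Replicates per (E, m) point.
#' @param base_seed Seed origin; disjoint blocks per grid point.
#' @param eps_onset Onset cutoff on `p_coop`.
#' @param engine `"cpp"` or `"r"`.
#' @return An object of class `deme_threshold`: list with `sweeps` (stacked
#'   sweep tibble with an `E` column) and `onset` (tibble `E`, `onset_m`;
#'   `onset_m` is `NA` when no grid point reaches the cutoff).
#' @export
sweep_threshold <- function(params, E_values, m_grid, n_runs = 100,
                            base_seed = 1, eps_onset = 0.01,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  m_grid <- sort(as.numeric(m_grid))
  block <- length(m_grid) * n_runs
  sweeps <- purrr::imap_dfr(as.numeric(E_values), function(Ei, i) {
    pi <- update_params(params, E = Ei)
    sw <- sweep_migration(pi, m_grid, n_runs = n_runs,
                          base_seed = base_seed + (i - 1L) * block,
                          engine = engine)
    sw
  })
  onset <- sweeps |>
    dplyr::group_by(.data$E) |>
    dplyr::summarise(onset_m = {
      hit <- .data$m[.data$p_coop >= eps_onset]
      if (length(hit) > 0) min(hit) else NA_real_
    }, .groups = "drop")
  structure(list(sweeps = sweeps, onset = onset, eps_onset = eps_onset,
                 params = params),
            class = "deme_threshold")
}

#' @export
print.deme_threshold <- function(x, ...) {
  cat("<deme_threshold>", length(unique(x$sweeps$E)), "threshold value(s)\n")
  print(x$onset)
  invisible(x)
}
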