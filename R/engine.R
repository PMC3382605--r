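# Replicate engine: life cycle orchestration, absorbing-state and
# stationarity detection, outcome classification.  run_replicate() uses the
# C++ engine by default; engine = "r" runs the literal stage-by-stage R
# transcription (same random-draw contract, identical trajectories).

OUTCOME_LEVELS <- c("EXTINCT", "COOP_FIXED", "COEXISTENCE", "UNRESOLVED")

#' One full generation of the life cycle
#'
#' Applies the three stages in the model's fixed order — prisoner's dilemma
#' game ([play_generation()]), migration ([migrate()]), selection
#' ([select_generation()]) — and advances the generation counter.
#'
#' @param state A `deme_state`.
#' @param params A [deme_params()] object.
#' @param net A `migration_network` on `params$D` demes.
#' @return The next `deme_state`.
#' @export
step_generation <- function(state, params, net) {
  state <- play_generation(state, params)
  state <- migrate(state, net, params$m)
  state <- select_generation(state, params)
  state$generation <- state$generation + 1L
  state
}

#' Absorbing-state check
#'
#' The dynamics has two absorbing states: total extinction and the
#' all-cooperator state (no evolutionary rule reintroduces a lost strategy).
#' An all-defector state is flagged but not terminal — whether it persists or
#' heads to extinction is left to the dynamics (it depends on whether the
#' punishment payoff clears the elimination threshold).
#'
#' @param state A `deme_state`.
#' @return `"EXTINCT"`, `"COOP_FIXED"`, `"ALL_D"`, or `NA_character_` for a
#'   mixed state.
#' @export
is_absorbing <- function(state) {
  stopifnot_state(state)
  n <- length(state$strategy)
  if (n == 0L) return("EXTINCT")
  nc <- sum(state$strategy)
  if (nc == n) return("COOP_FIXED")
  if (nc == 0L) return("ALL_D")
  NA_character_
}

#' Stationarity test on a cooperator-frequency trajectory
#'
#' The run is declared stationary when the mean cooperator frequency over the
#' last `window` generations differs from the mean over the previous
#' `window` generations by at most `tol`.
#'
#' @param traj A data frame with a `rho` column (one row per generation), or
#'   a numeric vector of cooperator frequencies.
#' @param window Window length `W` in generations.
#' @param tol Tolerance on the difference of window means.
#' @return `TRUE`/`FALSE`.
#' @export
detect_stationary <- function(traj, window, tol) {
  rho <- if (is.data.frame(traj)) traj$rho else as.numeric(traj)
  n <- length(rho)
  if (n < 2 * window) {
    stop("trajectory too short for stationarity test: need >= 2*window = ",
         2 * window, " generations, have ", n, call. = FALSE)
  }
  m2 <- plain_mean(rho[(n - window + 1L):n])
  m1 <- plain_mean(rho[(n - 2L * window + 1L):(n - window)])
  abs(m2 - m1) <= tol
}

# Pure-R engine loop (reference path).  Starts from `state` with the RNG
# already positioned; returns list(state, trajectory, outcome, final_rho).
run_engine_r <- function(state, params, net, max_generations,
                         detect = TRUE) {
  window <- params$stationarity_window
  tol <- params$stationarity_tol
  gens <- integer(0)
  rhos <- numeric(0)
  totals <- integer(0)
  occs <- integer(0)
  outcome <- "UNRESOLVED"
  final_rho <- NA_real_
  for (g in seq_len(max_generations)) {
    state <- step_generation(state, params, net)
    cs <- state_census(state)
    gens <- c(gens, state$generation)
    rhos <- c(rhos, if (is.na(cs$rho)) 0 else cs$rho)
    totals <- c(totals, cs$total_size)
    occs <- c(occs, cs$occupied_demes)
    if (detect) {
      if (cs$total_size == 0L) {
        outcome <- "EXTINCT"
        final_rho <- 0
        break
      }
      if (cs$rho == 1) {
        outcome <- "COOP_FIXED"
        final_rho <- 1
        break
      }
      nrec <- length(rhos)
      if (cs$rho > 0 && cs$rho < 1 && nrec >= 2L * window) {
        m2 <- plain_mean(rhos[(nrec - window + 1L):nrec])
        m1 <- plain_mean(rhos[(nrec - 2L * window + 1L):(nrec - window)])
        if (abs(m2 - m1) <= tol) {
          outcome <- "COEXISTENCE"
          final_rho <- m2
          break
        }
      }
    }
  }
  list(state = state,
       trajectory = tibble::tibble(generation = gens, rho = rhos,
                                   total_size = totals, occupied_demes = occs),
       outcome = outcome, final_rho = final_rho)
}

# C++ engine wrapper, same contract as run_engine_r().
run_engine_cpp <- function(state, params, net, max_generations,
                           detect = TRUE) {
  po <- params$payoffs
  res <- cpp_run_engine(state$strategy, state$fitness, state$deme,
                        state$D, state$N0, net$neighbors,
                        params$m, params$E, params$w,
                        po$T, po$R, po$P, po$S,
                        params$unpaired_decay, params$init_fitness,
                        as.integer(max_generations),
                        params$stationarity_window, params$stationarity_tol,
                        detect, state$generation)
  out_state <- new_state(res$generation, state$D, state$N0,
                         res$strategy, res$fitness, res$deme)
  list(state = out_state,
       trajectory = tibble::tibble(generation = as.integer(res$traj_gen),
                                   rho = res$traj_rho,
                                   total_size = as.integer(res$traj_total),
                                   occupied_demes = as.integer(res$traj_occ)),
       outcome = OUTCOME_LEVELS[res$outcome],
       final_rho = res$final_rho)
}

#' Run a single simulation replicate
#'
#' Seeds the RNG, builds the migration network and the founding population,
#' and iterates the life cycle until one of: extinction (`EXTINCT`), fixation
#' of cooperation (`COOP_FIXED`, cooperator frequency exactly 1), a detected
#' stationary mixed state (`COEXISTENCE`, with `final_rho` the mean cooperator
#' frequency over the last stationarity window), or the generation horizon
#' (`UNRESOLVED`).
#'
#' @param params A [deme_params()] object.
#' @param seed Integer seed for this replicate (defaults to `params$seed`).
#' @param engine `"cpp"` (fast engine, default) or `"r"` (literal
#'   stage-by-stage reference).  Both consume the identical RNG stream and
#'   produce identical trajectories for the same seed.
#' @param network Optional `migration_network` to use instead of generating
#'   one from `params$topology` (it is then excluded from the seeded stream).
#' @return An object of class `deme_replicate`: a list with `trajectory`
#'   (tibble of per-generation `generation`, `rho`, `total_size`,
#'   `occupied_demes`), `outcome`, `final_rho`, `generations_run`, `seed`,
#'   `network`, `state` (final state) and `params`.  See [tidy.deme_replicate()]
#'   and [glance.deme_replicate()].
#' @examples
#' p <- deme_params(N = 40, D = 4, m = 0.1, max_generations = 500,
#'                  stationarity_window = 50)
#' r <- run_replicate(p, seed = 1)
#' glance(r)
#' @export
run_replicate <- function(params, seed = params$seed,
                          engine = c("cpp", "r"), network = NULL) {
  engine <- match.arg(engine)
  params <- validate_params(params)
  set.seed(seed)
  net <- if (is.null(network)) generate_network(params$topology, params$D)
         else network
  if (net$D != params$D) stop("network has ", net$D, " nodes but D = ",
                              params$D, call. = FALSE)
  state <- init_population_state(params)
  runner <- if (engine == "cpp") run_engine_cpp else run_engine_r
  res <- runner(state, params, net, params$max_generations, detect = TRUE)
  structure(list(trajectory = res$trajectory,
                 outcome = res$outcome,
                 final_rho = res$final_rho,
                 generations_run = nrow(res$trajectory),
                 seed = as.integer(seed),
                 network = net,
                 state = res$state,
                 params = params),
            class = "deme_replicate")
}

#' Advance a replicate state by a fixed number of generations
#'
#' Runs exactly `n_steps` generations from a given state with no early
#' stopping — the workhorse for absorbing-state persistence checks and for
#' engine-equivalence comparisons.
#'
#' @param state A `deme_state`.
#' @param params A [deme_params()] object.
#' @param net A `migration_network`.
#' @param n_steps Number of generations to run.
#' @param engine `"cpp"` or `"r"`.
#' @return A list with `state` (final `deme_state`) and `trajectory` (tibble).
#' @export
step_generations <- function(state, params, net, n_steps,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  runner <- if (engine == "cpp") run_engine_cpp else run_engine_r
  res <- runner(state, params, net, n_steps, detect = FALSE)
  list(state = res$state, trajectory = res$trajectory)
}

#' @export
print.deme_replicate <- function(x, ...) {
  cat("<deme_replicate> seed", x$seed, "|", x$outcome, "after",
      x$generations_run, "generations | final rho",
      format(round(x$final_rho, 4)), "\n")
  invisible(x)
}
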