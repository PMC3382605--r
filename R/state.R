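# Population state: a flat roster of individuals kept sorted by deme, with
# within-deme position equal to roster order.  Strategy is integer coded
# (1 = cooperate, 0 = defect).  The roster ordering is part of the model's
# random-draw contract: pairing permutes roster positions, migrants are
# appended to their destination roster in processing order, daughters are
# appended at the end of their deme.

new_state <- function(generation, D, N0, strategy, fitness, deme) {
  structure(list(generation = as.integer(generation),
                 D = as.integer(D), N0 = as.integer(N0),
                 strategy = as.integer(strategy),
                 fitness = as.numeric(fitness),
                 deme = as.integer(deme)),
            class = "deme_state")
}

# Founders only; assumes the RNG is already positioned (one uniform per
# individual, canonical order).
init_population_state <- function(params) {
  n <- params$N
  strategy <- as.integer(stats::runif(n) < params$init_coop)
  new_state(0L, params$D, params$N0,
            strategy,
            rep(params$init_fitness, n),
            rep(seq_len(params$D), each = params$N0))
}

#' Initialise a structured population
#'
#' Builds the founding population: `D` demes each filled to carrying capacity
#' `N0`, every founder an independent cooperator with probability
#' `init_coop`, and every founding fitness equal to `init_fitness` (default 0,
#' the empty-history value of the learning fitness).  The RNG is seeded from
#' `params$seed` unless `seed` is given, so the same seed reproduces the
#' state exactly.
#'
#' @param params A [deme_params()] object.
#' @param seed Optional integer overriding `params$seed`.
#' @return An object of class `deme_state`.
#' @examples
#' st <- initialize_population(deme_params(N = 40, D = 4, seed = 7))
#' dplyr::count(tibble::as_tibble(st), deme)
#' @export
initialize_population <- function(params, seed = params$seed) {
  params <- validate_params(params)
  set.seed(seed)
  init_population_state(params)
}

#' @export
print.deme_state <- function(x, ...) {
  cs <- state_census(x)
  cat("<deme_state> generation", x$generation,
      "|", cs$total_size, "individuals in", cs$occupied_demes, "of", x$D,
      "demes | cooperator frequency",
      if (cs$total_size > 0) format(round(cs$rho, 4)) else "NA", "\n")
  invisible(x)
}

#' Tidy view of a population state
#'
#' @param x A `deme_state`.
#' @param ... Unused.
#' @return A tibble with one row per individual: `deme`, `position` (roster
#'   position within the deme), `strategy` (`"C"`/`"D"`), `fitness`.
#' @export
as_tibble.deme_state <- function(x, ...) {
  pos <- stats::ave(seq_along(x$deme), x$deme, FUN = seq_along)
  tibble::tibble(deme = x$deme,
                 position = as.integer(pos),
                 strategy = strategy_label(x$strategy),
                 fitness = x$fitness)
}

# Census observables (rho is NA for an empty population).
state_census <- function(state) {
  total <- length(state$strategy)
  list(rho = if (total > 0) sum(state$strategy) / total else NA_real_,
       total_size = total,
       occupied_demes = length(unique(state$deme)))
}

state_sizes <- function(state) {
  tabulate(state$deme, nbins = state$D)
}

# Indices (into the flat roster) of the members of deme d, in roster order.
deme_members <- function(state, d) {
  which(state$deme == d)
}

stopifnot_state <- function(state) {
  stopifnot(inherits(state, "deme_state"))
}
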