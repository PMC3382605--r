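#' Random pairing within a deme
#'
#' Draws a uniform random perfect matching of the deme roster: positions are
#' permuted by a Fisher-Yates shuffle and adjacent entries are paired.  With
#' an odd roster exactly one individual is left unpaired and sits the round
#' out.
#'
#' @param deme A data frame with one row per individual (only its row count is
#'   used), or a single integer roster size.
#' @return A list with `pairs`, a tibble of roster positions (`a`, `b`), and
#'   `leftover`, the unpaired position (`NA` if none).
#' @examples
#' set.seed(1)
#' pair_deme(7)
#' @export
pair_deme <- function(deme) {
  n <- if (is.data.frame(deme)) nrow(deme) else as.integer(deme)
  stopifnot(length(n) == 1, n >= 0)
  if (n < 2) {
    return(list(pairs = tibble::tibble(a = integer(), b = integer()),
                leftover = if (n == 1) 1L else NA_integer_))
  }
  perm <- rng_perm(n)
  npair <- n %/% 2L
  idx <- seq_len(npair) * 2L
  list(pairs = tibble::tibble(a = perm[idx - 1L], b = perm[idx]),
       leftover = if (n %% 2L == 1L) perm[n] else NA_integer_)
}

#' Learning fitness update
#'
#' The generation-accumulated fitness blends the previous fitness with the
#' current round payoff: `f' = (1 - w) f + w G`.  Iterating under a constant
#' payoff `G` converges geometrically to `G`, so fitness is bounded by the
#' largest payoff `T`; with the default `w = 1/2` the iterates from
#' `f0 = 0` are exactly `G (1 - 2^-n)`.
#'
#' @param f_prev Previous fitness (vectorised).
#' @param G Current round payoff (vectorised).
#' @param w Memory weight in `(0, 1]`.
#' @return The updated fitness, a convex combination of `f_prev` and `G`.
#' @examples
#' update_fitness(0, 1, 0.5)
#' @export
update_fitness <- function(f_prev, G, w = 0.5) {
  stopifnot(w > 0, w <= 1)
  (1 - w) * f_prev + w * G
}

#' Game stage of the life cycle
#'
#' In every deme, individuals are randomly paired ([pair_deme()]) and each
#' pair plays one round of the prisoner's dilemma; each paired individual's
#' fitness is updated with its round payoff via [update_fitness()].  An
#' unpaired individual keeps its fitness unchanged (or decays toward 0 when
#' `params$unpaired_decay` is set).  Strategies and deme sizes never change
#' at this stage.
#'
#' @param state A `deme_state`.
#' @param params A [deme_params()] object.
#' @return The updated `deme_state`.
#' @export
play_generation <- function(state, params) {
  stopifnot_state(state)
  po <- params$payoffs
  fitness <- state$fitness
  strategy <- state$strategy
  for (d in seq_len(state$D)) {
    mem <- deme_members(state, d)
    n <- length(mem)
    if (n == 0L) next
    mt <- pair_deme(n)
    if (nrow(mt$pairs) > 0L) {
      ia <- mem[mt$pairs$a]
      ib <- mem[mt$pairs$b]
      ga <- payoff_of(strategy[ia], strategy[ib], po)
      gb <- payoff_of(strategy[ib], strategy[ia], po)
      fitness[ia] <- update_fitness(fitness[ia], ga, params$w)
      fitness[ib] <- update_fitness(fitness[ib], gb, params$w)
    }
    if (!is.na(mt$leftover) && params$unpaired_decay) {
      il <- mem[mt$leftover]
      fitness[il] <- update_fitness(fitness[il], 0, params$w)
    }
  }
  state$fitness <- fitness
  state
}
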