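# Local selection: threshold elimination, then restoration of the carrying
# capacity by least-fit culling (oversized demes) or fitness-proportional
# expansion (undersized, non-empty demes).

# --- draw-consuming kernels shared by the R engine and the tibble API ------

# Indices (original order) surviving repeated least-fit removal down to
# `capacity`.  Ties at the minimum are broken uniformly at random (one draw
# per tie event; no draw when the minimum is unique).
cull_keep_indices <- function(fitness, capacity) {
  n <- length(fitness)
  alive <- rep(TRUE, n)
  for (r in seq_len(n - capacity)) {
    minval <- Inf
    for (i in seq_len(n)) {
      if (alive[i] && fitness[i] < minval) minval <- fitness[i]
    }
    cand <- which(alive & fitness == minval)
    pick <- if (length(cand) > 1L) cand[rng_index(length(cand))] else cand
    alive[pick] <- FALSE
  }
  which(alive)
}

# Parent index (into the survivor roster) for each of `births` daughters,
# drawn with replacement proportionally to fitness (negative weights clamped
# to 0; all-zero weights fall back to a uniform draw).
expand_parent_indices <- function(fitness, births) {
  vapply(seq_len(births), function(b) rng_roulette(fitness), integer(1))
}

# --- tibble API -------------------------------------------------------------

#' Threshold elimination within a deme
#'
#' Removes every individual whose fitness lies strictly below the elimination
#' threshold `E`; an individual with fitness exactly `E` survives.  Survivor
#' order is preserved.
#'
#' @param deme A data frame with a `fitness` column (one row per individual).
#' @param E Elimination threshold.
#' @return The surviving rows as a tibble.
#' @examples
#' eliminate_below_threshold(tibble::tibble(fitness = c(0.5, 0.3, 0.4)), E = 0.4)
#' @export
eliminate_below_threshold <- function(deme, E) {
  stopifnot(is.data.frame(deme), "fitness" %in% names(deme))
  tibble::as_tibble(deme[deme$fitness >= E, , drop = FALSE])
}

#' Cull an oversized deme back to capacity
#'
#' Repeatedly removes a least-fit individual (ties at the minimum broken
#' uniformly at random) until the deme is back at its carrying capacity.
#' Only migration can push a deme above capacity.
#'
#' @param deme A data frame with a `fitness` column, more than `capacity` rows.
#' @param capacity Carrying capacity `N0`.
#' @return A tibble with exactly `capacity` rows, original order preserved.
#' @export
cull_to_capacity <- function(deme, capacity) {
  stopifnot(is.data.frame(deme), "fitness" %in% names(deme))
  if (nrow(deme) <= capacity) {
    stop("cull_to_capacity() requires deme size > capacity", call. = FALSE)
  }
  keep <- cull_keep_indices(deme$fitness, capacity)
  tibble::as_tibble(deme[keep, , drop = FALSE])
}

#' Expand an undersized deme back to capacity
#'
#' Local expansion: parents are drawn with replacement from the surviving
#' members with probability proportional to fitness, and each daughter
#' inherits its parent's strategy but not its fitness (newborn fitness 0).
#' Parents are drawn from the pre-expansion survivors only.  An empty deme is
#' never expanded: recolonisation happens only through migration.
#'
#' @param deme A data frame with `strategy` and `fitness` columns,
#'   between 1 and `capacity - 1` rows.
#' @param capacity Carrying capacity `N0`.
#' @param newborn_fitness Fitness assigned to daughters (default 0).
#' @return A tibble with exactly `capacity` rows: the survivors followed by
#'   the daughters in birth order.
#' @export
expand_to_capacity <- function(deme, capacity, newborn_fitness = 0) {
  stopifnot(is.data.frame(deme), all(c("strategy", "fitness") %in% names(deme)))
  n <- nrow(deme)
  if (n == 0L) {
    stop("expand_to_capacity() cannot expand an empty deme: ",
         "recolonisation happens only through migration", call. = FALSE)
  }
  if (n >= capacity) {
    stop("expand_to_capacity() requires 0 < deme size < capacity", call. = FALSE)
  }
  parents <- expand_parent_indices(deme$fitness, capacity - n)
  daughters <- tibble::as_tibble(deme[parents, , drop = FALSE])
  daughters$fitness <- newborn_fitness
  dplyr::bind_rows(tibble::as_tibble(deme), daughters)
}

#' Selection stage of the life cycle
#'
#' Applies local selection independently in every deme: first threshold
#' elimination ([eliminate_below_threshold()]), then — depending on the
#' surviving size — least-fit culling down to `N0` ([cull_to_capacity()]),
#' fitness-proportional expansion up to `N0` ([expand_to_capacity()]),
#' nothing when the size is exactly `N0`, or nothing when the deme is empty.
#' After this stage every deme has size `N0` or 0.
#'
#' @param state A post-migration `deme_state`.
#' @param params A [deme_params()] object.
#' @return The post-selection `deme_state`.
#' @export
select_generation <- function(state, params) {
  stopifnot_state(state)
  N0 <- state$N0
  E <- params$E
  nb <- params$init_fitness
  out_strategy <- vector("list", state$D)
  out_fitness <- vector("list", state$D)
  out_deme <- vector("list", state$D)
  for (d in seq_len(state$D)) {
    mem <- deme_members(state, d)
    fit <- state$fitness[mem]
    str <- state$strategy[mem]
    keep <- fit >= E
    fit <- fit[keep]
    str <- str[keep]
    n <- length(fit)
    if (n > N0) {
      kept <- cull_keep_indices(fit, N0)
      fit <- fit[kept]
      str <- str[kept]
    } else if (n > 0L && n < N0) {
      parents <- expand_parent_indices(fit, N0 - n)
      str <- c(str, str[parents])
      fit <- c(fit, rep(nb, N0 - n))
    }
    out_strategy[[d]] <- str
    out_fitness[[d]] <- fit
    out_deme[[d]] <- rep(d, length(str))
  }
  new_state(state$generation, state$D, N0,
            unlist(out_strategy), unlist(out_fitness), unlist(out_deme))
}
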