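#' Migration-topology specification
#'
#' Chooses the deme-level migration graph: an Erdos-Renyi random graph
#' (`"er"`, Poisson degree distribution with mean `mean_degree`), the island
#' model (`"island"`, complete graph, zero degree variance), a scale-free
#' preferential-attachment graph (`"ba"`, power-law degrees, attachment count
#' `round(mean_degree / 2)` so mean degree matches the other topologies), or a
#' user-supplied edge list (`"user"`).
#'
#' @param kind One of `"er"`, `"island"`, `"ba"`, `"user"`.
#' @param mean_degree Target mean degree `z` (ignored for `"island"` and
#'   `"user"`).
#' @param edge_list For `kind = "user"`: either a path to a whitespace
#'   edge-list file (one `u v` pair per line, 0-based node ids) or a two-column
#'   matrix of 1-based deme ids.
#'
#' @return An object of class `topology_spec`.
#' @examples
#' topology_spec("er", mean_degree = 4)
#' topology_spec("island")
#' @export
topology_spec <- function(kind = c("er", "island", "ba", "user"),
                          mean_degree = 4, edge_list = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("er", "ba")) {
    if (!is.numeric(mean_degree) || length(mean_degree) != 1 || mean_degree <= 0) {
      stop("mean_degree must be a positive number", call. = FALSE)
    }
  }
  if (kind == "user" && is.null(edge_list)) {
    stop("topology \"user\" requires an edge_list", call. = FALSE)
  }
  structure(list(kind = kind, mean_degree = mean_degree, edge_list = edge_list),
            class = "topology_spec")
}

#' @export
print.topology_spec <- function(x, ...) {
  cat("<topology_spec> kind =", x$kind,
      if (x$kind %in% c("er", "ba")) paste0("(mean degree ", x$mean_degree, ")"),
      "\n")
  invisible(x)
}

#' Model parameters for the structured-population simulation
#'
#' Collects and validates every parameter of the life cycle.  `N` individuals
#' are split over `D` demes of carrying capacity `N0 = N / D`; each generation
#' consists of a prisoner's dilemma game stage within demes, migration along
#' the deme network with per-individual rate `m`, and local selection
#' (elimination below fitness threshold `E`, then restoration of `N0` by
#' culling or fitness-proportional expansion).
#'
#' @param N Total initial population size; must be divisible by `D`.
#' @param D Number of demes.
#' @param m Per-individual, per-generation migration probability, in `[0, 1]`.
#' @param E Elimination threshold (payoff units); must satisfy `E < R`, else
#'   even a pure cooperator deme would be wiped out.
#' @param payoffs A [payoff_matrix()].
#' @param w Fitness memory weight in `(0, 1]`: the fitness update is
#'   `f' = (1 - w) f + w G` where `G` is the round payoff.  The default
#'   `w = 1/2` averages past fitness and current payoff, giving a learning
#'   fitness bounded by the largest payoff `T`.
#' @param topology A [topology_spec()] for the migration network.
#' @param init_coop Initial cooperator probability: each founder is a
#'   cooperator independently with this probability.
#' @param init_fitness Fitness assigned to founders and to every newborn.
#' @param unpaired_decay If `TRUE`, the odd individual left without a partner
#'   updates its fitness with payoff 0; if `FALSE` (default) it keeps its
#'   fitness unchanged that generation.
#' @param max_generations Hard horizon for a replicate.
#' @param stationarity_window Window length `W` (generations) for stationarity
#'   detection: the run is declared stationary when the mean cooperator
#'   frequency over the last `W` generations differs from the mean over the
#'   previous `W` by at most `stationarity_tol`.
#' @param stationarity_tol Stationarity tolerance on the cooperator frequency.
#' @param seed Default RNG seed used by [initialize_population()] and
#'   [run_replicate()] when no seed is given explicitly.
#'
#' @return A validated object of class `deme_params` with the derived carrying
#'   capacity `N0` filled in.
#'
#' @examples
#' p <- deme_params(N = 400, D = 20, m = 0.1)
#' p$N0
#' @export
deme_params <- function(N = 400, D = 20, m = 0.1, E = 0.4,
                        payoffs = payoff_matrix(),
                        w = 0.5,
                        topology = topology_spec("er", mean_degree = 4),
                        init_coop = 0.5,
                        init_fitness = 0,
                        unpaired_decay = FALSE,
                        max_generations = 5000,
                        stationarity_window = 200,
                        stationarity_tol = 0.01,
                        seed = 1L) {
  params <- structure(
    list(N = as.integer(N), D = as.integer(D), N0 = NA_integer_,
         m = m, E = E, payoffs = payoffs, w = w, topology = topology,
         init_coop = init_coop, init_fitness = init_fitness,
         unpaired_decay = isTRUE(unpaired_decay),
         max_generations = as.integer(max_generations),
         stationarity_window = as.integer(stationarity_window),
         stationarity_tol = stationarity_tol,
         seed = as.integer(seed)),
    class = "deme_params")
  validate_params(params)
}

#' Validate model parameters
#'
#' Checks every invariant of a parameter set and fills in the carrying
#' capacity `N0 = N / D`.  Called by [deme_params()]; exported so externally
#' assembled parameter lists can be checked too.
#'
#' @param params An object of class `deme_params` (or a compatible list).
#' @return The validated `deme_params` object with `N0` computed.
#' @export
validate_params <- function(params) {
  with(params, {
    if (!is.numeric(N) || N < 1) stop("N must be a positive integer", call. = FALSE)
    if (!is.numeric(D) || D < 1) stop("D must be a positive integer", call. = FALSE)
    if (N %% D != 0) {
      stop("N (", N, ") must be divisible by the number of demes D (", D, ")",
           call. = FALSE)
    }
    if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0 || m > 1) {
      stop("migration rate m must lie in [0, 1]", call. = FALSE)
    }
    if (!inherits(payoffs, "payoff_matrix")) {
      payoff_matrix(payoffs$T, payoffs$R, payoffs$P, payoffs$S)  # revalidate
    }
    if (!is.numeric(E) || !is.finite(E)) stop("E must be finite", call. = FALSE)
    if (E >= payoffs$R) {
      stop("elimination threshold E (", E, ") must be below the reward R (",
           payoffs$R, "): otherwise even pure cooperation is eliminated",
           call. = FALSE)
    }
    if (!is.numeric(w) || w <= 0 || w > 1) {
      stop("fitness memory weight w must lie in (0, 1]", call. = FALSE)
    }
    if (!inherits(topology, "topology_spec")) {
      stop("topology must be a topology_spec()", call. = FALSE)
    }
    if (topology$kind == "er" && topology$mean_degree >= D) {
      stop("ER mean degree z (", topology$mean_degree,
           ") must be smaller than D (", D, ")", call. = FALSE)
    }
    if (!is.numeric(init_coop) || init_coop < 0 || init_coop > 1) {
      stop("init_coop must lie in [0, 1]", call. = FALSE)
    }
    if (max_generations < 1) stop("max_generations must be >= 1", call. = FALSE)
    if (stationarity_window < 1) stop("stationarity_window must be >= 1", call. = FALSE)
    if (stationarity_tol < 0) stop("stationarity_tol must be >= 0", call. = FALSE)
  })
  params$N0 <- params$N %/% params$D
  params
}

#' @export
print.deme_params <- function(x, ...) {
  cat("<deme_params>\n",
      " N =", x$N, " D =", x$D, " N0 =", x$N0, "\n",
      " m =", x$m, " E =", x$E, " w =", x$w, "\n",
      " payoffs: T =", x$payoffs$T, " R =", x$payoffs$R,
      " P =", x$payoffs$P, " S =", x$payoffs$S, "\n",
      " topology:", x$topology$kind,
      if (x$topology$kind %in% c("er", "ba")) paste0("(z = ", x$topology$mean_degree, ")"),
      "\n",
      " horizon =", x$max_generations,
      " window =", x$stationarity_window,
      " tol =", x$stationarity_tol, "\n")
  invisible(x)
}

# Replace selected fields of a deme_params and revalidate.
update_params <- function(params, ...) {
  changes <- list(...)
  for (nm in names(changes)) {
    if (!nm %in% names(params)) stop("unknown parameter: ", nm, call. = FALSE)
    params[[nm]] <- changes[[nm]]
  }
  params$N <- as.integer(params$N)
  params$D <- as.integer(params$D)
  validate_params(params)
}
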