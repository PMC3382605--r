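# Migration networks: undirected simple graphs on the D demes.  Generation
# goes through igraph; the object kept by the engines is a plain adjacency
# list (sorted neighbor ids) so both engines index neighbors identically.

new_migration_network <- function(D, edges, kind = "user") {
  edges <- normalize_edges(edges, D)
  neighbors <- vector("list", D)
  for (i in seq_len(D)) neighbors[[i]] <- integer()
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      u <- edges[k, 1]
      v <- edges[k, 2]
      neighbors[[u]] <- c(neighbors[[u]], v)
      neighbors[[v]] <- c(neighbors[[v]], u)
    }
    neighbors <- lapply(neighbors, sort)
  }
  structure(list(D = as.integer(D), edges = edges,
                 neighbors = neighbors,
                 degrees = vapply(neighbors, length, integer(1)),
                 kind = kind),
            class = "migration_network")
}

normalize_edges <- function(edges, D) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > D)) {
      stop("edge endpoint outside 1..D", call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loops are not allowed in a migration network", call. = FALSE)
    }
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("u", "v")
  edges
}

#' @export
print.migration_network <- function(x, ...) {
  cat("<migration_network>", x$kind, "|", x$D, "demes,", nrow(x$edges),
      "edges, mean degree", format(round(mean(x$degrees), 3)), "\n")
  invisible(x)
}

#' Degree table of a migration network
#'
#' @param x A `migration_network`.
#' @param ... Unused.
#' @return A tibble with columns `deme` and `degree`.
#' @export
as_tibble.migration_network <- function(x, ...) {
  tibble::tibble(deme = seq_len(x$D), degree = x$degrees)
}

#' Erdos-Renyi migration graph
#'
#' Each unordered pair of demes is linked independently with probability
#' `p = z / (D - 1)`, so the mean degree is `z` and the degree distribution is
#' Poisson in the large-`D` limit.  Isolated demes are kept as generated; set
#' `require_min_degree = TRUE` to resample until every deme has at least one
#' neighbour.
#'
#' @param D Number of demes.
#' @param z Target mean degree, `0 < z < D`.
#' @param require_min_degree Resample until min degree >= 1 (default off).
#' @return A `migration_network`.
#' @examples
#' set.seed(1)
#' generate_er(10, z = 3)
#' @export
generate_er <- function(D, z, require_min_degree = FALSE) {
  if (z <= 0 || z >= D) stop("need 0 < z < D for an ER graph", call. = FALSE)
  p <- z / (D - 1)
  repeat {
    g <- igraph::sample_gnp(D, p)
    net <- new_migration_network(D, igraph::as_edgelist(g, names = FALSE),
                                 kind = "er")
    if (!require_min_degree || all(net$degrees >= 1L)) return(net)
  }
}

#' Island-model migration graph
#'
#' Wright's island model: every deme neighbours every other deme, i.e. the
#' complete graph on `D` nodes.  Every degree equals `D - 1`; the degree
#' distribution has zero variance, making this the most homogeneous topology.
#'
#' @param D Number of demes, at least 2.
#' @return A `migration_network`.
#' @examples
#' generate_island(5)
#' @export
generate_island <- function(D) {
  if (D < 2) stop("island model needs D >= 2", call. = FALSE)
  g <- igraph::make_full_graph(D)
  new_migration_network(D, igraph::as_edgelist(g, names = FALSE), kind = "island")
}

#' Scale-free migration graph
#'
#' Barabasi-Albert preferential attachment with attachment count
#' `round(z / 2)`, started from a complete seed graph on `round(z / 2) + 1`
#' nodes so every deme ends with degree at least the attachment count.  The
#' mean degree is close to `z`, letting topologies be compared at matched mean
#' connectivity while the degree distribution is heavy-tailed (power law).
#'
#' @param D Number of demes.
#' @param z Target mean degree; `round(z / 2)` must be at least 1.
#' @return A `migration_network`.
#' @examples
#' set.seed(1)
#' generate_scale_free(50, z = 4)
#' @export
generate_scale_free <- function(D, z) {
  m_att <- as.integer(round(z / 2))
  if (m_att < 1) stop("scale-free attachment count round(z/2) must be >= 1",
                      call. = FALSE)
  if (D <= m_att + 1) stop("D too small for attachment count ", m_att,
                           call. = FALSE)
  seed_g <- igraph::make_full_graph(m_att + 1)
  g <- igraph::sample_pa(D, m = m_att, directed = FALSE,
                         start.graph = seed_g)
  new_migration_network(D, igraph::as_edgelist(g, names = FALSE), kind = "ba")
}

# Build the network named by a topology_spec (consumes RNG draws for the
# random kinds; none for island/user).
generate_network <- function(topology, D) {
  switch(topology$kind,
         er = generate_er(D, topology$mean_degree),
         island = generate_island(D),
         ba = generate_scale_free(D, topology$mean_degree),
         user = {
           el <- topology$edge_list
           if (is.character(el)) load_network(el, D = D)
           else new_migration_network(D, el, kind = "user")
         },
         stop("unknown topology kind: ", topology$kind, call. = FALSE))
}

#' Read / write an edge-list network file
#'
#' The file format is one whitespace-separated `u v` pair per line with
#' 0-based node ids.  `export_network()` followed by `load_network()` is the
#' identity on the edge set.
#'
#' @param path File path.
#' @param D Number of demes; defaults to the largest node id + 1.
#' @return `load_network()` returns a `migration_network`;
#'   `export_network()` invisibly returns `path`.
#' @export
load_network <- function(path, D = NULL) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("u", "v"),
                           colClasses = "integer")
  if (any(is.na(tab))) stop("malformed edge-list line in ", path, call. = FALSE)
  edges0 <- as.matrix(tab)
  if (any(edges0 < 0L)) stop("negative node id in ", path, call. = FALSE)
  if (is.null(D)) D <- max(edges0) + 1L
  if (any(edges0 >= D)) stop("node id >= D in ", path, call. = FALSE)
  new_migration_network(D, edges0 + 1L, kind = "user")
}

#' @rdname load_network
#' @param net A `migration_network`.
#' @export
export_network <- function(net, path) {
  stopifnot(inherits(net, "migration_network"))
  utils::write.table(net$edges - 1L, path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Migration stage of the life cycle
#'
#' Each individual independently migrates with probability `m`; a migrant
#' moves to a uniformly chosen neighbour of its current deme on the migration
#' network, carrying its strategy and fitness unchanged.  Individuals in
#' isolated (degree-0) demes never move.  Empty demes are legal destinations,
#' which is how an extinct deme gets recolonised.  After migration deme sizes
#' need not equal the carrying capacity; the individual multiset is conserved
#' exactly.
#'
#' Draw order (part of the engine contract): one uniform per individual in
#' roster order for the migration decision, then one uniform per migrant in
#' roster order for the destination.  Each deme's new roster is its stayers in
#' the old order followed by its immigrants in processing order.
#'
#' @param state A `deme_state`.
#' @param net A `migration_network` with `net$D == state$D`.
#' @param m Migration probability in `[0, 1]`.
#' @return The post-migration `deme_state`.
#' @export
migrate <- function(state, net, m) {
  stopifnot_state(state)
  stopifnot(inherits(net, "migration_network"), net$D == state$D)
  if (m < 0 || m > 1) stop("migration rate m must lie in [0, 1]", call. = FALSE)
  n <- length(state$deme)
  if (n == 0L || m == 0) return(state)
  u <- stats::runif(n)
  wants <- u < m
  new_deme <- state$deme
  moved <- logical(n)
  for (i in seq_len(n)) {
    if (!wants[i]) next
    d <- state$deme[i]
    k <- net$degrees[d]
    if (k == 0L) next
    j <- rng_index(k)
    new_deme[i] <- net$neighbors[[d]][j]
    moved[i] <- TRUE
  }
  # stayers keep their relative order; migrants append in processing order
  ord <- order(new_deme, moved, seq_len(n), method = "radix")
  state$deme <- new_deme[ord]
  state$strategy <- state$strategy[ord]
  state$fitness <- state$fitness[ord]
  state
}
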