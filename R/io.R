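# Configuration files, deterministic test fixtures, result serialization.

CONFIG_PARAM_KEYS <- c("N", "D", "m", "E", "w", "T", "R", "P", "S",
                       "topology", "mean_degree", "network_file",
                       "init_coop", "init_fitness", "unpaired_decay",
                       "max_generations", "stationarity_window",
                       "stationarity_tol", "seed")
CONFIG_RUN_KEYS <- c("n_runs", "out_dir")
CONFIG_SCHEMA_VERSION <- 1L

#' Load a simulation configuration
#'
#' Reads a YAML or JSON configuration (flat keys mirroring the
#' [deme_params()] arguments, with the payoffs as `T`, `R`, `P`, `S` and the
#' topology as `topology` / `mean_degree` / `network_file`), applies any
#' overrides on top (overrides win, mirroring CLI-flag precedence), and
#' validates the result.  Unknown keys are rejected by name.  Run settings
#' `n_runs` and `out_dir` are passed through separately.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for an
#'   empty base configuration.
#' @param overrides Named list of keys overriding the file.
#' @return A list with `params` (a validated [deme_params()]) and `settings`
#'   (list with `n_runs`, `out_dir`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    cfg <- switch(ext,
                  yaml = ,
                  yml = yaml::read_yaml(path),
                  json = jsonlite::read_json(path, simplifyVector = TRUE),
                  stop("unsupported config format: .", ext, call. = FALSE))
    if (is.null(cfg)) cfg <- list()
    # YAML 1.1 reads the bare keys N and T as booleans; map them back (the
    # only schema keys hitting this: quote them in the file to be explicit)
    names(cfg)[names(cfg) == "FALSE"] <- "N"
    names(cfg)[names(cfg) == "TRUE"] <- "T"
  }
  known <- c(CONFIG_PARAM_KEYS, CONFIG_RUN_KEYS, "schema_version")
  for (src in list(cfg, overrides)) {
    unknown <- setdiff(names(src), known)
    if (length(unknown) > 0) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$schema_version) &&
      cfg$schema_version != CONFIG_SCHEMA_VERSION) {
    stop("unsupported schema_version: ", cfg$schema_version, call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  args <- list()
  for (k in setdiff(CONFIG_PARAM_KEYS,
                    c("T", "R", "P", "S", "topology", "mean_degree",
                      "network_file"))) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  po_defaults <- payoff_matrix()
  po_args <- lapply(stats::setNames(nm = c("T", "R", "P", "S")), function(k) {
    if (!is.null(cfg[[k]])) cfg[[k]] else po_defaults[[k]]
  })
  args$payoffs <- do.call(payoff_matrix, po_args)
  topo_kind <- if (!is.null(cfg$topology)) cfg$topology else "er"
  args$topology <- topology_spec(
    topo_kind,
    mean_degree = if (!is.null(cfg$mean_degree)) cfg$mean_degree else 4,
    edge_list = cfg$network_file)
  params <- do.call(deme_params, args)
  list(params = params,
       settings = list(
         n_runs = if (!is.null(cfg$n_runs)) as.integer(cfg$n_runs) else 100L,
         out_dir = if (!is.null(cfg$out_dir)) cfg$out_dir else "."))
}

#' Deterministic population fixtures
#'
#' Small hand-specified population states used across the test suite and in
#' examples.  No randomness is involved: re-building a fixture always gives
#' the identical state.
#'
#' * `ALL_C` / `ALL_D` — every deme full of cooperators / defectors;
#' * `HALF_HALF` — the first half of every deme roster cooperates, the rest
#'   defects;
#' * `ONE_EMPTY_DEME` — deme 2 empty, all other demes full of cooperators
#'   (recolonisation through migration is possible);
#' * `SINGLE_DEFECTOR` — one defector at the first roster position of deme 1,
#'   cooperators everywhere else.
#'
#' @param kind One of the fixture names above.
#' @param D Number of demes.
#' @param N0 Carrying capacity per deme.
#' @param fitness Fitness assigned to every individual (default 0).
#' @return A `deme_state` at generation 0.
#' @examples
#' make_fixture("ONE_EMPTY_DEME", D = 3, N0 = 4)
#' @export
make_fixture <- function(kind = c("ALL_C", "ALL_D", "HALF_HALF",
                                  "ONE_EMPTY_DEME", "SINGLE_DEFECTOR"),
                         D = 3, N0 = 4, fitness = 0) {
  kind <- match.arg(kind)
  deme <- rep(seq_len(D), each = N0)
  n <- D * N0
  strategy <- switch(kind,
    ALL_C = rep(1L, n),
    ALL_D = rep(0L, n),
    HALF_HALF = rep(rep(c(1L, 0L), times = c(ceiling(N0 / 2), floor(N0 / 2))),
                    D),
    ONE_EMPTY_DEME = rep(1L, n),
    SINGLE_DEFECTOR = c(0L, rep(1L, n - 1L)))
  if (kind == "ONE_EMPTY_DEME") {
    if (D < 2) stop("ONE_EMPTY_DEME needs D >= 2", call. = FALSE)
    keep <- deme != 2L
    strategy <- strategy[keep]
    deme <- deme[keep]
    n <- sum(keep)
  }
  new_state(0L, D, N0, strategy, rep(fitness, n), deme)
}

#' Write ensemble result files
#'
#' Serialises analysis tables as tidy TSVs plus a JSON run manifest holding
#' the full parameter set, so that any experiment can be re-run from its
#' output directory alone.  Output is byte-reproducible: identical
#' parameters and seeds give identical files.
#'
#' @param tables A named list; recognised names are `ensemble` (a sweep /
#'   topology / threshold tibble, written to `ensemble.tsv`) and `phase`
#'   (a phase tibble or `deme_phase` object, written to `phase.tsv`).
#' @param out_dir Output directory, created if needed.
#' @param params A [deme_params()] recorded in the manifest.
#' @param base_seed,n_runs Seeding information recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(tables, out_dir, params = NULL, base_seed = NULL,
                          n_runs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  write_tsv_plain <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  if (!is.null(tables$ensemble)) {
    paths <- c(paths, write_tsv_plain(tables$ensemble,
                                      file.path(out_dir, "ensemble.tsv")))
  }
  if (!is.null(tables$phase)) {
    ph <- tables$phase
    if (inherits(ph, "deme_phase")) ph <- ph$phase
    paths <- c(paths, write_tsv_plain(ph, file.path(out_dir, "phase.tsv")))
  }
  manifest <- list(
    package = "demesim",
    version = as.character(utils::packageVersion("demesim")),
    schema_version = CONFIG_SCHEMA_VERSION,
    base_seed = base_seed,
    n_runs = n_runs,
    params = if (!is.null(params)) params_manifest(params))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, mf)
  invisible(paths)
}

params_manifest <- function(params) {
  list(N = params$N, D = params$D, N0 = params$N0, m = params$m,
       E = params$E, w = params$w,
       T = params$payoffs$T, R = params$payoffs$R,
       P = params$payoffs$P, S = params$payoffs$S,
       topology = params$topology$kind,
       mean_degree = params$topology$mean_degree,
       network_file = params$topology$edge_list,
       init_coop = params$init_coop, init_fitness = params$init_fitness,
       unpaired_decay = params$unpaired_decay,
       max_generations = params$max_generations,
       stationarity_window = params$stationarity_window,
       stationarity_tol = params$stationarity_tol,
       seed = params$seed)
}

#' Write replicate trajectories
#'
#' One tidy TSV per replicate (`trajectory_<seed>.tsv`) with columns
#' `generation`, `rho`, `total_size`, `occupied_demes`.
#'
#' @param replicates A list of `deme_replicate` objects.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_trajectories <- function(replicates, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(replicates, function(r) {
    p <- file.path(out_dir, paste0("trajectory_", r$seed, ".tsv"))
    utils::write.table(as.data.frame(r$trajectory), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
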