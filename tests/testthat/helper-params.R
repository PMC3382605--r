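# Shared helpers: small parameter sets and state utilities.

small_params <- function(...) {
  defaults <- list(N = 30, D = 5, m = 0.2, E = 0.4,
                   topology = topology_spec("island"),
                   max_generations = 200, stationarity_window = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(deme_params, args)
}

# multiset fingerprint of a state: (strategy, fitness) pairs irrespective of
# deme and order
state_multiset <- function(state) {
  sort(paste(state$strategy, sprintf("%.17g", state$fitness)))
}

deme_sizes <- function(state) {
  tabulate(state$deme, nbins = state$D)
}

# run one life-cycle stage sequence manually on a state (game, migrate,
# select), returning the state after each stage
staged_step <- function(state, params, net) {
  s1 <- play_generation(state, params)
  s2 <- migrate(s1, net, params$m)
  s3 <- select_generation(s2, params)
  list(game = s1, migrated = s2, selected = s3)
}
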