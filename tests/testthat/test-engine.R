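test_that("a generation applies game, migration, selection in order", {
  p <- small_params(m = 0.3)
  net <- generate_island(p$D)
  st <- initialize_population(p, seed = 21)
  # manual staging equals step_generation under the same draws
  set.seed(100)
  manual <- staged_step(st, p, net)$selected
  manual$generation <- manual$generation + 1L
  set.seed(100)
  stepped <- step_generation(st, p, net)
  expect_identical(stepped, manual)
  expect_identical(stepped$generation, st$generation + 1L)
})

test_that("all-cooperator dynamics without migration only relax fitness", {
  p <- small_params(m = 0)
  net <- generate_island(p$D)
  st <- make_fixture("ALL_C", D = p$D, N0 = p$N0, fitness = 0.6)
  set.seed(1)
  out <- step_generations(st, p, net, 30, engine = "r")$state
  expect_true(all(out$strategy == 1L))
  expect_identical(deme_sizes(out), rep(p$N0, p$D))
  # fitness relaxes toward R
  expect_true(all(abs(out$fitness - p$payoffs$R) < 1e-6))
})

test_that("an all-defector population is driven extinct under defaults", {
  p <- small_params(m = 0.2)
  net <- generate_island(p$D)
  # warmed-up defectors: fitness decays toward P < E, extinction within a
  # bounded horizon (f_k = P + (f0 - P) 2^-k < E once 2^-k < (E-P)/(f0-P))
  st <- make_fixture("ALL_D", D = p$D, N0 = p$N0, fitness = p$payoffs$T)
  set.seed(2)
  res <- step_generations(st, p, net, 10, engine = "cpp")
  expect_identical(res$trajectory$total_size[10], 0L)
})

test_that("is_absorbing labels empty, all-C and all-D states", {
  empty <- demesim:::new_state(0L, 2L, 3L, integer(0), numeric(0), integer(0))
  expect_identical(is_absorbing(empty), "EXTINCT")
  expect_identical(is_absorbing(make_fixture("ALL_C")), "COOP_FIXED")
  expect_identical(is_absorbing(make_fixture("ALL_D")), "ALL_D")
  expect_identical(is_absorbing(make_fixture("SINGLE_DEFECTOR")), NA_character_)
})

test_that("detect_stationary compares consecutive window means", {
  expect_true(detect_stationary(rep(0.5, 40), window = 20, tol = 0))
  drift <- seq(0, 1, length.out = 100)
  expect_false(detect_stationary(drift, window = 50, tol = 0.01))
  expect_error(detect_stationary(rep(0.5, 10), window = 20, tol = 0.01),
               "too short")

  # i.i.d. noise around a fixed mean passes at tol = 4 sd(diff of means)
  set.seed(6)
  W <- 100; sigma <- 0.05
  hits <- vapply(1:200, function(i) {
    detect_stationary(rnorm(2 * W, 0.5, sigma), window = W,
                      tol = 4 * sigma * sqrt(2 / W))
  }, logical(1))
  # normal bound: |N(0, sd)| <= 4 sd with probability > 0.9999
  expect_gt(mean(hits), 0.98)
})

test_that("the trajectory is fully determined by (params, seed)", {
  p <- small_params(m = 0.4, max_generations = 80)
  a <- run_replicate(p, seed = 9)
  b <- run_replicate(p, seed = 9)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$outcome, b$outcome)
  expect_identical(tidy(a), a$trajectory)
  expect_identical(glance(a)$outcome, a$outcome)
  # generations strictly increasing
  expect_true(all(diff(a$trajectory$generation) == 1L))
})

test_that("optimized and reference engines produce identical trajectories", {
  # fixed-horizon comparison, no early stopping
  p <- deme_params(N = 30, D = 5, m = 0.25, seed = 1,
                   topology = topology_spec("er", mean_degree = 2.5))
  for (s in 1:20) {
    set.seed(s)
    net <- demesim:::generate_network(p$topology, p$D)
    st <- demesim:::init_population_state(p)
    rng_snapshot <- .Random.seed
    cpp <- step_generations(st, p, net, 50, engine = "cpp")
    .Random.seed <<- rng_snapshot
    ref <- step_generations(st, p, net, 50, engine = "r")
    expect_identical(cpp$trajectory, ref$trajectory)
    expect_identical(cpp$state, ref$state)
  }
  # and through the full replicate path with outcome detection
  for (s in c(1, 7, 13)) {
    a <- run_replicate(small_params(m = 0.6), seed = s, engine = "cpp")
    b <- run_replicate(small_params(m = 0.6), seed = s, engine = "r")
    expect_identical(a$trajectory, b$trajectory)
    expect_identical(a$outcome, b$outcome)
    expect_identical(a$final_rho, b$final_rho)
  }
})

test_that("absorbing states are terminal", {
  p <- small_params(m = 0.3)
  net <- generate_island(p$D)

  # cooperation fixed: no defector ever reappears
  allC <- make_fixture("ALL_C", D = p$D, N0 = p$N0, fitness = 0.9)
  set.seed(4)
  cont <- step_generations(allC, p, net, 1000, engine = "cpp")
  expect_true(all(cont$trajectory$rho == 1))
  expect_true(all(cont$state$strategy == 1L))

  # extinction is forever
  empty <- demesim:::new_state(0L, p$D, p$N0, integer(0), numeric(0), integer(0))
  set.seed(4)
  cont2 <- step_generations(empty, p, net, 1000, engine = "cpp")
  expect_true(all(cont2$trajectory$total_size == 0L))
})

test_that("replicates classify their outcome from the dynamics", {
  # m = 0, small independent demes: absorption only, never coexistence
  p0 <- deme_params(N = 40, D = 4, m = 0, topology = topology_spec("island"),
                    max_generations = 2000)
  outs <- vapply(1:30, function(s) run_replicate(p0, seed = s)$outcome,
                 character(1))
  expect_true(all(outs %in% c("EXTINCT", "COOP_FIXED")))

  # an immediately exhausted horizon leaves a mixed state unresolved
  pu <- small_params(max_generations = 1)
  r <- run_replicate(pu, seed = 17)
  expect_identical(r$outcome, "UNRESOLVED")
  expect_identical(r$generations_run, 1L)
})
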