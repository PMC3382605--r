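test_that("ER generation matches its edge probability limits", {
  set.seed(1)
  # p = 1 (z = D - 1): complete graph
  full <- generate_er(6, z = 5)
  expect_identical(nrow(full$edges), 15L)
  expect_identical(full$degrees, rep(5L, 6))
  # z -> 0: empty graph
  empty <- generate_er(50, z = 1e-9)
  expect_identical(nrow(empty$edges), 0L)
  expect_error(generate_er(10, z = 10), "z < D")
})

test_that("ER degrees follow Poisson(z) at large D", {
  set.seed(7)
  net <- generate_er(2000, z = 4)
  ks <- 0:12
  obs <- tabulate(factor(net$degrees, levels = ks), nbins = length(ks))
  keep <- net$degrees <= 12
  probs <- stats::dpois(ks, 4) / sum(stats::dpois(ks, 4))
  # tail bins are sparse (expected counts ~1); the approximation warning is
  # expected and the test is conservative there
  test <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(test$p.value, 0.01)
  # sample mean degree near z
  expect_lt(abs(mean(net$degrees) - 4), 4 * sqrt(4 / 2000))
})

test_that("island model is the complete graph with zero degree variance", {
  net <- generate_island(5)
  expect_identical(nrow(net$edges), 10L)
  expect_identical(net$degrees, rep(4L, 5))
  expect_identical(stats::var(net$degrees), 0)
  expect_identical(nrow(generate_island(2)$edges), 1L)
  expect_error(generate_island(1), "D >= 2")
})

test_that("scale-free graphs match mean degree but are heterogeneous", {
  set.seed(3)
  net <- generate_scale_free(1000, z = 4)
  md <- mean(net$degrees)
  expect_gte(md, 3.5)
  expect_lte(md, 4.0)
  expect_gte(min(net$degrees), 2L)  # attachment count round(z/2)

  vars_ba <- vars_er <- numeric(20)
  for (i in 1:20) {
    set.seed(100 + i)
    vars_ba[i] <- stats::var(generate_scale_free(300, 4)$degrees)
    set.seed(100 + i)
    vars_er[i] <- stats::var(generate_er(300, 4)$degrees)
  }
  expect_gt(mean(vars_ba), mean(vars_er))
})

test_that("edge-list files round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 2"), path)
  net <- load_network(path, D = 3)
  expect_identical(net$degrees, c(1L, 2L, 1L))

  writeLines(c("2 2"), path)
  expect_error(load_network(path, D = 3), "self-loop")
  writeLines(c("0 5"), path)
  expect_error(load_network(path, D = 3), ">= D")

  set.seed(8)
  er <- generate_er(40, z = 3)
  export_network(er, path)
  back <- load_network(path, D = 40)
  expect_identical(back$edges, er$edges)
  expect_identical(back$neighbors, er$neighbors)
})

test_that("migration conserves the individual multiset and respects m", {
  p <- small_params()
  net <- generate_island(p$D)
  st <- initialize_population(p, seed = 2)
  st <- play_generation(st, p)

  # m = 0: identity
  expect_identical(migrate(st, net, 0), st)
  expect_error(migrate(st, net, 1.5), "m must lie")

  # multiset conservation at several rates
  for (m in c(0.1, 0.5, 1)) {
    set.seed(m * 100)
    out <- migrate(st, net, m)
    expect_identical(state_multiset(out), state_multiset(st))
    expect_identical(length(out$deme), length(st$deme))
  }
})

test_that("m = 1 on a two-deme graph forces a full swap", {
  k2 <- generate_island(2)
  st <- demesim:::new_state(0L, 2L, 10L, rep(1L, 10), rep(0.5, 10), rep(1L, 10))
  set.seed(4)
  out <- migrate(st, k2, 1)
  expect_identical(deme_sizes(out), c(0L, 10L))
})

test_that("individuals in isolated demes never move; empty demes receive", {
  # path graph 1-2, deme 3 isolated
  net <- demesim:::new_migration_network(3, rbind(c(1, 2)))
  st <- demesim:::new_state(0L, 3L, 4L,
                            rep(1L, 8), rep(0.5, 8),
                            rep(c(1L, 3L), each = 4))
  set.seed(9)
  out <- migrate(st, net, 1)
  sz <- deme_sizes(out)
  expect_identical(sz[3], 4L)           # isolated deme unchanged
  expect_identical(sz[1], 0L)           # everyone left deme 1
  expect_identical(sz[2], 4L)           # ... into the empty neighbour
})

test_that("migrant counts are binomial in N and m", {
  p <- deme_params(N = 2500, D = 50, m = 0.3, topology = topology_spec("island"))
  net <- generate_island(50)
  # tag each individual through its (unique) fitness value to count movers
  set.seed(11)
  total_moved <- 0
  st <- initialize_population(p, seed = 10)
  for (g in 1:200) {
    tagged <- st
    tagged$fitness <- seq_along(st$deme)  # unique tags survive migration
    out <- migrate(tagged, net, 0.3)
    before_deme <- st$deme[order(tagged$fitness)]
    after_deme <- out$deme[order(out$fitness)]
    total_moved <- total_moved + sum(before_deme != after_deme)
  }
  expect_lt(abs(total_moved / 200 - 0.3 * 2500),
            4 * sqrt(2500 * 0.3 * 0.7))
})

test_that("pure migration keeps long-run deme sizes at N0 on the island graph", {
  p <- deme_params(N = 250, D = 10, m = 1, topology = topology_spec("island"))
  net <- generate_island(10)
  st <- initialize_population(p, seed = 12)
  set.seed(12)
  sizes <- matrix(0L, nrow = 100, ncol = 10)
  for (g in 1:100) {
    st <- migrate(st, net, 1)
    sizes[g, ] <- deme_sizes(st)
  }
  # stationary uniform flow: mean size stays N0 = 25 within sampling noise
  expect_true(all(abs(colMeans(sizes) - 25) < 3))
  expect_identical(sum(sizes[100, ]), 250L)
})
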