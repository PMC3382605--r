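test_that("outcome summaries follow the hand-computed rules", {
  # fixed label multiset: p_coop = 2/3, p_coex = 1/3, conditional rho mean
  # counts fixation runs as exactly 1
  s <- summarize_outcomes(tibble::tibble(
    outcome = c("EXTINCT", "COOP_FIXED", "COEXISTENCE"),
    final_rho = c(0, 1, 0.6)))
  expect_equal(s$p_coop, 2 / 3)
  expect_equal(s$p_coex, 1 / 3)
  expect_equal(s$mean_rho, 0.8)
  expect_equal(s$p_coop_se, sqrt((2 / 3) * (1 / 3) / 3))

  # all fixed
  sf <- summarize_outcomes(tibble::tibble(outcome = rep("COOP_FIXED", 4),
                                          final_rho = rep(1, 4)))
  expect_equal(c(sf$p_coop, sf$p_coex, sf$mean_rho), c(1, 0, 1))

  # unresolved runs leave the denominators
  su <- summarize_outcomes(tibble::tibble(
    outcome = c("EXTINCT", "COOP_FIXED", "UNRESOLVED", "UNRESOLVED"),
    final_rho = c(0, 1, NA, NA)))
  expect_equal(su$n_resolved, 2L)
  expect_equal(su$p_coop, 0.5)

  # permutation invariance
  set.seed(1)
  tab <- tibble::tibble(outcome = sample(c("EXTINCT", "COOP_FIXED", "COEXISTENCE"),
                                         30, replace = TRUE),
                        final_rho = runif(30))
  expect_equal(summarize_outcomes(tab), summarize_outcomes(tab[sample(30), ]))

  expect_error(summarize_outcomes(tibble::tibble(outcome = "UNRESOLVED",
                                                 final_rho = NA)),
               "no resolved")
  expect_error(summarize_outcomes(tibble::tibble(outcome = "WON",
                                                 final_rho = 1)),
               "unknown outcome")
})

test_that("ensembles aggregate replicate outcomes reproducibly", {
  p <- small_params(m = 0.5, max_generations = 400)
  e <- run_ensemble(p, n_runs = 12, base_seed = 30)
  expect_identical(nrow(tidy(e)), 12L)
  expect_identical(tidy(e)$seed, 30:41)
  expect_equal(glance(e), summarize_outcomes(tidy(e)))
  # probabilities nested and bounded
  expect_lte(glance(e)$p_coex, glance(e)$p_coop)
  expect_gte(glance(e)$p_coex, 0)
  expect_lte(glance(e)$p_coop, 1)
  # reproducible
  e2 <- run_ensemble(p, n_runs = 12, base_seed = 30)
  expect_equal(tidy(e2), tidy(e))
})

test_that("migration sweeps return one summary row per rate", {
  p <- small_params(max_generations = 300)
  sw <- sweep_migration(p, m_grid = 0.1, n_runs = 8, base_seed = 2)
  expect_identical(nrow(sw), 1L)
  expect_s3_class(sw, "deme_sweep")

  sw3 <- sweep_migration(p, m_grid = c(0.1, 0.3, 0.8), n_runs = 8, base_seed = 2)
  expect_identical(nrow(sw3), 3L)
  expect_identical(sw3$m, c(0.1, 0.3, 0.8))
  # first grid point reuses the single-point seed block exactly
  expect_equal(sw3[1, setdiff(names(sw3), "m")], sw[1, setdiff(names(sw), "m")])
})

test_that("regime classification follows the decision table", {
  mk <- function(p_coop, p_coex, n = 1000) {
    tibble::tibble(p_coop = p_coop, p_coex = p_coex, n_resolved = n)
  }
  expect_identical(as.character(classify_regime(mk(0, 0))$regime), "EXTINCTION")
  expect_identical(as.character(classify_regime(mk(0.005, 0))$regime), "EXTINCTION")
  expect_identical(as.character(classify_regime(mk(1, 0))$regime), "PURE_COOP")
  expect_identical(as.character(classify_regime(mk(0.99, 0))$regime), "PURE_COOP")
  expect_identical(as.character(classify_regime(mk(0.4, 0))$regime), "COOP_LIKELY")
  expect_identical(as.character(classify_regime(mk(0.9, 0.5))$regime), "COEXISTENCE")
  # coexistence precedence over pure cooperation
  expect_identical(as.character(classify_regime(mk(1, 1))$regime), "COEXISTENCE")
  # vectorised over rows
  multi <- classify_regime(mk(c(0, 1, 0.4), c(0, 0, 0)))
  expect_identical(as.character(multi$regime),
                   c("EXTINCTION", "PURE_COOP", "COOP_LIKELY"))
  # cutoff must be resolvable by the ensemble size
  expect_error(classify_regime(mk(0.5, 0, n = 50)), "insufficient runs")
})

test_that("phase diagrams report D_c and skip non-divisor deme counts", {
  p <- deme_params(N = 40, D = 4, topology = topology_spec("island"),
                   max_generations = 600, stationarity_window = 50)
  expect_warning(
    pd <- phase_diagram(p, m_grid = c(0.01, 0.5), D_grid = c(2, 3, 8),
                        n_runs = 30, base_seed = 1, eps_onset = 1 / 30),
    "skipping D")
  expect_setequal(unique(tidy(pd)$D), c(2L, 8L))
  expect_identical(nrow(tidy(pd)), 4L)
  expect_true(all(tidy(pd)$N0 == 40 %/% tidy(pd)$D))
  gl <- glance(pd)
  expect_true(is.na(gl$D_c) || gl$D_c %in% c(2L, 8L))
})

test_that("threshold sweeps locate the onset migration rate", {
  # degenerate check through the public api: single E reduces to a sweep
  p <- small_params(max_generations = 300)
  th <- sweep_threshold(p, E_values = 0.3, m_grid = c(0.1, 0.5), n_runs = 8,
                        base_seed = 5, eps_onset = 0.125)
  sw <- sweep_migration(demesim:::update_params(p, E = 0.3), c(0.1, 0.5), n_runs = 8,
                        base_seed = 5)
  expect_equal(tidy(th)$p_coop, sw$p_coop)
  on <- glance(th)
  expect_identical(nrow(on), 1L)
  hit <- sw$m[sw$p_coop >= 0.125]
  expect_equal(on$onset_m, if (length(hit)) min(hit) else NA_real_)
})

test_that("autoplot methods return ggplot objects", {
  p <- small_params(m = 0.5, max_generations = 300)
  r <- run_replicate(p, seed = 3)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  sw <- sweep_migration(p, m_grid = c(0.2, 0.6), n_runs = 5, base_seed = 9)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})
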