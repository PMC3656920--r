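test_that("growth laws evaluate per their definitions", {
  gp <- growth_params("competition", g0 = 1, kappa = 1, alpha = 49)
  expect_equal(growth_rate("NP", 0, gp), 1)
  expect_equal(growth_rate("P", 0, gp), 0)   # cost at its admissible maximum
  expect_equal(growth_rate("NP", 1, gp), 50) # one unit of resource: 49-fold speed-up
  expect_equal(growth_rate(c("P", "NP"), c(0.5, 0.5), gp), c(24.5, 25.5))
  expect_error(growth_rate("NP", -0.1, gp), ">= 0")
  expect_error(growth_params("competition", kappa = 1.5), "kappa")

  # neutral variant forces zero cost and zero benefit
  gn <- growth_params("neutral", alpha = 7)
  expect_equal(gn$kappa, 0)
  expect_equal(gn$alpha, 0)
})

test_that("mutualism growth law is symmetric in the two types", {
  gp <- growth_params("mutualism", g0 = 1, kappa = 1, alpha = 10)
  expect_equal(growth_rate_mutualism("A", 0, gp), 0)
  expect_equal(growth_rate_mutualism("A", 0.3, gp),
               growth_rate_mutualism("B", 0.3, gp))
  # swapping types together with their complementary fields leaves rates fixed
  cA <- 0.4; cB <- 0.7
  expect_equal(growth_rate_mutualism("A", cB, gp),
               growth_rate_mutualism("B", cB, gp))
})

test_that("saturating growth law interpolates between its limits", {
  gp <- growth_params("competition_saturating", g0 = 1, kappa = 0.5, alpha = 8)
  cs <- c(0, 0.3, 2, 50)
  expect_equal(growth_rate_saturating("NP", cs, gp, Ks = Inf),
               growth_rate(rep("NP", 4), cs, gp))
  expect_equal(growth_rate_saturating("NP", 1e12, gp, Ks = 2),
               gp$g0 + gp$alpha * 2, tolerance = 1e-6)   # saturates at alpha * Ks
  expect_equal(growth_rate_saturating("NP", 2, gp, Ks = 2),
               gp$g0 + gp$alpha * 2 / 2)                 # half-saturation at c = Ks
})

test_that("event tables carry rate g/4 per directed cross-type pair", {
  # uniform grid: empty table
  tab <- build_event_table(matrix(1L, 4, 4), growth_params("neutral"))
  expect_equal(tab$total_rate, 0)
  expect_equal(nrow(tab$events), 0)

  # neutral single invader: 8 events, all rate g0/4, total 2 g0
  gi <- matrix(1L, 4, 4); gi[2, 3] <- 0L
  tab <- build_event_table(gi, growth_params("neutral", g0 = 1))
  expect_equal(nrow(tab$events), 8)
  expect_true(all(tab$events$rate == 0.25))
  expect_equal(tab$total_rate, 2)

  # competition on a 3x3 grid vs exhaustive scalar enumeration
  gp <- growth_params("competition", g0 = 1, kappa = 0.6, alpha = 3)
  pp <- resource_params(1)
  for (seed in 1:4) {
    g <- random_grid(3, 0.5, seed)
    if (nrow(cross_type_edges(g)) == 0) next
    field <- dense_field_solve(g, pp)
    tab <- build_event_table(g, gp, steady_state_field(g, pp))
    oracle <- naive_event_table_total(g, gp, field)
    expect_equal(tab$total_rate, oracle$total, tolerance = 1e-12)
    expect_equal(sum(tab$events$rate[tab$events$divider_type == 0L]),
                 oracle$np_to_p, tolerance = 1e-12)
  }
})

test_that("Doob-Gillespie sampling has exponential waits and rate-weighted picks", {
  gi <- matrix(1L, 4, 4); gi[2, 3] <- 0L
  tab <- build_event_table(gi, growth_params("neutral"))

  # single-event table: that event with probability 1
  one <- tab
  one$events <- one$events[3, , drop = FALSE]
  one$total_rate <- one$events$rate
  set.seed(1)
  expect_equal(sample_step(one)$index, 1L)

  # waiting-time mean = 1 / total_rate within 3 standard errors
  set.seed(2)
  n <- 20000
  taus <- replicate(n, sample_step(tab)$tau)
  expect_lt(abs(mean(taus) - 1 / tab$total_rate), 3 * sd(taus) / sqrt(n))

  # event frequencies match rate / total_rate (chi-square, unequal rates)
  gp <- growth_params("competition", g0 = 1, kappa = 1, alpha = 5)
  g <- random_grid(4, 0.5, 3)
  tab2 <- build_event_table(g, gp, steady_state_field(g, resource_params(2)))
  set.seed(3)
  picks <- replicate(20000, sample_step(tab2)$index)
  obs <- tabulate(picks, nbins = nrow(tab2$events))
  expected_p <- tab2$events$rate / tab2$total_rate
  keep <- expected_p > 0
  pval <- suppressWarnings(
    chisq.test(obs[keep], p = expected_p[keep] / sum(expected_p[keep]))$p.value)
  expect_gt(pval, 1e-4)

  # absorbed signal on an empty table
  expect_true(sample_step(build_event_table(matrix(0L, 3, 3),
                                            growth_params("neutral")))$absorbed)
})

test_that("apply_event replaces the target and keeps the field consistent", {
  pp <- resource_params(2)
  k <- single_source_kernel(6, pp)
  g <- random_grid(6, 0.5, 4)
  f <- steady_state_field(g, pp)
  tab <- build_event_table(g, growth_params("neutral"))
  ev <- tab$events[5, ]
  up <- apply_event(g, ev, f, k)
  expect_equal(up$grid[ev$target_row + 1, ev$target_col + 1], ev$divider_type)
  expect_equal(up$field, steady_state_field(up$grid, pp), tolerance = 1e-12)
  # re-applying the same event is stale
  expect_error(apply_event(up$grid, ev), "stale")
  # reverse event restores the grid
  rev <- ev
  rev$divider_type <- 1L - ev$divider_type
  expect_equal(apply_event(up$grid, rev)$grid, g)
})

test_that("the compiled loop matches the R event-table contract", {
  # initial total rate and selection bias recorded by the compiled loop
  # agree with build_event_table on the initial grid
  cfg <- sim_config(L = 6, variant = "competition", lambda = 1.5, alpha = 3,
                    kappa = 0.8, seed = 31, record_stride = 1, max_events = 5)
  sim <- run_until_fixation(cfg)
  set.seed(31)
  g0 <- make_grid(6, "mixed_50_50")
  tab <- build_event_table(g0, cfg$growth, steady_state_field(g0, cfg$resource))
  expect_equal(sim$trajectory$total_rate[1], tab$total_rate, tolerance = 1e-12)
  b0 <- sim$bias[sim$bias$np_count == sum(g0 == 0L), ]
  expect_equal(b0$mean_bias[1], selection_bias(tab), tolerance = 1e-12)
})

test_that("the replacement loop respects its invariants", {
  # uniform start: immediate absorption at time zero, no events
  u <- run_until_fixation(L = 4, variant = "neutral", init = matrix(1L, 4, 4),
                          seed = 1)
  expect_true(u$absorbed)
  expect_equal(u$fixation_time, 0)
  expect_equal(u$event_count, 0)
  expect_identical(u$winner, "P")

  # zero benefit at maximal cost: producers cannot divide, NP always fixes
  for (s in 1:5) {
    z <- run_until_fixation(L = 6, variant = "competition", lambda = 2,
                            alpha = 0, kappa = 1, seed = s)
    expect_identical(z$winner, "NP")
  }

  # NP fraction changes by exactly 1/L^2 per event
  tr <- run_until_fixation(sim_config(L = 5, variant = "neutral", seed = 7,
                                      record_stride = 1))$trajectory
  steps <- diff(tr$np_fraction[tr$event_index >= 1]) * 25
  expect_true(all(abs(abs(steps) - 1) < 1e-9))

  # replay determinism: same seed, same trajectory, same final grid
  a <- run_until_fixation(L = 8, variant = "competition", lambda = 3,
                          alpha = 10, seed = 99)
  b <- run_until_fixation(L = 8, variant = "competition", lambda = 3,
                          alpha = 10, seed = 99)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_grid, b$final_grid)

  # hitting max_events is flagged, never silently dropped
  m <- run_until_fixation(L = 8, variant = "neutral", seed = 5, max_events = 10)
  expect_false(m$absorbed)
  expect_true(is.na(m$winner))
  expect_equal(m$event_count, 10)
})

test_that("only boundary cells divide and the field tracks the grid exactly", {
  sim <- run_until_fixation(L = 16, variant = "competition", lambda = 10,
                            alpha = 49, seed = 13, max_events = 1000)
  fresh <- steady_state_field(sim$final_grid, resource_params(10))
  expect_lt(max(abs(sim$field - fresh)), 1e-9 * max(fresh))

  # mutualism: both fields track their producer sets
  sm <- run_until_fixation(L = 10, variant = "mutualism", lambda = 2,
                           alpha = 8, seed = 17, max_events = 2000)
  pp <- resource_params(2)
  expect_lt(max(abs(sm$field - steady_state_field(sm$final_grid, pp))), 1e-9)
  expect_lt(max(abs(sm$field_other -
                    steady_state_field(1L - sm$final_grid, pp))), 1e-9)
})

test_that("saturating variant runs through the nonlinear solver", {
  sim <- run_until_fixation(L = 4, variant = "competition_saturating",
                            lambda = 1.5, alpha = 4, kappa = 0.5, Ks = 2,
                            seed = 21, max_events = 400)
  expect_true(sim$absorbed || sim$event_count == 400)
  expect_true(all(diff(sim$trajectory$time) >= 0))
})

test_that("trajectory CSV and fixation JSON exports match their schemas", {
  sim <- run_until_fixation(L = 6, variant = "neutral", seed = 3)
  fcsv <- tempfile(fileext = ".csv")
  write_trajectory(sim, fcsv)
  expect_identical(readLines(fcsv, n = 1), "event_index,time,np_fraction,divider_type")
  fj <- tempfile(fileext = ".json")
  write_fixation_json(sim, fj)
  j <- jsonlite::read_json(fj)
  expect_named(j, c("winner", "fixation_time", "event_count", "absorbed",
                    "seed", "config_hash"))
  expect_identical(j$winner, sim$winner)
  expect_true(j$absorbed)
})
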