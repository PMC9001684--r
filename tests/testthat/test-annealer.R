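# Simulated-annealing optimization loop.

test_that("acceptance probability follows the annealing rule", {
  cfg <- anneal_config(g_t = 100, C0 = 10, C_end = 10)
  # improvements always accepted
  expect_equal(accept_probability(50, 40, 10, cfg), 1)
  expect_equal(accept_probability(50, 50, 10, cfg), 1)
  # after g_t, detrimental moves never accepted
  expect_equal(accept_probability(50, 60, 100, cfg), 0)
  expect_equal(accept_probability(50, 60, 1000, cfg), 0)
  # detriment equal to the tolerance: e^-1
  expect_equal(accept_probability(50, 60, 0, cfg), exp(-1))
  # exponential schedule interpolates C geometrically
  cfg2 <- anneal_config(g_t = 100, C0 = 10, C_end = 0.01)
  expect_equal(cooling_tolerance(0, 100, 10, 0.01, "exponential"), 10)
  expect_equal(cooling_tolerance(50, 100, 10, 0.01, "exponential"),
               sqrt(10 * 0.01))
  expect_equal(cooling_tolerance(100, 100, 10, 0.01, "linear"), 0.01)
  # C(g) is non-increasing under both schedules
  for (sched in c("exponential", "linear")) {
    cs <- vapply(0:99, cooling_tolerance, numeric(1), g_t = 100,
                 C0 = 10, C_end = 0.01, schedule = sched)
    expect_true(all(diff(cs) <= 0) && all(cs > 0))
  }
})

test_that("initial sets are seeded-reproducible and unique when forced", {
  fx <- make_targets(n_targets = 4, seed = 31)
  panel <- panel_candidates(fx$regions)
  set.seed(10); s1 <- init_set(panel)
  set.seed(10); s2 <- init_set(panel)
  expect_identical(s1$selection, s2$selection)
  expect_equal(set_loss(s1), loss_brute_force(selected_primers(s1)),
               tolerance = 1e-9)
  # single-pair targets admit exactly one initial set
  panel1 <- lapply(panel, function(t) {
    t$pairs <- t$pairs[1, , drop = FALSE]
    t
  })
  set.seed(1); a <- init_set(panel1)
  set.seed(99); b <- init_set(panel1)
  expect_identical(a$selection, b$selection)
})

test_that("proposals replace exactly k pairs with different ones", {
  fx <- make_targets(n_targets = 6, seed = 41)
  panel <- panel_candidates(fx$regions)
  set.seed(3)
  s <- init_set(panel)
  for (k in c(1L, 2L, 3L)) {
    plan <- propose(s, k)
    expect_equal(nrow(plan), k)
    expect_true(all(plan$new_row != plan$old_row))
    expect_false(anyDuplicated(plan$target_id) > 0)
  }
  set.seed(8); p1 <- propose(s, 2L)
  set.seed(8); p2 <- propose(s, 2L)
  expect_identical(p1, p2)
  # all-single-candidate panels cannot propose
  panel1 <- lapply(panel, function(t) { t$pairs <- t$pairs[1, , drop = FALSE]; t })
  set.seed(1)
  s1 <- init_set(panel1)
  expect_error(propose(s1), "no-op")
})

test_that("zero annealing budget degenerates to strict stochastic descent", {
  fx <- make_targets(n_targets = 6, seed = 51)
  panel <- panel_candidates(fx$regions)
  cfg <- anneal_config(g_t = 0, total_generations = 300, seed = 4)
  res <- optimize_panel(panel, cfg)
  expect_true(all(diff(res$trace$loss) <= 0))
  expect_equal(res$final_loss, min(res$trace$loss))
})

test_that("optimization is deterministic given seed and config", {
  fx <- make_targets(n_targets = 5, seed = 61)
  panel <- panel_candidates(fx$regions)
  cfg <- anneal_config(g_t = 100, total_generations = 150, seed = 7,
                       n_restarts = 2)
  r1 <- optimize_panel(panel, cfg)
  r2 <- optimize_panel(panel, cfg)
  expect_identical(r1$set$selection, r2$set$selection)
  expect_equal(r1$trace$loss, r2$trace$loss)
  expect_equal(r1$final_loss, set_loss(r1$set))
  # the returned best-seen record is consistent with the trace
  expect_equal(r1$best$loss,
               min(r1$trace$loss[r1$trace$restart == r1$restart]))
})

test_that("incremental losses survive a debug cross-check against brute force", {
  fx <- make_targets(n_targets = 4, seed = 71)
  panel <- panel_candidates(fx$regions)
  cfg <- anneal_config(g_t = 40, total_generations = 60, seed = 2)
  expect_no_error(optimize_panel(panel, cfg, debug_check_every = 10L))
})

test_that("the optimizer abandons planted 3'-complementary candidates", {
  # per target, pair 1 carries a forward primer whose 3' terminus is a
  # self-complementary motif (so every planted primer dimerizes with every
  # other planted primer and with itself), pair 2 is a clean alternative
  # built from an A/C-only alphabet, which admits no reverse-complementary
  # subsequences at all: the all-clean set has loss exactly zero
  set.seed(81)
  planted <- paste0(strrep("T", 5), "GGATCC")
  expect_gte(badness_pair(planted, planted), 2^6 * 2^4)
  clean_ac <- function(len) paste(sample(c("A", "C"), len, TRUE), collapse = "")
  clean_fp <- replicate(8, clean_ac(14))
  rps <- replicate(8, clean_ac(14))
  panel <- direct_panel(
    fp_sets = lapply(1:8, function(i) c(planted, clean_fp[i])),
    rp_sets = lapply(1:8, function(i) c(rps[i], rps[i])))
  cfg <- anneal_config(g_t = 300, total_generations = 450, seed = 1)
  avoided <- vapply(1:20, function(seed) {
    cfg$seed <- seed
    res <- optimize_panel(panel, cfg)
    init_loss <- res$trace$loss[1]
    all(res$set$selection == 2L) && res$final_loss < 0.05 * init_loss
  }, logical(1))
  expect_gte(mean(avoided), 0.95)
})
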