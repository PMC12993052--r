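test_that("a noise-free collection reproduces the true genotypes exactly", {
  cfg <- sim_config(n_cultivars = 8, miscall_rate = 0, missing_rate = 0,
                    mislabel_rate = 0, seed = 31L)
  sim <- simulate_collection(cfg)
  panel <- profile_panel(sim$profiles)
  geno <- sim$truth$genotypes
  for (i in seq_len(nrow(sim$profiles))) {
    cid <- sim$truth$sample_map$cultivar_id[i]
    k <- match(cid, geno$cultivar_id)
    for (mk in panel$marker) {
      expect_identical(sim$profiles[[mk]][[i]], geno[[mk]][[k]],
                       label = paste(sim$profiles$sample_id[i], mk))
    }
  }
  expect_identical(nrow(sim$truth$perturbations), 0L)
})

test_that("the same seed gives identical collections", {
  cfg <- sim_config(n_cultivars = 6, seed = 37L)
  s1 <- simulate_collection(cfg)
  s2 <- simulate_collection(cfg)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_collection(sim_config(n_cultivars = 6, seed = 38L))
  expect_false(identical(s1$profiles, s3$profiles))
})

test_that("replaying the perturbation log reproduces emitted profiles", {
  cfg <- sim_config(n_cultivars = 10, miscall_rate = 0.1, missing_rate = 0.1,
                    seed = 41L)
  sim <- simulate_collection(cfg)
  panel <- profile_panel(sim$profiles)
  replayed <- replay_perturbations(sim$truth, panel)
  for (i in seq_len(nrow(sim$profiles))) {
    sid <- sim$profiles$sample_id[i]
    for (mk in panel$marker) {
      expect_identical(sim$profiles[[mk]][[i]], replayed[[sid]][[mk]],
                       label = paste(sid, mk))
    }
  }
})

test_that("observed miscall counts match the configured rate", {
  rate <- 0.1
  cfg <- sim_config(n_cultivars = 100, prop_triploid = 0,
                    trees_per_cultivar = c(5L, 5L),
                    replicates_per_tree = c(2L, 2L),
                    miscall_rate = rate, missing_rate = 0, mislabel_rate = 0,
                    seed = 43L)
  sim <- simulate_collection(cfg)
  panel <- profile_panel(sim$profiles)
  # each emitted (sample, marker) exposes 2 alleles to independent miscall
  n_trials <- nrow(sim$profiles) * nrow(panel) * 2
  pert <- sim$truth$perturbations
  n_miscalls <- sum(lengths(regmatches(
    pert$detail[pert$type == "miscall"],
    gregexpr("->", pert$detail[pert$type == "miscall"]))))
  se <- sqrt(rate * (1 - rate) / n_trials)
  expect_lt(abs(n_miscalls / n_trials - rate), 3 * se)
})

test_that("recovery scoring matches hand-computed pair counts", {
  truth <- list(sample_map = tibble::tibble(
    sample_id = paste0("S", 1:6),
    cultivar_id = c("A", "A", "A", "B", "B", "C")))
  inferred <- tibble::tibble(
    group_id = c("g1", "g1", "g2", "g2", "g2", "g3"),
    sample_id = paste0("S", 1:6))
  # over the 15 pairs: true-together = 4 (3 in A, 1 in B),
  # inferred-together = 4 (1 in g1, 3 in g2), both = 1 + 1 = 2
  ev <- evaluate_recovery(inferred, truth)
  expect_equal(ev$precision, 2 / 4)
  expect_equal(ev$recall, 2 / 4)
  # ARI from the pair-count formula with expected index 4*4/15
  expected <- 4 * 4 / 15
  expect_equal(ev$adjusted_rand_index, (2 - expected) / ((4 + 4) / 2 - expected))
})

test_that("perfect and degenerate partitions score as expected", {
  truth <- list(sample_map = tibble::tibble(
    sample_id = paste0("S", 1:8),
    cultivar_id = rep(c("A", "B"), each = 4)))
  perfect <- tibble::tibble(group_id = rep(c("x", "y"), each = 4),
                            sample_id = paste0("S", 1:8))
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$adjusted_rand_index, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  lumped <- tibble::tibble(group_id = "all", sample_id = paste0("S", 1:8))
  ev2 <- evaluate_recovery(lumped, truth)
  expect_lt(ev2$precision, 1)
  expect_equal(ev2$recall, 1)
  expect_error(evaluate_recovery(
    tibble::tibble(group_id = "g", sample_id = "S99"), truth), "not in truth")
})

test_that("the ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  sim <- simulate_collection(sim_config(n_cultivars = 12, miscall_rate = 0.08,
                                        seed = 47L))
  groups <- cluster_profiles(sim$profiles)
  ev <- evaluate_recovery(groups, sim$truth)
  map <- sim$truth$sample_map
  inf <- groups$group_id[match(map$sample_id, groups$sample_id)]
  expect_equal(ev$adjusted_rand_index,
               mclust::adjustedRandIndex(map$cultivar_id, inf))
})

test_that("noisier sizing never improves recovery on average", {
  aris <- vapply(c(0, 0.1, 0.35), function(rate) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_collection(sim_config(
        n_cultivars = 12, trees_per_cultivar = c(3L, 3L),
        miscall_rate = rate, missing_rate = 0, seed = 100L + s))
      evaluate_recovery(cluster_profiles(sim$profiles), sim$truth)$adjusted_rand_index
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aris) <= 1e-9))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(miscall_rate = 1.5), "rates")
  expect_error(sim_config(n_cultivars = 0), "cultivar")
  expect_error(sim_config(panel = gfg_pear_panel()[0, ]), "no markers")
})
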