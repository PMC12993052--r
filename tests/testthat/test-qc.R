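test_that("binary encoding enumerates variants in panel-then-size order", {
  panel2 <- mini_panel(c("M1", "M2"))
  p <- make_profiles(list(A = list(M1 = c(100L, 104L), M2 = 200L),
                          B = list(M1 = c(100L, 106L), M2 = 200L)), panel2)
  enc <- binarize(p)
  expect_identical(enc$variant_index$marker, c("M1", "M1", "M1", "M2"))
  expect_identical(enc$variant_index$afl, c(100L, 104L, 106L, 200L))
  expect_identical(unname(enc$vectors["A", ]), c(1L, 1L, 0L, 1L))
  expect_identical(unname(enc$vectors["B", ]), c(1L, 0L, 1L, 1L))
})

test_that("a missing marker contributes all-zeros for its variants", {
  panel2 <- mini_panel(c("M1", "M2"))
  p <- make_profiles(list(A = list(M1 = c(100L, 104L), M2 = 200L),
                          B = list(M1 = c(100L, 104L))), panel2)
  enc <- binarize(p)
  expect_identical(unname(enc$vectors["B", enc$variant_index$marker == "M2"]), 0L)
})

test_that("binary Dice similarity follows the set-overlap formula", {
  expect_equal(binary_dice_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(binary_dice_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(binary_dice_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(binary_dice_similarity(c(0, 0), c(0, 0)), 1)  # degenerate case
  expect_error(binary_dice_similarity(c(1, 0), c(1, 0, 1)), "length")
})

test_that("retraceability agrees with the allele-set equality oracle", {
  sim <- simulate_collection(sim_config(n_cultivars = 15, seed = 17L))
  panel <- profile_panel(sim$profiles)
  res <- run_ssr_curation(sim$profiles)
  for (i in seq_len(nrow(res$representatives))) {
    gid <- res$representatives$group_id[i]
    if (nrow(res$representatives$checks[[i]])) next  # unverifiable
    members <- sim$profiles[sim$profiles$sample_id %in%
                              res$groups$sample_id[res$groups$group_id == gid], ]
    expect_identical(res$retrace$retraceable[res$retrace$group_id == gid],
                     retrace_oracle(res$representatives[i, ], members, panel),
                     label = gid)
  }
})

test_that("single-member groups are always retraceable at similarity 1", {
  panel2 <- mini_panel(c("M1", "M2"))
  p <- make_profiles(list(A = list(M1 = c(100L, 104L), M2 = 200L)), panel2)
  groups <- name_groups(list("A"))
  reps <- consensus_genotypes(p, groups, panel2)
  rt <- retrace_representatives(reps, p, groups, panel2)
  expect_true(rt$retraceable)
  expect_equal(rt$best_similarity, 1)
  expect_identical(rt$best_sample, "A")
})

test_that("a truly synthetic representative is flagged with similarity < 1", {
  panel2 <- mini_panel(c("M1", "M2"))
  # majority at M1 comes from A+B, majority at M2 from A+C; no single member
  # carries both winning combinations
  p <- make_profiles(list(A = list(M1 = c(100L, 104L), M2 = c(200L, 204L)),
                          B = list(M1 = c(100L, 104L), M2 = c(200L, 208L)),
                          C = list(M1 = c(100L, 108L), M2 = c(200L, 204L)),
                          D = list(M1 = c(100L, 108L), M2 = c(200L, 208L))),
                     panel2)
  # force one group of all four
  groups <- name_groups(list(c("A", "B", "C", "D")))
  reps <- consensus_genotypes(p, groups, panel2)
  rt <- retrace_representatives(reps, p, groups, panel2)
  if (nrow(reps$checks[[1]]) == 0L) {
    expect_identical(rt$retraceable,
                     retrace_oracle(reps[1, ], p, panel2))
    expect_true(rt$best_similarity <= 1)
  } else {
    expect_true(is.na(rt$retraceable))
  }
})

test_that("representatives with unresolved CHECKs are unverifiable", {
  panel1 <- mini_panel("M1", repeat_unit = NA)
  p <- make_profiles(list(A = list(M1 = c(100L, 104L)),
                          B = list(M1 = c(100L, 106L))), panel1)
  groups <- name_groups(list(c("A", "B")))
  reps <- consensus_genotypes(p, groups, panel1)
  expect_identical(nrow(reps$checks[[1]]), 1L)
  rt <- retrace_representatives(reps, p, groups, panel1)
  expect_true(is.na(rt$retraceable))
})

test_that("variant frequencies count carriers among amplified members", {
  panel1 <- mini_panel("M1")
  p <- make_profiles(list(A = list(M1 = c(100L, 104L)),
                          B = list(M1 = c(100L, 104L)),
                          C = list(M1 = c(100L, 104L)),
                          D = list(M1 = c(100L, 106L))), panel1)
  groups <- name_groups(list(c("A", "B", "C", "D")))
  reps <- consensus_genotypes(p, groups, panel1)
  fr <- variant_frequencies(reps[1, ], p, panel1)
  expect_equal(fr$frequency[fr$position == 1], 1)     # 100 carried by all
  expect_equal(fr$frequency[fr$position == 2], 0.75)  # 104 carried by 3 of 4
  expect_equal(attr(fr, "average_score"), mean(fr$frequency))
})

test_that("unanimous groups have frequency 1 everywhere", {
  sim <- simulate_collection(sim_config(n_cultivars = 4, miscall_rate = 0,
                                        missing_rate = 0, seed = 8L))
  res <- run_ssr_curation(sim$profiles)
  expect_true(all(res$frequencies$frequency == 1))
})

test_that("missing members shrink the frequency denominator", {
  panel1 <- mini_panel("M1")
  p <- make_profiles(list(A = list(M1 = c(100L, 104L)),
                          B = list(M1 = c(100L, 104L)),
                          C = list()), panel1)
  groups <- name_groups(list(c("A", "B", "C")))
  reps <- consensus_genotypes(p, groups, panel1)
  fr <- variant_frequencies(reps[1, ], p, panel1)
  expect_identical(unique(fr$n_amplified), 2L)
  expect_equal(fr$frequency, c(1, 1))
})

test_that("untied positions carry a strict plurality of conforming voters", {
  sim <- simulate_collection(sim_config(n_cultivars = 10, seed = 19L))
  panel <- profile_panel(sim$profiles)
  res <- run_ssr_curation(sim$profiles)
  log <- res$resolution_log
  for (i in seq_len(nrow(res$representatives))) {
    gid <- res$representatives$group_id[i]
    members <- sim$profiles[sim$profiles$sample_id %in%
                              res$groups$sample_id[res$groups$group_id == gid], ]
    for (mk in panel$marker) {
      vals <- res$representatives[[mk]][[i]]
      if (!length(vals)) next
      amp <- members[[mk]][lengths(members[[mk]]) > 0L]
      voters <- amp[lengths(amp) == length(vals)]
      for (p in seq_along(vals)) {
        if (is.na(vals[p])) next
        was_tie <- nrow(log) > 0 && any(log$group_id == gid & log$marker == mk &
                                          log$position == p)
        if (was_tie) next
        votes <- table(vapply(voters, `[`, integer(1), p))
        win <- votes[as.character(vals[p])]
        expect_true(all(votes[names(votes) != as.character(vals[p])] < win))
        # a two-candidate untied vote is a strict majority
        if (length(votes) <= 2) expect_gt(win / sum(votes), 0.5)
      }
    }
  }
})
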