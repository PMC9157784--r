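test_that("depth increases lakeward and the landscape is seed-reproducible", {
  cfg <- landscape_config(depth_noise_sd = 0, seed = 1)
  L <- generate_landscape(cfg)
  # zero noise: depth strictly monotone in shore distance along any column
  one_col <- L[L$col == 5, ]
  expect_true(all(diff(one_col$mean_depth[order(one_col$y)]) > 0))
  L2 <- generate_landscape(landscape_config(seed = 42))
  L3 <- generate_landscape(landscape_config(seed = 42))
  expect_identical(as.data.frame(L2), as.data.frame(L3))
  expect_false(identical(as.data.frame(L2),
                         as.data.frame(generate_landscape(landscape_config(seed = 43)))))
})

test_that("grid dimensions and the habitat table are fully populated", {
  L <- generate_landscape(landscape_config(nx = 60, ny = 40, seed = 2))
  expect_identical(nrow(L), 2400L)
  expect_true(all(habitat_variables() %in% names(L)))
  expect_false(anyNA(as.data.frame(L)[, habitat_variables()]))
  expect_true(all(L$mean_depth >= 0))
  pct <- grep("^pct_", habitat_variables(), value = TRUE)
  for (v in pct) expect_true(all(L[[v]] >= 0 & L[[v]] <= 100))
  expect_true(all(L$large_marina %in% c(0L, 1L)))
  expect_error(generate_landscape(landscape_config(nx = 1)), "degenerate")
  expect_error(landscape_config(n_launches = 0), "at least one")
})

test_that("community occupancy is depth-structured with a hard cutoff", {
  L <- generate_landscape(landscape_config(seed = 3))
  C <- generate_community(L, community_config(seed = 3))
  rich <- rowSums(C$presence)
  expect_lt(cor(rich, L$mean_depth, method = "spearman"), -0.5)
  expect_identical(sum(C$presence[L$mean_depth > 8, ]), 0L)
  expect_identical(sum(C$species$origin == "non_native"),
                   as.integer(round(0.2 * 50)))
  # deep-only landscape holds no plants at all
  deepL <- L
  deepL$mean_depth <- deepL$mean_depth + 10
  expect_identical(sum(generate_community(deepL, community_config(seed = 4))$presence),
                   0L)
})

test_that("native and non-native richness share a driver in surveys", {
  L <- generate_landscape(landscape_config(seed = 5))
  frame <- L; frame$weight <- 1
  pos <- vapply(1:25, function(s) {
    C <- generate_community(L, community_config(seed = 900 + s))
    sel <- spatially_balanced_sample(frame, 50, seed = 300 + s)
    inc <- survey_incidence(C, L, sel$cell_id, observation_config(seed = 600 + s))
    r <- native_nonnative_relationship(inc)$r
    !is.na(r) && r > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})

test_that("perfect detection recovers true cell presence at minimum effort", {
  L <- generate_landscape(landscape_config(seed = 6))
  C <- generate_community(L, community_config(seed = 6))
  cells <- rownames(C$presence)[order(-rowSums(C$presence))][1:5]
  sv <- simulate_survey(C, cells, observation_config(p_toss = 1, p_visual = 0,
                                                     seed = 7))
  expect_true(all(sv$effort$tosses == 4))
  inc <- survey_incidence(C, L, cells, observation_config(p_toss = 1,
                                                          p_visual = 0, seed = 7))
  expect_identical(unname(inc$presence[cells, ]),
                   unname(C$presence[cells, ]))
})

test_that("zero detection probability keeps empty units in the frame", {
  L <- generate_landscape(landscape_config(seed = 8))
  C <- generate_community(L, community_config(seed = 8))
  cells <- rownames(C$presence)[1:6]
  cfg <- observation_config(p_toss = 0, p_visual = 0, seed = 9)
  sv <- simulate_survey(C, cells, cfg)
  expect_identical(nrow(sv$records), 0L)
  inc <- survey_incidence(C, L, cells, cfg)
  expect_identical(nrow(inc$presence), 6L)
  expect_identical(sum(inc$presence), 0L)
})

test_that("toss effort obeys the stop rule bounds", {
  L <- generate_landscape(landscape_config(seed = 10))
  C <- generate_community(L, community_config(seed = 10))
  cells <- rownames(C$presence)[order(-rowSums(C$presence))][1:10]
  cfg <- observation_config(p_toss = 0.15, seed = 11)
  sv <- simulate_survey(C, cells, cfg)
  expect_true(all(sv$effort$tosses >= cfg$min_tosses))
  expect_true(all(sv$effort$tosses <= cfg$max_tosses))
  # low per-toss detection must sometimes trigger extra tosses
  expect_gt(sum(sv$effort$tosses > cfg$min_tosses), 0)
})

test_that("dispersed designs see the expected share of plant-free units", {
  L <- generate_landscape(landscape_config(seed = 12))
  frame <- L; frame$weight <- 1
  zf <- vapply(1:10, function(s) {
    C <- generate_community(L, community_config(seed = 400 + s))
    sel <- spatially_balanced_sample(frame, 60, seed = 500 + s)
    inc <- survey_incidence(C, L, sel$cell_id, observation_config(seed = 700 + s))
    mean(rowSums(inc$presence) == 0)
  }, numeric(1))
  expect_gt(mean(zf), 0.3)
  expect_lt(mean(zf), 0.5)
})

test_that("simulated surveys satisfy the incidence invariants by construction", {
  L <- generate_landscape(landscape_config(seed = 13))
  for (s in 1:5) {
    C <- generate_community(L, community_config(seed = 20 + s))
    frame <- L; frame$weight <- 1
    sel <- spatially_balanced_sample(frame, 30, seed = 40 + s)
    inc <- survey_incidence(C, L, sel$cell_id, observation_config(seed = 60 + s))
    ct <- tally_counts(inc)
    expect_identical(ct$m, 30L)
    expect_lte(ct$Q1 + ct$Q2, max(ct$Sobs, 1L))
    expect_equal(ct$incidences, sum(ct$per_species))
    expect_true(all(ct$per_species <= ct$m))
    # detections only where the species is truly present
    expect_true(all(!inc$presence | C$presence[rownames(inc$presence), ]))
  }
})

test_that("the simulator can be steered into both published count regimes", {
  L <- generate_landscape(landscape_config(seed = 14))
  frame <- L; frame$weight <- 1
  # regime A (thorough survey, few uniques): high detection, larger m
  C <- generate_community(L, community_config(seed = 15))
  selA <- spatially_balanced_sample(frame, 80, seed = 16)
  incA <- survey_incidence(C, L, selA$cell_id,
                           observation_config(p_toss = 0.6, seed = 17))
  ctA <- tally_counts(incA)
  # regime B (sparse survey, many uniques): low detection, small m
  selB <- spatially_balanced_sample(frame, 20, seed = 18)
  incB <- survey_incidence(C, L, selB$cell_id,
                           observation_config(p_toss = 0.10, p_visual = 0.1,
                                              seed = 19))
  ctB <- tally_counts(incB)
  expect_lt(ctA$Q1 / max(ctA$Sobs, 1), ctB$Q1 / max(ctB$Sobs, 1))
  expect_gt(ctB$Q1, ctB$Q2)
})
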