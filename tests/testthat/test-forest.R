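# habitat rows drawn from a synthetic landscape
habitat_fixture <- function(n = 120, seed = 1) {
  L <- generate_landscape(landscape_config(seed = seed))
  set.seed(seed)
  idx <- sample(nrow(L), n)
  h <- as.data.frame(L)[idx, c("cell_id", habitat_variables())]
  names(h)[1] <- "unit_id"
  rownames(h) <- NULL
  h
}

test_that("a depth-driven community is recovered by the depth-only model", {
  h <- habitat_fixture(150, seed = 2)
  rich <- round(12 * stats::plogis((4 - h$mean_depth) / 1.2))
  fit <- fit_richness_forest(h, rich, subset = "depth_only", seed = 3)
  expect_gt(fit$report$r2_overall, 0.9)
  expect_identical(fit$variables, "mean_depth")
})

test_that("pure-noise richness yields near-zero held-out r-squared", {
  h <- habitat_fixture(80, seed = 4)
  r2s <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    rich <- rpois(nrow(h), 4)
    fit <- fit_richness_forest(h, rich, subset = "all", ntree = 120,
                               seed = 2000 + s)
    fit$report$r2_test
  }, numeric(1))
  expect_lt(mean(r2s, na.rm = TRUE), 0.15)
})

test_that("model preconditions are enforced", {
  h <- habitat_fixture(30, seed = 5)
  expect_error(fit_richness_forest(h[1:10, ], rpois(10, 3)), "at least 20")
  expect_error(fit_richness_forest(h, rep(3, nrow(h))), "constant")
  expect_error(fit_richness_forest(h, rpois(nrow(h), 3),
                                   subset = c("mean_depth", "not_a_var")),
               "not_a_var")
  # the published reduced subset is accepted as-is
  fit <- fit_richness_forest(h, rpois(nrow(h), 3) + round(h$mean_depth),
                             subset = "reduced", ntree = 60, seed = 1)
  expect_setequal(fit$variables,
                  c("mean_depth", "pct_littoral", "max_fetch",
                    "dist_boat_launch", "dist_marina"))
})

test_that("importance percentages sum to 100 and rank the true driver first", {
  # independent predictors so importance is attributable to depth alone
  # (landscape habitat carries depth proxies like littoral fraction)
  set.seed(6)
  h <- as.data.frame(setNames(
    lapply(habitat_variables(), function(v) runif(150, 0, 10)),
    habitat_variables()))
  h$unit_id <- paste0("u", seq_len(nrow(h)))
  rich <- round(12 * stats::plogis((4 - h$mean_depth) / 1.2))
  firsts <- vapply(1:15, function(s) {
    fit <- fit_richness_forest(h, rich + rpois(length(rich), 1),
                               subset = "all", ntree = 120, seed = 300 + s)
    imp <- importance_percent(fit)
    expect_equal(sum(imp$percent_of_total), 100, tolerance = 0.1)
    imp$variable[1] == "mean_depth"
  }, logical(1))
  expect_gte(mean(firsts), 0.9)
})

test_that("a single-variable model holds all the importance", {
  h <- habitat_fixture(60, seed = 7)
  rich <- round(h$mean_depth) + rpois(nrow(h), 1)
  fit <- fit_richness_forest(h, rich, subset = "depth_only", ntree = 80,
                             seed = 1)
  imp <- importance_percent(fit)
  expect_equal(imp$percent_of_total, 100)
})

test_that("duplicated predictors split a variable's importance share", {
  h <- habitat_fixture(150, seed = 8)
  rich <- round(12 * stats::plogis((4 - h$mean_depth) / 1.2)) +
    rpois(nrow(h), 1)
  solo <- fit_richness_forest(h, rich, subset = c("mean_depth", "max_fetch"),
                              ntree = 300, seed = 9)
  imp_solo <- importance_percent(solo)
  share_solo <- imp_solo$percent_of_total[imp_solo$variable == "mean_depth"]
  h2 <- h
  h2$mean_depth_copy <- h2$mean_depth
  dup <- fit_richness_forest(h2, rich,
                             subset = c("mean_depth", "mean_depth_copy",
                                        "max_fetch"),
                             ntree = 300, seed = 9)
  imp_dup <- importance_percent(dup)
  share_dup <- sum(imp_dup$percent_of_total[
    imp_dup$variable %in% c("mean_depth", "mean_depth_copy")])
  expect_lt(abs(share_dup - share_solo), 5)
})

test_that("the >=5% rule reproduces the published reduced subset", {
  imp <- data.frame(
    variable = c("mean_depth", "pct_littoral", "max_fetch",
                 "dist_soft_shore", "dist_boat_launch", "pct_soft_shore",
                 "dist_marina", "mid_dist_docked_shore", "dist_lots_docks",
                 "dist_hard_shore", "prop_shore_to_water",
                 "dist_moderate_shore", "pct_hard_shore", "pct_lots_docks",
                 "dist_any_shore", "pct_moderate_shore", "pct_docks",
                 "large_marina"),
    gini_sum = c(1991.01, 1188.52, 767.82, 744.48, 551.95, 506.19, 424.68,
                 403.55, 385.58, 360.5, 349.66, 304.5, 126.35, 109, 71.32,
                 58.16, 45.2, 29.93))
  imp$percent_of_total <- 100 * imp$gini_sum / sum(imp$gini_sum)
  sel <- reduced_variable_selection(imp, 5,
                                    exclude = c("dist_soft_shore",
                                                "pct_soft_shore"))
  expect_true(all(c("mean_depth", "pct_littoral", "max_fetch",
                    "dist_boat_launch", "dist_marina") %in% sel))
  expect_false(any(c("dist_soft_shore", "pct_soft_shore") %in% sel))
  expect_true(all(imp$percent_of_total[match(sel, imp$variable)] >= 5))
  expect_error(reduced_variable_selection(imp, 100), "threshold")
  expect_setequal(reduced_variable_selection(imp, 0), imp$variable)
})

test_that("the reduced-model rule recovers known effect variables", {
  h <- habitat_fixture(200, seed = 10)
  hits <- vapply(1:10, function(s) {
    set.seed(500 + s)
    rich <- round(8 * stats::plogis((4 - h$mean_depth) / 1.2) +
                    3 * exp(-h$dist_boat_launch / 500)) + rpois(nrow(h), 1)
    fit <- fit_richness_forest(h, rich, subset = "all", ntree = 200,
                               seed = 600 + s)
    sel <- reduced_variable_selection(importance_percent(fit), 5)
    all(c("mean_depth", "dist_boat_launch") %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("predicted surfaces track the depth gradient and feed the mask", {
  L <- generate_landscape(landscape_config(seed = 11))
  h <- as.data.frame(L)[, c("cell_id", habitat_variables())]
  names(h)[1] <- "unit_id"
  rich <- round(12 * stats::plogis((4 - h$mean_depth) / 1.2))
  fit <- fit_richness_forest(h, rich, subset = "reduced", ntree = 150, seed = 12)
  surf <- predict_surface(fit, L, depth_mask_m = 6)
  expect_true(all(surf$value >= 0))
  expect_lt(cor(surf$value, L$mean_depth, method = "spearman"), -0.5)
  expect_identical(surf$masked, L$mean_depth > 6)
  L2 <- L; L2$mean_depth <- NULL
  expect_error(predict_surface(fit, L2), "mean_depth")
  # constant habitat -> constant predictions
  Lc <- L
  for (v in habitat_variables()) Lc[[v]] <- 1
  expect_equal(var(predict_surface(fit, Lc, depth_mask_m = Inf)$value), 0)
})

test_that("reports are reproducible given the seed", {
  h <- habitat_fixture(80, seed = 13)
  rich <- round(h$mean_depth) + rpois(nrow(h), 2)
  f1 <- fit_richness_forest(h, rich, subset = "reduced", ntree = 100, seed = 7)
  f2 <- fit_richness_forest(h, rich, subset = "reduced", ntree = 100, seed = 7)
  expect_identical(f1$report, f2$report)
  expect_identical(importance_percent(f1), importance_percent(f2))
})
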