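# Forest-based regression of sample-unit richness on habitat variables,
# Gini-importance aggregation, and the >=5% reduced-model screening rule.

#' The habitat variable set used by the richness models
#'
#' The 18 per-cell habitat attributes: depth, littoral fraction, fetch,
#' shoreline type distances and percentages, and proxies for human points
#' of introduction (boat launches, marinas, docks).
#'
#' @return character vector of variable names.
#' @export
habitat_variables <- function() {
  c("mean_depth", "pct_littoral", "max_fetch",
    "dist_soft_shore", "dist_hard_shore", "dist_moderate_shore",
    "dist_any_shore", "pct_soft_shore", "pct_hard_shore",
    "pct_moderate_shore", "dist_boat_launch", "dist_marina",
    "mid_dist_docked_shore", "dist_lots_docks", "prop_shore_to_water",
    "pct_lots_docks", "pct_docks", "large_marina")
}

#' Default reduced variable subset
#'
#' The five variables retained by the >=5% Gini-importance rule after
#' excluding the two soft-shoreline variables (hard to derive
#' consistently from remote data): mean depth, percent littoral zone,
#' maximum fetch, and minimum distances to boat launch and marina.
#'
#' @return character vector.
#' @export
reduced_variables_default <- function() {
  c("mean_depth", "pct_littoral", "max_fetch", "dist_boat_launch",
    "dist_marina")
}

#' Fit a regression forest of richness on habitat variables
#'
#' Random-forest regression of per-unit observed species richness on a
#' habitat attribute table, with a seeded train/test split, reporting
#' squared correlations between observed and predicted richness on the
#' training units, the held-out test units, and all units pooled.
#'
#' @param habitat data frame with a `unit_id` column plus habitat
#'   variables (see [habitat_variables()]).
#' @param richness numeric vector of observed richness, aligned with
#'   `habitat` rows (or named by `unit_id`).
#' @param subset `"all"` (all available habitat variables), `"reduced"`
#'   (see [reduced_variables_default()]), `"depth_only"`, or a character
#'   vector of variable names.
#' @param split_fraction fraction of units used for training.
#' @param ntree number of trees.
#' @param seed RNG seed for the split and the forest.
#' @return object of class `richness_forest`: list with `model`
#'   (randomForest), `report` (data frame with `r2_train`, `r2_test`,
#'   `r2_overall`), `variables`, `train_idx`.
#' @export
fit_richness_forest <- function(habitat, richness, subset = "all",
                                split_fraction = 0.8, ntree = 500, seed = 1) {
  habitat <- as.data.frame(habitat)
  if (!is.null(names(richness)) && "unit_id" %in% names(habitat)) {
    richness <- richness[habitat$unit_id]
  }
  richness <- as.numeric(richness)
  if (length(richness) != nrow(habitat)) stop("richness/habitat length mismatch")
  if (nrow(habitat) < 20) stop("need at least 20 sample units")
  if (sd(richness) == 0) stop("constant richness: r-squared undefined")
  vars <- if (length(subset) > 1) subset else switch(
    subset,
    all = intersect(habitat_variables(), names(habitat)),
    reduced = reduced_variables_default(),
    depth_only = "mean_depth",
    subset)
  missing_vars <- setdiff(vars, names(habitat))
  if (length(missing_vars)) {
    stop("habitat table lacks variable(s): ", paste(missing_vars, collapse = ", "))
  }
  X <- habitat[, vars, drop = FALSE]
  set.seed(seed)
  n <- nrow(X)
  train <- sort(sample.int(n, max(2, round(split_fraction * n))))
  test <- setdiff(seq_len(n), train)
  model <- randomForest::randomForest(X[train, , drop = FALSE], richness[train],
                                      ntree = ntree)
  pred_all <- predict(model, newdata = X)
  r2 <- function(obs, pred) {
    if (length(obs) < 3 || sd(obs) == 0 || sd(pred) == 0) return(NA_real_)
    cor(obs, pred)^2
  }
  report <- data.frame(
    r2_train = round(r2(richness[train], pred_all[train]), 2),
    r2_test = round(r2(richness[test], pred_all[test]), 2),
    r2_overall = round(r2(richness, pred_all), 2))
  structure(list(model = model, report = report, variables = vars,
                 train_idx = train),
            class = "richness_forest")
}

#' @export
print.richness_forest <- function(x, ...) {
  cat("richness_forest:", length(x$variables), "variables;",
      sprintf("r2 train/test/overall = %.2f/%.2f/%.2f\n",
              x$report$r2_train, x$report$r2_test, x$report$r2_overall))
  invisible(x)
}

#' Gini-importance table
#'
#' Per-variable summed impurity decrease (Gini/node-purity sums over all
#' trees) and its percentage of the total, sorted descending. The
#' percentages sum to 100 up to rounding.
#'
#' @param fit a `richness_forest`.
#' @return data frame with columns `variable`, `gini_sum`,
#'   `percent_of_total`.
#' @export
importance_percent <- function(fit) {
  stopifnot(inherits(fit, "richness_forest"))
  imp <- randomForest::importance(fit$model)
  out <- data.frame(variable = rownames(imp),
                    gini_sum = as.numeric(imp[, "IncNodePurity"]),
                    stringsAsFactors = FALSE)
  out$percent_of_total <- 100 * out$gini_sum / sum(out$gini_sum)
  out <- out[order(-out$gini_sum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select variables for a reduced model by the importance rule
#'
#' Keeps variables whose Gini importance is at least `threshold_percent`
#' of the total, minus explicit exclusions (e.g. shoreline-type variables
#' that are impractical to derive for new sites).
#'
#' @param importance output of [importance_percent()].
#' @param threshold_percent inclusion threshold (default 5).
#' @param exclude character vector of variables to drop regardless.
#' @return character vector of retained variable names.
#' @export
reduced_variable_selection <- function(importance, threshold_percent = 5,
                                       exclude = character()) {
  if (nrow(importance) == 0) stop("empty importance table")
  keep <- importance$variable[importance$percent_of_total >= threshold_percent]
  keep <- setdiff(keep, exclude)
  if (!length(keep)) {
    stop("no variables pass the ", threshold_percent,
         "% importance threshold; lower the threshold")
  }
  keep
}

#' Predict a richness surface over a sample frame
#'
#' Applies a fitted richness forest to the frame's habitat attributes,
#' clamping predictions at 0, and attaches the depth mask so the surface
#' can drive percentile inclusion weights.
#'
#' @param fit a `richness_forest`.
#' @param frame a `sample_frame` carrying all model variables as columns.
#' @param depth_mask_m mask threshold in metres (`Inf` disables).
#' @return a `richness_surface` (see [interpolate_richness()]).
#' @export
predict_surface <- function(fit, frame, depth_mask_m = 6) {
  stopifnot(inherits(fit, "richness_forest"))
  missing_vars <- setdiff(fit$variables, names(frame))
  if (length(missing_vars)) {
    stop("frame lacks model variable(s): ", paste(missing_vars, collapse = ", "))
  }
  vals <- pmax(predict(fit$model, newdata = as.data.frame(frame)[, fit$variables,
                                                                 drop = FALSE]), 0)
  masked <- if ("mean_depth" %in% names(frame) && is.finite(depth_mask_m)) {
    frame$mean_depth > depth_mask_m
  } else rep(FALSE, nrow(frame))
  structure(data.frame(cell_id = frame$cell_id, value = as.numeric(vals),
                       masked = masked, stringsAsFactors = FALSE),
            class = c("richness_surface", "data.frame"))
}
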