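# Synthetic plant community: per-cell species presence driven by depth
# suitability, human-access features and a shared cell-quality driver.

#' Community generator configuration
#'
#' Defaults mirror the community structure observed in Great Lakes coastal
#' plant surveys: a pool of ~50 taxa of which one fifth are non-native;
#' occupancy declining logistically with depth (midpoint 4 m), no
#' occupancy at all beyond a hard 8-m cutoff and little beyond 6 m;
#' heavy-tailed (lognormal) species base occupancies so that any given
#' survey yields uniques and duplicates; a modest richness boost near
#' launches and marinas; and a lognormal cell-quality multiplier shared by
#' native and non-native species, which induces their positive richness
#' correlation.
#'
#' @param S_true species pool size.
#' @param nonnative_fraction fraction of the pool that is non-native.
#' @param depth_midpoint,depth_slope logistic depth-suitability parameters
#'   (metres); suitability is `plogis((depth_midpoint - depth)/depth_slope)`.
#' @param depth_cutoff hard depth cutoff (m): zero occupancy beyond it.
#' @param base_occupancy_meanlog,base_occupancy_sdlog lognormal parameters
#'   of species base occupancy (capped at `base_occupancy_cap`).
#' @param base_occupancy_cap upper cap on base occupancy.
#' @param feature_boost occupancy multiplier within `feature_radius` m of
#'   a launch or marina.
#' @param feature_radius radius (m) of the feature boost.
#' @param quality_sdlog lognormal sd of the shared cell-quality driver.
#' @param growth_form_probs named probabilities for species growth forms
#'   (submerged-dominated, as observed).
#' @param seed RNG seed.
#' @return list of class `community_config`.
#' @export
community_config <- function(S_true = 50, nonnative_fraction = 0.2,
                             depth_midpoint = 4, depth_slope = 1,
                             depth_cutoff = 8,
                             base_occupancy_meanlog = log(0.08),
                             base_occupancy_sdlog = 1.2,
                             base_occupancy_cap = 0.8,
                             feature_boost = 1.5, feature_radius = 300,
                             quality_sdlog = 0.6,
                             growth_form_probs = c(submerged = 0.54,
                                                   emergent = 0.18,
                                                   floating = 0.12,
                                                   free_floating = 0.08,
                                                   other = 0.08),
                             seed = 1) {
  if (nonnative_fraction < 0 || nonnative_fraction > 1) {
    stop("nonnative_fraction must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "community_config")
}

#' Generate a synthetic plant community over a landscape
#'
#' Samples per-cell species presence with occupancy probability
#' `base_occupancy[j] * depth_suitability(cell) * feature_boost(cell) *
#' cell_quality(cell)`, truncated to \[0, 1\] and hard-zeroed beyond the
#' depth cutoff. The cell-quality multiplier is common to every species,
#' so native and non-native per-cell richness share a driver and are
#' positively correlated in surveys.
#'
#' @param landscape frame from [generate_landscape()].
#' @param config a [community_config()].
#' @return object of class `true_community`: list with `presence`
#'   (cell x species logical matrix), `species` (attribute table),
#'   `occupancy` (matrix of probabilities), `S_true` (species present in
#'   at least one cell) and `config`.
#' @export
generate_community <- function(landscape, config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  S <- config$S_true
  n_nn <- round(config$nonnative_fraction * S)
  species <- data.frame(
    code = sprintf("sp%03d", seq_len(S)),
    name = sprintf("Synthetic taxon %d", seq_len(S)),
    origin = rep(c("non_native", "native"), c(n_nn, S - n_nn)),
    growth_form = sample(names(config$growth_form_probs), S, replace = TRUE,
                         prob = config$growth_form_probs),
    stringsAsFactors = FALSE)

  base <- pmin(rlnorm(S, config$base_occupancy_meanlog,
                      config$base_occupancy_sdlog), config$base_occupancy_cap)
  depth <- landscape$mean_depth
  suit <- stats::plogis((config$depth_midpoint - depth) / config$depth_slope)
  suit[depth > config$depth_cutoff] <- 0
  feat <- pmin(landscape$dist_boat_launch, landscape$dist_marina) <=
    config$feature_radius
  boost <- ifelse(feat, config$feature_boost, 1)
  quality <- rlnorm(nrow(landscape), 0, config$quality_sdlog)
  occupancy <- outer(suit * boost * quality, base)
  occupancy <- pmin(occupancy, 1)
  presence <- matrix(rbinom(length(occupancy), 1, occupancy) == 1,
                     nrow = nrow(landscape),
                     dimnames = list(landscape$cell_id, species$code))
  structure(list(presence = presence, species = species,
                 occupancy = occupancy,
                 S_true = sum(colSums(presence) > 0), config = config),
            class = "true_community")
}

#' @export
print.true_community <- function(x, ...) {
  cat("true_community:", nrow(x$presence), "cells x", ncol(x$presence),
      "species;", x$S_true, "species present\n")
  invisible(x)
}
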