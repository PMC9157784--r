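# End-to-end desk-scale experiments: estimator recovery against known true
# richness, and adaptive (two-stage, richness-weighted) versus dispersed
# single-stage designs at equal total effort.

#' Chao2 recovery experiment against simulated truth
#'
#' For each sampling effort in `m_values`, repeatedly (over `n_seeds`
#' seeded replicates) generates a community on the landscape, draws a
#' dispersed spatially balanced sample of that size, simulates the
#' rake-toss survey, estimates richness with [chao2()] (variant chosen by
#' the ICE rule) and scores it against the community's true richness.
#'
#' @param m_values integer vector of sample sizes.
#' @param n_seeds replicates per sample size.
#' @param landscape a landscape frame (shared across replicates).
#' @param community_cfg,observation_cfg configs whose seeds are re-derived
#'   per replicate.
#' @param base_seed integer; replicate seeds are derived from it.
#' @return list with `runs` (data frame `m`, `seed`, `Sobs`, `Sest`,
#'   `S_true`, `bias`, `covered`) and `summary` (per `m`: median bias —
#'   true minus estimated richness, so positive means underestimation —
#'   median absolute bias, and CI coverage of `S_true`).
#' @export
recovery_experiment <- function(m_values = c(20, 80), n_seeds = 200,
                                landscape = generate_landscape(),
                                community_cfg = community_config(),
                                observation_cfg = observation_config(),
                                base_seed = 1) {
  runs <- list()
  frame <- landscape
  frame$weight <- 1
  for (mi in seq_along(m_values)) {
    m <- m_values[mi]
    for (s in seq_len(n_seeds)) {
      seed <- (base_seed + 7919L * mi + s) %% .Machine$integer.max
      ccfg <- community_cfg; ccfg$seed <- seed
      ocfg <- observation_cfg; ocfg$seed <- seed + 1L
      comm <- generate_community(landscape, ccfg)
      sel <- spatially_balanced_sample(frame, m, seed = seed + 2L)
      inc <- survey_incidence(comm, landscape, sel$cell_id, ocfg)
      est <- chao2(inc)
      runs[[length(runs) + 1L]] <- data.frame(
        m = m, seed = seed, Sobs = est$counts$Sobs, Sest = est$Sest,
        S_true = comm$S_true, bias = comm$S_true - est$Sest,
        covered = est$ci_low <= comm$S_true & comm$S_true <= est$ci_high)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$m), function(d) {
    data.frame(m = d$m[1], median_bias = median(d$bias),
               median_abs_bias = median(abs(d$bias)),
               ci_coverage = mean(d$covered))
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ[order(summ$m), , drop = FALSE])
}

#' Adaptive two-stage versus dispersed design at equal effort
#'
#' Pairs, over seeded replicates, (a) a single-stage dispersed spatially
#' balanced design of `2 * stage_n` units against (b) a two-stage design:
#' `stage_n` dispersed units, an inverse-distance richness surface
#' interpolated from their observed richness, percentile inclusion
#' weights from that surface (with the depth mask), and a second
#' spatially balanced stage of `stage_n` further units. The comparison
#' metric is the number of distinct species detected by each design.
#'
#' @param n_seeds number of paired replicates.
#' @param stage_n units per stage.
#' @param landscape,community_cfg,observation_cfg as in
#'   [recovery_experiment()].
#' @param depth_mask_m depth mask for the stage-two surface.
#' @param base_seed integer seed root.
#' @return list with `runs` (per seed: species detected by each design)
#'   and `adaptive_wins` (fraction of replicates where the adaptive
#'   design detected at least as many species).
#' @export
adaptive_design_experiment <- function(n_seeds = 200, stage_n = 30,
                                       landscape = generate_landscape(),
                                       community_cfg = community_config(),
                                       observation_cfg = observation_config(),
                                       depth_mask_m = 6, base_seed = 1) {
  frame <- landscape
  frame$weight <- 1
  runs <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    seed <- (base_seed + 104729L + s * 13L) %% .Machine$integer.max
    ccfg <- community_cfg; ccfg$seed <- seed
    ocfg <- observation_cfg
    comm <- generate_community(landscape, ccfg)

    # single-stage dispersed design
    ocfg$seed <- seed + 1L
    disp <- spatially_balanced_sample(frame, 2 * stage_n, seed = seed + 2L)
    inc_d <- survey_incidence(comm, landscape, disp$cell_id, ocfg)
    disp_S <- sum(colSums(inc_d$presence) > 0)

    # two-stage adaptive design: dispersed stage 1, richness-weighted stage 2
    ocfg$seed <- seed + 3L
    st1 <- spatially_balanced_sample(frame, stage_n, seed = seed + 4L)
    inc_1 <- survey_incidence(comm, landscape, st1$cell_id, ocfg)
    rich1 <- data.frame(cell_id = rownames(inc_1$presence),
                        richness = rowSums(inc_1$presence))
    surf <- interpolate_richness(rich1, frame, method = "idw",
                                 depth_mask_m = depth_mask_m)
    frame2 <- assign_weights(frame, "percentile_surface", surface = surf)
    frame2$weight[frame2$cell_id %in% st1$cell_id] <- 0
    st2 <- spatially_balanced_sample(frame2, stage_n, seed = seed + 5L)
    ocfg$seed <- seed + 6L
    inc_2 <- survey_incidence(comm, landscape, st2$cell_id, ocfg)
    adapt_S <- sum((colSums(inc_1$presence) + colSums(inc_2$presence)) > 0)

    runs[[s]] <- data.frame(seed = seed, dispersed_S = disp_S,
                            adaptive_S = adapt_S)
  }
  runs <- do.call(rbind, runs)
  list(runs = runs, adaptive_wins = mean(runs$adaptive_S >= runs$dispersed_S))
}
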