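# Synthetic coastal landscape generator: a gridded sample frame with a
# depth field increasing away from a shoreline, shoreline typing, and
# human-access features (boat launches, marinas, docks), populating the
# full habitat attribute set used by the richness models.

#' Landscape generator configuration
#'
#' Defaults emulate a mid-sized Great Lakes coastal site: an 800-cell
#' (4 km x 2 km) frame of 100-m cells with the shoreline along the
#' southern edge, depth increasing lakeward to about 10 m with metre-scale
#' noise, a littoral fraction shrinking with depth, and a small number of
#' boat launches and marinas on the shore.
#'
#' @param nx,ny grid dimensions (cells).
#' @param cell_size cell side in metres.
#' @param max_depth depth at the far (lakeward) edge in metres.
#' @param depth_shape exponent of the depth profile in shore distance.
#' @param depth_noise_sd standard deviation of depth noise (m).
#' @param littoral_depth depth (m) at which the littoral fraction of a
#'   cell reaches zero.
#' @param shallow_zone_depth depth threshold (m) splitting the frame into
#'   `shallow`/`deep` zones.
#' @param n_launches,n_marinas number of boat launches / marinas placed on
#'   the shoreline (at least one of each when features are enabled).
#' @param shore_radius radius (m) for neighbourhood shoreline percentages.
#' @param seed RNG seed.
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(nx = 40, ny = 20, cell_size = 100,
                             max_depth = 10, depth_shape = 1,
                             depth_noise_sd = 0.5, littoral_depth = 6,
                             shallow_zone_depth = 4,
                             n_launches = 2, n_marinas = 2,
                             shore_radius = 500, seed = 1) {
  if (nx < 2 || ny < 2) stop("degenerate grid dimensions")
  if (n_launches < 1 || n_marinas < 1) stop("need at least one launch and one marina")
  structure(as.list(environment()), class = "landscape_config")
}

#' Generate a synthetic coastal landscape
#'
#' Builds a [build_frame()] grid whose cells carry a synthetic but
#' spatially coherent habitat: depth increases with distance from the
#' shoreline (southern edge) plus seeded noise, shoreline segments are
#' typed soft/moderate/hard in arcs with dock runs in the harbour third,
#' and launches/marinas sit on the shore. All habitat variables of
#' [habitat_variables()] are populated per cell; distances are measured
#' from the shoreward cell edge.
#'
#' @param config a [landscape_config()].
#' @return a `sample_frame` with habitat columns, zone labels
#'   (`shallow`/`deep`) and attribute `features` (launch/marina/dock
#'   positions).
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  cs <- config$cell_size
  frame <- build_frame(c(0, config$nx * cs, 0, config$ny * cs), cell_size = cs)
  Lx <- config$nx * cs; Ly <- config$ny * cs

  shore_dist <- frame$y                    # shoreline along y = 0
  depth <- config$max_depth * (shore_dist / Ly)^config$depth_shape +
    rnorm(nrow(frame), 0, config$depth_noise_sd)
  frame$mean_depth <- pmax(depth, 0.1)
  frame$max_depth <- frame$mean_depth + 0.5
  frame$zone <- ifelse(frame$mean_depth < config$shallow_zone_depth,
                       "shallow", "deep")
  frame$pct_littoral <- 100 * pmin(pmax(1 - frame$mean_depth / config$littoral_depth, 0), 1)
  # longest open-water run: the shoreline blocks south, other edges open water
  frame$max_fetch <- pmax(frame$x, Lx - frame$x, Ly - frame$y)

  # shoreline segments, one per column of cells
  seg_x <- (seq_len(config$nx) - 0.5) * cs
  third <- ceiling(config$nx / 3)
  seg_type <- rep(c("soft", "moderate", "hard"),
                  c(third, third, config$nx - 2 * third))
  docked <- seq_len(config$nx) > 2 * third      # docks along the hard arc
  lots <- docked & (seq_len(config$nx) %% 2 == 0)

  edge_dist <- function(px) {
    # distance from the shoreward cell edge to shoreline points at y = 0
    d <- sqrt(outer(frame$x, px, "-")^2 + outer(frame$y - cs / 2, rep(0, length(px)), "-")^2)
    apply(d, 1, min)
  }
  frame$dist_soft_shore <- edge_dist(seg_x[seg_type == "soft"])
  frame$dist_moderate_shore <- edge_dist(seg_x[seg_type == "moderate"])
  frame$dist_hard_shore <- edge_dist(seg_x[seg_type == "hard"])
  frame$dist_any_shore <- pmin(frame$dist_soft_shore, frame$dist_moderate_shore,
                               frame$dist_hard_shore)
  # neighbourhood shoreline composition around the nearest shore point
  near_seg <- vapply(frame$x, function(x) which.min(abs(seg_x - x)), integer(1))
  in_radius <- abs(outer(seg_x[near_seg], seg_x, "-")) <= config$shore_radius
  comp <- function(flag) {
    100 * rowSums(sweep(in_radius, 2, flag, "&")) / rowSums(in_radius)
  }
  frame$pct_soft_shore <- comp(seg_type == "soft")
  frame$pct_moderate_shore <- comp(seg_type == "moderate")
  frame$pct_hard_shore <- comp(seg_type == "hard")
  frame$pct_docks <- comp(docked)
  frame$pct_lots_docks <- comp(lots)
  frame$prop_shore_to_water <- rowSums(in_radius) * cs /
    (pi * config$shore_radius^2 / 1e4) / 100
  docked_mid <- if (any(docked)) mean(seg_x[docked]) else Lx / 2
  frame$mid_dist_docked_shore <- sqrt((frame$x - docked_mid)^2 +
                                        (frame$y - cs / 2)^2)
  frame$dist_lots_docks <- if (any(lots)) edge_dist(seg_x[lots]) else
    rep(sqrt(Lx^2 + Ly^2), nrow(frame))

  launch_x <- seg_x[round(seq(1, config$nx, length.out = config$n_launches + 2))[
    2:(config$n_launches + 1)]]
  marina_x <- seg_x[pmax(1, round(config$nx * seq(0.8, 0.95,
                                                  length.out = config$n_marinas)))]
  frame$dist_boat_launch <- edge_dist(launch_x)
  frame$dist_marina <- edge_dist(marina_x)
  frame$large_marina <- as.integer(frame$dist_marina <= config$shore_radius)

  attr(frame, "features") <- list(launch_x = launch_x, marina_x = marina_x,
                                  seg_x = seg_x, seg_type = seg_type,
                                  docked = docked, lots = lots)
  attr(frame, "config") <- config
  frame
}
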