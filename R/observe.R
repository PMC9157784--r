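# Observation model: the station/rake-toss sampling process within each
# selected sample unit, with its minimum-effort stop rule.

#' Observation process configuration
#'
#' Four discrete stations per sample unit (the cell corners), a minimum of
#' four rake tosses per station, and per-toss per-species detection
#' probabilities given presence. Floating and emergent growth forms also
#' get one visual-detection chance per station (the boat crew scans the
#' water surface while raking); the visual rates are free parameters of
#' the simulator, not field-estimated quantities.
#'
#' @param stations stations per sample unit.
#' @param min_tosses minimum rake tosses per station.
#' @param max_tosses safety cap on tosses per station.
#' @param p_toss per-toss detection probability of a present species.
#' @param p_visual per-station visual detection probability for floating,
#'   free-floating and emergent growth forms.
#' @param seed RNG seed.
#' @return list of class `observation_config`.
#' @export
observation_config <- function(stations = 4, min_tosses = 4, max_tosses = 20,
                               p_toss = 0.3, p_visual = 0.35, seed = 1) {
  if (min_tosses < 1) stop("need at least one toss per station")
  if (p_toss < 0 || p_toss > 1 || p_visual < 0 || p_visual > 1) {
    stop("detection probabilities must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "observation_config")
}

#' Simulate the rake-toss survey of selected cells
#'
#' For each selected cell, visits `stations` discrete stations; at each
#' station the crew makes rake tosses, each detecting every species
#' present in the cell independently with probability `p_toss`, plus one
#' visual scan for surface-visible growth forms. Tossing continues past
#' the minimum while the most recent toss yielded a species new to that
#' station (the stop rule), up to `max_tosses`. With `p_toss = 1` the
#' fourth toss never adds a new species, so effort stays at the minimum.
#'
#' @param community a `true_community`.
#' @param cells vector of selected `cell_id`s (or a selection data
#'   frame). Cells with no plants still appear in the output's unit set.
#' @param config an [observation_config()].
#' @return list with `records` (long data frame `unit_id`, `station_id`,
#'   `species_code` — one row per station-level detection), `units`
#'   (unit table covering every surveyed cell) and `effort` (data frame of
#'   tosses per station).
#' @export
simulate_survey <- function(community, cells, config = observation_config()) {
  stopifnot(inherits(community, "true_community"))
  if (is.data.frame(cells)) cells <- cells$cell_id
  cells <- as.character(cells)
  if (!all(cells %in% rownames(community$presence))) {
    stop("selected cells missing from the community")
  }
  set.seed(config$seed)
  visual_forms <- c("floating", "free_floating", "emergent")
  visual <- community$species$growth_form %in% visual_forms
  codes <- community$species$code
  rec <- vector("list", length(cells))
  effort <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    present <- which(community$presence[cells[ci], ])
    unit_rows <- list()
    tosses_used <- integer(config$stations)
    for (st in seq_len(config$stations)) {
      found <- logical(length(present))
      if (length(present)) {
        # visual scan
        vis <- visual[present] & runif(length(present)) < config$p_visual
        found <- found | vis
        t <- 0L
        repeat {
          t <- t + 1L
          hit <- runif(length(present)) < config$p_toss
          new_hit <- any(hit & !found)
          found <- found | hit
          if (t >= config$max_tosses) break
          if (t >= config$min_tosses && !new_hit) break
        }
        tosses_used[st] <- t
      } else {
        tosses_used[st] <- config$min_tosses
      }
      if (any(found)) {
        unit_rows[[st]] <- data.frame(
          unit_id = cells[ci], station_id = paste0("s", st),
          species_code = codes[present[found]], stringsAsFactors = FALSE)
      }
    }
    rec[[ci]] <- if (length(unit_rows)) do.call(rbind, unit_rows) else NULL
    effort[[ci]] <- data.frame(unit_id = cells[ci],
                               station_id = paste0("s", seq_len(config$stations)),
                               tosses = tosses_used, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  if (is.null(records)) {
    records <- data.frame(unit_id = character(), station_id = character(),
                          species_code = character(), stringsAsFactors = FALSE)
  }
  units <- data.frame(unit_id = cells, stringsAsFactors = FALSE)
  list(records = records, units = units, effort = do.call(rbind, effort))
}

#' Survey a selection and aggregate to an incidence matrix
#'
#' Convenience wrapper: [simulate_survey()] then [read_incidence()], using
#' the community's species table and the landscape's cell attributes.
#'
#' @param community a `true_community`.
#' @param landscape the landscape frame the community was generated on.
#' @param cells selected cell ids (or selection data frame).
#' @param config an [observation_config()].
#' @return an `incidence_matrix`.
#' @export
survey_incidence <- function(community, landscape, cells,
                             config = observation_config()) {
  sv <- simulate_survey(community, cells, config)
  units <- landscape[match(sv$units$unit_id, landscape$cell_id),
                     intersect(c("cell_id", "x", "y", "zone", "mean_depth",
                                 "max_depth"), names(landscape)), drop = FALSE]
  names(units)[names(units) == "cell_id"] <- "unit_id"
  read_incidence(sv$records, community$species, units)
}
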