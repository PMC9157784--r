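# Sample-frame construction and inclusion-weight assignment for gridded
# coastal survey designs.

#' Build a gridded sample frame
#'
#' Overlays an axis-aligned grid of square cells (default 100 m per side)
#' on a rectangular extent, optionally dropping masked cells (e.g. land),
#' and assigns each cell to exactly one zone. Cells are addressed by their
#' lower-left corner on half-open intervals; centroids are reported.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size side length in metres (> 0).
#' @param zones either `NULL` (all cells `"unzoned"`), a function
#'   `f(x, y)` of centroid coordinates returning a zone label per cell, or
#'   a vector of labels of length equal to the number of (unmasked) cells.
#' @param mask optional function `f(x, y)` returning `TRUE` for cells to
#'   *keep*, or a logical vector over the grid (row-major, x fastest).
#' @return object of class `sample_frame`: a data frame with columns
#'   `cell_id`, `x`, `y` (centroids), `row`, `col`, `zone`, `weight`
#'   (initialised to 1), and attribute `cell_size`.
#' @export
build_frame <- function(extent, cell_size = 100, zones = NULL, mask = NULL) {
  if (cell_size <= 0) stop("cell size must be positive")
  if (length(extent) != 4) stop("extent must be c(xmin, xmax, ymin, ymax)")
  nx <- floor((extent[2] - extent[1]) / cell_size)
  ny <- floor((extent[4] - extent[3]) / cell_size)
  if (nx < 1 || ny < 1) stop("extent is empty at this cell size")
  g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  x <- extent[1] + (g$col - 0.5) * cell_size
  y <- extent[3] + (g$row - 0.5) * cell_size
  keep <- rep(TRUE, nrow(g))
  if (is.function(mask)) keep <- mapply(mask, x, y)
  else if (!is.null(mask)) keep <- as.logical(mask)
  frame <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(g))),
                      x = x, y = y, row = g$row, col = g$col,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (is.function(zones)) {
    frame$zone <- as.character(mapply(zones, frame$x, frame$y))
  } else if (!is.null(zones)) {
    if (length(zones) != nrow(frame)) stop("zones vector length mismatch")
    frame$zone <- as.character(zones)
  } else {
    frame$zone <- "unzoned"
  }
  if (anyNA(frame$zone)) stop("every cell needs a zone label")
  frame$weight <- 1
  rownames(frame) <- NULL
  attr(frame, "cell_size") <- cell_size
  class(frame) <- c("sample_frame", "data.frame")
  frame
}

#' Default percentile-to-weight map for richness surfaces
#'
#' Inclusion weights by percentile class of the predicted richness
#' surface: cells at or above the 90th percentile get weight 0.6, then
#' 0.5, 0.4, 0.3 and 0.2 for each decile down to the 50th, and 0.1 below
#' the 50th percentile.
#'
#' @param breaks percentile lower bounds, descending.
#' @param weights inclusion weights for each class, with one extra final
#'   value for cells below the last break.
#' @return object of class `weight_map`.
#' @export
weight_map <- function(breaks = c(90, 80, 70, 60, 50),
                       weights = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1)) {
  if (length(weights) != length(breaks) + 1) {
    stop("need one more weight than breaks (the below-last-break class)")
  }
  if (is.unsorted(rev(breaks))) stop("breaks must be descending")
  if (any(diff(weights) > 0)) stop("weights must be non-increasing")
  if (any(weights <= 0 | weights > 1)) stop("weights must lie in (0, 1]")
  structure(list(breaks = breaks, weights = weights), class = "weight_map")
}

#' Assign inclusion weights to a sample frame
#'
#' Three weighting modes mirror the stages of an adaptive survey:
#' \describe{
#'   \item{`uniform`}{equal weight everywhere (dispersed first-year
#'     design).}
#'   \item{`zone_allocation`}{expected sampling effort split between zones
#'     in fixed proportions (e.g. 75% shallow / 25% deep): each cell in
#'     zone `z` gets weight proportional to `alloc[z] / n_cells[z]`.}
#'   \item{`percentile_surface`}{cells are ranked by a predicted richness
#'     surface over unmasked cells and weighted through a [weight_map()];
#'     a cell's percentile is the percentage of unmasked cells with
#'     strictly smaller surface value. Masked (e.g. too-deep) cells get
#'     the minimum weight or are dropped.}
#' }
#' Weights are rescaled to a maximum of 1 (relative inclusion
#' probabilities; [spatially_balanced_sample()] normalises to the sample
#' size).
#'
#' @param frame a `sample_frame`.
#' @param mode one of `"uniform"`, `"zone_allocation"`,
#'   `"percentile_surface"`.
#' @param allocation named numeric vector of zone shares (sums to 1) for
#'   `zone_allocation` mode. Zones absent from the vector share the
#'   remaining allocation equally.
#' @param surface a `richness_surface` (see [interpolate_richness()] /
#'   [predict_surface()]) for `percentile_surface` mode.
#' @param map a [weight_map()].
#' @param masked one of `"min_weight"` (default: masked cells keep the
#'   lowest map weight) or `"exclude"` (masked cells are removed).
#' @return the frame with its `weight` column replaced (and a
#'   `weight_class` column in percentile mode).
#' @export
assign_weights <- function(frame, mode = c("uniform", "zone_allocation",
                                           "percentile_surface"),
                           allocation = NULL, surface = NULL,
                           map = weight_map(), masked = c("min_weight", "exclude")) {
  mode <- match.arg(mode)
  masked <- match.arg(masked)
  if (mode == "uniform") {
    frame$weight <- 1
    return(frame)
  }
  if (mode == "zone_allocation") {
    if (is.null(allocation)) stop("zone_allocation mode needs an allocation vector")
    zones <- unique(frame$zone)
    alloc <- allocation[intersect(names(allocation), zones)]
    if (sum(alloc) > 1 + 1e-9) stop("zone allocations sum to more than 1")
    rest <- setdiff(zones, names(alloc))
    if (length(rest)) alloc <- c(alloc, setNames(rep((1 - sum(alloc)) / length(rest),
                                                     length(rest)), rest))
    ncell <- table(frame$zone)
    w <- alloc[frame$zone] / as.numeric(ncell[frame$zone])
    frame$weight <- as.numeric(w / max(w))
    return(frame)
  }
  # percentile_surface
  if (is.null(surface)) stop("percentile_surface mode needs a richness surface")
  v <- surface$value[match(frame$cell_id, surface$cell_id)]
  msk <- surface$masked[match(frame$cell_id, surface$cell_id)]
  msk[is.na(msk)] <- TRUE
  if (masked == "exclude") {
    frame <- frame[!msk, , drop = FALSE]
    v <- v[!msk]; msk <- msk[!msk]
  }
  w <- rep(map$weights[length(map$weights)], nrow(frame))
  cls <- rep(sprintf("<%gth", map$breaks[length(map$breaks)]), nrow(frame))
  un <- which(!msk)
  if (length(un)) {
    vv <- v[un]
    pct <- 100 * (rank(vv, ties.method = "min") - 1) / length(vv)
    # class 1 = at/above the first break, ..., last class = below the last
    idx <- length(map$breaks) + 1 - findInterval(pct, rev(map$breaks))
    w[un] <- map$weights[idx]
    lbl <- c(sprintf(">=%gth", map$breaks), sprintf("<%gth", map$breaks[length(map$breaks)]))
    cls[un] <- lbl[idx]
  }
  frame$weight <- w
  frame$weight_class <- cls
  rownames(frame) <- NULL
  frame
}

#' Summarise spatial coverage of a selection
#'
#' Per zone (or per weight class): number of frame cells, number selected,
#' the proportion selected, and the zone area in hectares.
#'
#' @param frame a `sample_frame`.
#' @param selection a selection as returned by
#'   [spatially_balanced_sample()], or a vector of selected `cell_id`s.
#' @param by grouping column, default `"zone"`.
#' @return data frame with columns `zone`, `cells`, `cells_surveyed`,
#'   `proportion`, `area_ha`.
#' @export
design_summary <- function(frame, selection, by = "zone") {
  ids <- if (is.data.frame(selection)) selection$cell_id else as.character(selection)
  cell_ha <- attr(frame, "cell_size")^2 / 1e4
  grp <- frame[[by]]
  agg <- lapply(split(seq_len(nrow(frame)), grp), function(i) {
    data.frame(cells = length(i),
               cells_surveyed = sum(frame$cell_id[i] %in% ids))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(zone = names(agg), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$proportion <- ifelse(out$cells > 0, out$cells_surveyed / out$cells, 0)
  out$area_ha <- out$cells * cell_ha
  names(out)[1] <- by
  out
}
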