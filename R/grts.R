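# Spatially balanced (GRTS) sample selection: quadrant-recursive
# hierarchical randomization of cell addresses, systematic selection with
# probability proportional to inclusion weight, and reverse-hierarchical
# ordering so that any prefix of the output is itself spatially balanced.

# Base-4 quadrant digits of each cell from its grid row/col (level 1 is the
# coarsest quadrant split).
quadrant_digits <- function(frame, k) {
  c0 <- frame$col - 1L
  r0 <- frame$row - 1L
  digits <- matrix(0L, nrow(frame), k)
  for (l in seq_len(k)) {
    sh <- k - l
    xb <- bitwAnd(bitwShiftR(c0, sh), 1L)
    yb <- bitwAnd(bitwShiftR(r0, sh), 1L)
    digits[, l] <- 2L * yb + xb
  }
  digits
}

# Independently permute the four child quadrants of every node of the
# address tree; returns the randomized digit matrix.
randomize_addresses <- function(digits) {
  k <- ncol(digits)
  n <- nrow(digits)
  rand <- digits
  recurse <- function(idx, level) {
    if (level > k || length(idx) <= 1) return(invisible(NULL))
    perm <- sample.int(4L) - 1L          # new digit for original digit 0..3
    rand[idx, level] <<- perm[digits[idx, level] + 1L]
    for (d in 0:3) {
      child <- idx[digits[idx, level] == d]
      if (length(child) > 1) recurse(child, level + 1L)
    }
    invisible(NULL)
  }
  recurse(seq_len(n), 1L)
  rand
}

address_rank <- function(addr) {
  # lexicographic rank of base-4 address rows
  do.call(order, lapply(seq_len(ncol(addr)), function(j) addr[, j]))
}

# Cap inclusion probabilities at 1, redistributing the excess.
inclusion_probs <- function(w, n) {
  pi <- rep(0, length(w))
  active <- w > 0
  if (n > sum(active)) stop("n exceeds the number of positive-weight cells")
  repeat {
    pi[active] <- (n - sum(!active & pi == 1)) * w[active] / sum(w[active])
    over <- active & pi >= 1
    if (!any(pi[active] > 1)) break
    pi[over] <- 1
    active <- active & !over
    if (!any(active)) break
  }
  pi[pi > 1] <- 1
  pi
}

#' Spatially balanced (GRTS) sample from a weighted frame
#'
#' Draws `n` cells with inclusion probability proportional to the frame's
#' `weight` column using generalized random tessellation stratified
#' sampling: cells receive quadrant-recursive hierarchical addresses whose
#' digits are independently permuted at every node of the quadrant tree,
#' the cells are mapped to a line in randomized-address order, and a
#' systematic sample of unit steps with a random start selects cells along
#' that line. Selected cells are returned in reverse-hierarchical order,
#' so any prefix of the output is itself a spatially balanced sample.
#'
#' @param frame a `sample_frame` with positive weights on selectable
#'   cells.
#' @param n sample size (at most the number of positive-weight cells).
#' @param seed integer RNG seed (mandatory: designs must be reproducible).
#' @return data frame of the selected rows of `frame` with an added
#'   `selected_order` column (reverse-hierarchical position) and `pi`
#'   (inclusion probability). The full frame's reverse-hierarchical cell
#'   order is attached as attribute `rho_all` for zone-repair reserves.
#' @export
spatially_balanced_sample <- function(frame, n, seed) {
  stopifnot(inherits(frame, "data.frame"), n >= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  k <- max(1L, ceiling(log2(max(frame$row, frame$col))))
  digits <- quadrant_digits(frame, k)
  rand <- randomize_addresses(digits)
  ord <- address_rank(rand)                       # randomized address order
  pi <- inclusion_probs(frame$weight, n)
  cum <- cumsum(pi[ord])
  u <- runif(1)
  hits <- findInterval(u + seq_len(n) - 1, c(0, cum), rightmost.closed = FALSE)
  hits <- unique(hits[hits >= 1 & hits <= length(ord)])
  sel_idx <- ord[hits]
  # reverse-hierarchical ordering
  rev_addr <- rand[, rev(seq_len(k)), drop = FALSE]
  rho_full <- do.call(order, lapply(seq_len(k), function(j) rev_addr[, j]))
  rho_pos <- match(seq_len(nrow(frame)), rho_full)
  sel_idx <- sel_idx[order(rho_pos[sel_idx])]
  out <- frame[sel_idx, , drop = FALSE]
  out$pi <- pi[sel_idx]
  out$selected_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "rho_all") <- frame$cell_id[rho_full]
  attr(out, "cell_size") <- attr(frame, "cell_size")
  out
}

#' Enforce a per-zone minimum on a selection
#'
#' Guarantees each zone at least `ceiling(min_zone_fraction * basis)`
#' selected cells, where the basis is either the zone's total frame size
#' (the "at least ten percent of the sample units in a zone" rule) or the
#' overall selection size. Deficits are filled by continuing the
#' deficient zone's reverse-hierarchical order (the reserve attached to
#' the selection); when `keep_n = TRUE`, cells are dropped from the tail
#' of the selection, only from zones above their minimum, to preserve the
#' total.
#'
#' @param selection output of [spatially_balanced_sample()].
#' @param frame the frame the selection was drawn from.
#' @param min_zone_fraction minimum fraction in \[0, 1).
#' @param basis `"zone_frame"` (default) or `"selection"`.
#' @param keep_n keep the total selection size fixed.
#' @return adjusted selection (same columns; `selected_order` renumbered).
#' @export
enforce_zone_minimum <- function(selection, frame, min_zone_fraction = 0.10,
                                 basis = c("zone_frame", "selection"),
                                 keep_n = TRUE) {
  basis <- match.arg(basis)
  if (min_zone_fraction < 0 || min_zone_fraction >= 1) {
    stop("min_zone_fraction must lie in [0, 1)")
  }
  rho_all <- attr(selection, "rho_all")
  if (is.null(rho_all)) stop("selection lacks the reverse-hierarchical reserve")
  n <- nrow(selection)
  zones <- sort(unique(frame$zone))
  zone_cells <- table(factor(frame$zone, levels = zones))
  need <- if (basis == "zone_frame") {
    ceiling(min_zone_fraction * as.numeric(zone_cells))
  } else {
    rep(ceiling(min_zone_fraction * n), length(zones))
  }
  names(need) <- zones
  need <- pmin(need, as.numeric(zone_cells))
  if (keep_n && sum(need) > n) {
    stop("infeasible zone minimum; zones: ", paste(zones, collapse = ", "))
  }
  sel_ids <- selection$cell_id
  frame_zone <- setNames(frame$zone, frame$cell_id)
  repeat {
    have <- table(factor(frame_zone[sel_ids], levels = zones))
    deficit <- need - as.numeric(have)
    if (all(deficit <= 0)) break
    z <- zones[which(deficit > 0)[1]]
    reserve <- rho_all[frame_zone[rho_all] == z & !(rho_all %in% sel_ids)]
    if (!length(reserve)) stop("infeasible zone minimum; zones: ", z)
    sel_ids <- c(sel_ids, reserve[1])
    if (keep_n && length(sel_ids) > n) {
      # drop the last-ordered selected cell from a zone above its minimum
      have2 <- table(factor(frame_zone[sel_ids], levels = zones))
      droppable <- rev(sel_ids)[vapply(rev(sel_ids), function(id) {
        zz <- frame_zone[[id]]
        have2[[zz]] > need[[zz]]
      }, logical(1))]
      if (!length(droppable)) stop("infeasible zone minimum: nothing droppable")
      sel_ids <- setdiff(sel_ids, droppable[1])
    }
  }
  keep_order <- c(selection$cell_id[selection$cell_id %in% sel_ids],
                  setdiff(sel_ids, selection$cell_id))
  out <- frame[match(keep_order, frame$cell_id), , drop = FALSE]
  out$pi <- selection$pi[match(keep_order, selection$cell_id)]
  out$selected_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "rho_all") <- rho_all
  attr(out, "cell_size") <- attr(selection, "cell_size")
  out
}

#' Simple random sample from a frame (comparison baseline)
#'
#' @param frame a `sample_frame`.
#' @param n sample size.
#' @param seed RNG seed.
#' @return selected rows of the frame.
#' @export
srs_sample <- function(frame, n, seed) {
  set.seed(seed)
  out <- frame[sample.int(nrow(frame), n), , drop = FALSE]
  out$selected_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "cell_size") <- attr(frame, "cell_size")
  out
}

#' Voronoi spatial-balance metric
#'
#' Assigns every frame cell to its nearest selected cell and returns the
#' variance of the resulting cell counts across selected cells. Perfectly
#' spread samples give low variance; clumped samples give high variance.
#'
#' @param frame a `sample_frame`.
#' @param selection selection data frame or vector of `cell_id`s.
#' @return variance of nearest-neighbour cell counts.
#' @export
spatial_balance_variance <- function(frame, selection) {
  ids <- if (is.data.frame(selection)) selection$cell_id else as.character(selection)
  sel <- frame[match(ids, frame$cell_id), , drop = FALSE]
  d2 <- outer(frame$x, sel$x, "-")^2 + outer(frame$y, sel$y, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  counts <- tabulate(nearest, nbins = nrow(sel))
  var(counts)
}
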