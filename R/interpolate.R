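# Richness surfaces: inverse-distance weighting (reference method) and a
# simple ordinary-kriging option, with a depth mask for cells too deep to
# support plants.

#' Interpolate a species-richness surface over a frame
#'
#' Builds a full-frame predicted richness surface from richness observed
#' at sampled cells. Inverse-distance weighting (IDW) is the reference
#' method: it is an exact interpolator (the surface equals the
#' observation at an observed cell) and needs no model fitting. Ordinary
#' kriging with an exponential variogram (moment-fitted) is available as
#' an option; with all observations identical no variogram is fitted and
#' the constant surface is returned. Cells with `mean_depth` greater than
#' `depth_mask_m` are flagged as masked — they carry values but no
#' percentile class downstream (plants are not expected there, so survey
#' weight should not be spent on them).
#'
#' @param observed data frame with columns `cell_id` and `richness` (cells
#'   must exist in the frame), or a named vector `cell_id -> richness`.
#' @param frame a `sample_frame`; a `mean_depth` column activates the
#'   depth mask.
#' @param method `"idw"` or `"ordinary_kriging"`.
#' @param power IDW power parameter.
#' @param depth_mask_m mask threshold in metres (`Inf` disables, e.g. for
#'   sites nowhere deeper than the euphotic zone).
#' @return object of class `richness_surface`: data frame with columns
#'   `cell_id`, `value` (>= 0) and `masked`.
#' @export
interpolate_richness <- function(observed, frame,
                                 method = c("idw", "ordinary_kriging"),
                                 power = 2, depth_mask_m = 6) {
  method <- match.arg(method)
  if (!is.data.frame(observed)) {
    observed <- data.frame(cell_id = names(observed), richness = as.numeric(observed),
                           stringsAsFactors = FALSE)
  }
  if (nrow(observed) < 3) stop("need at least 3 observed cells")
  oi <- match(observed$cell_id, frame$cell_id)
  if (anyNA(oi)) stop("observed cells missing from frame: ",
                      paste(observed$cell_id[is.na(oi)], collapse = ", "))
  ox <- frame$x[oi]; oy <- frame$y[oi]; oz <- observed$richness
  if (method == "idw" || var(oz) == 0) {
    d <- sqrt(outer(frame$x, ox, "-")^2 + outer(frame$y, oy, "-")^2)
    vals <- numeric(nrow(frame))
    exact <- apply(d, 1, function(r) {
      hit <- which(r == 0)
      if (length(hit)) hit[1] else NA_integer_
    })
    w <- 1 / d^power
    w[!is.finite(w)] <- 0
    vals <- as.numeric(w %*% oz) / rowSums(w)
    vals[!is.na(exact)] <- oz[exact[!is.na(exact)]]
  } else {
    vals <- krige_exponential(ox, oy, oz, frame$x, frame$y)
  }
  vals <- pmax(vals, 0)
  masked <- if ("mean_depth" %in% names(frame)) {
    frame$mean_depth > depth_mask_m
  } else rep(FALSE, nrow(frame))
  structure(data.frame(cell_id = frame$cell_id, value = vals, masked = masked,
                       stringsAsFactors = FALSE),
            class = c("richness_surface", "data.frame"))
}

# Ordinary kriging with a moment-fitted exponential variogram
# gamma(h) = c0 + c1 * (1 - exp(-h / a)).
krige_exponential <- function(ox, oy, oz, px, py) {
  n <- length(oz)
  h <- as.matrix(dist(cbind(ox, oy)))
  # empirical variogram on binned lags
  ij <- which(upper.tri(h), arr.ind = TRUE)
  lag <- h[ij]; gam <- 0.5 * (oz[ij[, 1]] - oz[ij[, 2]])^2
  brk <- quantile(lag, probs = seq(0, 1, length.out = 8))
  bin <- cut(lag, unique(brk), include.lowest = TRUE)
  gh <- tapply(gam, bin, mean); hh <- tapply(lag, bin, mean)
  ok <- is.finite(gh) & is.finite(hh)
  gh <- gh[ok]; hh <- hh[ok]
  sill <- max(gh); a0 <- max(hh) / 3
  fit <- try(optimise(function(a) {
    sum((gh - sill * (1 - exp(-hh / a)))^2)
  }, interval = c(max(hh) / 100, max(hh) * 3)), silent = TRUE)
  a <- if (inherits(fit, "try-error")) a0 else fit$minimum
  c0 <- 1e-8 * sill; c1 <- sill
  gfun <- function(d) c0 + c1 * (1 - exp(-d / a))
  G <- rbind(cbind(gfun(h), 1), c(rep(1, n), 0))
  diag(G)[seq_len(n)] <- 0
  pd <- sqrt(outer(px, ox, "-")^2 + outer(py, oy, "-")^2)
  rhs <- rbind(t(gfun(pd)), 1)
  lambda <- try(solve(G, rhs), silent = TRUE)
  if (inherits(lambda, "try-error")) {
    lambda <- solve(G + diag(1e-6 * sill, n + 1), rhs)
  }
  as.numeric(t(lambda[seq_len(n), , drop = FALSE]) %*% oz)
}
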