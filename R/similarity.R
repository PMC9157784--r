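# Simplified Morisita (Morisita-Horn) similarity between two surveys'
# species incidence-frequency vectors.

#' Simplified Morisita similarity of two assemblages
#'
#' Morisita--Horn index on incidence-frequency vectors, aligned over the
#' union of species names:
#' \deqn{C_H = \frac{2 \sum_i x_i y_i}
#'   {\left(\sum_i x_i^2 / X^2 + \sum_i y_i^2 / Y^2\right) X Y}}
#' with `X = sum(x)`, `Y = sum(y)`. The index is 1 for identical relative
#' incidence structure, and 0 exactly when no species are shared.
#'
#' @param x,y named numeric vectors of per-species incidence frequencies
#'   (or `incidence_counts`/`incidence_matrix` objects, whose frequency
#'   vectors are used). Species absent from one survey count as zeros.
#' @return list with `index` and `shared_species`.
#' @export
simplified_morisita <- function(x, y) {
  x <- frequency_vector(x)
  y <- frequency_vector(y)
  if (sum(x) <= 0 || sum(y) <= 0) stop("both assemblages must be non-empty")
  sp <- union(names(x), names(y))
  xv <- setNames(numeric(length(sp)), sp); xv[names(x)] <- x
  yv <- setNames(numeric(length(sp)), sp); yv[names(y)] <- y
  X <- sum(xv); Y <- sum(yv)
  index <- 2 * sum(xv * yv) / ((sum(xv^2) / X^2 + sum(yv^2) / Y^2) * X * Y)
  list(index = index, shared_species = sum(xv > 0 & yv > 0))
}

frequency_vector <- function(x) {
  if (inherits(x, "incidence_matrix")) x <- tally_counts(x)
  if (inherits(x, "incidence_counts")) {
    if (is.null(x$per_species)) stop("per-species frequencies required")
    x <- x$per_species
  }
  if (is.null(names(x))) names(x) <- paste0("sp", seq_along(x))
  x[x > 0]
}
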