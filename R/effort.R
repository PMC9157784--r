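# Projection of the additional sampling effort needed to detect a target
# fraction of the estimated species pool (incidence form of the
# nonparametric extrapolation of Chao et al. 2009).

# Classic-variant inputs for effort projection, regardless of which variant
# was reported for Sest: the extrapolation model is derived from the classic
# estimator, and only classic inputs reproduce the published projections.
effort_inputs <- function(estimate) {
  stopifnot(inherits(estimate, "richness_estimate"))
  cts <- estimate$counts
  if (cts$Q2 == 0) {
    stop("effort projection undefined with Q2 = 0; ",
         "no duplicate species to anchor the extrapolation ",
         "(use the bias-corrected estimate qualitatively instead)")
  }
  A <- (cts$m - 1) / cts$m
  Sest <- cts$Sobs + A * cts$Q1^2 / (2 * cts$Q2)
  list(m = cts$m, Sobs = cts$Sobs, Q1 = cts$Q1, Q2 = cts$Q2, A = A,
       Sest = Sest, Q0 = Sest - cts$Sobs)
}

#' Additional samples needed to detect a fraction of the species pool
#'
#' Under the extrapolation model the number of still-undetected species
#' decays exponentially with added effort, at a rate set by the ratio of
#' duplicates to uniques. The additional number of sample units needed to
#' raise detection from `Sobs` to `g * Sest` is
#' \deqn{m_g = \frac{(m-1) Q_1}{2 Q_2}\,
#'   \ln\!\frac{Q_0}{(1 - g)\,S_{est}}}
#' with the classic-variant `Sest` and `Q0 = Sest - Sobs` (the factor
#' `(m-1) = m (m-1)/m` carries the estimator's finite-sample correction
#' into the extrapolation slope). Whenever `Sobs/Sest >= g` no additional
#' effort is needed and 0 is returned.
#'
#' @param estimate a `richness_estimate` (its counts are reused; the
#'   projection always uses classic-variant inputs and requires `Q2 > 0`).
#' @param g target fraction of `Sest` in (0, 1).
#' @param rounded round the result half-to-even to a whole number of
#'   sample units (as reported in survey tables); set `FALSE` for the
#'   continuous value.
#' @return object of class `effort_projection`: list with `g`,
#'   `m_additional`, `Sest`, `Q0`.
#' @export
effort_to_fraction <- function(estimate, g = 0.95, rounded = TRUE) {
  if (length(g) != 1 || g <= 0 || g >= 1) stop("g must lie strictly in (0, 1)")
  inp <- effort_inputs(estimate)
  if (inp$Sobs / inp$Sest >= g) {
    m_add <- 0
  } else {
    m_add <- (inp$m - 1) * inp$Q1 / (2 * inp$Q2) *
      log(inp$Q0 / ((1 - g) * inp$Sest))
    if (rounded) m_add <- round(m_add)
  }
  structure(list(g = g, m_additional = m_add, Sest = inp$Sest, Q0 = inp$Q0),
            class = "effort_projection")
}

#' Additional samples needed for an effectively complete census
#'
#' The exponential-decay model never reaches the asymptote exactly, so a
#' full census (`g = 1`) is operationalised as sampling until the expected
#' number of still-undetected species falls below a small residual
#' `delta = min(0.1, 0.01 * Sest)` species (the cap keeps the census effort
#' at least as large as the `g = 0.99` effort for small pools):
#' \deqn{m_{100} = \frac{(m-1) Q_1}{2 Q_2}\, \ln(Q_0 / \delta)}
#' Published full-census projections computed by other tools agree with
#' this convention only approximately; treat the value as an order of
#' magnitude.
#'
#' @inheritParams effort_to_fraction
#' @return `effort_projection` with `g = 1`.
#' @export
effort_to_census <- function(estimate, rounded = TRUE) {
  inp <- effort_inputs(estimate)
  if (inp$Q0 <= 0) {
    return(structure(list(g = 1, m_additional = 0, Sest = inp$Sest, Q0 = inp$Q0),
                     class = "effort_projection"))
  }
  delta <- min(0.1, 0.01 * inp$Sest)
  m_add <- (inp$m - 1) * inp$Q1 / (2 * inp$Q2) * log(inp$Q0 / delta)
  m_add <- max(m_add, 0)
  if (rounded) m_add <- round(m_add)
  structure(list(g = 1, m_additional = m_add, Sest = inp$Sest, Q0 = inp$Q0),
            class = "effort_projection")
}

#' @export
print.effort_projection <- function(x, ...) {
  cat(sprintf("effort_projection: g = %s -> %s additional sample units\n",
              format(x$g), format(x$m_additional)))
  invisible(x)
}
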