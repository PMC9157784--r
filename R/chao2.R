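# Chao2 incidence-based richness estimation, the ICE heterogeneity rule for
# choosing between the classic and bias-corrected forms, and log-transform
# confidence intervals.

#' Chao2 estimate of total species richness
#'
#' Nonparametric minimum estimator of total richness from replicated
#' incidence data, extrapolating the number of undetected species from the
#' uniques (`Q1`) and duplicates (`Q2`). With `A = (m-1)/m`:
#' \deqn{S_{classic} = S_{obs} + A\,Q_1^2 / (2 Q_2)}
#' \deqn{S_{bc} = S_{obs} + A\,Q_1 (Q_1 - 1) / (2 (Q_2 + 1))}
#' The classic form requires `Q2 > 0`; when requested with `Q2 = 0` the
#' bias-corrected form is used instead, with a warning. When `Q1 = 0` both
#' forms reduce to `Sobs`.
#'
#' The estimator's variance follows the variant-matched formulas of Chao
#' (1987) as implemented in EstimateS, and a 95% interval is attached via
#' the log-transform of the undetected component (see [chao2_ci()]).
#'
#' @param counts an `incidence_counts` object (or an `incidence_matrix`,
#'   which is tallied first).
#' @param variant `"auto"` (choose by the ICE heterogeneity rule, see
#'   [select_variant()]), `"classic"` or `"bias_corrected"`.
#' @param conf confidence level for the interval.
#' @return object of class `richness_estimate`: list with `counts`,
#'   `variant`, `A`, `Sest`, `Q0`, `variance`, `ci_low`, `ci_high`,
#'   `cv_ice`.
#' @export
chao2 <- function(counts, variant = c("auto", "classic", "bias_corrected"),
                  conf = 0.95) {
  variant <- match.arg(variant)
  if (inherits(counts, "incidence_matrix")) counts <- counts_with_minfreq(counts)
  stopifnot(inherits(counts, "incidence_counts"))
  m <- counts$m
  if (m < 2) stop("Chao2 needs at least 2 sample units")
  Sobs <- counts$Sobs; Q1 <- counts$Q1; Q2 <- counts$Q2
  A <- (m - 1) / m
  cv <- tryCatch(ice_cv(counts), error = function(e) NA_real_)
  if (variant == "auto") variant <- select_variant(cv)
  if (variant == "classic" && Q2 == 0 && Q1 > 0) {
    warning("classic Chao2 undefined with Q2 = 0; using bias-corrected form")
    variant <- "bias_corrected"
  }
  if (Q1 == 0) {
    Sest <- as.numeric(Sobs)
    variance <- 0
  } else if (variant == "classic") {
    Sest <- Sobs + A * Q1^2 / (2 * Q2)
    R <- Q1 / Q2
    variance <- Q2 * (0.5 * A * R^2 + A^2 * R^3 + 0.25 * A^2 * R^4)
  } else {
    Sest <- Sobs + A * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
    variance <- A   * Q1 * (Q1 - 1)     / (2 * (Q2 + 1)) +
                A^2 * Q1 * (2 * Q1 - 1)^2 / (4 * (Q2 + 1)^2) +
                A^2 * Q1^2 * Q2 * (Q1 - 1)^2 / (4 * (Q2 + 1)^4)
  }
  est <- structure(list(counts = counts, variant = variant, A = A,
                        Sest = Sest, Q0 = Sest - Sobs, variance = variance,
                        cv_ice = cv, conf = conf),
                   class = "richness_estimate")
  ci <- chao2_ci(est, conf = conf)
  est$ci_low <- ci[["ci_low"]]; est$ci_high <- ci[["ci_high"]]
  est
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(
    "Chao2 (%s): Sest = %.1f (%.1f-%.1f), Sobs = %d, Q1 = %d, Q2 = %d, ICE CV = %s\n",
    x$variant, x$Sest, x$ci_low, x$ci_high, x$counts$Sobs, x$counts$Q1,
    x$counts$Q2, ifelse(is.na(x$cv_ice), "NA", sprintf("%.2f", x$cv_ice))))
  invisible(x)
}

#' Log-transform confidence interval for a Chao2 estimate
#'
#' With `T = Sest - Sobs` and
#' `K = exp(z * sqrt(log(1 + var / T^2)))`, the interval is
#' `(Sobs + T/K, Sobs + T*K)`; the lower bound therefore never drops below
#' `Sobs`. When `T = 0` the interval degenerates to `(Sobs, Sobs)`.
#'
#' @param estimate a `richness_estimate` with a non-negative `variance`.
#' @param conf confidence level.
#' @return named numeric vector `c(ci_low, ci_high)`.
#' @export
chao2_ci <- function(estimate, conf = 0.95) {
  stopifnot(inherits(estimate, "richness_estimate"))
  if (estimate$variance < 0) stop("negative variance: formula misapplied")
  Sobs <- estimate$counts$Sobs
  Tt <- estimate$Sest - Sobs
  if (Tt <= 0 || estimate$variance == 0) {
    return(c(ci_low = Sobs + Tt, ci_high = Sobs + Tt))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  K <- exp(z * sqrt(log(1 + estimate$variance / Tt^2)))
  c(ci_low = Sobs + Tt / K, ci_high = Sobs + Tt * K)
}

#' ICE heterogeneity coefficient of variation
#'
#' Coefficient of variation of the incidence distribution as defined for
#' the incidence-based coverage estimator (ICE) of Lee & Chao (1994),
#' computed over the infrequent species (incidence frequency 1--10):
#' with `n_inf` the total incidence of infrequent species, sample coverage
#' `C = 1 - Q1/n_inf`, and `m_inf` the number of units holding at least one
#' infrequent species,
#' \deqn{\gamma^2 = \max\Big(\frac{S_{inf}}{C}\,
#'   \frac{m_{inf}}{m_{inf}-1}\,
#'   \frac{\sum_k k(k-1) Q_k}{n_{inf}^2} - 1,\; 0\Big)}
#' and `CV = sqrt(gamma^2)`.
#'
#' When called on bare counts (no matrix), `m_inf` is taken from the
#' `m_infreq` field (defaulting to `m`). When every infrequent species is a
#' unique (`C = 0`) the CV is reported as `Inf`, which selects the classic
#' estimator downstream.
#'
#' @param x `incidence_matrix` or `incidence_counts` (requires
#'   `per_species` frequencies).
#' @return non-negative CV value (possibly `Inf`), or 0 when there are no
#'   infrequent species.
#' @export
ice_cv <- function(x) {
  if (inherits(x, "incidence_matrix")) x <- counts_with_minfreq(x)
  stopifnot(inherits(x, "incidence_counts"))
  if (is.null(x$per_species)) {
    stop("ice_cv needs per-species incidence frequencies")
  }
  if (x$m < 2) stop("ICE CV needs at least 2 sample units")
  f <- x$per_species[x$per_species >= 1]
  infreq <- f[f <= 10]
  if (length(infreq) == 0) return(0)
  n_inf <- sum(infreq)
  Q1 <- sum(infreq == 1)
  C_ice <- 1 - Q1 / n_inf
  if (C_ice <= 0) return(Inf)
  m_inf <- max(2L, min(x$m_infreq, x$m))
  S_inf <- length(infreq)
  sum_kk1 <- sum(infreq * (infreq - 1))
  gamma2 <- max((S_inf / C_ice) * (m_inf / (m_inf - 1)) * sum_kk1 / n_inf^2 - 1, 0)
  sqrt(gamma2)
}

#' Choose the Chao2 variant from the ICE CV
#'
#' Reports the bias-corrected estimate unless there is substantial
#' heterogeneity among species detection probabilities (ICE CV > 0.5), in
#' which case the uncorrected (classic) form is used.
#'
#' @param cv ICE coefficient of variation; `NA` falls back to
#'   `"bias_corrected"`.
#' @return `"classic"` or `"bias_corrected"`.
#' @export
select_variant <- function(cv) {
  if (is.na(cv)) return("bias_corrected")
  if (cv > 0.5) "classic" else "bias_corrected"
}

#' Percentage of the estimated species pool detected
#'
#' @param estimate a `richness_estimate` (or anything with `Sest` and
#'   embedded `counts`).
#' @param digits rounding for reporting (integer percent by default).
#' @return `100 * Sobs / Sest`, rounded.
#' @export
percent_detected <- function(estimate, digits = 0) {
  stopifnot(inherits(estimate, "richness_estimate"))
  if (estimate$Sest <= 0) stop("Sest must be positive")
  round(100 * estimate$counts$Sobs / estimate$Sest, digits)
}
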