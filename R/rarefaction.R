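# Sample-based rarefaction: analytic (hypergeometric) expectation with an
# unconditional variance, plus a seeded resampling mode.

#' Sample-based rarefaction (species accumulation) curve
#'
#' Expected species richness in a random subset of `t` of the `m` sample
#' units, computed analytically from the per-species incidence frequencies
#' `s_j`:
#' \deqn{E[S_t] = \sum_j \left(1 - \binom{m - s_j}{t} / \binom{m}{t}\right)}
#' The default variance is the unconditional (moment-based) estimator,
#' which anchors the curve's uncertainty to the estimated total richness
#' `S~` (classic Chao2, falling back to the bias-corrected form and then
#' `Sobs`):
#' \deqn{\sigma^2(t) = \sum_j (1 - \alpha_{jt})^2 - E[S_t]^2 / \tilde S}
#' where `alpha_jt = C(m - s_j, t) / C(m, t)`. Unlike a variance
#' conditional on the observed matrix it does not collapse to zero at
#' `t = m`. A resampling mode draws `t`-unit subsets without replacement
#' (seeded) and reports the empirical mean and standard deviation.
#'
#' @param x `incidence_matrix`, `incidence_counts` with frequencies, or a
#'   bare named frequency vector together with `m`.
#' @param t integer vector of pooled-sample sizes, default `1:m`.
#' @param m number of sample units (only needed for a bare frequency
#'   vector).
#' @param method `"analytic"` or `"resample"`.
#' @param nrep,seed resampling replicates and seed (`method = "resample"`;
#'   the seed is mandatory there so curves are reproducible).
#' @param conf confidence level for the normal-approximation interval.
#' @return data frame of class `rarefaction_curve` with columns `t`,
#'   `expected_S`, `sd`, `ci_low`, `ci_high`.
#' @export
rarefy <- function(x, t = NULL, m = NULL, method = c("analytic", "resample"),
                   nrep = 1000, seed = NULL, conf = 0.95) {
  method <- match.arg(method)
  presence <- NULL
  if (inherits(x, "incidence_matrix")) {
    presence <- x$presence
    freq <- colSums(presence)
    m <- nrow(presence)
  } else if (inherits(x, "incidence_counts")) {
    if (is.null(x$per_species)) stop("rarefy needs per-species frequencies")
    freq <- x$per_species
    m <- x$m
  } else {
    freq <- x
    if (is.null(m)) stop("supply m with a bare frequency vector")
  }
  freq <- freq[freq >= 1]
  if (is.null(t)) t <- seq_len(m)
  if (any(t < 1 | t > m)) stop("t must lie in 1..m")
  t <- as.integer(t)

  if (method == "resample") {
    if (is.null(presence)) stop("resampling mode needs an incidence matrix")
    if (is.null(seed)) stop("resampling mode requires a seed")
    set.seed(seed)
    est <- vapply(t, function(tt) {
      s <- vapply(seq_len(nrep), function(i) {
        rows <- sample.int(m, tt)
        sum(colSums(presence[rows, , drop = FALSE]) > 0)
      }, numeric(1))
      c(mean(s), sd(s))
    }, numeric(2))
    out <- data.frame(t = t, expected_S = est[1, ], sd = est[2, ])
  } else {
    # alpha_jt via log-binomial ratios; exact and overflow-safe
    alpha <- vapply(t, function(tt) {
      a <- numeric(length(freq))
      ok <- (m - freq) >= tt
      a[ok] <- exp(lchoose(m - freq[ok], tt) - lchoose(m, tt))
      a
    }, numeric(length(freq)))
    alpha <- matrix(alpha, nrow = length(freq))
    expected <- colSums(1 - alpha)
    S_tilde <- rarefaction_pool_size(m, freq)
    v <- colSums((1 - alpha)^2) - expected^2 / S_tilde
    v[v < 0] <- 0
    out <- data.frame(t = t, expected_S = expected, sd = sqrt(v))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  out$ci_low <- pmax(out$expected_S - z * out$sd, 0)
  out$ci_high <- out$expected_S + z * out$sd
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

# Richness anchor for the unconditional rarefaction variance.
rarefaction_pool_size <- function(m, freq) {
  cts <- incidence_counts(m, per_species = freq)
  A <- (m - 1) / m
  if (cts$Q2 > 0) {
    cts$Sobs + A * cts$Q1^2 / (2 * cts$Q2)
  } else if (cts$Q1 > 0) {
    cts$Sobs + A * cts$Q1 * (cts$Q1 - 1) / (2 * (cts$Q2 + 1))
  } else {
    cts$Sobs
  }
}

#' Initial accumulation-rate diagnostic
#'
#' The lowest percentage of the estimated total richness that could be
#' accumulated by the first `t0` samples, minimised over random
#' reorderings of the sample units: a proxy for how slowly the species
#' accumulation curve can start.
#'
#' @param matrix an `incidence_matrix`.
#' @param t0 number of initial samples.
#' @param Sest estimated total richness used as the denominator (defaults
#'   to the classic Chao2 anchor).
#' @param nrep number of random reorderings.
#' @param seed RNG seed (mandatory).
#' @return list with `percent` (minimum percent of `Sest` accumulated by
#'   `t0` samples) and `t0`.
#' @export
lowest_accumulation <- function(matrix, t0 = 2, Sest = NULL, nrep = 1000,
                                seed = NULL) {
  stopifnot(inherits(matrix, "incidence_matrix"))
  if (is.null(seed)) stop("lowest_accumulation requires a seed")
  presence <- matrix$presence
  m <- nrow(presence)
  if (t0 < 1 || t0 > m) stop("t0 must lie in 1..m")
  if (is.null(Sest)) Sest <- rarefaction_pool_size(m, colSums(presence))
  set.seed(seed)
  s <- vapply(seq_len(nrep), function(i) {
    rows <- sample.int(m, t0)
    sum(colSums(presence[rows, , drop = FALSE]) > 0)
  }, numeric(1))
  list(percent = round(100 * min(s) / Sest), t0 = t0)
}
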