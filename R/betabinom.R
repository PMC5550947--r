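# Beta-binomial probability machinery in the (p, theta) parametrization:
# p = alpha/(alpha+beta) is the expected proportion of sample-1 counts,
# theta = 1/(alpha+beta) the overdispersion rate; theta = 0 degenerates to
# the binomial.

#' Beta-binomial parameter pair
#'
#' Bundles the proportion/overdispersion parametrization of the
#' beta-binomial: `p = alpha/(alpha+beta)` and `theta = 1/(alpha+beta)`.
#' `theta = 0` is the binomial limit.
#'
#' @param p Proportion in (0, 1).
#' @param theta Overdispersion rate, >= 0.
#' @return A list of class `bb_params` with elements `p`, `theta`, and (when
#'   `theta > 0`) the implied `alpha`, `beta`.
#' @export
#' @examples
#' bb_params(0.5, 0.1)
bb_params <- function(p, theta) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(theta), length(theta) == 1L)
  if (p <= 0 || p >= 1) stop("'p' must lie strictly inside (0, 1)")
  if (theta < 0) stop("'theta' must be non-negative")
  out <- list(p = p, theta = theta)
  if (theta > 0) {
    out$alpha <- p / theta
    out$beta <- (1 - p) / theta
  }
  structure(out, class = "bb_params")
}

#' Beta-binomial probability mass function
#'
#' Probability of observing `n` sample-1 reads and `m` sample-2 reads at a
#' position, given the total `n + m`, under the beta-binomial with proportion
#' `p` and overdispersion `theta`.  At `theta = 0` this is exactly
#' `dbinom(n, n + m, p)`.
#'
#' @param n,m Non-negative integer counts (vectorized, recycled).
#' @param p Proportion in (0, 1).
#' @param theta Overdispersion rate >= 0 (vectorized, recycled).
#' @param log Return log-probabilities?
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' bb_pmf(1, 1, p = 0.5, theta = 0)    # binomial: 0.5
#' sum(bb_pmf(0:5, 5:0, p = 0.3, theta = 0.1))  # normalization: 1
bb_pmf <- function(n, m, p, theta, log = FALSE) {
  if (any(p <= 0) || any(p >= 1)) stop("'p' must lie strictly inside (0, 1)")
  if (any(theta < 0)) stop("'theta' must be non-negative")
  if (any(n < 0) || any(m < 0)) stop("counts must be non-negative")
  k <- max(length(n), length(m), length(theta))
  n <- rep_len(n, k); m <- rep_len(m, k); theta <- rep_len(theta, k)
  t <- n + m
  out <- numeric(k)
  bin <- theta == 0
  if (any(bin)) {
    out[bin] <- stats::dbinom(n[bin], t[bin], p, log = TRUE)
  }
  if (any(!bin)) {
    a <- p / theta[!bin]
    b <- (1 - p) / theta[!bin]
    out[!bin] <- lchoose(t[!bin], n[!bin]) +
      lbeta(n[!bin] + a, m[!bin] + b) - lbeta(a, b)
  }
  if (log) out else exp(out)
}

#' Gene log-likelihood under the beta-binomial proportion model
#'
#' Reparametrized beta-binomial log-likelihood of one gene, summed over
#' positions:
#' \deqn{\sum_j \Big[\sum_{k=0}^{n_j-1}\log(p + k\theta_j)
#'   + \sum_{k=0}^{m_j-1}\log(1-p + k\theta_j)
#'   - \sum_{k=0}^{n_j+m_j-1}\log(1 + k\theta_j)\Big].}
#' The combinatorial constant `log choose(n+m, n)` is omitted by default; it
#' cancels in every likelihood-ratio, nested-model and AIC difference
#' computed on the same counts.
#'
#' The default evaluation uses log-gamma differences,
#' `sum_{k<n} log(p + k theta) = lgamma(n + p/theta) - lgamma(p/theta) +
#' n log theta`, switching to a second-order binomial expansion where
#' `theta` is tiny and to the exact binomial at `theta = 0`.  `method =
#' "direct"` evaluates the sums term by term and exists as a slow reference
#' path.
#'
#' @param n,m Count vectors over positions (same length).
#' @param p Scalar gene proportion.  Values outside (0, 1) give `-Inf` when
#'   the counts conflict with the boundary, 0 otherwise.
#' @param theta Overdispersion rate per position (scalar or vector, >= 0).
#' @param method `"auto"` (log-gamma with small-theta guards) or `"direct"`
#'   (term-by-term summation).
#' @param include_constant Add `sum(lchoose(n + m, n))` for absolute
#'   likelihood reporting.
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' gene_loglik(1, 0, p = 0.3, theta = 0.2)  # log(0.3)
gene_loglik <- function(n, m, p, theta, method = c("auto", "direct"),
                        include_constant = FALSE) {
  method <- match.arg(method)
  stopifnot(length(n) == length(m), length(p) == 1L)
  if (any(theta < 0)) stop("'theta' must be non-negative")
  theta <- rep_len(theta, length(n))
  t <- n + m
  cst <- if (include_constant) sum(lchoose(t, n)) else 0
  if (p <= 0) return(if (any(n > 0)) -Inf else cst)
  if (p >= 1) return(if (any(m > 0)) -Inf else cst)
  q <- 1 - p
  if (method == "direct") {
    ll <- 0
    for (j in seq_along(n)) {
      th <- theta[j]
      ll <- ll +
        sum(log(p + th * seq_len(n[j]) - th)) +
        sum(log(q + th * seq_len(m[j]) - th)) -
        sum(log(1 + th * seq_len(t[j]) - th))
    }
    return(ll + cst)
  }
  ll <- numeric(length(n))
  # exact binomial limit
  zero <- theta == 0
  if (any(zero)) ll[zero] <- n[zero] * log(p) + m[zero] * log(q)
  # tiny positive theta: lgamma differences at p/theta > ~1e10 lose the
  # 1e-8 relative precision we promise, so expand around the binomial
  tiny <- !zero & theta * pmax(t - 1, 0) < 1e-8 * min(p, q)
  if (any(tiny)) {
    th <- theta[tiny]
    ll[tiny] <- n[tiny] * log(p) + m[tiny] * log(q) +
      th * (n[tiny] * (n[tiny] - 1) / (2 * p) +
              m[tiny] * (m[tiny] - 1) / (2 * q) -
              t[tiny] * (t[tiny] - 1) / 2)
  }
  big <- !zero & !tiny
  if (any(big)) {
    th <- theta[big]
    a <- p / th; b <- q / th; ab <- 1 / th
    ll[big] <- lgamma(n[big] + a) - lgamma(a) +
      lgamma(m[big] + b) - lgamma(b) -
      lgamma(t[big] + ab) + lgamma(ab)
  }
  sum(ll) + cst
}

#' Maximize the gene likelihood over the proportion
#'
#' One-dimensional bounded maximization of [gene_loglik()] over
#' `p` in `(eps, 1 - eps)` with the overdispersion vector held fixed.  When
#' `theta` is identically zero the binomial closed form
#' `sum(n) / sum(n + m)` is returned exactly.
#'
#' @param n,m Count vectors over positions.
#' @param theta Per-position overdispersion (scalar or vector).
#' @param eps Boundary buffer for the search interval.
#' @param tol Convergence tolerance passed to [stats::optimize()].
#' @return Estimated proportion, or `NA` for an all-zero gene.
#' @export
update_p <- function(n, m, theta, eps = 1e-9, tol = 1e-8) {
  sn <- sum(n); sm <- sum(m)
  if (sn + sm == 0) {
    warning("all-zero gene: proportion undefined")
    return(NA_real_)
  }
  if (all(theta == 0)) {
    return(min(max(sn / (sn + sm), eps), 1 - eps))
  }
  opt <- stats::optimize(function(p) gene_loglik(n, m, p, theta),
                         interval = c(eps, 1 - eps), maximum = TRUE, tol = tol)
  opt$maximum
}

#' Fit the pair-specific overdispersion scale D
#'
#' Maximizes the summed beta-binomial log-likelihood over all genes with
#' respect to `log D`, holding the trained depth exponent `gamma` and
#' local-sequence coefficients `beta` (entering through the per-position
#' offsets `eta0`) and the gene proportions fixed.  `D` is the multiplicative
#' overdispersion scale of one particular sample pair (the library effect):
#' `theta_ij = D * exp(eta0_ij)` with
#' `eta0_ij = sum(beta * I) + gamma * log(n_ij + m_ij)`.
#'
#' @param prepared List with one element per gene, each a list with numeric
#'   vectors `n`, `m` and `eta0` (see [prepare_pair_loglik()]).
#' @param p Gene proportions: scalar, or vector named by gene.
#' @param interval Search interval for `log D`.
#' @param tol Convergence tolerance in `log D`.
#' @return List with `logD`, `D`, the attained `loglik`, and `flat` (`TRUE`
#'   when the likelihood carries no information about `D`, e.g. every
#'   position has total depth 1).
#' @export
fit_pair_D <- function(prepared, p, interval = c(-30, 10), tol = 1e-6) {
  stopifnot(length(prepared) >= 1L)
  if (length(p) == 1L) p <- stats::setNames(rep(p, length(prepared)), names(prepared))
  f <- function(logD) {
    tot <- 0
    for (g in names(prepared)) {
      pg <- prepared[[g]]
      pe <- p[[g]]
      if (is.na(pe)) next
      tot <- tot + gene_loglik(pg$n, pg$m, pe, exp(logD + pg$eta0))
    }
    tot
  }
  probe <- vapply(c(interval[1], mean(interval), interval[2]), f, numeric(1))
  if (!all(is.finite(probe))) stop("non-finite likelihood across the D search range")
  if (max(probe) - min(probe) < 1e-8) {
    return(list(logD = NA_real_, D = NA_real_, loglik = probe[2], flat = TRUE))
  }
  opt <- stats::optimize(f, interval = interval, maximum = TRUE, tol = tol)
  list(logD = opt$maximum, D = exp(opt$maximum), loglik = opt$objective, flat = FALSE)
}
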