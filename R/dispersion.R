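# Method-of-moments estimation of the per-position overdispersion rate from
# replicate pairs, and the depth / positional diagnostics built on it.

#' Neutral proportion of a sample pair
#'
#' Genome-wide ratio of sample-1 counts to total counts over all genes and
#' positions.  Assuming most genes do not change between the samples, this
#' is the null value of every gene's proportion.
#'
#' @param pair List of [pair_counts()] objects, one per gene, for one sample
#'   pair.
#' @return Proportion in (0, 1).
#' @export
neutral_proportion <- function(pair) {
  sn <- sum(vapply(pair, function(pc) sum(pc$n), numeric(1)))
  sm <- sum(vapply(pair, function(pc) sum(pc$m), numeric(1)))
  if (sn + sm == 0) stop("cannot estimate neutral proportion: zero grand total")
  sn / (sn + sm)
}

#' Gene-level proportion of a sample pair
#'
#' @param pc A [pair_counts()] object.
#' @return `sum(n) / (sum(n) + sum(m))`, or `NA` for an all-zero gene.
#' @export
gene_proportion <- function(pc) {
  sn <- sum(pc$n); sm <- sum(pc$m)
  if (sn + sm == 0) return(NA_real_)
  sn / (sn + sm)
}

#' Method-of-moments overdispersion estimate per position
#'
#' Estimates the beta-binomial overdispersion rate of the proportion at each
#' position from the squared deviations observed in `R` replicate pairs:
#' \deqn{\hat\theta_j = \frac{\frac1R\sum_r\big[\sigma_{jr}/(p_{nr}(1-p_{nr}))
#'   - 1/(n_{jr}+m_{jr})\big]}{1 - \frac1R\sum_r \sigma_{jr}/(p_{nr}(1-p_{nr}))}}
#' with \eqn{\sigma_{jr} = (n_{jr}/(n_{jr}+m_{jr}) - p_{nr})^2}, the squared
#' deviation of the observed pair proportion from that pair's neutral
#' proportion.  The estimate may be negative from sampling noise (the caller
#' decides flooring) and is invalid when the denominator is non-positive.
#'
#' @param n,m Matrices (positions x pairs) or vectors (one position) of
#'   counts; every pair must have positive depth at every position.
#' @param p_nr Per-pair neutral proportions, strictly inside (0, 1).
#' @return List with `theta` (estimate, `NA` where invalid) and `valid`.
#' @export
#' @examples
#' estimate_theta(8, 2, 0.5)$theta  # 0.40625
estimate_theta <- function(n, m, p_nr) {
  if (!is.matrix(n)) n <- matrix(n, nrow = 1L)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  stopifnot(ncol(n) == length(p_nr), all(dim(n) == dim(m)))
  if (any(p_nr <= 0 | p_nr >= 1)) stop("p_nr must lie strictly inside (0, 1)")
  t <- n + m
  if (any(t == 0)) stop("zero-depth pair at some position")
  sig <- sweep(n / t, 2L, p_nr)^2
  b <- sweep(sig, 2L, p_nr * (1 - p_nr), `/`)
  num <- rowMeans(b - 1 / t)
  den <- 1 - rowMeans(b)
  valid <- den > 0
  theta <- ifelse(valid, num / den, NA_real_)
  list(theta = theta, valid = valid)
}

#' Build the regression dataset of per-position dispersion estimates
#'
#' Applies [estimate_theta()] across all genes and positions of a replicate
#' pair set, attaching the depth covariate (mean pair total over pairs) and
#' the local-sequence window.  Positions failing the `min_depth` filter in
#' any pair are excluded; non-positive estimates are floored (and flagged)
#' rather than dropped because the log-linear regression needs `log(theta)`.
#'
#' @param pair_sets List over replicate pairs; each element is a named list
#'   of [pair_counts()] objects (same genes and positions in every pair).
#' @param cfg A [filter_config()]; `min_depth` is applied per pair.
#' @param floor Replacement for non-positive estimates before logs.
#' @return A `data.frame` of class `theta_observations` with columns
#'   `gene_id`, `position`, `strand`, `theta_raw`, `theta_hat`, `depth`,
#'   `context`, `floored`, `invalid`, `context_missing`.
#' @export
build_theta_observations <- function(pair_sets, cfg = filter_config(),
                                     floor = 1e-6) {
  stopifnot(length(pair_sets) >= 1L, floor > 0)
  p_nr <- vapply(pair_sets, neutral_proportion, numeric(1))
  genes <- names(pair_sets[[1]])
  min_depth <- max(1L, cfg$min_depth)
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    pcs <- lapply(pair_sets, `[[`, g)
    pos <- pcs[[1]]$positions
    if (!all(vapply(pcs, function(pc) identical(pc$positions, pos), logical(1))))
      stop("alignment error: replicate pairs cover different positions for ", g)
    N <- vapply(pcs, `[[`, numeric(length(pos)), "n")
    M <- vapply(pcs, `[[`, numeric(length(pos)), "m")
    if (length(pos) == 1L) { N <- matrix(N, 1L); M <- matrix(M, 1L) }
    t <- N + M
    keep <- rowSums(t < min_depth) == 0
    if (!any(keep)) next
    est <- estimate_theta(N[keep, , drop = FALSE], M[keep, , drop = FALSE], p_nr)
    ctx <- pcs[[1]]$context[keep]
    floored <- !is.na(est$theta) & est$theta <= 0
    rows[[gi]] <- data.frame(
      gene_id = g,
      position = pos[keep],
      strand = pcs[[1]]$strand,
      theta_raw = est$theta,
      theta_hat = ifelse(floored, floor, est$theta),
      depth = rowMeans(t[keep, , drop = FALSE]),
      context = ctx,
      floored = floored,
      invalid = !est$valid,
      context_missing = is.na(ctx) | grepl("N", ctx),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no position passed the depth filter")
  rownames(out) <- NULL
  class(out) <- c("theta_observations", "data.frame")
  out
}

#' Dispersion-versus-depth diagnostic
#'
#' Bins positions by log10 mean depth and reports the per-bin mean of
#' log10 theta-hat, together with separate aggregates for positions whose
#' first four downstream bases are GGGG or AAAA (hexamer-priming
#' diagnostics: GGGG starts attract more reads, AAAA fewer).
#'
#' @param obs A [build_theta_observations()] data frame.
#' @param n_bins Number of equal-width bins in log10 depth (>= 2).
#' @return Data frame with one row per non-empty bin.
#' @export
depth_dispersion_profile <- function(obs, n_bins = 20L) {
  if (n_bins < 2L) stop("'n_bins' must be at least 2")
  ok <- !obs$invalid & is.finite(obs$theta_hat) & obs$theta_hat > 0
  obs <- obs[ok, , drop = FALSE]
  if (!nrow(obs)) stop("no usable observations")
  lx <- log10(obs$depth)
  ly <- log10(obs$theta_hat)
  br <- seq(min(lx), max(lx), length.out = n_bins + 1L)
  bin <- findInterval(lx, br, rightmost.closed = TRUE, all.inside = TRUE)
  down4 <- rep(NA_character_, nrow(obs))
  has_ctx <- !obs$context_missing
  if (any(has_ctx)) {
    K <- nchar(obs$context[which(has_ctx)[1]])
    down4[has_ctx] <- substr(obs$context[has_ctx], K / 2 + 1, K / 2 + 4)
  }
  agg <- function(sel) {
    vapply(seq_len(n_bins), function(b) {
      v <- ly[sel & bin == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  cnt <- function(sel) vapply(seq_len(n_bins), function(b) sum(sel & bin == b), numeric(1))
  all_sel <- rep(TRUE, nrow(obs))
  out <- data.frame(
    bin = seq_len(n_bins),
    log10_depth_mid = (br[-1] + br[-length(br)]) / 2,
    mean_log10_theta = agg(all_sel),
    n = cnt(all_sel),
    mean_log10_theta_gggg = agg(!is.na(down4) & down4 == "GGGG"),
    n_gggg = cnt(!is.na(down4) & down4 == "GGGG"),
    mean_log10_theta_aaaa = agg(!is.na(down4) & down4 == "AAAA"),
    n_aaaa = cnt(!is.na(down4) & down4 == "AAAA"))
  out[out$n > 0, , drop = FALSE]
}

#' Positional dispersion diagnostic
#'
#' Ranks positions by distance to the 3' end of their gene and splits them
#' into `n_parts` categories with equal numbers of data points; part 1 is
#' the gene tail.  Protocols that size-select fragments after PCR show
#' inflated overdispersion in part 1.
#'
#' @param obs A [build_theta_observations()] data frame.
#' @param genes A [gene_models()] data frame (for gene lengths).
#' @param n_parts Number of equal-count categories (default 10).
#' @return Data frame with columns `part`, `mean_theta`, `n`.
#' @export
positional_profile <- function(obs, genes, n_parts = 10L) {
  ok <- !obs$invalid & is.finite(obs$theta_hat)
  obs <- obs[ok, , drop = FALSE]
  if (nrow(obs) < n_parts) stop("fewer positions than parts")
  len <- stats::setNames(genes$length, genes$gene_id)
  dist_end <- len[obs$gene_id] - obs$position
  ord <- order(dist_end)
  part <- integer(nrow(obs))
  part[ord] <- ceiling(seq_len(nrow(obs)) * n_parts / nrow(obs))
  data.frame(
    part = seq_len(n_parts),
    mean_theta = vapply(seq_len(n_parts),
                        function(k) mean(obs$theta_hat[part == k]), numeric(1)),
    n = as.vector(table(factor(part, levels = seq_len(n_parts)))))
}

#' Serialize dispersion observations
#' @param obs A [build_theta_observations()] data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_theta_observations <- function(obs, path) {
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
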