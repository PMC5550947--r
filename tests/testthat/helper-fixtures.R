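# Small fixtures built in code.

# one hand-made paired_counts object
toy_pair <- function(n, m, sequence = NULL, K = 2L, gene_id = "g1",
                     strand = "antisense") {
  L <- length(n)
  if (is.null(sequence)) sequence <- paste(rep("A", L), collapse = "")
  structure(list(gene_id = gene_id, strand = strand,
                 positions = seq_len(L) - 1L,
                 n = as.numeric(n), m = as.numeric(m),
                 depth = as.numeric(n + m),
                 context = position_contexts(sequence, seq_len(L) - 1L, K),
                 K = as.integer(K)),
            class = "paired_counts")
}

# a synthetic theta_observations table generated directly from the
# log-linear model (design-level simulation)
toy_obs <- function(n, logD, gamma, beta = NULL, sigma = 0.3, K = 8L,
                    depth_meanlog = log(200), depth_sdlog = 1.5, seed = 1L) {
  set.seed(seed)
  spec <- design_spec(K = K)
  depth <- rlnorm(n, depth_meanlog, depth_sdlog)
  ctx <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), K, replace = TRUE), collapse = ""),
    character(1))
  bvec <- stats::setNames(rep(0, 3L * K), bbdisp:::seq_col_names(spec))
  if (!is.null(beta)) bvec[names(beta)] <- beta
  mdl <- constant_model()
  mdl$variant <- "depth_free"; mdl$K <- K
  mdl$coded_bases <- spec$coded_bases; mdl$offsets <- spec$offsets
  mdl$beta <- bvec
  eff <- seq_effect(mdl, ctx)
  ltheta <- logD + gamma * log(depth) + eff + rnorm(n, 0, sigma)
  structure(data.frame(gene_id = "g1", position = seq_len(n) - 1L,
                       strand = "antisense", theta_raw = exp(ltheta),
                       theta_hat = exp(ltheta), depth = depth, context = ctx,
                       floored = FALSE, invalid = FALSE,
                       context_missing = FALSE, stringsAsFactors = FALSE),
            class = c("theta_observations", "data.frame"))
}

# minimal fit_state stand-in for lrt_genes
toy_state <- function(genes, ll_alt, ll_null, p_hat = NULL) {
  k <- length(genes)
  structure(list(gene_id = genes,
                 p_hat = stats::setNames(if (is.null(p_hat)) rep(0.5, k) else p_hat, genes),
                 ll_alt = stats::setNames(ll_alt, genes),
                 ll_null = stats::setNames(ll_null, genes),
                 testable = stats::setNames(rep(TRUE, k), genes)),
            class = "fit_state")
}
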