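# Two-stage fitting and the likelihood-ratio differential-expression test.
# Stage 1 (train): the depth exponent gamma and local-sequence coefficients
# beta are estimated on replicate pairs with no expected biological
# difference.  Stage 2 (fit_test_pair): for each test pair the library
# scale D is fitted by maximum likelihood and, when comparing groups, the
# gene proportions are updated iteratively until the deviance decreases by
# less than the convergence threshold.

#' Pipeline configuration
#'
#' @param variant Overdispersion model variant used for testing
#'   (`"binomial"`, `"constant"`, `"primer_free"`, `"full"`).
#' @param K Local-sequence window length.
#' @param filters A [filter_config()].
#' @param theta_floor Floor for non-positive moment estimates.
#' @param convergence Relative deviance decrease below which the iterative
#'   D / proportion refit stops (default 0.01, i.e. 1%).
#' @param max_iter Iteration cap for the refit loop.
#' @param p_adjust Multiple-testing method (see [stats::p.adjust()]).
#' @param seed Optional seed recorded with runs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(variant = "primer_free", K = 80L,
                            filters = filter_config(), theta_floor = 1e-6,
                            convergence = 0.01, max_iter = 50L,
                            p_adjust = "BH", seed = NULL) {
  if (convergence <= 0 || convergence > 1)
    stop("'convergence' must lie in (0, 1]")
  structure(list(variant = variant, K = as.integer(K), filters = filters,
                 theta_floor = theta_floor, convergence = convergence,
                 max_iter = as.integer(max_iter), p_adjust = p_adjust,
                 seed = seed),
            class = "pipeline_config")
}

#' Constant-dispersion and binomial model stubs
#'
#' Placeholder models for the variants that carry no trained parameters:
#' `constant_model()` is the beta-binomial with a single free scale `D`
#' (fitted per pair), `binomial_model()` has `theta = 0` everywhere.
#' @return An `overdispersion_model`.
#' @export
constant_model <- function() {
  structure(list(variant = "constant", logD = 0, gamma = 0, beta = NULL,
                 K = NA_integer_, reference_base = NA_character_,
                 coded_bases = NULL, offsets = NULL, strand = NA_character_,
                 sigma2 = NA_real_, n_obs = NA_integer_,
                 r_squared = NA_real_, rank_deficient = FALSE),
            class = "overdispersion_model")
}

#' @rdname constant_model
#' @export
binomial_model <- function() {
  m <- constant_model()
  m$variant <- "binomial"
  m
}

#' Train the overdispersion model on replicate pairs
#'
#' Runs the stage-1 estimation: per-pair neutral proportions, the
#' method-of-moments dispersion estimates ([build_theta_observations()]),
#' the indicator design and the least-squares fit.  Local-sequence
#' coefficients are fitted separately for each strand present; the returned
#' model's intercept is the training-set `log D`, which stage 2 replaces
#' with a pair-specific value.
#'
#' @param pair_sets List over replicate pairs of named per-gene
#'   [pair_counts()] lists (all pairs must share no expected biological
#'   difference).
#' @param spec A [design_spec()]; its depth/sequence flags are adjusted to
#'   the requested variant.
#' @param variant Model variant to fit.
#' @param cfg A [filter_config()].
#' @param floor Floor for non-positive moment estimates.
#' @return An `overdispersion_model`, or a named list of them (one per
#'   strand) when several strands are present.
#' @export
train <- function(pair_sets, spec = design_spec(), variant = "full",
                  cfg = filter_config(), floor = 1e-6) {
  if (!length(pair_sets)) stop("empty replicate pair set")
  obs <- build_theta_observations(pair_sets, cfg = cfg, floor = floor)
  spec$include_depth <- variant %in% c("full", "primer_free")
  spec$include_sequence <- variant %in% c("full", "depth_free")
  fit_one <- function(o, st) fit_theta_model(build_design(o, spec), variant,
                                             strand = st)
  strands <- unique(obs$strand)
  if (length(strands) == 1L) return(fit_one(obs, strands))
  stats::setNames(lapply(strands, function(st)
    fit_one(obs[obs$strand == st, , drop = FALSE], st)), strands)
}

#' Precompute per-gene likelihood offsets for a sample pair
#'
#' For each gene, caches the counts and the fixed part of the log
#' overdispersion, `eta0 = seq_effect + gamma * log(n + m)`, so that
#' `theta = exp(logD + eta0)` during the `D` search.
#'
#' @param pair Named list of [pair_counts()] for one sample pair.
#' @param model An `overdispersion_model`.
#' @return Named list of per-gene components.
#' @export
prepare_pair_loglik <- function(pair, model) {
  lapply(pair, function(pc) {
    eta0 <- switch(model$variant,
      binomial = NULL,
      constant = numeric(length(pc$n)),
      primer_free = model$gamma * log(pmax(pc$depth, 1)),
      full = model$gamma * log(pmax(pc$depth, 1)) +
        seq_effect(model, pc$context),
      depth_free = seq_effect(model, pc$context),
      stop("unknown model variant: ", model$variant))
    list(gene_id = pc$gene_id, n = pc$n, m = pc$m, eta0 = eta0)
  })
}

pair_theta <- function(prepared_gene, logD) {
  if (is.null(prepared_gene$eta0)) 0 else exp(logD + prepared_gene$eta0)
}

#' Fit one test pair under a trained overdispersion model
#'
#' Stage-2 fitting for a single sample pair.  The gene proportions start at
#' the pair's neutral proportion; the library scale `D` is fitted by
#' maximizing the beta-binomial likelihood with `gamma` and `beta` held at
#' their trained values; in `"comparison"` mode the per-gene proportions are
#' then re-estimated and the two steps alternate until the relative
#' deviance decrease falls below the configured threshold.  In
#' `"replicate"` mode the proportion stays fixed at the neutral value and a
#' single `D` fit is performed.
#'
#' @param pair Named list of [pair_counts()] over genes.
#' @param model An `overdispersion_model` (use [binomial_model()] /
#'   [constant_model()] for the untrained variants).
#' @param cfg A [pipeline_config()].
#' @param mode `"comparison"` or `"replicate"`.
#' @return List of class `fit_state`: per-gene `p_hat`, `ll_alt`
#'   (log-likelihood at `p_hat`), `ll_null` (at the neutral proportion),
#'   `D`, `logD`, `p_n`, the deviance history and iteration count.
#' @export
fit_test_pair <- function(pair, model, cfg = pipeline_config(),
                          mode = c("comparison", "replicate")) {
  mode <- match.arg(mode)
  prepared <- prepare_pair_loglik(pair, model)
  genes <- names(prepared)
  p_n <- neutral_proportion(pair)
  p_hat <- stats::setNames(rep(p_n, length(genes)), genes)
  testable <- vapply(prepared, function(pg) sum(pg$n) + sum(pg$m) > 0, logical(1))
  p_hat[!testable] <- NA_real_
  logD <- NA_real_
  flat <- FALSE
  total_ll <- function(p, logD) {
    sum(vapply(genes[testable], function(g) {
      pg <- prepared[[g]]
      gene_loglik(pg$n, pg$m, p[[g]], pair_theta(pg, logD))
    }, numeric(1)))
  }
  deviance <- numeric(0)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    if (model$variant != "binomial") {
      dfit <- fit_pair_D(prepared[testable], p_hat[testable])
      if (dfit$flat) {
        flat <- TRUE
        warning("likelihood is flat in D (no dispersion information); ",
                "keeping previous scale")
        if (is.na(logD)) logD <- 0
      } else logD <- dfit$logD
    }
    if (mode == "replicate") {
      deviance <- c(deviance, -2 * total_ll(p_hat, logD))
      break
    }
    for (g in genes[testable]) {
      pg <- prepared[[g]]
      p_hat[[g]] <- update_p(pg$n, pg$m, pair_theta(pg, logD))
    }
    dev <- -2 * total_ll(p_hat, logD)
    if (length(deviance)) {
      prev <- deviance[length(deviance)]
      if (dev > prev + 1e-9 * abs(prev))
        stop("deviance increased during iterative fitting (", prev,
             " -> ", dev, ")")
      deviance <- c(deviance, dev)
      if ((prev - dev) < cfg$convergence * abs(prev)) break
    } else {
      deviance <- c(deviance, dev)
      if (cfg$convergence >= 1) break
    }
    if (n_iter >= cfg$max_iter) break
  }
  ll_alt <- ll_null <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes[testable]) {
    pg <- prepared[[g]]
    th <- pair_theta(pg, logD)
    ll_null[[g]] <- gene_loglik(pg$n, pg$m, p_n, th)
    ll_alt[[g]] <- if (mode == "replicate") ll_null[[g]] else
      gene_loglik(pg$n, pg$m, p_hat[[g]], th)
  }
  structure(list(gene_id = genes, p_hat = p_hat, ll_alt = ll_alt,
                 ll_null = ll_null, logD = logD,
                 D = if (is.na(logD)) NA_real_ else exp(logD),
                 p_n = p_n, deviance = deviance, n_iter = n_iter,
                 variant = model$variant, mode = mode, flat = flat,
                 testable = testable),
            class = "fit_state")
}

#' Likelihood-ratio test per gene across sample pairs
#'
#' For each cross-group sample pair, `chi2_r = -2 ln L(p_n) + 2 ln L(p_i)`
#' follows a chi-square distribution with 1 degree of freedom under the
#' null; with several pairs the per-pair scores are summed and the degrees
#' of freedom add.  Tiny negative scores from optimizer jitter are floored
#' at 0.
#'
#' @param states List of [fit_test_pair()] results (mode `"comparison"`),
#'   one per (group-1, group-2) sample pair, covering the same genes.
#' @param method Multiple-testing adjustment (default `"BH"`).
#' @return Data frame of class `gene_test_results` with columns `gene_id`,
#'   `p_hat`, `chi2`, `df`, `pvalue`, `qvalue`, `untestable`.
#' @export
lrt_genes <- function(states, method = "BH") {
  stopifnot(length(states) >= 1L)
  genes <- states[[1]]$gene_id
  for (st in states) if (!identical(st$gene_id, genes))
    stop("fit states cover different gene sets")
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = length(genes))
  chi2 <- rowSums(as_mat(vapply(states, function(st)
    pmax(0, 2 * (st$ll_alt - st$ll_null)), numeric(length(genes)))))
  testable <- rowSums(as_mat(vapply(states, function(st) !st$testable,
                                    logical(length(genes))))) == 0
  p_hat <- rowMeans(as_mat(vapply(states, `[[`, numeric(length(genes)), "p_hat")))
  df <- length(states)
  pvalue <- ifelse(testable, stats::pchisq(chi2, df, lower.tail = FALSE), NA)
  out <- data.frame(gene_id = genes, p_hat = p_hat, chi2 = ifelse(testable, chi2, NA),
                    df = df, pvalue = pvalue,
                    qvalue = adjust_pvalues(pvalue, method),
                    untestable = !testable, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_test_results", "data.frame")
  out
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (Benjamini-Hochberg by default);
#' `NA` p-values stay `NA`.
#'
#' @param pvalues Numeric vector in (0, 1].
#' @param method Adjustment method.
#' @return Adjusted q-values.
#' @export
adjust_pvalues <- function(pvalues, method = "BH") {
  stats::p.adjust(pvalues, method = method)
}

#' Compare the four nested dispersion models on replicate pairs
#'
#' For every replicate pair the gene proportions are fixed at the pair's
#' neutral proportion and each variant's remaining free parameter (the
#' library scale `D`; none for the binomial) is fitted by maximum
#' likelihood.  Reports the mean log-likelihood, the mean percent
#' likelihood change versus the nested predecessor, a nested chi-square
#' test (per-pair statistics and degrees of freedom summed), and the mean
#' AIC under two parameter-counting conventions: `k_pair` counts only the
#' per-pair free parameters (0, 1, 1, 1 - `gamma` and `beta` are trained on
#' separate data), `k_total` counts every model parameter (0, 1, 2,
#' 2 + 3K).
#'
#' @param pairs List over replicate pairs of named per-gene [pair_counts()]
#'   lists.
#' @param trained Named list with the trained `primer_free` and (optional)
#'   `full` models.
#' @param variants Variants to include, in nesting order.
#' @param cfg A [pipeline_config()].
#' @return Data frame of class `model_comparison` with one row per variant.
#' @export
compare_models <- function(pairs, trained,
                           variants = c("binomial", "constant",
                                        "primer_free", "full"),
                           cfg = pipeline_config()) {
  stopifnot(length(pairs) >= 1L)
  labels <- c(binomial = "bi", constant = "bb+D", primer_free = "bb+D+g",
              full = "bb+D+g+coe")
  model_for <- function(v) switch(v,
    binomial = binomial_model(),
    constant = constant_model(),
    primer_free = trained$primer_free,
    full = trained$full)
  ll <- matrix(NA_real_, length(pairs), length(variants))
  for (r in seq_along(pairs)) {
    for (vi in seq_along(variants)) {
      mdl <- model_for(variants[vi])
      if (is.null(mdl)) stop("no trained model supplied for variant ",
                             variants[vi])
      st <- fit_test_pair(pairs[[r]], mdl, cfg, mode = "replicate")
      ll[r, vi] <- sum(st$ll_null, na.rm = TRUE)
    }
  }
  K <- if (!is.null(trained$primer_free)) {
    if (!is.null(trained$full)) trained$full$K else trained$primer_free$K
  } else 80L
  k_total_all <- c(binomial = 0, constant = 1, primer_free = 2,
                   full = 2 + 3 * K)
  k_pair_all <- c(binomial = 0, constant = 1, primer_free = 1, full = 1)
  out <- data.frame(variant = variants, label = labels[variants],
                    mean_loglik = colMeans(ll),
                    k_pair = k_pair_all[variants],
                    k_total = k_total_all[variants],
                    stringsAsFactors = FALSE)
  out$mean_aic <- 2 * out$k_pair - 2 * out$mean_loglik
  out$mean_aic_total <- 2 * out$k_total - 2 * out$mean_loglik
  out$pct_change <- NA_real_
  out$chi2_nested <- NA_real_
  out$df_nested <- NA_real_
  out$p_nested <- NA_real_
  for (i in seq_along(variants)[-1]) {
    d <- pmax(0, 2 * (ll[, i] - ll[, i - 1L]))
    out$pct_change[i] <- mean(100 * (ll[, i] - ll[, i - 1L]) /
                                abs(ll[, i - 1L]))
    out$chi2_nested[i] <- sum(d)
    df1 <- k_total_all[variants[i]] - k_total_all[variants[i - 1L]]
    out$df_nested[i] <- df1 * length(pairs)
    out$p_nested[i] <- stats::pchisq(out$chi2_nested[i], out$df_nested[i],
                                     lower.tail = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Assemble per-gene sample pairs from count tracks
#'
#' Applies the 3'-end filters and pairs the tracks of two samples for every
#' gene and strand both samples cover.
#'
#' @param counts Named list of [base_start_counts()] (see
#'   [load_counts_table()]).
#' @param genes A [gene_models()] data frame.
#' @param sample_a,sample_b Sample identifiers.
#' @param cfg A [filter_config()].
#' @param K Context window length.
#' @return Named list of [pair_counts()] keyed by `gene_id` (single strand)
#'   or `gene_id.strand`.
#' @export
make_pair <- function(counts, genes, sample_a, sample_b,
                      cfg = filter_config(), K = 80L) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (st in unique(genes$strand)) {
      ka <- counts_key(g$gene_id, st, sample_a)
      kb <- counts_key(g$gene_id, st, sample_b)
      if (is.null(counts[[ka]]) || is.null(counts[[kb]])) next
      a <- apply_filters(counts[[ka]], g, cfg)
      b <- apply_filters(counts[[kb]], g, cfg)
      if (is.null(a) || is.null(b)) next
      key <- if (length(unique(genes$strand)) == 1L) g$gene_id else
        paste(g$gene_id, st, sep = ".")
      out[[key]] <- pair_counts(a, b, g, K = K)
    }
  }
  out
}

#' Differential-expression test between two groups
#'
#' Enumerates all (group-1, group-2) sample pairs, fits each pair under the
#' trained model ([fit_test_pair()], mode `"comparison"`), and combines the
#' per-pair likelihood-ratio scores ([lrt_genes()]).  A single sample per
#' group is allowed: the model then borrows the dispersion information
#' trained on replicates.
#'
#' @param counts Named list of count tracks.
#' @param genes A [gene_models()] data frame.
#' @param sample_sheet Data frame with `sample_id` and `group` (exactly two
#'   groups).
#' @param model Trained `overdispersion_model`.
#' @param cfg A [pipeline_config()].
#' @return A [lrt_genes()] results table.
#' @export
de_test <- function(counts, genes, sample_sheet, model,
                    cfg = pipeline_config()) {
  groups <- split(sample_sheet$sample_id, sample_sheet$group)
  if (length(groups) != 2L) stop("exactly two groups are required")
  states <- list()
  for (sa in groups[[1]]) for (sb in groups[[2]]) {
    pair <- make_pair(counts, genes, sa, sb, cfg$filters, cfg$K)
    if (!length(pair)) stop("no shared genes between ", sa, " and ", sb)
    states[[paste(sa, sb, sep = ":")]] <-
      fit_test_pair(pair, model, cfg, mode = "comparison")
  }
  lrt_genes(states, method = cfg$p_adjust)
}

#' Write a gene test result table
#' @param results A [lrt_genes()] data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
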