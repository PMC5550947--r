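# Linearized overdispersion models: indicator design over the local
# sequence window, ordinary least squares on log(theta-hat), and
# cross-validated goodness of fit.
#
#   log(theta_j) = log(D) + sum_k sum_h beta_kh I(b_jk = h) + gamma*log(depth_j)
#
# Window positions k = 1..K map to signed offsets -K/2..-1, +1..+K/2 around
# the read-start base, which itself is excluded.

#' Design specification for the overdispersion regression
#'
#' @param K Even window length (default 80: 40 nt each side of the read
#'   start, following the hexamer-bias literature).
#' @param reference_base Base absorbed into the intercept (default `"G"`;
#'   coefficients are fitted for the other three bases).
#' @param include_depth Include the `log(depth)` column.
#' @param include_sequence Include the `3K` base-indicator columns.
#' @return List of class `design_spec` with the coded bases and signed
#'   window offsets.
#' @export
design_spec <- function(K = 80L, reference_base = "G",
                        include_depth = TRUE, include_sequence = TRUE) {
  K <- as.integer(K)
  if (K <= 0L || K %% 2L != 0L) stop("'K' must be even and positive")
  reference_base <- match.arg(reference_base, c("A", "C", "G", "T"))
  coded <- if (reference_base == "G") c("A", "T", "C") else
    setdiff(c("A", "T", "C", "G"), reference_base)
  structure(list(K = K, reference_base = reference_base, coded_bases = coded,
                 include_depth = isTRUE(include_depth),
                 include_sequence = isTRUE(include_sequence),
                 offsets = c(-(K %/% 2L):-1L, 1L:(K %/% 2L))),
            class = "design_spec")
}

seq_col_names <- function(spec) {
  as.vector(vapply(seq_len(spec$K), function(k)
    paste0("seq_", spec$offsets[k], "_", spec$coded_bases),
    character(length(spec$coded_bases))))
}

# positions x K character matrix from context strings (assumed complete)
context_matrix <- function(context, K) {
  mat <- matrix(unlist(strsplit(context, "", fixed = TRUE), use.names = FALSE),
                ncol = K, byrow = TRUE)
  mat
}

#' Build the regression design from dispersion observations
#'
#' Response is `log(theta_hat)`; predictors are an intercept, optionally
#' `log(depth)`, and optionally `3K` 0/1 base indicators over the window.
#' Rows with invalid estimates are dropped; when sequence columns are
#' requested, rows with missing or `N`-containing windows are dropped too
#' (they re-enter likelihood computation later with sequence effect 0).
#'
#' Non-positive moment estimates (sampling noise) are excluded by default:
#' flooring them to a fixed small value places a point mass many log-units
#' below the signal and badly attenuates the depth slope.  Set
#' `include_floored = TRUE` to keep the floored values instead.
#'
#' @param obs A [build_theta_observations()] data frame.
#' @param spec A [design_spec()].
#' @param include_floored Keep rows whose estimate was floored.
#' @return List of class `theta_design` with `y`, `X`, `rows` (indices into
#'   `obs`) and `spec`.
#' @export
build_design <- function(obs, spec = design_spec(), include_floored = FALSE) {
  if (!nrow(obs)) stop("empty observation set")
  keep <- !obs$invalid & is.finite(obs$theta_hat) & obs$theta_hat > 0
  if (!include_floored) keep <- keep & !obs$floored
  if (spec$include_sequence) keep <- keep & !obs$context_missing
  if (!any(keep)) stop("no usable rows for the design")
  obs_k <- obs[keep, , drop = FALSE]
  ncols <- 1L + spec$include_depth +
    (spec$include_sequence) * 3L * spec$K
  X <- matrix(0, nrow(obs_k), ncols)
  cn <- "(Intercept)"
  X[, 1L] <- 1
  j <- 1L
  if (spec$include_depth) {
    j <- j + 1L
    X[, j] <- log(obs_k$depth)
    cn <- c(cn, "log_depth")
  }
  if (spec$include_sequence) {
    bad_len <- nchar(obs_k$context) != spec$K
    if (any(bad_len)) stop("context length differs from K")
    cm <- context_matrix(obs_k$context, spec$K)
    for (k in seq_len(spec$K)) {
      for (h in spec$coded_bases) {
        j <- j + 1L
        X[, j] <- as.numeric(cm[, k] == h)
      }
    }
    cn <- c(cn, seq_col_names(spec))
  }
  colnames(X) <- cn
  structure(list(y = log(obs_k$theta_hat), X = X, rows = which(keep),
                 spec = spec),
            class = "theta_design")
}

variant_columns <- function(design, variant) {
  cn <- colnames(design$X)
  want <- switch(variant,
    full = cn,
    primer_free = setdiff(cn, seq_col_names(design$spec)),
    depth_free = setdiff(cn, "log_depth"),
    constant = "(Intercept)",
    stop("unknown model variant: ", variant))
  if (variant %in% c("full", "depth_free") && !design$spec$include_sequence)
    stop("design was built without sequence columns; variant '", variant,
         "' needs them")
  if (variant %in% c("full", "primer_free") && !design$spec$include_depth)
    stop("design was built without the depth column; variant '", variant,
         "' needs it")
  want
}

#' Fit an overdispersion model by least squares
#'
#' Ordinary least squares of `log(theta_hat)` on the requested predictor
#' subset.  Variants: `"full"` (depth + sequence), `"primer_free"` (depth
#' only, all `beta = 0`), `"depth_free"` (sequence only, `gamma = 0`),
#' `"constant"` (intercept only).  The log of sample dispersion is treated
#' as approximately Gaussian, which makes least squares an efficient
#' estimator of `gamma` and the `beta` coefficients.
#'
#' @param design A [build_design()] result.
#' @param variant Model variant.
#' @param strand Optional strand label stored with the fit.
#' @return List of class `overdispersion_model` with `logD` (intercept),
#'   `gamma`, `beta` (named `3K` vector, or `NULL` when the variant has no
#'   sequence term), fit diagnostics (`sigma2`, `n_obs`, `r_squared`), and
#'   the design spec.
#' @export
fit_theta_model <- function(design, variant = c("full", "primer_free",
                                                "depth_free", "constant"),
                            strand = NA_character_) {
  variant <- match.arg(variant)
  cols <- variant_columns(design, variant)
  X <- design$X[, cols, drop = FALSE]
  y <- design$y
  if (nrow(X) < ncol(X)) stop("fewer rows than columns: cannot fit")
  # degenerate all-constant predictors carry no information; drop with warning
  keep_col <- rep(TRUE, ncol(X))
  if (ncol(X) > 1L) {
    sds <- apply(X[, -1L, drop = FALSE], 2L, function(v) max(v) - min(v))
    if (any(sds == 0)) {
      warning("dropping constant predictor(s): ",
              paste(colnames(X)[-1L][sds == 0], collapse = ", "))
      keep_col[-1L][sds == 0] <- FALSE
    }
  }
  fit <- stats::lm.fit(X[, keep_col, drop = FALSE], y)
  rank_deficient <- fit$rank < sum(keep_col)
  if (rank_deficient)
    warning("rank-deficient design; unidentifiable coefficients set to 0")
  coefs <- stats::setNames(rep(0, ncol(X)), colnames(X))
  got <- fit$coefficients
  got[is.na(got)] <- 0
  coefs[names(got)] <- got
  res <- fit$residuals
  sigma2 <- sum(res^2) / max(1L, nrow(X) - fit$rank)
  sst <- sum((y - mean(y))^2)
  spec <- design$spec
  beta <- NULL
  if (variant %in% c("full", "depth_free")) {
    beta <- coefs[seq_col_names(spec)]
  }
  structure(list(variant = variant,
                 logD = unname(coefs["(Intercept)"]),
                 gamma = if (variant %in% c("full", "primer_free"))
                   unname(coefs["log_depth"]) else 0,
                 beta = beta,
                 K = spec$K,
                 reference_base = spec$reference_base,
                 coded_bases = spec$coded_bases,
                 offsets = spec$offsets,
                 strand = strand,
                 sigma2 = sigma2,
                 n_obs = nrow(X),
                 r_squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
                 rank_deficient = rank_deficient),
            class = "overdispersion_model")
}

#' @export
print.overdispersion_model <- function(x, ...) {
  cat(sprintf("overdispersion model '%s' (strand %s): log D = %.4f, gamma = %.4f\n",
              x$variant, x$strand, x$logD, x$gamma))
  if (!is.null(x$beta))
    cat(sprintf("  %d local-sequence coefficients over a %d-nt window (ref %s)\n",
                length(x$beta), x$K, x$reference_base))
  cat(sprintf("  n = %d, residual variance = %.4f, in-sample R2 = %.3f\n",
              x$n_obs, x$sigma2, x$r_squared))
  invisible(x)
}

#' Cross-validated goodness of fit of an overdispersion model
#'
#' Observations are randomly split into `folds` groups of equal size; each
#' group in turn is held out, the model fitted on the rest, and R-squared
#' computed on the held-out group as the regression sum of squares divided
#' by the total sum of squares (`r2`); the conventional
#' `1 - SSE/SST` is reported alongside (`r2_sse`).  The whole split is
#' repeated `repeats` times and the overall value is the mean of all
#' `folds * repeats` rounds.
#'
#' @param obs A [build_theta_observations()] data frame.
#' @param spec A [design_spec()].
#' @param variant Model variant, as in [fit_theta_model()].
#' @param folds,repeats Cross-validation layout (default 5-fold, 10
#'   repeats).
#' @param seed Integer seed making the splits reproducible.
#' @return List of class `cv_result` with `r_squared` (mean SSR/SST),
#'   `r_squared_sse`, and `per_round` (one row per fold and repeat).
#' @export
cross_validated_r2 <- function(obs, spec = design_spec(),
                               variant = "full", folds = 5L, repeats = 10L,
                               seed = 1L) {
  design <- build_design(obs, spec)
  cols <- variant_columns(design, variant)
  X <- design$X[, cols, drop = FALSE]
  y <- design$y
  n <- length(y)
  if (n < folds * ncol(X)) stop("insufficient rows for cross-validation")
  set.seed(seed)
  out <- vector("list", repeats * folds)
  i <- 0L
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- stats::lm.fit(X[!test, , drop = FALSE], y[!test])
      bh <- fit$coefficients
      bh[is.na(bh)] <- 0
      pred <- drop(X[test, , drop = FALSE] %*% bh)
      yt <- y[test]
      sst <- sum((yt - mean(yt))^2)
      i <- i + 1L
      out[[i]] <- data.frame(repeat_ = r, fold = f,
                             r2 = sum((pred - mean(yt))^2) / sst,
                             r2_sse = 1 - sum((yt - pred)^2) / sst)
    }
  }
  per_round <- do.call(rbind, out)
  structure(list(variant = variant,
                 r_squared = mean(per_round$r2),
                 r_squared_sse = mean(per_round$r2_sse),
                 per_round = per_round),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validated R2 (%s): %.3f (SSR/SST) / %.3f (1 - SSE/SST) over %d rounds\n",
              x$variant, x$r_squared, x$r_squared_sse, nrow(x$per_round)))
  invisible(x)
}

#' Local-sequence coefficient profile
#'
#' Reindexes the fitted `beta` coefficients to signed offsets around the
#' read start (negative upstream, positive downstream; the read-start base
#' itself, offset 0, is excluded) for plotting against position.
#'
#' @param model An [fit_theta_model()] result with sequence coefficients.
#' @return Data frame with columns `offset`, `base`, `estimate`.
#' @export
coefficient_profile <- function(model) {
  if (is.null(model$beta))
    stop("model variant '", model$variant, "' has no sequence coefficients")
  data.frame(
    offset = rep(model$offsets, each = length(model$coded_bases)),
    base = rep(model$coded_bases, times = model$K),
    estimate = unname(model$beta))
}

#' Sequence effect of an overdispersion model
#'
#' Evaluates `sum_k beta_k,base(k)` for each context window; windows that
#' are missing, incomplete or contain `N` contribute 0 (those positions
#' still enter the likelihood, with no sequence adjustment).
#'
#' @param model An `overdispersion_model`.
#' @param context Character vector of `K`-mers (may contain `NA`).
#' @return Numeric vector of per-position sequence effects.
#' @export
seq_effect <- function(model, context) {
  out <- numeric(length(context))
  if (is.null(model$beta)) return(out)
  ok <- !is.na(context) & nchar(context) == model$K & !grepl("N", context)
  if (!any(ok)) return(out)
  bases <- c("A", "C", "G", "T")
  bm <- matrix(0, model$K, 4L, dimnames = list(NULL, bases))
  nb <- length(model$coded_bases)
  for (k in seq_len(model$K)) {
    bm[k, model$coded_bases] <- model$beta[(k - 1L) * nb + seq_len(nb)]
  }
  cm <- context_matrix(context[ok], model$K)
  eff <- numeric(nrow(cm))
  for (k in seq_len(model$K)) {
    eff <- eff + bm[k, ][cm[, k]]
  }
  out[ok] <- eff
  out
}

#' Write a fitted overdispersion model to a coefficient file
#'
#' Flat tab-separated table (`term`, `position_offset`, `base`, `estimate`)
#' preceded by a small structured header (`# key value` lines).
#'
#' @param model An `overdispersion_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# variant", model$variant),
               paste("# strand", model$strand),
               paste("# K", model$K),
               paste("# reference_base", model$reference_base)), con)
  tab <- data.frame(term = c("intercept", "log_depth"),
                    position_offset = NA_integer_, base = NA_character_,
                    estimate = c(model$logD, model$gamma))
  if (!is.null(model$beta)) {
    prof <- coefficient_profile(model)
    tab <- rbind(tab, data.frame(term = "sequence",
                                 position_offset = prof$offset,
                                 base = prof$base, estimate = prof$estimate))
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path Coefficient file path.
#' @return An `overdispersion_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " "))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  tab <- utils::read.delim(text = lines[!startsWith(lines, "# ")],
                           stringsAsFactors = FALSE)
  spec <- design_spec(K = as.integer(meta[["K"]]),
                      reference_base = meta[["reference_base"]])
  variant <- meta[["variant"]]
  beta <- NULL
  if (variant %in% c("full", "depth_free")) {
    seqs <- tab[tab$term == "sequence", ]
    beta <- stats::setNames(rep(0, 3L * spec$K), seq_col_names(spec))
    beta[paste0("seq_", seqs$position_offset, "_", seqs$base)] <- seqs$estimate
  }
  structure(list(variant = variant,
                 logD = tab$estimate[tab$term == "intercept"],
                 gamma = tab$estimate[tab$term == "log_depth"],
                 beta = beta, K = spec$K,
                 reference_base = spec$reference_base,
                 coded_bases = spec$coded_bases, offsets = spec$offsets,
                 strand = meta[["strand"]],
                 sigma2 = NA_real_, n_obs = NA_integer_,
                 r_squared = NA_real_, rank_deficient = FALSE),
            class = "overdispersion_model")
}
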