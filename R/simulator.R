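# Ground-truth simulator for base-level read-start counts.
#
# A sample pair is generated position by position: the total t_ij is drawn
# from a log-normal-rate Poisson depth model (optionally modulated by the
# first four bases downstream of the start, emulating hexamer-priming
# enrichment), the overdispersion theta_ij is evaluated from the generative
# model using the drawn total as the depth covariate, and n_ij is split off
# t_ij beta-binomially with the gene's true proportion.
#
# Replicate sets use the equivalent gamma-Poisson construction: sample s at
# position j draws u_sj ~ Gamma(shape = 1/(2 theta_j), rate = shape) and
# x_sj ~ Poisson(lambda_j/2 * u_sj), so that conditional on the pair total
# any two samples form an exact beta-binomial pair with proportion 1/2 and
# overdispersion theta_j (evaluated at the expected pair depth lambda_j).

#' Simulation configuration
#'
#' Defaults describe a deeply sequenced spike-in-like experiment: 200 genes
#' of 500 nt, per-position pair totals log-normal around 200 (spanning
#' roughly 10 to 10^4), and a depth-dependent overdispersion
#' `theta = D * depth^gamma` with `D = 1`, `gamma = -0.8`, i.e. theta about
#' 0.025 at depth 100, declining with depth.
#'
#' @param G Number of genes.
#' @param gene_length Fixed length, or `c(min, max)` for uniform lengths.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of the expected
#'   per-position pair total.
#' @param p_n Shared proportion of non-changed genes (sample-1 fraction).
#' @param de_fraction Fraction of genes that are differentially expressed.
#' @param de_p Proportion of the DE genes.
#' @param theta_model List with `variant` (`"binomial"`, `"constant"`,
#'   `"primer_free"`, `"full"`), `D`, `gamma`, and for `"full"` /
#'   `"depth_free"` a `beta` data frame with columns `offset`, `base`,
#'   `value` (unlisted coefficients are 0).
#' @param K Local-sequence window length.
#' @param seq_depth_multipliers Named numeric vector of depth multipliers
#'   keyed by the first four downstream bases (e.g.
#'   `c(GGGG = 4, AAAA = 0.25)`); `NULL` disables sequence-modulated depth.
#' @param tail_factor,tail_length Multiplier applied to theta over the last
#'   `tail_length` positions of each gene (fragmentation-after-PCR tail
#'   effect); `tail_factor = 1` disables it.
#' @param strand Strand label of the simulated tracks.
#' @param base_probs Composition of the random gene sequences.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(G = 200L, gene_length = 500L,
                       depth_meanlog = log(200), depth_sdlog = 1.5,
                       p_n = 0.5, de_fraction = 0, de_p = 0.7,
                       theta_model = list(variant = "primer_free", D = 1,
                                          gamma = -0.8, beta = NULL),
                       K = 80L,
                       seq_depth_multipliers = NULL,
                       tail_factor = 1, tail_length = 200L,
                       strand = "antisense",
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for every simulation")
  stopifnot(G >= 1, all(gene_length >= 1), depth_sdlog >= 0,
            p_n > 0, p_n < 1, de_fraction >= 0, de_fraction <= 1,
            de_p > 0, de_p < 1, tail_factor > 0)
  if (!is.null(theta_model$D) && theta_model$D < 0)
    stop("theta scale D must be non-negative")
  structure(list(G = as.integer(G), gene_length = gene_length,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 p_n = p_n, de_fraction = de_fraction, de_p = de_p,
                 theta_model = theta_model, K = as.integer(K),
                 seq_depth_multipliers = seq_depth_multipliers,
                 tail_factor = tail_factor, tail_length = as.integer(tail_length),
                 strand = strand, base_probs = base_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Beta-binomial random draws
#'
#' @param t Totals (vector).
#' @param p Proportion.
#' @param theta Overdispersion per draw (vector, recycled); 0 gives
#'   binomial draws.
#' @return Integer vector of sample-1 counts.
#' @export
rbetabinom <- function(t, p, theta) {
  k <- length(t)
  theta <- rep_len(theta, k)
  out <- integer(k)
  bin <- theta == 0 | t == 0
  if (any(bin)) out[bin] <- stats::rbinom(sum(bin), t[bin], p)
  if (any(!bin)) {
    q <- stats::rbeta(sum(!bin), p / theta[!bin], (1 - p) / theta[!bin])
    out[!bin] <- stats::rbinom(sum(!bin), t[!bin], q)
  }
  out
}

random_gene_sequences <- function(G, lengths, base_probs) {
  bases <- names(base_probs)
  vapply(seq_len(G), function(i)
    paste(sample(bases, lengths[i], replace = TRUE, prob = base_probs),
          collapse = ""),
    character(1))
}

sim_gene_lengths <- function(cfg) {
  if (length(cfg$gene_length) == 1L) rep(as.integer(cfg$gene_length), cfg$G)
  else sample(seq(cfg$gene_length[1], cfg$gene_length[2]), cfg$G, replace = TRUE)
}

# per-position depth multipliers from the first four downstream bases
depth_multipliers <- function(sequence, L, mult) {
  if (is.null(mult)) return(rep(1, L))
  down4 <- substring(sequence, seq_len(L) + 1L, seq_len(L) + 4L)
  out <- rep(1, L)
  hit <- match(down4, names(mult))
  ok <- !is.na(hit) & nchar(down4) == 4L
  out[ok] <- mult[hit[ok]]
  out
}

# beta data frame -> named coefficient vector aligned with the design
beta_truth_vector <- function(beta, spec) {
  out <- stats::setNames(rep(0, 3L * spec$K), seq_col_names(spec))
  if (is.null(beta)) return(out)
  nm <- paste0("seq_", beta$offset, "_", beta$base)
  bad <- !nm %in% names(out)
  if (any(bad)) stop("planted beta outside the window/coded bases: ",
                     paste(nm[bad], collapse = ", "))
  out[nm] <- beta$value
  out
}

truth_model <- function(cfg) {
  tm <- cfg$theta_model
  spec <- design_spec(K = cfg$K)
  m <- constant_model()
  m$variant <- tm$variant
  m$K <- spec$K
  m$reference_base <- spec$reference_base
  m$coded_bases <- spec$coded_bases
  m$offsets <- spec$offsets
  m$logD <- log(max(tm$D, .Machine$double.xmin))
  m$gamma <- if (!is.null(tm$gamma)) tm$gamma else 0
  if (tm$variant %in% c("full", "depth_free"))
    m$beta <- beta_truth_vector(tm$beta, spec)
  m
}

theta_from_truth <- function(model, cfg, depth, context, L) {
  if (model$variant == "binomial") return(rep(0, L))
  eta <- model$logD
  if (model$variant %in% c("primer_free", "full"))
    eta <- eta + model$gamma * log(pmax(depth, 1))
  eta <- eta + seq_effect(model, context)
  theta <- rep_len(exp(eta), L)
  theta[depth == 0] <- 0
  if (cfg$tail_factor != 1 && cfg$tail_length > 0) {
    tail_idx <- seq.int(max(1L, L - cfg$tail_length + 1L), L)
    theta[tail_idx] <- theta[tail_idx] * cfg$tail_factor
  }
  theta
}

#' Simulate a sample pair with known truth
#'
#' Per position: the total `t` is Poisson with a log-normal rate
#' (sequence-modulated when configured), `theta` is evaluated from the
#' generative overdispersion model using the drawn total as the depth
#' covariate, and `n ~ beta-binomial(t; p_i, theta)`, `m = t - n`.
#'
#' @param cfg A [sim_config()].
#' @return List with `pairs` (named per-gene [pair_counts()]), `genes`
#'   ([gene_models()]), and `truth` (per-gene proportions, DE labels,
#'   per-position theta and totals, the generating model and config).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lengths <- sim_gene_lengths(cfg)
  seqs <- random_gene_sequences(cfg$G, lengths, cfg$base_probs)
  ids <- sprintf("g%04d", seq_len(cfg$G))
  genes <- gene_models(ids, seqs, strand = cfg$strand)
  n_de <- round(cfg$de_fraction * cfg$G)
  de <- stats::setNames(rep(FALSE, cfg$G), ids)
  if (n_de > 0) de[sample(cfg$G, n_de)] <- TRUE
  p_true <- stats::setNames(ifelse(de, cfg$de_p, cfg$p_n), ids)
  model <- truth_model(cfg)
  pairs <- theta_truth <- depth_truth <- vector("list", cfg$G)
  names(pairs) <- names(theta_truth) <- names(depth_truth) <- ids
  for (i in seq_len(cfg$G)) {
    L <- lengths[i]
    ctx <- position_contexts(seqs[i], seq_len(L) - 1L, cfg$K)
    lambda <- stats::rlnorm(L, cfg$depth_meanlog, cfg$depth_sdlog) *
      depth_multipliers(seqs[i], L, cfg$seq_depth_multipliers)
    t <- stats::rpois(L, lambda)
    theta <- theta_from_truth(model, cfg, t, ctx, L)
    n <- rbetabinom(t, p_true[i], theta)
    a <- base_start_counts(ids[i], "s1", cfg$strand, n)
    b <- base_start_counts(ids[i], "s2", cfg$strand, t - n)
    pairs[[i]] <- pair_counts(a, b, genes[i, ], K = cfg$K)
    theta_truth[[i]] <- theta
    depth_truth[[i]] <- t
  }
  list(pairs = pairs, genes = genes,
       truth = list(p = p_true, de = de, theta = theta_truth,
                    depth = depth_truth, model = model, config = cfg))
}

#' Simulate a set of exchangeable replicate samples
#'
#' All samples share the neutral proportion; conditional on any pair's
#' total, the split is exactly beta-binomial with the configured
#' overdispersion (gamma-Poisson construction), so every unordered pair is
#' a valid replicate pair.  The overdispersion is evaluated at the expected
#' pair depth; an optional per-sample library-effect multiplier jitters the
#' effective pair-specific scale `D`.
#'
#' @param cfg A [sim_config()] (replicates are simulated with balanced
#'   library sizes, so the pairwise proportion is 1/2).
#' @param n_samples Number of replicate samples (>= 2).
#' @param jitter_sd Log-normal standard deviation of the per-sample
#'   dispersion multiplier (0 = all pairs share `D` exactly).
#' @return List with `counts` (per gene, a positions x samples matrix),
#'   `genes`, `sample_ids`, and `truth`.
#' @export
simulate_replicates <- function(cfg, n_samples = 4L, jitter_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"), n_samples >= 2L)
  set.seed(cfg$seed)
  lengths <- sim_gene_lengths(cfg)
  seqs <- random_gene_sequences(cfg$G, lengths, cfg$base_probs)
  ids <- sprintf("g%04d", seq_len(cfg$G))
  genes <- gene_models(ids, seqs, strand = cfg$strand)
  model <- truth_model(cfg)
  d_s <- exp(stats::rnorm(n_samples, 0, jitter_sd))
  counts <- theta_truth <- lambda_truth <- vector("list", cfg$G)
  names(counts) <- names(theta_truth) <- names(lambda_truth) <- ids
  for (i in seq_len(cfg$G)) {
    L <- lengths[i]
    ctx <- position_contexts(seqs[i], seq_len(L) - 1L, cfg$K)
    lambda <- stats::rlnorm(L, cfg$depth_meanlog, cfg$depth_sdlog) *
      depth_multipliers(seqs[i], L, cfg$seq_depth_multipliers)
    theta <- theta_from_truth(model, cfg, lambda, ctx, L)
    x <- matrix(0L, L, n_samples)
    for (s in seq_len(n_samples)) {
      pos <- theta * d_s[s] > 0
      u <- rep(1, L)
      if (any(pos)) {
        shape <- 1 / (2 * theta[pos] * d_s[s])
        u[pos] <- stats::rgamma(sum(pos), shape = shape, rate = shape)
      }
      x[, s] <- stats::rpois(L, lambda / 2 * u)
    }
    counts[[i]] <- x
    theta_truth[[i]] <- theta
    lambda_truth[[i]] <- lambda
  }
  list(counts = counts, genes = genes,
       sample_ids = sprintf("r%02d", seq_len(n_samples)),
       truth = list(theta = theta_truth, lambda = lambda_truth,
                    d_sample = d_s, model = model, config = cfg))
}

#' Build replicate pair sets from simulated replicates
#'
#' Converts a [simulate_replicates()] result into the list-of-pairs
#' structure consumed by [build_theta_observations()] and [train()].
#'
#' @param sim A [simulate_replicates()] result.
#' @param pairs 2-row matrix of sample index pairs (default: all unordered
#'   combinations).
#' @return List over pairs of named per-gene [pair_counts()] lists.
#' @export
replicate_pair_set <- function(sim, pairs = NULL) {
  n_samples <- length(sim$sample_ids)
  if (is.null(pairs)) pairs <- utils::combn(n_samples, 2L)
  cfg <- sim$truth$config
  # contexts are shared across pairs; compute once per gene
  ctxs <- lapply(seq_len(nrow(sim$genes)), function(i)
    position_contexts(sim$genes$sequence[i],
                      seq_len(sim$genes$length[i]) - 1L, cfg$K))
  lapply(seq_len(ncol(pairs)), function(r) {
    s1 <- pairs[1, r]; s2 <- pairs[2, r]
    out <- lapply(seq_len(nrow(sim$genes)), function(i) {
      g <- sim$genes[i, ]
      n <- sim$counts[[g$gene_id]][, s1]
      m <- sim$counts[[g$gene_id]][, s2]
      structure(list(gene_id = g$gene_id, strand = g$strand,
                     positions = seq_len(g$length) - 1L,
                     n = as.numeric(n), m = as.numeric(m),
                     depth = as.numeric(n + m), context = ctxs[[i]],
                     K = cfg$K),
                class = "paired_counts")
    })
    stats::setNames(out, sim$genes$gene_id)
  })
}

#' Write simulator output as text fixtures
#'
#' Emits the tab-separated count table, the gene FASTA, a sample sheet and
#' the ground-truth tables; the files round-trip through
#' [load_counts_table()] / [read_gene_fasta()] to the in-memory objects.
#' Optionally also writes one minimal coordinate-sorted BAM per sample
#' (single-end reads, one per counted start).
#'
#' @param sim A [simulate_pair()] or [simulate_replicates()] result.
#' @param dir Output directory (created if needed).
#' @param bam Also emit BAM files (requires `Rsamtools`).
#' @param read_length Read length used for the emitted alignments.
#' @return Named list of written paths, invisibly.
#' @export
emit_fixtures <- function(sim, dir, bam = FALSE, read_length = 36L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sim$genes
  paths <- list(fasta = file.path(dir, "genes.fa"),
                counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth_genes.tsv"))
  write_gene_fasta(genes, paths$fasta)
  tracks <- list()
  if (!is.null(sim$pairs)) {
    sample_ids <- c("s1", "s2")
    group <- c("group1", "group2")
    for (g in names(sim$pairs)) {
      pc <- sim$pairs[[g]]
      tracks[[counts_key(g, pc$strand, "s1")]] <-
        base_start_counts(g, "s1", pc$strand, pc$n)
      tracks[[counts_key(g, pc$strand, "s2")]] <-
        base_start_counts(g, "s2", pc$strand, pc$m)
    }
    truth <- data.frame(gene_id = names(sim$truth$p),
                        p_true = unname(sim$truth$p),
                        de = unname(sim$truth$de))
  } else {
    sample_ids <- sim$sample_ids
    group <- rep("rep", length(sample_ids))
    for (g in genes$gene_id) {
      st <- genes$strand[genes$gene_id == g]
      for (s in seq_along(sample_ids)) {
        tracks[[counts_key(g, st, sample_ids[s])]] <-
          base_start_counts(g, sample_ids[s], st, sim$counts[[g]][, s])
      }
    }
    truth <- data.frame(gene_id = genes$gene_id, p_true = 0.5, de = FALSE)
  }
  write_counts_table(tracks, paths$counts)
  utils::write.table(data.frame(sample_id = sample_ids, group = group),
                     paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (bam) {
    for (s in sample_ids) {
      keys <- names(tracks)[endsWith(names(tracks), paste0("\r", s))]
      paths[[paste0("bam_", s)]] <-
        write_minimal_bam(tracks[keys], genes, file.path(dir, s), read_length)
    }
  }
  invisible(paths)
}

# Write tracks as SAM text and convert to a sorted, indexed BAM.
write_minimal_bam <- function(tracks, genes, stem, read_length = 36L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("writing BAM requires the 'Rsamtools' package")
  sam <- paste0(stem, ".sam")
  con <- file(sam, "w")
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (i in seq_len(nrow(genes)))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", genes$gene_id[i], genes$length[i]), con)
  qn <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (key in names(tracks)) {
      bc <- tracks[[key]]
      if (bc$gene_id != g$gene_id) next
      nz <- which(bc$counts > 0)
      for (j in nz) {
        len <- min(read_length, g$length - j + 1L)
        seqr <- substr(g$sequence, j, j + len - 1L)
        for (k in seq_len(bc$counts[j])) {
          qn <- qn + 1L
          writeLines(sprintf("r%07d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                             qn, g$gene_id, j, len, seqr), con)
        }
      }
    }
  }
  close(con)
  bam <- Rsamtools::asBam(sam, stem, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}
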