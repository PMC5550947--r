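# I/O and construction of base-level read-start count tracks.
# Coordinates are 0-based half-open internally; 1-based only at text-format
# boundaries (SAM/BAM POS).

#' Gene models (spliced transcript sequences)
#'
#' A gene model is one contiguous nucleotide sequence per gene (spliced
#' transcript coordinates); projecting multi-exon genomic alignments onto
#' transcripts is the caller's responsibility.  The strand label records
#' which cDNA strand the read-start track belongs to and is used to fit
#' local-sequence coefficients separately per strand.
#'
#' @param gene_id Character vector of unique identifiers.
#' @param sequence Character vector of sequences over A/C/G/T/N, same length.
#' @param strand `"sense"` or `"antisense"` (recycled).
#' @return A `data.frame` of class `gene_models` with columns `gene_id`,
#'   `strand`, `length`, `sequence`.
#' @export
#' @examples
#' gene_models("g1", "ACGTACGT")
gene_models <- function(gene_id, sequence, strand = "antisense") {
  stopifnot(length(gene_id) == length(sequence))
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  strand <- rep_len(match.arg(strand, c("sense", "antisense"), several.ok = TRUE),
                    length(gene_id))
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) stop("sequences may only contain A, C, G, T, N: ",
                     paste(gene_id[bad], collapse = ", "))
  if (any(nchar(sequence) == 0)) stop("gene length must be positive")
  structure(
    data.frame(gene_id = as.character(gene_id), strand = strand,
               length = nchar(sequence), sequence = sequence,
               stringsAsFactors = FALSE),
    class = c("gene_models", "data.frame"))
}

#' Read gene/transcript sequences from a FASTA file
#'
#' @param path FASTA file (one record per gene/transcript).
#' @param strand Strand label attached to every gene.
#' @return A [gene_models()] data frame.
#' @export
read_gene_fasta <- function(path, strand = "antisense") {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the 'Biostrings' package")
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  gene_models(ids, as.character(seqs), strand = strand)
}

#' Write gene sequences to FASTA
#' @param genes A [gene_models()] data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(stats::setNames(genes$sequence, genes$gene_id))
    Biostrings::writeXStringSet(x, path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(genes))) {
      writeLines(paste0(">", genes$gene_id[i]), con)
      writeLines(substring(genes$sequence[i],
                           seq(1, genes$length[i], 60),
                           pmin(seq(60, genes$length[i] + 59, 60), genes$length[i])),
                 con)
    }
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `group` and optionally
#' `library_id`.
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(ss)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  ss
}

#' Filtering configuration for count tracks
#'
#' @param read_length_trim Positions removed from the 3' end of each gene
#'   where no full-length read can start (e.g. 76 for 76-nt reads).
#' @param tail_trim Additional 3'-end removal; 200 is recommended for
#'   protocols that size-select fragments after PCR amplification, where the
#'   transcript tail shows inflated overdispersion.
#' @param min_depth Minimum per-pair total depth `n + m` for a position to
#'   enter dispersion estimation.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(read_length_trim = 0L, tail_trim = 0L, min_depth = 5L) {
  stopifnot(read_length_trim >= 0, tail_trim >= 0, min_depth >= 0)
  structure(list(read_length_trim = as.integer(read_length_trim),
                 tail_trim = as.integer(tail_trim),
                 min_depth = as.integer(min_depth)),
            class = "filter_config")
}

#' Per-gene read-start count track for one sample
#'
#' @param gene_id,sample_id,strand Identifiers.
#' @param counts Non-negative integer vector indexed by 0-based position.
#' @return List of class `base_counts`.
#' @export
base_start_counts <- function(gene_id, sample_id, strand, counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  structure(list(gene_id = gene_id, sample_id = sample_id,
                 strand = match.arg(strand, c("sense", "antisense")),
                 counts = as.numeric(counts)),
            class = "base_counts")
}

counts_key <- function(gene_id, strand, sample_id) {
  paste(gene_id, strand, sample_id, sep = "\r")
}

#' Load a per-base count table
#'
#' Reads a tab-separated table with columns `gene_id`, `strand`, `position`
#' (0-based), `sample_id`, `count` (gzip transparently supported) and
#' expands it into zero-filled per-gene tracks.
#'
#' @param path Count table path.
#' @param genes A [gene_models()] data frame supplying gene lengths.
#' @param sample_sheet Optional sample sheet (data frame with `sample_id`);
#'   rows whose `sample_id` is absent from it raise a configuration error.
#' @return Named list of [base_start_counts()] tracks, keyed internally by
#'   (gene, strand, sample); also carries a `samples` attribute.
#' @export
load_counts_table <- function(path, genes, sample_sheet = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "strand", "position", "sample_id", "count")
  if (nrow(tab) == 0) {
    warning("empty count table: ", path)
    return(structure(list(), samples = character(0)))
  }
  if (!all(need %in% names(tab)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$count < 0)) stop("negative count in ", path)
  if (!is.null(sample_sheet)) {
    unknown <- setdiff(unique(tab$sample_id), sample_sheet$sample_id)
    if (length(unknown))
      stop("sample_id not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  missing_genes <- setdiff(unique(tab$gene_id), genes$gene_id)
  if (length(missing_genes))
    stop("gene_id not in gene models: ", paste(missing_genes, collapse = ", "))
  len <- stats::setNames(genes$length, genes$gene_id)
  out <- list()
  for (grp in split(tab, counts_key(tab$gene_id, tab$strand, tab$sample_id))) {
    g <- grp$gene_id[1]
    L <- len[[g]]
    if (any(grp$position < 0 | grp$position >= L))
      stop("position out of range for gene ", g)
    cnt <- numeric(L)
    cnt[grp$position + 1L] <- grp$count
    key <- counts_key(g, grp$strand[1], grp$sample_id[1])
    out[[key]] <- base_start_counts(g, grp$sample_id[1], grp$strand[1], cnt)
  }
  structure(out, samples = unique(tab$sample_id))
}

#' Serialize count tracks to the tab-separated format
#'
#' Writes only positions with non-zero counts; [load_counts_table()]
#' restores the zero-filled tracks, so the round trip is exact.
#'
#' @param counts Named list of [base_start_counts()] tracks.
#' @param path Output path (use a `.gz` suffix for compression).
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  rows <- lapply(counts, function(bc) {
    nz <- which(bc$counts > 0)
    if (!length(nz)) return(NULL)
    data.frame(gene_id = bc$gene_id, strand = bc$strand,
               position = nz - 1L, sample_id = bc$sample_id,
               count = bc$counts[nz], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), strand = character(),
                      position = integer(), sample_id = character(),
                      count = numeric())
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate a count track at the 3' end
#'
#' Removes the last `read_length_trim + tail_trim` positions of the gene
#' (where no full-length read can start, plus the optional protocol-specific
#' tail), leaving positions `0 .. J - trims - 1`.  Trimmed positions are
#' removed, not zeroed.
#'
#' @param counts A [base_start_counts()] track covering the full gene.
#' @param gene One row of a [gene_models()] data frame.
#' @param cfg A [filter_config()].
#' @return The truncated track, or `NULL` (with a warning) when the trims
#'   consume the whole gene.
#' @export
apply_filters <- function(counts, gene, cfg = filter_config()) {
  stopifnot(inherits(counts, "base_counts"))
  trim <- cfg$read_length_trim + cfg$tail_trim
  if (length(counts$counts) != gene$length)
    stop("track length does not match gene length for ", gene$gene_id)
  if (trim >= gene$length) {
    warning("gene ", gene$gene_id, " excluded: trims >= gene length")
    return(NULL)
  }
  counts$counts <- counts$counts[seq_len(gene$length - trim)]
  counts
}

#' Local-sequence windows around positions
#'
#' Context of position `j` (0-based) is the `K/2` bases immediately before
#' and the `K/2` bases immediately after `j`; the read-start base itself is
#' excluded.  Positions whose window extends past the sequence get `NA`.
#'
#' @param sequence Gene sequence.
#' @param positions 0-based positions.
#' @param K Even window length.
#' @return Character vector of `K`-mers (or `NA`).
#' @export
position_contexts <- function(sequence, positions, K = 80L) {
  if (K %% 2L != 0L || K <= 0L) stop("'K' must be even and positive")
  L <- nchar(sequence)
  half <- K %/% 2L
  ok <- positions >= half & positions + half <= L - 1L
  out <- rep(NA_character_, length(positions))
  if (any(ok)) {
    j <- positions[ok]
    out[ok] <- paste0(substring(sequence, j - half + 1L, j),
                      substring(sequence, j + 2L, j + half + 1L))
  }
  out
}

#' Pair two count tracks position by position
#'
#' Builds the position-aligned pair `(n_j, m_j)` for one gene together with
#' the per-position total depth and the local-sequence window used by the
#' overdispersion model.
#'
#' @param a,b [base_start_counts()] tracks for the two samples (same gene,
#'   strand, and filtered positions).
#' @param gene Matching row of a [gene_models()] data frame (the full
#'   sequence: windows may extend into a trimmed tail).
#' @param K Even window length (default 80: 40 nt each side).
#' @return List of class `paired_counts` with `gene_id`, `strand`,
#'   `positions`, `n`, `m`, `depth`, `context`.
#' @export
pair_counts <- function(a, b, gene, K = 80L) {
  stopifnot(inherits(a, "base_counts"), inherits(b, "base_counts"))
  if (a$gene_id != b$gene_id || a$strand != b$strand)
    stop("tracks are for different genes or strands")
  if (length(a$counts) != length(b$counts))
    stop("alignment error: tracks cover different position sets")
  if (a$gene_id != gene$gene_id) stop("gene model does not match tracks")
  positions <- seq_along(a$counts) - 1L
  structure(list(gene_id = a$gene_id, strand = a$strand,
                 positions = positions, n = a$counts, m = b$counts,
                 depth = a$counts + b$counts,
                 context = position_contexts(gene$sequence, positions, K),
                 K = as.integer(K)),
            class = "paired_counts")
}

# reference-space width of a SAM CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    if (!length(ops)) return(NA_real_)
    n <- as.numeric(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

#' Extract read-start counts from a BAM file
#'
#' Counts, for every gene (BAM reference) and position, the uniquely mapped
#' reads whose 5' end maps there.  Uniqueness is approximated by a mapping
#' quality threshold.  In `stranded_mate` mode (dUTP protocol) the mate
#' identity assigns the strand: first-in-pair reads are counted on the
#' antisense strand, second-in-pair on the sense strand; in `unstranded`
#' mode every read is assigned the gene's annotated strand.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param genes A [gene_models()] data frame; genes absent from the BAM
#'   header are skipped with a warning.
#' @param strand_mode `"unstranded"` or `"stranded_mate"`.
#' @param mapq_min Minimum mapping quality for a read to count as uniquely
#'   mapped (default 10).
#' @param sample_id Sample label for the returned tracks (default: BAM base
#'   name).
#' @return Named list of [base_start_counts()] tracks.
#' @export
counts_from_bam <- function(bam, genes,
                            strand_mode = c("unstranded", "stranded_mate"),
                            mapq_min = 10L, sample_id = NULL) {
  strand_mode <- match.arg(strand_mode)
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the 'Rsamtools' package")
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index not found for ", bam)
  if (is.null(sample_id)) sample_id <- sub("\\.bam$", "", basename(bam))
  hdr <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  absent <- setdiff(genes$gene_id, hdr)
  if (length(absent))
    warning("genes absent from BAM header skipped: ",
            paste(absent, collapse = ", "))
  prm <- Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "mapq", "flag", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = prm)[[1]]
  keep <- !is.na(x$mapq) & x$mapq >= mapq_min
  x <- lapply(x, `[`, keep)
  # 5' start: leftmost base for + alignments, rightmost for - alignments
  start5 <- ifelse(x$strand == "-",
                   x$pos + cigar_ref_width(x$cigar) - 1, x$pos)
  read_strand <- if (strand_mode == "stranded_mate") {
    ifelse(bitwAnd(x$flag, 64L) > 0L, "antisense",
           ifelse(bitwAnd(x$flag, 128L) > 0L, "sense", NA_character_))
  } else rep(NA_character_, length(x$pos))
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    if (!g %in% hdr) next
    sel <- which(x$rname == g)
    st_vec <- if (strand_mode == "unstranded") rep(genes$strand[i], length(sel))
              else ifelse(is.na(read_strand[sel]), genes$strand[i], read_strand[sel])
    for (st in unique(c(genes$strand[i], st_vec))) {
      pos0 <- start5[sel[st_vec == st]] - 1  # to 0-based
      pos0 <- pos0[pos0 >= 0 & pos0 < genes$length[i]]
      cnt <- tabulate(pos0 + 1L, nbins = genes$length[i])
      out[[counts_key(g, st, sample_id)]] <-
        base_start_counts(g, sample_id, st, cnt)
    }
  }
  structure(out, samples = sample_id)
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("paired_counts: gene %s (%s), %d positions, sum n = %g, sum m = %g\n",
              x$gene_id, x$strand, length(x$positions), sum(x$n), sum(x$m)))
  invisible(x)
}
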