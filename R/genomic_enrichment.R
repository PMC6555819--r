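# Genomic enrichment: interval operations (via GenomicRanges), PWM region
# scoring, and ROC/AUC with Wilcoxon rank-sum significance. All user-facing
# coordinates are 0-based half-open (BED convention).

regions_to_gr <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start < 0) || any(x$start >= x$end))
    stop("invalid intervals: need 0 <= start < end", call. = FALSE)
  strand <- if ("strand" %in% names(x))
    ifelse(x$strand %in% c("+", "-"), x$strand, "*") else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1L, x$end),
                         strand = strand)
}

gr_to_regions <- function(gr, template = NULL) {
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  out
}

#' Reciprocal-overlap filter
#'
#' Returns the intervals of `a` that have a partner in `b` covering at least
#' `frac` of each interval's own length (boundary inclusive). With the default
#' `frac = 0.5` this is the 50% reciprocal-overlap rule used to define
#' reproducible bound regions.
#'
#' @param a,b Region data.frames (`chrom`, `start`, `end`, 0-based half-open).
#' @param frac Required fraction of both lengths, in (0, 1].
#' @return The qualifying rows of `a`.
#' @export
reciprocal_overlap <- function(a, b, frac = 0.5) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  if (!nrow(a) || !nrow(b)) return(a[integer(0), , drop = FALSE])
  ga <- regions_to_gr(a)
  gb <- regions_to_gr(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
  if (!length(hits)) return(a[integer(0), , drop = FALSE])
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(ga[q], gb[s],
                                                       ignore.strand = TRUE))
  ok <- ov >= frac * GenomicRanges::width(ga[q]) &
        ov >= frac * GenomicRanges::width(gb[s])
  a[sort(unique(q[ok])), , drop = FALSE]
}

#' Size-matched negative regions from accessible chromatin
#'
#' Subtracts all bound (ChIP) regions from the accessible (DNase) regions and
#' draws, for every positive region, one random region of identical length
#' from the remaining space. Negatives therefore never intersect the bound
#' set, and their length multiset equals that of the positives.
#'
#' @param dnase,chip,positives Region data.frames (0-based half-open).
#' @param rng_seed Integer seed; output is reproducible given it.
#' @return Region data.frame of `nrow(positives)` negatives.
#' @export
build_negatives <- function(dnase, chip, positives, rng_seed = NULL) {
  eligible <- GenomicRanges::setdiff(
    GenomicRanges::reduce(regions_to_gr(dnase), ignore.strand = TRUE),
    GenomicRanges::reduce(regions_to_gr(chip), ignore.strand = TRUE),
    ignore.strand = TRUE)
  ew <- GenomicRanges::width(eligible)
  lens <- positives$end - positives$start
  deficit <- sum(!vapply(lens, function(L) any(ew >= L), TRUE))
  if (deficit > 0L)
    stop("insufficient eligible space: ", deficit, " positive region(s) have ",
         "no DNase-minus-ChIP interval long enough for size matching",
         call. = FALSE)
  with_rng(rng_seed, {
    rows <- lapply(lens, function(L) {
      ok <- which(ew >= L)
      slots <- ew[ok] - L + 1L
      j <- ok[sample.int(length(ok), 1L, prob = slots)]
      off <- sample.int(ew[j] - L + 1L, 1L) - 1L
      data.frame(chrom = as.character(GenomicRanges::seqnames(eligible[j])),
                 start = GenomicRanges::start(eligible[j]) - 1L + off,
                 end = GenomicRanges::start(eligible[j]) - 1L + off + L,
                 strand = ".", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$name <- sprintf("neg%04d", seq_len(nrow(out)))
    out
  })
}

# Log-odds sums for all windows of an encoded sequence; ambiguous bases (NA
# code) contribute log2(1) = 0 by the background-probability convention.
pwm_window_scores <- function(seq_int, S) {
  L <- ncol(S)
  nw <- length(seq_int) - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- S[cbind(seq_int[j:(j + nw - 1L)], j)]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

#' PWM score of a sequence
#'
#' Scans every window on both strands, summing per-position log-odds, and
#' aggregates by the maximum window score (default) or the sum over windows.
#' Invariant under reverse complement of the input. Ambiguity characters (N)
#' contribute zero.
#'
#' @param sequence DNA string, at least as long as the PWM.
#' @param pwm A [pwm_from_pfm()] matrix.
#' @param aggregate `"max"` (default) or `"sum"`.
#' @return Scalar score in bits.
#' @export
score_region <- function(sequence, pwm, aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  S <- as_base_matrix(unclass(pwm), "pwm")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string", call. = FALSE)
  fwd <- dna_encode(sequence)
  if (length(fwd) < ncol(S))
    stop("sequence (", length(fwd), " nt) shorter than the PWM (",
         ncol(S), " positions)", call. = FALSE)
  rev <- 5L - rev(fwd)          # NA stays NA
  all_scores <- c(pwm_window_scores(fwd, S), pwm_window_scores(rev, S))
  if (aggregate == "max") max(all_scores) else sum(all_scores)
}

#' Score a set of regions against a genome
#'
#' @param regions Region data.frame (0-based half-open).
#' @param genome `DNAStringSet`, FASTA path or character vector.
#' @param pwm A `pwm`.
#' @inheritParams score_region
#' @return Numeric vector of region scores.
#' @export
score_regions <- function(regions, genome, pwm, aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  genome <- load_genome(genome)
  seqs <- extract_region_sequences(regions, genome)
  vapply(seqs, score_region, 0, pwm = pwm, aggregate = aggregate,
         USE.NAMES = FALSE)
}

extract_region_sequences <- function(regions, genome) {
  genome <- load_genome(genome)
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss))
    stop("chromosome(s) missing from genome: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vapply(seq_len(nrow(regions)), function(i)
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i])), "")
}

#' ROC/AUC with Wilcoxon rank-sum significance
#'
#' AUC is the probability that a positive region outscores a negative one
#' (ties counted half), computed exactly from the Mann-Whitney U statistic:
#' `AUC = U / (n_pos * n_neg)`. Significance is the two-sided Wilcoxon
#' rank-sum test with continuity correction, Bonferroni-adjusted across the
#' `n_models` PWMs tested in the run.
#'
#' @param pos_scores,neg_scores Numeric score vectors (>= 1 each).
#' @param n_models Number of models tested, for Bonferroni (default 1).
#' @return Object of class `roc_result`: `auc`, `n_pos`, `n_neg`,
#'   `u_statistic`, `p_value`, `p_adjusted`, and `curve` (data.frame of
#'   FPR/TPR points).
#' @export
roc_auc <- function(pos_scores, neg_scores, n_models = 1L) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("pos_scores and neg_scores must be non-empty", call. = FALSE)
  if (!all(is.finite(pos_scores)) || !all(is.finite(neg_scores)))
    stop("scores must be finite", call. = FALSE)
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  wt <- suppressWarnings(stats::wilcox.test(pos_scores, neg_scores,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  u <- unname(wt$statistic)
  auc <- u / (n_pos * n_neg)

  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  curve <- data.frame(
    fpr = c(0, vapply(thr, function(t) mean(neg_scores >= t), 0)),
    tpr = c(0, vapply(thr, function(t) mean(pos_scores >= t), 0)))
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg, u_statistic = u,
                 p_value = wt$p.value,
                 p_adjusted = min(1, wt$p.value * n_models),
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC = %.3f (n_pos = %d, n_neg = %d)\n",
                     "  U = %.1f, p = %.3g, Bonferroni p = %.3g\n"),
              x$auc, x$n_pos, x$n_neg, x$u_statistic, x$p_value, x$p_adjusted))
  invisible(x)
}

#' Filter peaks to putative active (functional) regions
#'
#' Keeps peaks overlapping the strand-aware window upstream of the
#' transcription start site of any differentially expressed gene: for a
#' plus-strand gene with TSS at position `t` the window is `[t - window, t)`;
#' for a minus-strand gene at `p` it is `[p, p + window)`. The
#' `"up_and_down"` geometry uses `[t - window, t + window)` irrespective of
#' strand.
#'
#' @param peaks Region data.frame (0-based half-open).
#' @param tss data.frame with columns `gene`, `chrom`, `position` (0-based),
#'   `strand`.
#' @param de_genes Character vector of differentially expressed gene ids
#'   (e.g. fold-change > 2, adjusted p < 0.01 upon agonist treatment).
#' @param window Window size in bp (default 10000).
#' @param geometry `"upstream_only"` (default) or `"up_and_down"`.
#' @return The qualifying rows of `peaks`.
#' @export
active_peak_filter <- function(peaks, tss, de_genes, window = 10000L,
                               geometry = "upstream_only") {
  if (!geometry %in% c("upstream_only", "up_and_down"))
    stop("unknown geometry: ", geometry, call. = FALSE)
  de <- tss[tss$gene %in% de_genes, , drop = FALSE]
  if (!nrow(de) || !nrow(peaks)) return(peaks[integer(0), , drop = FALSE])
  if (geometry == "upstream_only" &&
      (!"strand" %in% names(de) || any(!de$strand %in% c("+", "-"))))
    stop("upstream_only geometry requires +/- strands for all DE TSSs",
         call. = FALSE)
  win <- if (geometry == "upstream_only") {
    data.frame(chrom = de$chrom,
               start = ifelse(de$strand == "+", de$position - window,
                              de$position),
               end = ifelse(de$strand == "+", de$position,
                            de$position + window))
  } else {
    data.frame(chrom = de$chrom, start = de$position - window,
               end = de$position + window)
  }
  win$start <- pmax(win$start, 0L)
  win <- win[win$end > win$start, , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(regions_to_gr(peaks),
                                      regions_to_gr(win),
                                      ignore.strand = TRUE)
  peaks[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Read / write BED interval files
#'
#' Thin wrappers over `rtracklayer` returning/accepting the package's 0-based
#' half-open region data.frames.
#'
#' @param path BED file path.
#' @param regions Region data.frame.
#' @return A region data.frame (read) or `path` invisibly (write).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- gr_to_regions(gr)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  gr <- regions_to_gr(regions)
  if ("name" %in% names(regions)) names(gr) <- regions$name
  if ("score" %in% names(regions)) gr$score <- regions$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
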