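#' Ground-truth occupancy model for synthetic PBM data
#'
#' The generative stand-in for heterodimer binding is a dual-mode additive
#' energy model: a full-site matrix over the 12 + spacer_len site positions,
#' and 5'/3' half-site matrices over 11 positions (5-bp flank plus the 6-bp
#' half-site), each weighted by a nonnegative mode weight, plus a constant
#' nonspecific baseline. Occupancy of a sequence is the Boltzmann-weighted sum
#' over all windows on both strands.
#'
#' @param full_energy,hs5_energy,hs3_energy 4 x L energy matrices (rows
#'   A,C,G,T; lower = better binding) or `NULL` for an absent mode.
#' @param mode_weights Named nonnegative weights `c(full=, h5=, h3=)`.
#' @param baseline Nonspecific signal added to every sequence (default 1).
#' @return Object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(full_energy = NULL, hs5_energy = NULL,
                               hs3_energy = NULL,
                               mode_weights = c(full = 1, h5 = 0, h3 = 0),
                               baseline = 1) {
  mats <- list(full = full_energy, h5 = hs5_energy, h3 = hs3_energy)
  for (nm in names(mats))
    if (!is.null(mats[[nm]])) mats[[nm]] <- as_base_matrix(mats[[nm]], nm)
  w <- c(full = 0, h5 = 0, h3 = 0)
  w[names(mode_weights)] <- mode_weights
  if (any(w < 0)) stop("mode weights must be nonnegative", call. = FALSE)
  active <- names(w)[w > 0]
  if (!length(active)) stop("at least one mode weight must be > 0", call. = FALSE)
  missing_mat <- active[vapply(mats[active], is.null, TRUE)]
  if (length(missing_mat))
    stop("mode(s) ", paste(missing_mat, collapse = ", "),
         " have weight > 0 but no energy matrix", call. = FALSE)
  if (!is.finite(baseline) || baseline < 0)
    stop("baseline must be a nonnegative finite scalar", call. = FALSE)
  structure(list(energies = mats, mode_weights = w, baseline = baseline),
            class = "ground_truth_model")
}

#' Noise model for simulated fluorescence
#'
#' Array intensities are positive and right-skewed, so replicate noise is
#' multiplicative lognormal; orientation o2 carries a constant multiplicative
#' bias emulating the orientation-specific effects seen on real arrays.
#'
#' @param lognormal_sigma Standard deviation of log-intensity noise (> 0
#'   required for a stochastic model; 0 allowed for noise-free simulation).
#' @param replicate_count Replicates per orientation the design assumes.
#' @param orientation_bias Multiplicative factor applied to o2 probes.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(lognormal_sigma = 0.1, replicate_count = 5L,
                        orientation_bias = 0.85) {
  if (lognormal_sigma < 0) stop("lognormal_sigma must be >= 0", call. = FALSE)
  if (replicate_count < 1L) stop("replicate_count must be >= 1", call. = FALSE)
  if (orientation_bias <= 0) stop("orientation_bias must be > 0", call. = FALSE)
  structure(list(lognormal_sigma = lognormal_sigma,
                 replicate_count = as.integer(replicate_count),
                 orientation_bias = orientation_bias),
            class = "noise_model")
}

# Additive energies of all windows of an encoded sequence under a 4 x L matrix.
window_energies <- function(seq_int, E) {
  L <- ncol(E)
  nw <- length(seq_int) - L + 1L
  s <- numeric(nw)
  for (j in seq_len(L)) s <- s + E[cbind(seq_int[j:(j + nw - 1L)], j)]
  s
}

#' Occupancy of a sequence under a ground-truth model
#'
#' Sums `w_mode * exp(-E_mode(window))` over every window on both strands and
#' every active mode, plus the baseline. Symmetric under reverse complement.
#'
#' @param sequence DNA string (ACGT).
#' @param model A [ground_truth_model()].
#' @return Nonnegative scalar.
#' @export
occupancy <- function(sequence, model) {
  stopifnot(inherits(model, "ground_truth_model"))
  sequence <- validate_dna(sequence, "sequence")
  fwd <- dna_encode(sequence)
  rev <- 5L - rev(fwd)                     # reverse complement in integer code
  occ <- model$baseline
  for (nm in names(model$energies)) {
    w <- model$mode_weights[[nm]]
    E <- model$energies[[nm]]
    if (is.null(E) || w == 0) next
    if (length(fwd) < ncol(E))
      stop("sequence (", length(fwd), " nt) shorter than the ", nm,
           " energy window (", ncol(E), " nt)", call. = FALSE)
    occ <- occ + w * (sum(exp(-window_energies(fwd, E))) +
                      sum(exp(-window_energies(rev, E))))
  }
  occ
}

occupancy_many <- function(sequences, model) {
  vapply(sequences, occupancy, 0, model = model, USE.NAMES = FALSE)
}

#' Simulate a PBM fluorescence table
#'
#' One intensity per probe: occupancy of its (orientation-independent)
#' sequence, times the o2 orientation bias where applicable, times lognormal
#' replicate noise, times a constant gain. The true occupancies are retained
#' in the `truth` attribute.
#'
#' @param library A [build_library()] object.
#' @param model A [ground_truth_model()].
#' @param noise A [noise_model()].
#' @param rng_seed Integer seed; tables are bitwise reproducible given it.
#' @param gain Constant fluorescence scale factor (default 100).
#' @param array_id Label recorded in the `array_id` column.
#' @return data.frame of class `fluorescence_table` with columns `probe_id`,
#'   `intensity`, `array_id`; attribute `truth` holds per-sequence occupancy.
#' @export
simulate_fluorescence <- function(library, model, noise, rng_seed = NULL,
                                  gain = 100, array_id = "array1") {
  stopifnot(inherits(library, "probe_library"),
            inherits(model, "ground_truth_model"),
            inherits(noise, "noise_model"))
  probes <- library$probes
  useq <- unique(probes$unique_seq)
  occ <- occupancy_many(useq, model)
  occ_probe <- occ[match(probes$unique_seq, useq)]
  bias <- ifelse(probes$orientation == "o2", noise$orientation_bias, 1)
  intensity <- with_rng(rng_seed,
    occ_probe * bias * gain *
      stats::rlnorm(nrow(probes), 0, noise$lognormal_sigma))
  out <- data.frame(probe_id = probes$probe_id, intensity = intensity,
                    array_id = array_id, stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(unique_seq = useq, occupancy = occ,
                                   stringsAsFactors = FALSE)
  class(out) <- c("fluorescence_table", "data.frame")
  out
}

#' Build matched seeds and ground-truth model for one binding mode
#'
#' Convenience constructor used by simulations and tests: plants a consensus
#' (AGGTCA) preference of configurable sharpness and returns seeds whose
#' engaged half-sites are near-consensus. For the half-site modes the
#' non-engaged half is a fixed non-consensus sequence (CTCGAG, its own reverse
#' complement and maximally distant from AGGTCA) so the planted mode is
#' identifiable.
#'
#' @param mode `"full"`, `"5prime_half"` or `"3prime_half"`.
#' @param n_seeds Seeds to generate (default 24).
#' @param spacer_len Spacer length (default 1, i.e. DR1).
#' @param pref Frequency of the preferred base at informative positions
#'   (default 0.85); the planted PFM has `pref` at the consensus base and
#'   `(1-pref)/3` elsewhere, uniform columns at spacer/flank positions.
#' @param weight Mode weight of the planted mode (default 500).
#' @param max_mut Maximum substitutions in each engaged half-site of a seed
#'   (default 1).
#' @param rng_seed Integer seed.
#' @return List with elements `seeds`, `model` ([ground_truth_model()]),
#'   `pfm` (planted site PFM, class `pfm`) and `mode`.
#' @export
mode_truth <- function(mode = c("full", "5prime_half", "3prime_half"),
                       n_seeds = 24L, spacer_len = 1L, pref = 0.85,
                       weight = 500, max_mut = 1L, rng_seed = NULL) {
  mode <- match.arg(mode)
  consensus <- "AGGTCA"
  anti <- "CTCGAG"
  site_pfm <- planted_site_pfm(mode, spacer_len, pref)
  # energies relative to the best base per column, so the consensus window
  # scores exp(0); softmax(-E) still recovers the planted PFM exactly
  E <- -log(unclass(site_pfm))
  E <- sweep(E, 2L, apply(E, 2L, min), "-")
  model <- switch(mode,
    full = ground_truth_model(full_energy = E,
                              mode_weights = c(full = weight)),
    `5prime_half` = ground_truth_model(hs5_energy = E,
                                       mode_weights = c(h5 = weight)),
    `3prime_half` = ground_truth_model(hs3_energy = E,
                                       mode_weights = c(h3 = weight)))
  seeds <- with_rng(rng_seed, {
    out <- list()
    ctxs <- character(0)
    guard <- 0L
    while (length(out) < n_seeds) {
      guard <- guard + 1L
      if (guard > 10000L) stop("seed generation failed", call. = FALSE)
      hs5 <- if (mode == "3prime_half") anti else mutate_bases(consensus, max_mut)
      hs3 <- if (mode == "5prime_half") anti else mutate_bases(consensus, max_mut)
      sd <- seed_sequence(sprintf("%s_DR%d_s%02d", mode, spacer_len,
                                  length(out) + 1L),
                          hs5 = hs5,
                          spacer = if (spacer_len) random_dna(spacer_len) else "",
                          hs3 = hs3,
                          flank5 = random_dna(5L), flank3 = random_dna(5L))
      ctx <- seed_context(sd)
      if (length(ctxs) && min(vapply(ctxs, hamming, 0L, b = ctx)) < 3L) next
      ctxs <- c(ctxs, ctx)
      out[[length(out) + 1L]] <- sd
    }
    out
  })
  list(seeds = seeds, model = model, pfm = site_pfm, mode = mode)
}

# Planted PFM in the frame of the generating energy window: full = bare site
# (12 + S), half modes = 5-bp flank + 6-bp half-site (11 positions).
planted_site_pfm <- function(mode, spacer_len, pref = 0.85) {
  consensus_cols <- function(hs) {
    m <- matrix((1 - pref) / 3, 4L, nchar(hs), dimnames = list(DNA_BASES, NULL))
    m[cbind(dna_encode(hs), seq_len(nchar(hs)))] <- pref
    m
  }
  uniform <- function(k) matrix(0.25, 4L, k, dimnames = list(DNA_BASES, NULL))
  m <- switch(mode,
    full = cbind(consensus_cols("AGGTCA"),
                 if (spacer_len) uniform(spacer_len),
                 consensus_cols("AGGTCA")),
    `5prime_half` = cbind(uniform(5L), consensus_cols("AGGTCA")),
    `3prime_half` = cbind(consensus_cols("AGGTCA"), uniform(5L)))
  structure(m, class = "pfm", source = "planted")
}

mutate_bases <- function(x, max_mut) {
  k <- sample.int(max_mut + 1L, 1L) - 1L
  if (k == 0L) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  for (p in sample.int(length(chars), k))
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate a genomic enrichment benchmark
#'
#' Generates a synthetic chromosome, lays out non-overlapping positive and
#' negative regions, plants a motif instance (sampled column-wise from `motif`)
#' in each positive with probability `planted_fraction`, and builds TSS /
#' differentially-expressed-gene tables placing a subset of positives within
#' `upstream_window` bp upstream of DE genes. Coordinates are 0-based
#' half-open throughout.
#'
#' @param n_pos,n_neg Numbers of positive / negative regions.
#' @param region_len Region length in bp (must be >= the motif width).
#' @param motif A `pfm` (4 x L).
#' @param planted_fraction Probability a positive region carries a planted
#'   instance (0-1).
#' @param rng_seed Integer seed.
#' @param de_fraction Fraction of positive regions tied to a DE gene TSS
#'   (default 0.5).
#' @param upstream_window Window used when placing TSSs (default 10000).
#' @return List with `pos`, `neg` (region data.frames: chrom, start, end,
#'   strand, name), `genome` (`DNAStringSet`), `tss` (gene, chrom, position,
#'   strand), `de_genes` (character), and `truth` (per-positive plant record).
#' @export
simulate_genomic_benchmark <- function(n_pos, n_neg, region_len = 200L,
                                       motif, planted_fraction = 1,
                                       rng_seed = NULL, de_fraction = 0.5,
                                       upstream_window = 10000L) {
  motif <- as_base_matrix(unclass(motif), "motif")
  if (region_len < ncol(motif))
    stop("region_len (", region_len, ") is shorter than the motif (",
         ncol(motif), ")", call. = FALSE)
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must be in [0, 1]", call. = FALSE)
  with_rng(rng_seed, {
    n <- n_pos + n_neg
    gap <- region_len
    genome_len <- n * (region_len + gap) + upstream_window + 2000L
    g <- strsplit(random_dna(genome_len), "", fixed = TRUE)[[1L]]
    starts <- gap %/% 2L + (seq_len(n) - 1L) * (region_len + gap)
    is_pos <- sample(rep(c(TRUE, FALSE), c(n_pos, n_neg)))
    pos_starts <- starts[is_pos]
    neg_starts <- starts[!is_pos]

    planted <- stats::runif(n_pos) < planted_fraction
    offsets <- rep(NA_integer_, n_pos)
    instances <- rep(NA_character_, n_pos)
    W <- ncol(motif)
    for (i in which(planted)) {
      inst <- vapply(seq_len(W), function(j)
        sample(DNA_BASES, 1L, prob = motif[, j]), "")
      off <- sample.int(region_len - W + 1L, 1L) - 1L
      g[(pos_starts[i] + off + 1L):(pos_starts[i] + off + W)] <- inst
      offsets[i] <- off
      instances[i] <- paste(inst, collapse = "")
    }

    pos <- data.frame(chrom = "chrS", start = pos_starts,
                      end = pos_starts + region_len, strand = ".",
                      name = sprintf("pos%04d", seq_len(n_pos)),
                      stringsAsFactors = FALSE)
    neg <- data.frame(chrom = "chrS", start = neg_starts,
                      end = neg_starts + region_len, strand = ".",
                      name = sprintf("neg%04d", seq_len(n_neg)),
                      stringsAsFactors = FALSE)

    # TSS / DE tables: DE genes sit downstream of a subset of positives so
    # the peak falls inside the strand-aware upstream window; decoy genes sit
    # near negatives and are not DE.
    n_de <- max(1L, round(de_fraction * n_pos))
    de_idx <- sort(sample.int(n_pos, n_de))
    tss_de <- data.frame(
      gene = sprintf("gene_de%03d", seq_along(de_idx)),
      chrom = "chrS",
      position = pos$end[de_idx] +
        sample.int(max(1L, upstream_window - region_len), length(de_idx)),
      strand = "+", stringsAsFactors = FALSE)
    n_decoy <- min(n_neg, n_de)
    decoy_idx <- sample.int(n_neg, n_decoy)
    tss_decoy <- data.frame(
      gene = sprintf("gene_bg%03d", seq_len(n_decoy)),
      chrom = "chrS",
      position = neg$end[decoy_idx] +
        sample.int(max(1L, upstream_window - region_len), n_decoy),
      strand = "+", stringsAsFactors = FALSE)
    tss <- rbind(tss_de, tss_decoy)
    tss$position <- pmin(tss$position, genome_len - 1L)

    truth <- data.frame(name = pos$name, planted = planted,
                        offset = offsets, instance = instances,
                        de_gene = NA_character_, stringsAsFactors = FALSE)
    truth$de_gene[de_idx] <- tss_de$gene

    list(pos = pos, neg = neg,
         genome = Biostrings::DNAStringSet(c(chrS = paste(g, collapse = ""))),
         tss = tss, de_genes = tss_de$gene, truth = truth)
  })
}
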