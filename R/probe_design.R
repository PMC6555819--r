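#' Construct a validated 6-bp half-site
#'
#' Nuclear receptors of the RXR-heterodimer class bind 6-bp half-sites with
#' consensus RGKTCA, arranged as direct repeats (DR0-DR5). A half-site here is
#' any 6-letter ACGT string; degeneracy relative to the consensus is a
#' property of the chosen seed, not of the type.
#'
#' @param bases Character scalar, exactly 6 letters from ACGT.
#' @return The validated, uppercased half-site string.
#' @export
half_site <- function(bases) {
  validate_dna(bases, "half-site", len = 6L)
}

#' Define a direct-repeat seed sequence
#'
#' A seed is a full direct-repeat site -- 5' half-site, spacer of 0-5 bp,
#' 3' half-site -- together with 5-bp flanks on either side. The flanked site
#' (the "context", 22 + spacer_len bp) is the region across which
#' single-nucleotide variants are enumerated.
#'
#' @param seed_id Identifier, unique within a library.
#' @param hs5,hs3 6-bp half-sites (see [half_site()]).
#' @param spacer DNA string of length 0-5 between the half-sites.
#' @param flank5,flank3 5-bp flanking sequences.
#' @return An object of class `seed_sequence`.
#' @export
seed_sequence <- function(seed_id, hs5, spacer, hs3, flank5, flank3) {
  stopifnot(is.character(seed_id), length(seed_id) == 1L, nzchar(seed_id))
  hs5 <- half_site(hs5)
  hs3 <- half_site(hs3)
  spacer <- validate_dna(spacer, "spacer")
  if (nchar(spacer) > 5L)
    stop("spacer must be 0-5 bp, got ", nchar(spacer), call. = FALSE)
  flank5 <- validate_dna(flank5, "flank5", len = 5L)
  flank3 <- validate_dna(flank3, "flank3", len = 5L)
  structure(
    list(seed_id = seed_id, hs5 = hs5, spacer = spacer, hs3 = hs3,
         flank5 = flank5, flank3 = flank3, spacer_len = nchar(spacer)),
    class = "seed_sequence")
}

#' @export
print.seed_sequence <- function(x, ...) {
  cat(sprintf("<seed_sequence> %s  DR%d\n  %s [%s] %s [%s] %s\n",
              x$seed_id, x$spacer_len, x$flank5, x$hs5,
              if (nchar(x$spacer)) x$spacer else "-", x$hs3, x$flank3))
  invisible(x)
}

#' Flanked direct-repeat context of a seed
#'
#' @param seed A [seed_sequence()].
#' @param flank_len Number of flanking bases to include on each side (0-5).
#' @return DNA string of length `12 + spacer_len + 2 * flank_len`.
#' @export
seed_context <- function(seed, flank_len = 5L) {
  stopifnot(inherits(seed, "seed_sequence"))
  if (flank_len < 0L || flank_len > 5L)
    stop("flank_len must be between 0 and 5", call. = FALSE)
  paste0(substr(seed$flank5, 6L - flank_len, 5L),
         seed$hs5, seed$spacer, seed$hs3,
         substr(seed$flank3, 1L, flank_len))
}

# Centre a context within the 34-nt variable region, padding with the fixed
# neutral filler (left pad drawn from the tail of FILLER_5 so padding bases
# adjacent to the context are stable as the pad grows).
embed_in_variable_region <- function(context, region_len = 34L) {
  len <- nchar(context)
  if (len > region_len)
    stop("context (", len, " nt) exceeds the ", region_len,
         "-nt variable region", call. = FALSE)
  pad <- region_len - len
  left <- pad %/% 2L
  right <- pad - left
  paste0(substr(FILLER_5, nchar(FILLER_5) - left + 1L, nchar(FILLER_5)),
         context,
         substr(FILLER_3, 1L, right))
}

#' Enumerate all single-nucleotide-variant probe sequences for a seed
#'
#' Every position of the flanked direct-repeat context (half-sites, spacer and
#' both flanks) is substituted with the three alternative bases, giving
#' `3 * (12 + spacer_len + 2 * flank_len)` variants. For a 13-bp DR1 site with
#' 5-bp flanks that is 69 unique SNV sequences.
#'
#' @param seed A [seed_sequence()].
#' @param flank_len Flanking bases included on each side (default 5).
#' @return A data.frame with columns `position` (0-based within the context),
#'   `base` (the substituted base), `context` (the variant context) and
#'   `variable_region` (the variant embedded in the 34-nt probe region).
#' @export
enumerate_snv_probes <- function(seed, flank_len = 5L) {
  ctx <- seed_context(seed, flank_len)
  chars <- strsplit(ctx, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  out <- vector("list", 3L * L)
  k <- 0L
  for (p in seq_len(L)) {
    for (b in setdiff(DNA_BASES, chars[p])) {
      k <- k + 1L
      v <- chars
      v[p] <- b
      vctx <- paste(v, collapse = "")
      out[[k]] <- data.frame(position = p - 1L, base = b, context = vctx,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$variable_region <- vapply(res$context, embed_in_variable_region, "")
  rownames(res) <- NULL
  res
}

#' Ablate the most informative position of one half-site
#'
#' Returns the seed with exactly one base changed: the half-site position that
#' contributes most to the binding score under `model` is replaced with the
#' base scoring lowest at that position (ties broken toward the lowest
#' position index / alphabetically first base).
#'
#' @param seed A [seed_sequence()].
#' @param model A `pwm` or `energy_matrix` (4 x L, rows A,C,G,T) covering
#'   either the bare site (L = 12 + spacer_len) or the flanked context.
#' @param half `"5prime"` or `"3prime"`.
#' @return A new `seed_sequence` (id suffixed `_abl5` / `_abl3`).
#' @export
ablate_half_site <- function(seed, model, half = c("5prime", "3prime")) {
  half <- match.arg(half)
  stopifnot(inherits(seed, "seed_sequence"))
  m <- as_base_matrix(unclass(model), "model")
  site_len <- 12L + seed$spacer_len
  offset <- if (ncol(m) == site_len) 0L
    else if (ncol(m) == site_len + 10L) 5L
    else stop("model has ", ncol(m), " positions; expected ", site_len,
              " (site) or ", site_len + 10L, " (flanked context)",
              call. = FALSE)
  hs_cols <- if (half == "5prime") offset + 1:6 else offset + 6L + seed$spacer_len + 1:6
  hs_seq <- if (half == "5prime") seed$hs5 else seed$hs3
  bases <- dna_encode(hs_seq)
  contrib <- m[cbind(bases, hs_cols)]
  pos <- which.max(contrib)                       # ties -> lowest index
  worst <- which.min(m[, hs_cols[pos]])           # ties -> first base (A first)
  new_hs <- strsplit(hs_seq, "", fixed = TRUE)[[1L]]
  new_hs[pos] <- DNA_BASES[worst]
  new_hs <- paste(new_hs, collapse = "")
  out <- seed
  out$seed_id <- paste0(seed$seed_id, if (half == "5prime") "_abl5" else "_abl3")
  if (half == "5prime") out$hs5 <- new_hs else out$hs3 <- new_hs
  out
}

#' Sample random genomic background probe sequences
#'
#' Draws fixed-length windows uniformly from a genome, discarding any window
#' containing N or a single-base run longer than three nucleotides.
#'
#' @param genome A `DNAStringSet`, a FASTA path, or a character vector of
#'   chromosome sequences.
#' @param n Number of background sequences (default 500).
#' @param length Window length (default 34).
#' @param rng_seed Integer seed; sampling is reproducible given the seed.
#' @return Character vector of `n` DNA strings.
#' @export
sample_background <- function(genome, n = 500L, length = 34L, rng_seed = NULL) {
  genome <- load_genome(genome)
  if (n == 0L) return(character(0))
  widths <- Biostrings::width(genome)
  eligible_chroms <- which(widths >= length)
  if (!length(eligible_chroms))
    stop("no chromosome is at least ", length, " nt long", call. = FALSE)
  n_slots <- sum(widths[eligible_chroms] - length + 1L)
  with_rng(rng_seed, {
    out <- character(0)
    tries <- 0L
    while (base::length(out) < n && tries < 200L) {
      tries <- tries + 1L
      need <- (n - base::length(out)) * 3L + 10L
      slot <- sample.int(n_slots, min(need, n_slots), replace = TRUE)
      offs <- cumsum(c(0L, widths[eligible_chroms] - length + 1L))
      chrom_idx <- findInterval(slot - 1L, offs, rightmost.closed = FALSE)
      start <- slot - offs[chrom_idx]
      cand <- as.character(Biostrings::subseq(
        genome[eligible_chroms[chrom_idx]], start = start, width = length))
      keep <- !grepl("[^ACGT]", cand) &
        vapply(cand, max_base_run, 0L) <= 3L
      out <- unique(c(out, cand[keep]))
    }
    if (base::length(out) < n)
      stop("insufficient eligible genome sequence: needed ", n,
           " background probes but only ", base::length(out),
           " passed the N / repeat filters", call. = FALSE)
    out[seq_len(n)]
  })
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) {
    gs <- Biostrings::DNAStringSet(toupper(genome))
    if (is.null(names(gs))) names(gs) <- paste0("chr", seq_along(gs))
    return(gs)
  }
  stop("genome must be a DNAStringSet, FASTA path, or character vector",
       call. = FALSE)
}

#' Generate direct-repeat seed sequences around the RGKTCA consensus
#'
#' Seeds combine half-sites exhibiting a range of degeneracy: each half-site
#' is drawn from the RGKTCA consensus (R resolved to A/G, K to G/T) and then
#' carries 0-2 random substitutions; spacers and flanks are random. Seeds are
#' rejected until all contexts at the same spacer length are pairwise at
#' Hamming distance >= 3, which guarantees the SNV neighbourhoods of distinct
#' seeds never collide.
#'
#' @param n_per_spacer Seeds per spacer length (default 24).
#' @param spacer_range Integer vector of spacer lengths (default 0:5).
#' @param max_mut Maximum substitutions per half-site (default 2).
#' @param rng_seed Integer seed.
#' @return List of [seed_sequence()] objects.
#' @export
generate_seeds <- function(n_per_spacer = 24L, spacer_range = 0:5,
                           max_mut = 2L, rng_seed = NULL) {
  with_rng(rng_seed, {
    seeds <- list()
    for (S in spacer_range) {
      ctxs <- character(0)
      made <- 0L
      guard <- 0L
      while (made < n_per_spacer) {
        guard <- guard + 1L
        if (guard > 10000L)
          stop("failed to generate ", n_per_spacer,
               " well-separated seeds at spacer length ", S, call. = FALSE)
        sd <- seed_sequence(
          seed_id = sprintf("DR%d_s%02d", S, made + 1L),
          hs5 = degenerate_half_site(max_mut),
          spacer = if (S > 0L) random_dna(S) else "",
          hs3 = degenerate_half_site(max_mut),
          flank5 = random_dna(5L), flank3 = random_dna(5L))
        ctx <- seed_context(sd)
        if (length(ctxs) && min(vapply(ctxs, hamming, 0L, b = ctx)) < 3L)
          next
        ctxs <- c(ctxs, ctx)
        made <- made + 1L
        seeds[[length(seeds) + 1L]] <- sd
      }
    }
    seeds
  })
}

degenerate_half_site <- function(max_mut = 2L) {
  hs <- c(sample(c("A", "G"), 1L), "G", sample(c("G", "T"), 1L), "T", "C", "A")
  k <- sample.int(max_mut + 1L, 1L) - 1L
  if (k > 0L) {
    pos <- sample.int(6L, k)
    for (p in pos) hs[p] <- sample(setdiff(DNA_BASES, hs[p]), 1L)
  }
  paste(hs, collapse = "")
}

#' Build the combinatorial probe library
#'
#' Expands seeds into the full probe set: the seed sequences themselves, every
#' single-nucleotide variant across half-sites, spacer and flanks, and random
#' genomic background probes, each replicated in both orientations (o2 is the
#' reverse complement of the o1 variable region). Unique SNV sequences get
#' `reps_snv` replicates per orientation (10 probes by default); all other
#' unique sequences get `reps_other` (8 probes). Half-site ablation variants
#' are single-nucleotide variants by construction, so they are recorded in an
#' `ablations` annotation table pointing at the matching SNV sequence rather
#' than as duplicate probe rows (preserving the multiplicity invariant).
#'
#' @param seeds List of [seed_sequence()], `seeds_per_spacer` per spacer
#'   length; see [generate_seeds()].
#' @param seeds_per_spacer Required seeds per spacer length (default 24).
#' @param flank_len Flank bases included in SNV enumeration (default 5).
#' @param reps_snv Replicates per orientation for SNV sequences (default 5).
#' @param reps_other Replicates per orientation for all other sequences
#'   (default 4).
#' @param n_background Number of random genomic background probes (default
#'   500).
#' @param background_seqs Optional character vector of 34-nt background
#'   sequences (e.g. from [sample_background()]). When `NULL`, random
#'   synthetic sequences passing the same N/repeat filters are generated.
#' @param ablation_model Optional 4 x L scoring matrix used to place the
#'   half-site ablations (see [ablate_half_site()]); default is a consensus
#'   RGKTCA half-site model applied to both halves.
#' @param rng_seed Integer seed for background generation.
#' @return An object of class `probe_library` with elements `probes`
#'   (one row per physical probe), `seeds`, `ablations`, `design_params`
#'   and `counts` (unique sequences per category and spacer length).
#' @export
build_library <- function(seeds, seeds_per_spacer = 24L, flank_len = 5L,
                          reps_snv = 5L, reps_other = 4L,
                          n_background = 500L, background_seqs = NULL,
                          ablation_model = NULL, rng_seed = NULL) {
  stopifnot(length(seeds) > 0L)
  ids <- vapply(seeds, function(s) s$seed_id, "")
  if (anyDuplicated(ids))
    stop("duplicate seed ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "), call. = FALSE)
  spacers <- vapply(seeds, function(s) s$spacer_len, 0L)
  per <- table(spacers)
  if (any(per < seeds_per_spacer))
    stop("fewer than ", seeds_per_spacer, " seeds at spacer length(s) ",
         paste(names(per)[per < seeds_per_spacer], collapse = ", "),
         call. = FALSE)

  # Unique sequences per seed family (seed context + all SNV contexts).
  fam <- lapply(seeds, function(sd) {
    snv <- enumerate_snv_probes(sd, flank_len)
    ctx <- seed_context(sd, flank_len)
    rbind(
      data.frame(seed_id = sd$seed_id, category = "seed",
                 variant_position = NA_integer_, variant_base = NA_character_,
                 spacer_len = sd$spacer_len,
                 unique_seq = embed_in_variable_region(ctx),
                 stringsAsFactors = FALSE),
      data.frame(seed_id = sd$seed_id, category = "snv",
                 variant_position = snv$position, variant_base = snv$base,
                 spacer_len = sd$spacer_len, unique_seq = snv$variable_region,
                 stringsAsFactors = FALSE))
  })
  uniq <- do.call(rbind, fam)

  dup <- duplicated(uniq$unique_seq) | duplicated(uniq$unique_seq, fromLast = TRUE)
  if (any(dup)) {
    clash <- uniq[dup, ]
    pair <- unique(clash$seed_id[clash$unique_seq == clash$unique_seq[1L]])
    stop("seed collision: sequence sets of seeds ",
         paste(pair, collapse = " and "), " share probe sequences",
         call. = FALSE)
  }

  # Half-site ablations: always coincide with one SNV of the same seed.
  if (is.null(ablation_model)) ablation_model <- consensus_site_model(flank_len)
  abl <- do.call(rbind, lapply(seeds, function(sd) {
    do.call(rbind, lapply(c("5prime", "3prime"), function(h) {
      model <- ablation_model
      if (is.function(model)) model <- model(sd)
      a <- ablate_half_site(sd, model, h)
      data.frame(seed_id = sd$seed_id, half = h,
                 unique_seq = embed_in_variable_region(seed_context(a, flank_len)),
                 stringsAsFactors = FALSE)
    }))
  }))
  abl$snv_of_seed <- vapply(seq_len(nrow(abl)), function(i)
    abl$unique_seq[i] %in% uniq$unique_seq[uniq$seed_id == abl$seed_id[i]],
    TRUE)

  # Background probes.
  if (is.null(background_seqs)) {
    background_seqs <- with_rng(rng_seed, {
      out <- character(0)
      while (length(out) < n_background) {
        cand <- vapply(seq_len(n_background), function(i) random_dna(34L), "")
        cand <- cand[vapply(cand, max_base_run, 0L) <= 3L]
        out <- unique(c(out, cand))
      }
      out[seq_len(n_background)]
    })
  }
  if (length(background_seqs) != n_background)
    stop("expected ", n_background, " background sequences, got ",
         length(background_seqs), call. = FALSE)
  bg <- data.frame(seed_id = NA_character_, category = "background",
                   variant_position = NA_integer_, variant_base = NA_character_,
                   spacer_len = NA_integer_,
                   unique_seq = toupper(background_seqs),
                   stringsAsFactors = FALSE)
  if (any(bg$unique_seq %in% uniq$unique_seq))
    stop("background sequences collide with seed/SNV sequences", call. = FALSE)

  bg$label <- sprintf("bg%04d", seq_len(nrow(bg)))
  uniq$label <- ifelse(uniq$category == "seed",
                       paste0(uniq$seed_id, "_wt"),
                       sprintf("%s_p%02d%s", uniq$seed_id,
                               uniq$variant_position, uniq$variant_base))
  all_uniq <- rbind(uniq, bg)

  reps <- ifelse(all_uniq$category == "snv", reps_snv, reps_other)
  n_each <- 2L * reps
  idx <- rep(seq_len(nrow(all_uniq)), n_each)
  probes <- all_uniq[idx, c("seed_id", "category", "variant_position",
                            "variant_base", "spacer_len", "unique_seq", "label")]
  # first `reps` copies of each sequence are o1, the rest o2
  probes$orientation <- unlist(lapply(reps, function(r) rep(c("o1", "o2"), each = r)),
                               use.names = FALSE)
  probes$replicate_index <- unlist(lapply(reps, function(r) c(seq_len(r), seq_len(r))),
                                   use.names = FALSE)
  rc <- revcomp(all_uniq$unique_seq)
  probes$variable_region <- ifelse(probes$orientation == "o1",
                                   probes$unique_seq, rc[idx])
  probes$primer_region <- PRIMER_REGION
  probes$probe_id <- sprintf("%s_%s_r%d", probes$label, probes$orientation,
                             probes$replicate_index)
  rownames(probes) <- NULL
  probes <- probes[, c("probe_id", "seed_id", "category", "variant_position",
                       "variant_base", "spacer_len", "orientation",
                       "replicate_index", "unique_seq", "variable_region",
                       "primer_region")]

  counts <- as.data.frame(table(category = all_uniq$category,
                                spacer_len = addNA(factor(all_uniq$spacer_len))),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, ]
  names(counts)[3L] <- "n_unique"

  structure(
    list(probes = probes, seeds = seeds, ablations = abl,
         design_params = list(seeds_per_spacer = seeds_per_spacer,
                              spacer_range = sort(unique(spacers)),
                              flank_len = flank_len, reps_snv = reps_snv,
                              reps_other = reps_other,
                              n_background = n_background),
         counts = counts),
    class = "probe_library")
}

# Default scoring model for ablation placement: consensus RGKTCA preference
# (A/G and G/T split evenly at the degenerate positions) over both half-sites,
# flat elsewhere, in the flanked-context frame.
consensus_site_model <- function(flank_len = 5L) {
  function(seed) {
    L <- 12L + seed$spacer_len + 2L * flank_len
    m <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
    hs_cols <- list(flank_len + 1:6, flank_len + 6L + seed$spacer_len + 1:6)
    for (cols in hs_cols) {
      m[, cols[1L]] <- c(0.5, -1, 0.5, -1)       # R = A/G
      m[, cols[2L]] <- c(-1, -1, 1, -1)          # G
      m[, cols[3L]] <- c(-1, -1, 0.5, 0.5)       # K = G/T
      m[, cols[4L]] <- c(-1, -1, -1, 1)          # T
      m[, cols[5L]] <- c(-1, 1, -1, -1)          # C
      m[, cols[6L]] <- c(1, -1, -1, -1)          # A
    }
    m
  }
}

#' @export
print.probe_library <- function(x, ...) {
  cat("<probe_library>\n")
  cat("  seeds:", length(x$seeds), " probes:", nrow(x$probes),
      " unique sequences:", length(unique(x$probes$unique_seq)), "\n")
  cat("  design:", paste(names(x$design_params),
                         vapply(x$design_params, function(v) paste(v, collapse = ":"), ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a probe library probe table
#'
#' The probe table is written as a tab-separated file (one row per probe) and
#' optionally the unique variable regions as FASTA.
#'
#' @param library A `probe_library`.
#' @param path Output TSV path.
#' @param fasta Optional FASTA path for unique variable regions.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(library, path, fasta = NULL) {
  stopifnot(inherits(library, "probe_library"))
  utils::write.table(library$probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta)) {
    first <- !duplicated(library$probes$unique_seq)
    labels <- sub("_o[12]_r\\d+$", "", library$probes$probe_id[first])
    seqs <- Biostrings::DNAStringSet(
      stats::setNames(library$probes$unique_seq[first], labels))
    Biostrings::writeXStringSet(seqs, fasta)
  }
  invisible(path)
}
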