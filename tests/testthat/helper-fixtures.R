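# Shared fixtures (memoized across test files) and independent brute-force
# oracles. Oracles are deliberately written as plain double loops, separate
# from any package code path they check.

fx_env <- new.env(parent = emptyenv())
fx <- function(name, build) {
  if (!exists(name, envir = fx_env)) assign(name, build(), envir = fx_env)
  get(name, envir = fx_env)
}

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_chr <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                   collapse = ""))

mutate_at <- function(x, k) {
  chars <- strsplit(x, "")[[1]]
  if (k > 0) for (p in sample(seq_along(chars), k))
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

# One simulated PBM experiment for a planted binding mode.
make_mode_sim <- function(mode, n_seeds = 8, spacer_len = 1, seed = 100,
                          n_background = 60, sigma = 0.1) {
  mt <- mode_truth(mode, n_seeds = n_seeds, spacer_len = spacer_len,
                   rng_seed = seed)
  lib <- build_library(mt$seeds, seeds_per_spacer = n_seeds,
                       n_background = n_background, rng_seed = seed + 1)
  fl <- simulate_fluorescence(lib, mt$model, noise_model(sigma),
                              rng_seed = seed + 2)
  list(truth = mt, lib = lib, fl = fl,
       profile = compute_zscores(fl, lib))
}

# Seeds whose half-sites are deliberately asymmetric in quality (one side
# near consensus, the other carrying two substitutions), used by the
# DBD-mutant transition simulations.
asym_seeds <- function(n, spacer_len = 1, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    ctxs <- character(0)
    while (length(out) < n) {
      good <- mutate_at("AGGTCA", sample(0:1, 1))
      bad <- mutate_at("AGGTCA", 2)
      side5 <- sample(c(TRUE, FALSE), 1)
      sd <- seed_sequence(sprintf("asym%02d", length(out) + 1),
                          hs5 = if (side5) good else bad,
                          spacer = if (spacer_len) rand_seq(spacer_len) else "",
                          hs3 = if (side5) bad else good,
                          flank5 = rand_seq(5), flank3 = rand_seq(5))
      ctx <- seed_context(sd)
      dist_ok <- !length(ctxs) ||
        min(vapply(ctxs, function(c2) sum(strsplit(c2, "")[[1]] !=
                                          strsplit(ctx, "")[[1]]), 0L)) >= 3L
      if (!dist_ok) next
      ctxs <- c(ctxs, ctx)
      out[[length(out) + 1]] <- sd
    }
    out
  })
}

# --- independent oracles -----------------------------------------------------

# Occupancy by explicit enumeration of every window on both strands.
oracle_occupancy <- function(sequence, energies, weights, baseline) {
  total <- baseline
  for (nm in names(energies)) {
    E <- energies[[nm]]
    if (is.null(E) || weights[[nm]] == 0) next
    L <- ncol(E)
    for (s in c(sequence, rc_chr(sequence))) {
      chars <- strsplit(s, "")[[1]]
      for (start in seq_len(nchar(s) - L + 1)) {
        e <- 0
        for (j in seq_len(L)) e <- e + E[chars[start + j - 1], j]
        total <- total + weights[[nm]] * exp(-e)
      }
    }
  }
  unname(total)
}

# Max window log-odds score by explicit enumeration (N scores 0).
oracle_score <- function(sequence, S) {
  best <- -Inf
  L <- ncol(S)
  for (s in c(sequence, rc_chr(sequence))) {
    chars <- strsplit(s, "")[[1]]
    for (start in seq_len(nchar(s) - L + 1)) {
      sc <- 0
      for (j in seq_len(L)) {
        b <- chars[start + j - 1]
        if (b %in% BASES) sc <- sc + S[b, j]
      }
      best <- max(best, sc)
    }
  }
  best
}

# AUC by counting all positive/negative pairs (ties count one half).
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# Reciprocal overlap by checking all interval pairs.
oracle_reciprocal <- function(a, b, frac) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= frac * (a$end[i] - a$start[i]) &&
          ov >= frac * (b$end[j] - b$start[j])) {
        keep[i] <- TRUE
        break
      }
    }
  }
  a[keep, , drop = FALSE]
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(300, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_pfm <- function(L) {
  m <- matrix(stats::runif(4 * L, 0.05, 1), 4, L,
              dimnames = list(BASES, NULL))
  structure(sweep(m, 2, colSums(m), "/"), class = "pfm")
}
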