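#' Delta-z energy matrix for one seed
#'
#' At every position of the flanked direct-repeat context the four base
#' variants are the seed itself (the seed base) plus the three SNV probes.
#' The energy-matrix entry is each variant's replicate-averaged z-score minus
#' the median z-score of the four variants at that position, so the median of
#' every column is zero by construction. Positive delta-z marks a favourable
#' base, negative a penalizing one.
#'
#' @param profile A [compute_zscores()] binding profile containing the seed
#'   and all of its SNVs.
#' @param seed The [seed_sequence()].
#' @param flank_len Flank bases included in the context (default 5).
#' @return 4 x L matrix of class `energy_matrix` (rows A,C,G,T, columns the
#'   22 + spacer_len context positions). Attributes: `seed_id`, `spacer_len`,
#'   `flank_len`, `context`, `seed_zmax` (max replicate-averaged z over the
#'   seed and its SNVs) and `z` (the raw 4 x L z matrix).
#' @export
delta_z_matrix <- function(profile, seed, flank_len = 5L) {
  stopifnot(inherits(seed, "seed_sequence"))
  ctx <- seed_context(seed, flank_len)
  L <- nchar(ctx)
  rows <- profile[!is.na(profile$seed_id) & profile$seed_id == seed$seed_id, ]
  z_seed <- rows$mean_z[rows$category == "seed"]
  if (length(z_seed) != 1L)
    stop("profile does not contain the seed probe for ", seed$seed_id,
         call. = FALSE)
  snv <- rows[rows$category == "snv", ]
  key <- paste(snv$variant_position, snv$variant_base)

  seed_bases <- dna_encode(ctx)
  zmat <- matrix(NA_real_, 4L, L, dimnames = list(DNA_BASES, NULL))
  zmat[cbind(seed_bases, seq_len(L))] <- z_seed
  want_pos <- rep(0:(L - 1L), each = 3L)
  want_base <- unlist(lapply(seq_len(L), function(p)
    setdiff(DNA_BASES, DNA_BASES[seed_bases[p]])), use.names = FALSE)
  idx <- match(paste(want_pos, want_base), key)
  if (anyNA(idx)) {
    missing <- paste0("pos ", want_pos[is.na(idx)], ">",
                      want_base[is.na(idx)])
    stop("missing SNV variant(s) for ", seed$seed_id, ": ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ...", call. = FALSE)
  }
  zmat[cbind(match(want_base, DNA_BASES), want_pos + 1L)] <- snv$mean_z[idx]

  dz <- sweep(zmat, 2L, apply(zmat, 2L, stats::median), "-")
  structure(dz, class = "energy_matrix",
            seed_id = seed$seed_id, spacer_len = seed$spacer_len,
            flank_len = flank_len, context = ctx,
            seed_zmax = max(zmat), z = zmat)
}

#' Softmax scaling parameter beta
#'
#' The z-to-frequency transform uses `beta = numerator / seed_zmax` with the
#' numerator fixed at 15, where `seed_zmax` is the maximum replicate-averaged
#' z-score over the seed and all of its SNVs.
#'
#' @param seed_zmax Maximum z-score over seed + SNVs (> 0).
#' @param numerator Numerator of the transform (default 15).
#' @return Positive scalar beta.
#' @export
beta_param <- function(seed_zmax, numerator = 15) {
  if (!is.finite(seed_zmax) || seed_zmax <= 0)
    stop("seed_zmax must be positive and finite (got ", seed_zmax,
         "); beta is only defined for bound seeds", call. = FALSE)
  numerator / seed_zmax
}

#' Position frequency matrix from per-base z-scores
#'
#' Boltzmann (softmax) transform: at each position,
#' `f_i = exp(beta * z_i) / sum_k exp(beta * z_k)`. Columns sum to 1; the
#' transform is invariant to adding a constant to all four z at a position,
#' so raw z and delta-z give identical PFMs.
#'
#' @param z 4 x L matrix of z-scores (rows A,C,G,T).
#' @param beta Positive scalar, typically [beta_param()].
#' @return 4 x L matrix of class `pfm`.
#' @export
pfm_from_zscores <- function(z, beta) {
  z <- as_base_matrix(z, "z")
  if (!is.finite(beta) || beta < 0)
    stop("beta must be finite and nonnegative", call. = FALSE)
  structure(softmax_cols(beta * z), class = "pfm", source = "single_seed")
}

#' Per-seed PFM from a binding profile
#'
#' Convenience wrapper: builds the [delta_z_matrix()], sets
#' `beta = beta_numerator / seed_zmax`, and applies [pfm_from_zscores()].
#'
#' @inheritParams delta_z_matrix
#' @param beta_numerator Numerator of the beta transform (default 15).
#' @return A `pfm` carrying the energy matrix's seed attributes.
#' @export
pfm_from_profile <- function(profile, seed, beta_numerator = 15,
                             flank_len = 5L) {
  em <- delta_z_matrix(profile, seed, flank_len)
  beta <- beta_param(attr(em, "seed_zmax"), beta_numerator)
  p <- pfm_from_zscores(attr(em, "z"), beta)
  attr(p, "seed_id") <- attr(em, "seed_id")
  attr(p, "spacer_len") <- attr(em, "spacer_len")
  attr(p, "flank_len") <- attr(em, "flank_len")
  attr(p, "seed_zmax") <- attr(em, "seed_zmax")
  p
}

#' Position weight matrix (log-odds) from a PFM
#'
#' Implements the printed formalism: per position j and base i,
#' `p_ij = (f_ij + s * b_i) / (sum_i f_ij + s)` with pseudocount `s`, and
#' `S_ij = log2(p_ij / b_i)`. A column equal to the background maps to
#' all-zero log-odds.
#'
#' @param pfm 4 x L frequency matrix (`pfm`).
#' @param background Named base frequencies summing to 1 (default uniform;
#'   see [dnase_background()] for the genomic default).
#' @param s Pseudocount (default 0.001).
#' @return 4 x L matrix of class `pwm` with attributes `background`,
#'   `pseudocount` and `prob` (the pseudocounted probabilities).
#' @export
pwm_from_pfm <- function(pfm, background = uniform_background(), s = 0.001) {
  f <- as_base_matrix(unclass(pfm), "pfm")
  b <- background[DNA_BASES]
  if (anyNA(b)) stop("background must be named with A, C, G, T", call. = FALSE)
  if (any(b <= 0)) stop("background frequencies must be positive", call. = FALSE)
  if (abs(sum(b) - 1) > 1e-6) stop("background must sum to 1", call. = FALSE)
  if (s <= 0) stop("pseudocount s must be > 0", call. = FALSE)
  p <- sweep(f + s * b, 2L, colSums(f) + s, "/")
  S <- log2(p / b)
  structure(S, class = "pwm", background = b, pseudocount = s, prob = p)
}

#' Background base frequencies
#'
#' `dnase_background()` returns the genomic background used for enrichment
#' scoring (A 0.24, C 0.26, G 0.26, T 0.24, the nucleotide distribution of
#' reproducible DNase accessible regions); `uniform_background()` the flat
#' 0.25 default used elsewhere.
#'
#' @return Named numeric vector over A, C, G, T.
#' @export
dnase_background <- function() c(A = 0.24, C = 0.26, G = 0.26, T = 0.24)

#' @rdname dnase_background
#' @export
uniform_background <- function() c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

#' Average PFMs in a shared coordinate frame
#'
#' Element-wise mean of the matrices followed by column renormalization.
#' Half-site PFMs share the flank + half-site frame regardless of spacer
#' length, so they may be averaged across all spacer lengths.
#'
#' @param pfms List of `pfm` matrices of identical dimension.
#' @return A `pfm` with `source = "averaged"`.
#' @export
average_pfms <- function(pfms) {
  stopifnot(length(pfms) >= 1L)
  mats <- lapply(pfms, function(p) as_base_matrix(unclass(p), "pfm"))
  dims <- vapply(mats, ncol, 0L)
  if (length(unique(dims)) != 1L)
    stop("PFMs have different lengths (", paste(unique(dims), collapse = ", "),
         "); align them to a shared frame first", call. = FALSE)
  m <- Reduce(`+`, mats) / length(mats)
  m <- sweep(m, 2L, colSums(m), "/")
  structure(m, class = "pfm", source = "averaged", n_averaged = length(mats))
}

#' Per-position information content of a PFM
#'
#' Kullback-Leibler information of each column relative to the background, in
#' bits: `sum_i f_i * log2(f_i / b_i)` (zero frequencies contribute zero).
#' Nonnegative; 2 bits for a deterministic column under a uniform background.
#'
#' @param pfm A `pfm`.
#' @param background Named base frequencies (default uniform).
#' @return Numeric vector, one value per position.
#' @export
information_content <- function(pfm, background = uniform_background()) {
  f <- as_base_matrix(unclass(pfm), "pfm")
  b <- background[DNA_BASES]
  terms <- f * log2(sweep(f, 1L, b, "/"))
  terms[f == 0] <- 0
  pmax(colSums(terms), 0)
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d positions (source: %s)\n", ncol(x),
              attr(x, "source") %||% "unknown"))
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("<energy_matrix> seed %s, %d positions, seed_zmax %.2f\n",
              attr(x, "seed_id") %||% "?", ncol(x),
              attr(x, "seed_zmax") %||% NA))
  print(round(unclass(x), 2))
  invisible(x)
}
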