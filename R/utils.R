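# Shared low-level helpers: DNA validation/encoding, seeded evaluation,
# small numeric utilities. Nothing here is exported.

DNA_BASES <- c("A", "C", "G", "T")

# Neutral filler used to pad the direct-repeat context out to the 34-nt
# variable region. Chosen to contain no half-site-like word (GGTCA/TGACC)
# and no single-base run longer than 2.
FILLER_5 <- "ATCGTACGTA"
FILLER_3 <- "TACGTACGAT"

# Constant 24-nt primer region shared by all probes (array double-stranding
# primer; excluded from every analysis).
PRIMER_REGION <- "CCTTCATTCTACGCTGTCAATCGC"

validate_dna <- function(x, what = "sequence", len = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- toupper(x)
  if (nchar(x) > 0L && grepl("[^ACGT]", x))
    stop(what, " contains characters outside ACGT: ", x, call. = FALSE)
  if (!is.null(len) && nchar(x) != len)
    stop(what, " must have length ", len, ", got ", nchar(x), call. = FALSE)
  x
}

# Integer-encode a DNA string: A=1, C=2, G=3, T=4; anything else (N, ...) NA.
dna_encode <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], DNA_BASES)
}

dna_decode <- function(idx) paste(DNA_BASES[idx], collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Longest single-base run in a DNA string.
max_base_run <- function(x) {
  if (nchar(x) == 0L) return(0L)
  max(rle(strsplit(x, "", fixed = TRUE)[[1L]])$lengths)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL uses the current stream.
with_rng <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

random_dna <- function(n, base_probs = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_probs), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# Column-wise softmax of a 4 x L matrix, numerically guarded.
softmax_cols <- function(m) {
  shifted <- sweep(m, 2L, apply(m, 2L, max), "-")
  e <- exp(shifted)
  sweep(e, 2L, colSums(e), "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a 4 x L base matrix (rows A,C,G,T), returning it with rownames set.
as_base_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != 4L)
    stop(what, " must be a 4 x L matrix with rows A, C, G, T", call. = FALSE)
  if (!all(is.finite(m)))
    stop(what, " contains non-finite values", call. = FALSE)
  rownames(m) <- DNA_BASES
  m
}

# Stable hash of an R object via its deparsed form (provenance stamping).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
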