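#' Rescale arrays to a common median intensity
#'
#' A simplified between-array normalization: every array is multiplicatively
#' rescaled so that its median log-intensity over the probes shared by all
#' arrays equals the across-array mean of those medians. Rank order within
#' each array is preserved. This is a deliberately simple median-scaling
#' stand-in for full microarray regression normalization, and is labelled as
#' such; downstream z-scores are in any case invariant to global
#' multiplicative rescaling.
#'
#' @param tables List of fluorescence tables (`probe_id`, `intensity`, ...).
#' @return List of rescaled tables, same shape.
#' @export
scale_arrays <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  shared <- Reduce(intersect, lapply(tables, function(t) t$probe_id))
  if (!length(shared)) stop("arrays share no probes", call. = FALSE)
  meds <- vapply(tables, function(t)
    stats::median(log(t$intensity[t$probe_id %in% shared])), 0)
  target <- mean(meds)
  Map(function(t, m) {
    t$intensity <- t$intensity * exp(target - m)
    t
  }, tables, meds)
}

#' Convert raw fluorescence to background-referenced z-scores
#'
#' Per unique probe sequence, replicate intensities from one orientation are
#' log-transformed (default) and averaged; the averaged value `x` is then
#' standardized against the 500 random genomic background probes on the same
#' scale: `z = (x - mu_bg) / sd_bg`. Background sequences therefore have mean
#' z = 0 and sd = 1 by construction, and z-scores are invariant to any global
#' multiplicative rescaling of the array.
#'
#' @param table Fluorescence table (`probe_id`, `intensity`).
#' @param library The [build_library()] the probe ids resolve against.
#' @param orientation `"o1"` (default, the orientation used for all final
#'   analyses) or `"o2"`.
#' @param scale `"log"` (default) or `"linear"` intensity scale.
#' @param summary `"mean"` (default) or `"median"` replicate summary.
#' @param background_min Minimum background sequences required (default 10).
#' @return data.frame of class `binding_profile` with one row per unique
#'   sequence: `unique_seq`, `seed_id`, `category`, `variant_position`,
#'   `variant_base`, `spacer_len`, `mean_z`, `n_replicates`. Attributes:
#'   `background_stats` (mu, sd), `orientation`, `scale`.
#' @export
compute_zscores <- function(table, library, orientation = "o1",
                            scale = c("log", "linear"),
                            summary = c("mean", "median"),
                            background_min = 10L) {
  scale <- match.arg(scale)
  summary <- match.arg(summary)
  stopifnot(inherits(library, "probe_library"))
  orientation <- match.arg(orientation, c("o1", "o2"))
  meta_cols <- c("probe_id", "unique_seq", "seed_id", "category",
                 "variant_position", "variant_base", "spacer_len",
                 "orientation")
  m <- merge(table[, c("probe_id", "intensity")],
             library$probes[, meta_cols], by = "probe_id")
  m <- m[m$orientation == orientation, ]
  if (!nrow(m)) stop("no probes found for orientation ", orientation,
                     call. = FALSE)
  if (any(m$intensity < 0)) stop("negative intensities", call. = FALSE)
  v <- if (scale == "log") log(pmax(m$intensity, .Machine$double.xmin))
       else m$intensity

  f <- factor(m$unique_seq, levels = unique(m$unique_seq))
  x <- if (summary == "mean") tapply(v, f, mean) else tapply(v, f, stats::median)
  n <- as.integer(tapply(v, f, length))
  first <- !duplicated(m$unique_seq)
  prof <- data.frame(
    unique_seq = levels(f),
    seed_id = m$seed_id[first],
    category = m$category[first],
    variant_position = m$variant_position[first],
    variant_base = m$variant_base[first],
    spacer_len = m$spacer_len[first],
    x = as.numeric(x), n_replicates = n,
    stringsAsFactors = FALSE)

  expected <- ifelse(prof$category == "snv", library$design_params$reps_snv,
                     library$design_params$reps_other)
  if (any(prof$n_replicates < expected))
    warning(sum(prof$n_replicates < expected),
            " sequence(s) are missing replicates; averaging over available",
            call. = FALSE)

  bg <- prof$x[prof$category == "background"]
  if (length(bg) < background_min)
    stop("only ", length(bg), " background sequences observed (need >= ",
         background_min, ")", call. = FALSE)
  mu <- mean(bg)
  sdv <- stats::sd(bg)
  if (sdv <= 0) stop("background sd is not positive", call. = FALSE)
  prof$mean_z <- (prof$x - mu) / sdv
  prof$x <- NULL

  attr(prof, "background_stats") <- c(mu = mu, sd = sdv)
  attr(prof, "orientation") <- orientation
  attr(prof, "scale") <- scale
  class(prof) <- c("binding_profile", "data.frame")
  prof
}

#' Concordance (R squared) between two binding profiles
#'
#' Squared Pearson correlation of `mean_z` over the sequences shared by the
#' two profiles, e.g. replicate arrays or the two detection antibodies of a
#' heterodimer experiment. Symmetric in its arguments.
#'
#' @param a,b `binding_profile` objects.
#' @return Scalar in \[0, 1\].
#' @export
concordance <- function(a, b) {
  m <- merge(a[, c("unique_seq", "mean_z")], b[, c("unique_seq", "mean_z")],
             by = "unique_seq", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L)
    stop("need at least 3 shared sequences, got ", nrow(m), call. = FALSE)
  stats::cor(m$mean_z_a, m$mean_z_b)^2
}
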