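#' Classify the binding mode of one seed
#'
#' From a seed's delta-z energy matrix, each half-site's perturbation score is
#' the sum over its six positions of the per-position delta-z range
#' (max over bases minus min over bases); flank and spacer positions do not
#' contribute. A half-site is "engaged" when its perturbation is at least
#' `engage_abs` z-units AND at least `engage_frac` of the two half-sites'
#' combined perturbation. Seeds whose maximum replicate-averaged z-score over
#' seed + SNVs falls below `z_threshold` are called `none`; otherwise the mode
#' is `full` (both halves engaged), `5prime_half` or `3prime_half` (exactly
#' one). If neither half clears `engage_abs`, the relative rule alone decides,
#' with exact ties resolving to `full` (conservative toward the canonical
#' full-site model). The engagement rule is this package's operationalization
#' of full- versus half-site clustering; both knobs are tunable.
#'
#' @param em An [delta_z_matrix()] energy matrix.
#' @param seed The matching [seed_sequence()].
#' @param z_threshold Affinity cutoff on `seed_zmax` (default 3.0).
#' @param engage_frac Minimum share of total perturbation (default 0.25).
#' @param engage_abs Minimum absolute perturbation in z-units (default 2.0).
#' @return Object of class `mode_call`: list with `seed_id`, `spacer_len`,
#'   `mode`, `zmax`, `perturbation_5`, `perturbation_3`.
#' @export
classify_mode <- function(em, seed, z_threshold = 3, engage_frac = 0.25,
                          engage_abs = 2) {
  stopifnot(inherits(em, "energy_matrix"), inherits(seed, "seed_sequence"))
  flank_len <- attr(em, "flank_len") %||% 5L
  L_expect <- 12L + seed$spacer_len + 2L * flank_len
  if (ncol(em) != L_expect)
    stop("energy matrix has ", ncol(em), " positions but seed ",
         seed$seed_id, " implies ", L_expect, call. = FALSE)
  hs5_cols <- flank_len + 1:6
  hs3_cols <- flank_len + 6L + seed$spacer_len + 1:6
  rng <- apply(unclass(em), 2L, function(col) max(col) - min(col))
  p5 <- sum(rng[hs5_cols])
  p3 <- sum(rng[hs3_cols])
  zmax <- attr(em, "seed_zmax")

  mode <- if (zmax < z_threshold) "none" else {
    total <- p5 + p3
    eng5 <- p5 >= engage_abs && total > 0 && p5 >= engage_frac * total
    eng3 <- p3 >= engage_abs && total > 0 && p3 >= engage_frac * total
    if (eng5 && eng3) "full"
    else if (eng5) "5prime_half"
    else if (eng3) "3prime_half"
    else if (total > 0 && p5 != p3) {
      # neither half clears engage_abs: fall back to the relative rule
      if (p5 > p3) "5prime_half" else "3prime_half"
    } else "full"
  }
  structure(list(seed_id = seed$seed_id, spacer_len = seed$spacer_len,
                 mode = mode, zmax = zmax,
                 perturbation_5 = p5, perturbation_3 = p3),
            class = "mode_call")
}

#' @export
print.mode_call <- function(x, ...) {
  cat(sprintf("<mode_call> %s (DR%d): %s  zmax=%.2f  pert5=%.1f pert3=%.1f\n",
              x$seed_id, x$spacer_len, x$mode, x$zmax,
              x$perturbation_5, x$perturbation_3))
  invisible(x)
}

#' Classify binding modes for many seeds
#'
#' @param profile A [compute_zscores()] binding profile.
#' @param seeds List of [seed_sequence()] objects.
#' @param flank_len Flank bases in the context (default 5).
#' @inheritParams classify_mode
#' @return data.frame with one row per seed: `seed_id`, `spacer_len`, `mode`,
#'   `zmax`, `perturbation_5`, `perturbation_3`.
#' @export
classify_modes <- function(profile, seeds, z_threshold = 3,
                           engage_frac = 0.25, engage_abs = 2,
                           flank_len = 5L) {
  rows <- lapply(seeds, function(sd) {
    em <- delta_z_matrix(profile, sd, flank_len)
    call <- classify_mode(em, sd, z_threshold, engage_frac, engage_abs)
    as.data.frame(unclass(call), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spacer-preference landscape
#'
#' One row per seed with `zmax` at or above the affinity threshold, per spacer
#' length, carrying the seed's maximum SNV z-score and its binding-mode call;
#' seeds below threshold are not represented. Box-plot summary statistics
#' (median, quartiles, 1.5 IQR whiskers) per spacer length and mode are
#' attached as the `summary` attribute.
#'
#' @param calls data.frame of mode calls ([classify_modes()]).
#' @param z_threshold Affinity cutoff (default 3.0).
#' @param nr_id Optional receptor label recorded in the table.
#' @return data.frame of class `landscape_table` (`nr_id`, `spacer_len`,
#'   `seed_id`, `zmax`, `mode`).
#' @export
spacer_landscape <- function(calls, z_threshold = 3, nr_id = "NR") {
  keep <- calls[calls$zmax >= z_threshold, , drop = FALSE]
  out <- data.frame(nr_id = rep(nr_id, nrow(keep)), spacer_len = keep$spacer_len,
                    seed_id = keep$seed_id, zmax = keep$zmax,
                    mode = keep$mode, stringsAsFactors = FALSE)
  out <- out[order(out$spacer_len, -out$zmax), ]
  rownames(out) <- NULL
  smry <- do.call(rbind, lapply(
    split(out, list(out$spacer_len, out$mode), drop = TRUE),
    function(g) {
      bs <- grDevices::boxplot.stats(g$zmax)$stats
      data.frame(spacer_len = g$spacer_len[1L], mode = g$mode[1L],
                 n = nrow(g), whisker_lo = bs[1L], q1 = bs[2L],
                 median = bs[3L], q3 = bs[4L], whisker_hi = bs[5L],
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(smry)) rownames(smry) <- NULL
  attr(out, "summary") <- smry
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("landscape_table", "data.frame")
  out
}

MODE_LEVELS <- c("full", "5prime_half", "3prime_half", "none")

#' Mode-transition counts between two conditions
#'
#' 4 x 4 table counting seeds moving from their mode in condition A (rows) to
#' their mode in condition B (columns), e.g. wild type versus a DNA-binding
#' domain mutant. Row sums equal condition A's mode counts; the grand total
#' equals the number of shared seeds.
#'
#' @param calls_a,calls_b Mode-call data.frames over identical seed sets.
#' @return 4 x 4 integer matrix over full, 5prime_half, 3prime_half, none.
#' @export
mode_transitions <- function(calls_a, calls_b) {
  if (!setequal(calls_a$seed_id, calls_b$seed_id)) {
    only_a <- setdiff(calls_a$seed_id, calls_b$seed_id)
    only_b <- setdiff(calls_b$seed_id, calls_a$seed_id)
    stop("seed sets differ; only in A: ",
         paste(utils::head(only_a, 5L), collapse = ", "),
         "; only in B: ", paste(utils::head(only_b, 5L), collapse = ", "),
         call. = FALSE)
  }
  b_mode <- calls_b$mode[match(calls_a$seed_id, calls_b$seed_id)]
  as.matrix(table(factor(calls_a$mode, MODE_LEVELS),
                  factor(b_mode, MODE_LEVELS)))
}
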