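# End-to-end orchestration: a declarative config drives
# design -> simulate (or load) -> normalize -> motifs -> modes -> enrich,
# writing provenance-stamped tables into a run directory.

#' Default pipeline configuration
#'
#' A nested list of every stage's parameters. `run_pipeline()` rejects unknown
#' keys, so copies of this object are the supported way to build configs.
#' The defaults describe a compact demonstration run (4 seeds per spacer at
#' DR0-DR1, 60 background probes); study-scale parameters are 24 seeds per
#' spacer across DR0-DR5 with 500 background probes.
#'
#' @return Named list of stage parameter lists.
#' @export
default_config <- function() {
  list(
    design = list(seeds_per_spacer = 4L, spacer_range = 0:1, flank_len = 5L,
                  reps_snv = 5L, reps_other = 4L, n_background = 60L,
                  seed = 101L),
    simulate = list(mode = "full", spacer_len = 1L, pref = 0.85, weight = 500,
                    sigma = 0.1, orientation_bias = 0.85, gain = 100,
                    seed = 202L),
    normalize = list(orientation = "o1", scale = "log", summary = "mean",
                     background_min = 10L),
    motifs = list(beta_numerator = 15, pseudocount = 0.001,
                  background = "uniform"),
    modes = list(z_threshold = 3, engage_frac = 0.25, engage_abs = 2),
    enrich = list(enabled = FALSE, n_pos = 150L, n_neg = 150L,
                  region_len = 200L, planted_fraction = 0.9, seed = 303L,
                  n_models = 1L))
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; unknown keys are
#' rejected by [run_pipeline()].
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

check_config <- function(config) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    extra <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(extra))
      stop("unknown key(s) in config$", sec, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  modifyList(ref, config)
}

stamp_table <- function(df, path, hash, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nrpbm %s; stage %s; config_hash %s",
                     as.character(utils::packageVersion("nrpbm")),
                     stage, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_stamped <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full synthetic-PBM analysis pipeline
#'
#' Executes design, simulation, normalization, motif inference and mode
#' classification (plus, optionally, a genomic-enrichment benchmark) under a
#' single declarative config, writing tab-separated outputs -- each stamped
#' with the package version and a config hash -- into `out_dir`. Rerunning
#' with an identical config reproduces identical tables.
#'
#' @param config Config list (see [default_config()]); unknown keys error
#'   before any stage runs.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the config, config hash, per-stage objects
#'   and output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  config <- check_config(config)
  hash <- object_hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # design + simulate: the planted binding mode defines both the seeds and
  # the ground truth, so seeds come from mode_truth() at the configured
  # spacer length plus generate_seeds() for the remaining strata.
  des <- config$design
  sim <- config$simulate
  truth <- mode_truth(sim$mode, n_seeds = des$seeds_per_spacer,
                      spacer_len = sim$spacer_len, pref = sim$pref,
                      weight = sim$weight, rng_seed = des$seed)
  other <- setdiff(des$spacer_range, sim$spacer_len)
  seeds <- truth$seeds
  if (length(other))
    seeds <- c(seeds, generate_seeds(des$seeds_per_spacer, other,
                                     rng_seed = des$seed + 1L))
  lib <- build_library(seeds, seeds_per_spacer = des$seeds_per_spacer,
                       flank_len = des$flank_len, reps_snv = des$reps_snv,
                       reps_other = des$reps_other,
                       n_background = des$n_background,
                       rng_seed = des$seed + 2L)
  paths$probes <- stamp_table(lib$probes, file.path(out_dir, "probes.tsv"),
                              hash, "design")

  fl <- simulate_fluorescence(lib, truth$model,
                              noise_model(sim$sigma, des$reps_snv,
                                          sim$orientation_bias),
                              rng_seed = sim$seed, gain = sim$gain)
  paths$fluorescence <- stamp_table(as.data.frame(fl),
                                    file.path(out_dir, "fluorescence.tsv"),
                                    hash, "simulate")
  paths$truth <- stamp_table(attr(fl, "truth"),
                             file.path(out_dir, "truth_occupancy.tsv"),
                             hash, "simulate")

  nrm <- config$normalize
  profile <- compute_zscores(fl, lib, orientation = nrm$orientation,
                             scale = nrm$scale, summary = nrm$summary,
                             background_min = nrm$background_min)
  paths$zscores <- stamp_table(as.data.frame(profile),
                               file.path(out_dir, "zscores.tsv"),
                               hash, "normalize")

  mot <- config$motifs
  bg <- if (identical(mot$background, "dnase")) dnase_background()
        else uniform_background()
  zmaxes <- vapply(seeds, function(sd) {
    rows <- profile[!is.na(profile$seed_id) & profile$seed_id == sd$seed_id, ]
    max(rows$mean_z)
  }, 0)
  bound <- zmaxes >= config$modes$z_threshold
  pfms <- lapply(seeds[bound], function(sd)
    pfm_from_profile(profile, sd, mot$beta_numerator, des$flank_len))
  names(pfms) <- vapply(seeds[bound], function(sd) sd$seed_id, "")
  if (length(pfms)) {
    paths$pfms <- file.path(out_dir, "pfms.meme")
    write_meme(pfms, paths$pfms, background = bg)
  }

  md <- config$modes
  calls <- classify_modes(profile, seeds, z_threshold = md$z_threshold,
                          engage_frac = md$engage_frac,
                          engage_abs = md$engage_abs,
                          flank_len = des$flank_len)
  paths$mode_calls <- stamp_table(calls, file.path(out_dir, "mode_calls.tsv"),
                                  hash, "modes")
  landscape <- spacer_landscape(calls, z_threshold = md$z_threshold)
  paths$landscape <- stamp_table(as.data.frame(landscape),
                                 file.path(out_dir, "landscape.tsv"),
                                 hash, "modes")

  roc <- NULL
  if (isTRUE(config$enrich$enabled) && length(pfms)) {
    en <- config$enrich
    avg <- average_pfms(pfms)
    site_cols <- (des$flank_len + 1L):(ncol(avg) - des$flank_len)
    site_pfm <- structure(unclass(avg)[, site_cols], class = "pfm",
                          source = "averaged")
    pwm <- pwm_from_pfm(site_pfm, background = bg,
                        s = mot$pseudocount)
    bench <- simulate_genomic_benchmark(en$n_pos, en$n_neg, en$region_len,
                                        site_pfm, en$planted_fraction,
                                        rng_seed = en$seed)
    roc <- roc_auc(score_regions(bench$pos, bench$genome, pwm),
                   score_regions(bench$neg, bench$genome, pwm),
                   n_models = en$n_models)
    paths$roc <- file.path(out_dir, "roc.json")
    jsonlite::write_json(
      list(config_hash = hash, auc = roc$auc, n_pos = roc$n_pos,
           n_neg = roc$n_neg, u_statistic = roc$u_statistic,
           p_value = roc$p_value, p_adjusted = roc$p_adjusted),
      paths$roc, auto_unbox = TRUE, digits = NA)
    paths$roc_curve <- stamp_table(roc$curve,
                                   file.path(out_dir, "roc_curve.tsv"),
                                   hash, "enrich")
  }

  invisible(list(config = config, config_hash = hash, out_dir = out_dir,
                 library = lib, truth = truth, profile = profile,
                 pfms = pfms, calls = calls, landscape = landscape,
                 roc = roc, paths = paths))
}

#' Render figures and a summary for a completed run
#'
#' Produces sequence logos for the averaged PFM, the spacer-preference
#' landscape, the ROC curve (when the enrichment stage ran) and a markdown
#' summary. Figures for missing stage outputs are skipped with a warning.
#'
#' @param run A [run_pipeline()] result, or a run directory path.
#' @param out_dir Where to write figures (default: `<run>/report`).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(run, out_dir = NULL) {
  if (is.character(run)) run <- list(out_dir = run, paths = list())
  out_dir <- out_dir %||% file.path(run$out_dir, "report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  save_plot <- function(p, name, width = 7, height = 4) {
    f <- file.path(out_dir, name)
    grDevices::png(f, width = width * 100, height = height * 100, res = 100)
    print(p)
    grDevices::dev.off()
    written <<- c(written, f)
  }

  pfm_file <- file.path(run$out_dir, "pfms.meme")
  if (file.exists(pfm_file)) {
    pfms <- read_meme(pfm_file)
    save_plot(plot_logo(average_pfms(pfms)) +
                ggplot2::ggtitle("Averaged binding logo"),
              "logo_averaged.png")
  } else warning("no PFM output; skipping logo figure", call. = FALSE)

  land_file <- file.path(run$out_dir, "landscape.tsv")
  if (file.exists(land_file)) {
    save_plot(plot_landscape(read_stamped(land_file)), "landscape.png")
  } else warning("no landscape output; skipping landscape figure",
                 call. = FALSE)

  curve_file <- file.path(run$out_dir, "roc_curve.tsv")
  if (file.exists(curve_file)) {
    roc_meta <- jsonlite::read_json(file.path(run$out_dir, "roc.json"))
    save_plot(plot_roc_curve(read_stamped(curve_file), roc_meta$auc),
              "roc.png", width = 5, height = 5)
  }

  md <- file.path(out_dir, "report.md")
  lines <- c("# nrpbm run summary", "",
             sprintf("- run directory: %s", run$out_dir),
             sprintf("- figures: %s",
                     paste(basename(written), collapse = ", ")))
  if (file.exists(land_file)) {
    land <- read_stamped(land_file)
    lines <- c(lines, "",
               sprintf("- seeds above threshold: %d", nrow(land)),
               sprintf("- modes: %s",
                       paste(names(table(land$mode)), table(land$mode),
                             sep = "=", collapse = ", ")))
  }
  writeLines(lines, md)
  invisible(c(written, md))
}
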