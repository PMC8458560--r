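#' End-to-end in-silico encounter pipeline
#'
#' Chains the package's stages for both genotype presets: generate the
#' synthetic measured-like cohort, summarise its motility, synthesize long
#' tracks by step remixing, and run the DC-encounter simulation at each DC
#' density. All stage seeds are derived deterministically from `seed`, so
#' the same master seed reproduces every output byte for byte. When
#' `out_dir` is given, each stage writes its standard TSV/JSON artefact plus
#' a `run_config.json` sidecar recording the configuration and seed.
#'
#' @param seed master RNG seed.
#' @param genotypes presets to run, a subset of `c("WT", "ITK")`.
#' @param n_measured tracks per synthetic measured cohort.
#' @param n_synthetic long tracks to synthesize per genotype.
#' @param dc_counts DC densities to simulate.
#' @param config an [arena_config()] (its `n_dc` is overridden by
#'   `dc_counts`).
#' @param out_dir output directory, or `NULL` to skip file output.
#' @param verbose print stage progress.
#' @return list of class `"tcellscan_run"`: per-genotype list with elements
#'   `cohort`, `motility`, `synthetic`, `encounters` (one
#'   `encounter_result` per DC density), plus `report`, a data.frame of
#'   mean +/- SD contact fractions per genotype and DC density with the
#'   WT - ITK difference.
#' @export
run_full_pipeline <- function(seed = 1, genotypes = c("WT", "ITK"),
                              n_measured = 60, n_synthetic = 200,
                              dc_counts = c(50, 10000),
                              config = arena_config(),
                              out_dir = NULL, verbose = TRUE) {
  genotypes <- match.arg(genotypes, c("WT", "ITK"), several.ok = TRUE)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 3L * length(genotypes))
  dim(stage_seeds) <- c(3L, length(genotypes))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  runs <- list()
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    if (verbose) message("[", g, "] generating measured-like cohort")
    cohort <- generate_cohort(cohort_preset(g, n_tracks = n_measured),
                              seed = stage_seeds[1L, gi])
    mt <- motility(cohort)
    if (verbose) message("[", g, "] remixing ", n_synthetic, " tracks")
    syn <- synthesize_tracks(cohort, n_tracks = n_synthetic,
                             duration = config$duration, dt = config$dt,
                             seed = stage_seeds[2L, gi])
    encs <- list()
    for (nd in dc_counts) {
      if (verbose) message("[", g, "] encounter simulation, ", nd, " DCs")
      cfg <- config
      cfg$n_dc <- nd
      encs[[as.character(nd)]] <-
        run_experiment(syn, cfg, seed = stage_seeds[3L, gi] + match(nd,
                                                                    dc_counts))
    }
    runs[[g]] <- list(cohort = cohort, motility = mt, synthetic = syn,
                      encounters = encs)
    if (!is.null(out_dir)) {
      write_tracks(cohort, file.path(out_dir, paste0(g, "_cohort.tsv")))
      write_tracks(syn, file.path(out_dir, paste0(g, "_synthetic.tsv")))
      write_motility(mt, file.path(out_dir, paste0(g, "_motility")))
      for (nd in names(encs))
        utils::write.table(
          data.frame(rep = seq_along(encs[[nd]]$per_rep_contact_fraction),
                     contact_fraction = encs[[nd]]$per_rep_contact_fraction),
          file.path(out_dir, paste0(g, "_encounters_", nd, "dc.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report <- do.call(rbind, lapply(names(runs), function(g)
    do.call(rbind, lapply(names(runs[[g]]$encounters), function(nd) {
      e <- runs[[g]]$encounters[[nd]]
      data.frame(genotype = g, n_dc = as.numeric(nd),
                 mean_contact_fraction = e$mean_contact_fraction,
                 sd_contact_fraction = e$sd_contact_fraction)
    }))))
  if (all(c("WT", "ITK") %in% report$genotype)) {
    wt <- report[report$genotype == "WT", ]
    itk <- report[report$genotype == "ITK", ]
    diffs <- merge(wt, itk, by = "n_dc", suffixes = c("_wt", "_itk"))
    diffs$wt_minus_itk <- diffs$mean_contact_fraction_wt -
      diffs$mean_contact_fraction_itk
    attr(report, "difference") <- diffs[, c("n_dc", "wt_minus_itk")]
  }
  out <- c(runs, list(report = report,
                      seed = seed))
  class(out) <- "tcellscan_run"
  if (!is.null(out_dir)) {
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sidecar <- list(seed = seed, genotypes = genotypes,
                    n_measured = n_measured, n_synthetic = n_synthetic,
                    dc_counts = dc_counts,
                    arena = unclass(config),
                    package_version =
                      as.character(utils::packageVersion("tcellscan")))
    jsonlite::write_json(sidecar, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.tcellscan_run <- function(x, ...) {
  cat("In-silico T cell scanning run (seed ", x$seed, ")\n", sep = "")
  print(x$report)
  d <- attr(x$report, "difference")
  if (!is.null(d)) {
    cat("WT - ITK contact-fraction difference (percentage points):\n")
    print(d)
  }
  invisible(x)
}

#' Write a motility summary to TSV/JSON files
#'
#' Writes `<stem>_speeds.tsv` (per-track mean speeds),
#' `<stem>_turning.tsv` (binned turning-angle frequencies),
#' `<stem>_displacement.tsv` (mean displacement curve) and `<stem>.json`
#' (scalar summary).
#'
#' @param x a [motility()] object.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_motility <- function(x, stem) {
  stopifnot(inherits(x, "motility"))
  w <- function(df, suffix)
    utils::write.table(df, paste0(stem, suffix), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(data.frame(track_id = names(x$per_track_mean_speed),
               mean_speed = unname(x$per_track_mean_speed)), "_speeds.tsv")
  w(x$turning_angle_hist, "_turning.tsv")
  w(x$displacement_curve, "_displacement.tsv")
  jsonlite::write_json(list(n_tracks = x$n_tracks,
                            cohort_mean_speed = x$cohort_mean_speed,
                            sem = x$sem,
                            motility_coefficient = x$motility_coefficient,
                            dt = x$dt, fit_window = x$fit_window),
                       paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
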