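#' Pipeline run configuration
#'
#' Bundles the per-stage parameter blocks of [run_pipeline()]. The input
#' panel is given either in memory (`panel`) or as a PLINK `prefix` +
#' `format` pair; population labels come from the FAM/PED family-ID column.
#'
#' @param panel a [genotype_panel()], or `NULL` to read from `prefix`.
#' @param prefix,format PLINK input location, see [read_panel()].
#' @param outdir output directory for artifacts (created if needed);
#'   `NULL` keeps everything in memory.
#' @param qc a [qc_config()].
#' @param roh a [roh_params()].
#' @param pca_k number of principal components (default 2).
#' @param outlier_n_sd PC-cluster outlier multiplier ([flag_cluster_outliers()]);
#'   `NULL` disables outlier removal.
#' @param island_threshold,min_island_snps,max_join_gap_bp island-calling
#'   parameters, see [call_islands()].
#' @param L_aut autosome length in bp for `F_ROH` and coverage; `NULL` uses
#'   the panel's mapped span ([map_span_bp()]).
#' @param freq_by allele-frequency scope for the inbreeding estimators.
#' @param seed integer recorded in artifact provenance headers (the pipeline
#'   itself is deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(panel = NULL, prefix = NULL, format = "bed",
                       outdir = NULL, qc = qc_config(), roh = roh_params(),
                       pca_k = 2L, outlier_n_sd = 3,
                       island_threshold = 0.20, min_island_snps = 5L,
                       max_join_gap_bp = 5e5, L_aut = 2.5e9,
                       freq_by = "population", seed = 1L) {
  if (is.null(panel) && is.null(prefix))
    stop("either `panel` or `prefix` must be given")
  if (!is.null(prefix)) {
    need <- if (format == "bed") c(".bed", ".bim", ".fam") else c(".ped", ".map")
    miss <- !file.exists(paste0(prefix, need))
    if (any(miss)) stop("missing input file(s): ",
                        paste(paste0(prefix, need)[miss], collapse = ", "))
  }
  structure(list(panel = panel, prefix = prefix, format = format,
                 outdir = outdir, qc = qc, roh = roh, pca_k = as.integer(pca_k),
                 outlier_n_sd = outlier_n_sd,
                 island_threshold = island_threshold,
                 min_island_snps = as.integer(min_island_snps),
                 max_join_gap_bp = max_join_gap_bp, L_aut = L_aut,
                 freq_by = freq_by, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Thin convenience wrapper: top-level keys map to [run_config()] arguments,
#' with `qc` and `roh` sub-blocks passed to [qc_config()] and [roh_params()].
#' Requires the `yaml` package.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the `yaml` package")
  y <- yaml::read_yaml(path)
  if (!is.null(y$qc)) y$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$roh)) y$roh <- do.call(roh_params, y$roh)
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.provenance <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  hashable <- cfg[setdiff(names(cfg), c("panel", "outdir"))]
  writeLines(deparse(hashable), tmp)
  h <- unname(tools::md5sum(tmp))
  c(paste0("# autozyg ", as.character(utils::packageVersion("autozyg"))),
    paste0("# config_hash=", h),
    paste0("# seed=", cfg$seed))
}

.write_artifact <- function(df, path, prov, footer = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(footer)) writeLines(footer, con)
  invisible(path)
}

#' Run the full ROH / inbreeding / island pipeline
#'
#' Stages run in a fixed order: input, QC, population structure (IBS matrix,
#' principal components, optional cluster-outlier removal), ROH detection,
#' inbreeding coefficients and correlations, ROH islands with LD ratios,
#' and report tables. A stage failure halts the run with the stage named.
#' When `cfg$outdir` is set, every artifact is written as TSV with a
#' provenance header (package version, config hash, seed); rerunning with an
#' identical config reproduces identical files.
#'
#' @param cfg a [run_config()].
#' @return (Invisibly) a list with `panel` (post-QC, post-outlier),
#'   `qc_report`, `pca`, `outliers`, `segments`, `summary` (length-class
#'   table), `records`, `correlations`, `tracks` (per-SNP ROH incidence,
#'   all populations stacked), `islands`, `L_aut` and `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  panel <- .stage("input", {
    if (!is.null(cfg$panel)) cfg$panel
    else read_panel(cfg$prefix, cfg$format)
  })
  qc <- .stage("qc", apply_qc(panel, cfg$qc))
  panel <- qc$panel

  pca <- .stage("popstruct", {
    sim <- ibs_similarity(panel)
    pca_from_similarity(sim, k = min(cfg$pca_k, n_samples(panel) - 1L))
  })
  outliers <- NULL
  if (!is.null(cfg$outlier_n_sd) &&
      all(table(panel$samples$population) >= 3L) &&
      ncol(pca$coordinates) >= 2L) {
    outliers <- .stage("popstruct",
      flag_cluster_outliers(pca, panel$samples$population, cfg$outlier_n_sd))
    if (nrow(outliers))
      panel <- panel_subset(
        panel, samples = !(panel$samples$sample_id %in% outliers$sample_id))
  }

  L_aut <- if (is.null(cfg$L_aut)) map_span_bp(panel) else cfg$L_aut
  segments <- .stage("roh", detect_roh(panel, cfg$roh))
  n_pop <- table(panel$samples$population)
  n_pop <- stats::setNames(as.integer(n_pop), names(n_pop))
  summary_tab <- .stage("roh",
    classify_and_summarise(segments, n_pop, L_aut))

  records <- .stage("inbreeding",
    inbreeding_coefficients(panel, segments, L_aut, cfg$freq_by))
  ok_pops <- names(n_pop)[n_pop >= 3L]
  correlations <- if (length(ok_pops)) .stage("inbreeding",
    correlate_estimators(records[records$population %in% ok_pops, ]))
  else NULL

  isl_res <- .stage("islands", {
    tracks <- list(); islands <- list()
    for (g in names(n_pop)) {
      seg_g <- segments[segments$population == g, , drop = FALSE]
      tr <- roh_frequency(seg_g, panel$map, n_pop[[g]])
      tr$population <- g
      tracks[[g]] <- tr
      isl <- call_islands(tr, cfg$island_threshold, cfg$min_island_snps,
                          cfg$max_join_gap_bp)
      if (nrow(isl)) {
        sub <- panel_subset(panel,
                            samples = panel$samples$population == g)
        isl <- islands_r2_ratio(isl, sub)
        isl$population <- g
        islands[[g]] <- isl
      }
    }
    list(tracks = do.call(rbind, tracks),
         islands = if (length(islands)) do.call(rbind, islands) else
           data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      peak_fraction = numeric(), mean_fraction = numeric(),
                      r2_ratio = numeric(), population = character()))
  })
  tracks <- isl_res$tracks; rownames(tracks) <- NULL
  islands <- isl_res$islands; rownames(islands) <- NULL

  res <- list(panel = panel, qc_report = qc$report, pca = pca,
              outliers = outliers, segments = segments,
              summary = summary_tab, records = records,
              correlations = correlations, tracks = tracks,
              islands = islands, L_aut = L_aut, n_pop = n_pop, files = NULL)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    prov <- .provenance(cfg)
    fp <- function(f) file.path(cfg$outdir, f)
    .stage("report", {
      write_qc_report(qc$report, fp("qc_report.tsv"))
      co <- as.data.frame(pca$coordinates)
      co <- cbind(sample_id = rownames(pca$coordinates),
                  population = panel$samples$population[
                    match(rownames(pca$coordinates),
                          panel$samples$sample_id)], co)
      .write_artifact(co, fp("pca_coordinates.tsv"), prov,
                      footer = paste0("# variance_explained=",
                                      paste(signif(pca$variance_explained, 6),
                                            collapse = ",")))
      .write_artifact(segments, fp("roh_segments.tsv"), prov)
      .write_artifact(records, fp("inbreeding.tsv"), prov)
      .write_artifact(tracks, fp("roh_frequency.tsv"), prov)
      .write_artifact(islands, fp("islands.tsv"), prov)
      render_tables(res, cfg$outdir, prov)
    })
    res$files <- list.files(cfg$outdir, full.names = TRUE)
  }
  invisible(res)
}

#' Render report tables from pipeline results
#'
#' Writes the display tables of a run: the ROH length-class summary
#' (`table1_roh_classes.tsv`), per-population means of the four inbreeding
#' coefficients with their dispersion (`table2_inbreeding.tsv`; the
#' dispersion column is the sample SD), the estimator correlations
#' (`table3_correlations.tsv`) and a Manhattan-plot-ready per-SNP ROH
#' incidence track (`manhattan_track.tsv`). Table values are rounded for
#' display (percentages and correlations to 2 decimals, coefficients to 3);
#' the pipeline artifacts keep full precision.
#'
#' @param res result list from [run_pipeline()].
#' @param dir output directory.
#' @param prov provenance header lines (default: none).
#' @return (Invisibly) the paths written.
#' @export
render_tables <- function(res, dir, prov = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  t1 <- res$summary
  for (cn in c("percentage", "mean_length_mb", "sd_length_mb", "coverage_pct"))
    t1[[cn]] <- round(t1[[cn]], 2)
  .write_artifact(t1, fp("table1_roh_classes.tsv"), prov)

  t2 <- do.call(rbind, lapply(split(res$records, res$records$population),
    function(df) {
      row <- data.frame(population = df$population[1L])
      for (f in c("F_GRM", "F_HOM", "F_UNI", "F_ROH")) {
        row[[paste0(f, "_mean")]] <- round(mean(df[[f]]), 3)
        row[[paste0(f, "_dispersion")]] <- round(stats::sd(df[[f]]), 3)
      }
      row
    }))
  rownames(t2) <- NULL
  .write_artifact(t2, fp("table2_inbreeding.tsv"), prov)

  t3 <- res$correlations
  if (is.null(t3))
    t3 <- data.frame(population = character(), f1 = character(),
                     f2 = character(), r = numeric(), degenerate = logical())
  t3$r <- round(t3$r, 2)
  .write_artifact(t3, fp("table3_correlations.tsv"), prov)

  .write_artifact(res$tracks[, c("population", "chromosome", "position_bp",
                                 "fraction")],
                  fp("manhattan_track.tsv"), prov)
  invisible(vapply(c("table1_roh_classes.tsv", "table2_inbreeding.tsv",
                     "table3_correlations.tsv", "manhattan_track.tsv"),
                   fp, character(1)))
}
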