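#' Assemble a pipeline configuration
#'
#' Central container of thresholds and seeds; every printed default of the
#' method is the package default here (20-kb bins, 200-kb RT bins, 2e5
#' minimum reads, MAPQ 30, DIMAPD tail alpha 0.01, 160 RPMb per haploid
#' fallback coverage threshold, 2.5% replication-percentage intervals,
#' stage gates 30/40-60/70%).
#'
#' @param ... overrides of the defaults below.
#' @return named list of class `scrt_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(bin_size = 20000L, rt_bin_size = 200000L,
              min_reads = 200000, mapq_min = 30L,
              ploidy_limits = c(1, 8), target_ploidy = NULL,
              dimapd_alpha = 0.01, s_threshold = NULL,
              shift_first = NULL, shift_second = NULL,
              rpmb_per_haploid = 160,
              interval_width = 0.025, gc_grid = 0.01,
              stage_early = 0.30, stage_mid = c(0.40, 0.60),
              stage_late = 0.70, seed = 1L)
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = "scrt_config")
}

#' Run the full single-cell replication-timing pipeline
#'
#' Executes CNV calling, phase staging (metadata when provided, otherwise
#' manual threshold when set, otherwise automatic DIMAPD outliers),
#' S-progression correction, RT extraction and pseudo-bulk averaging, and
#' writes all artefacts to `out_dir`: per-cell QC and phase tables,
#' per-cell segment BED, the binary scRT matrix, the pseudo-bulk RT
#' bedGraph (1 = early) and the serialised configuration.
#'
#' @param counts bins x cells raw count matrix.
#' @param bins bin annotation table.
#' @param out_dir output directory (created if missing); NULL to skip
#'   writing.
#' @param config from [pipeline_config()].
#' @param phase_metadata optional data frame `cell_id`, `phase`.
#' @return list of class `scrt_run`: `cnv`, `phases`, `correction`,
#'   `rt` (`scrt_result`), `config`.
#' @export
run_pipeline <- function(counts, bins, out_dir = NULL,
                         config = pipeline_config(),
                         phase_metadata = NULL) {
  set.seed(config$seed)
  cnv <- call_cnv(counts, bins, min_reads = config$min_reads,
                  ploidy_limits = config$ploidy_limits,
                  target_ploidy = config$target_ploidy,
                  mapq_min = config$mapq_min)
  phases <- if (!is.null(phase_metadata)) {
    apply_phase_metadata(cnv$qc, phase_metadata)
  } else if (!is.null(config$s_threshold)) {
    call_phase_manual(cnv$qc, config$s_threshold)
  } else {
    call_phase_auto(cnv$qc, alpha = config$dimapd_alpha)
  }
  correction <- correct_s_progression(cnv$qc, phases,
                                      shift_first = config$shift_first,
                                      shift_second = config$shift_second)
  rt <- compute_rt(cnv, correction, rt_bin_size = config$rt_bin_size)
  run <- structure(list(cnv = cnv, phases = phases,
                        correction = correction, rt = rt,
                        config = config),
                   class = "scrt_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write pipeline artefacts to a directory
#'
#' @param run `scrt_run` object.
#' @param out_dir target directory.
#' @return the directory, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- dplyr::left_join(run$cnv$qc,
                         run$correction$cells[, c("cell_id", "phase",
                                                  "ploidy",
                                                  "replication_fraction")],
                         by = "cell_id", suffix = c("_raw", ""))
  utils::write.table(qc, file.path(out_dir, "cell_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seg <- dplyr::bind_rows(lapply(names(run$cnv$segments), function(id) {
    s <- run$cnv$segments[[id]]
    tibble::tibble(chrom = s$chrom, start = s$start, end = s$end,
                   cn = s$cn, cell_id = id)
  }))
  utils::write.table(seg, file.path(out_dir, "segments.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  rtm <- run$rt$rtm
  mat <- cbind(run$rt$rt_bins, t(rtm$scrt))
  utils::write.table(mat, file.path(out_dir, "scrt_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(run$rt$rt_bins, run$rt$pseudobulk$rt,
                 file.path(out_dir, "pseudobulk_rt.bedGraph"))
  cfg <- run$config
  cfg <- lapply(cfg, function(x) if (is.null(x)) NA else x)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
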