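#' Pipeline configuration
#'
#' Collects file paths, thresholds and seeds for [run_pipeline()]. Threshold
#' defaults are the consensus procedure's standard operating points: 2.5-fold
#' versus each mutant, 5-fold over the control bait, Z >= 2, a 10% local
#' window, and adjusted p < 0.1.
#'
#' @param counts,metadata Spectral-count and sample-metadata TSV paths
#'   (BioID stage; optional).
#' @param clones,ref Clone FASTA and optional reference FASTA paths (SHM
#'   stage; optional).
#' @param out_dir Output directory (created if needed).
#' @param fold_thresh,a2_fold_thresh,z_thresh,window_frac,alpha BioID
#'   thresholds.
#' @param pseudocount Fold pseudocount; `NULL` for the data-driven default.
#' @param min_identity SHM alignment identity threshold.
#' @param seed Seed recorded in the run report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, clones = NULL,
                            ref = NULL, out_dir = tempfile("aidquant_run_"),
                            fold_thresh = 2.5, a2_fold_thresh = 5,
                            z_thresh = 2, window_frac = 0.10, alpha = 0.1,
                            pseudocount = NULL, min_identity = 0.8,
                            seed = NULL) {
  stopifnot(fold_thresh > 0, a2_fold_thresh > 0, z_thresh > 0,
            window_frac > 0, alpha > 0)
  structure(list(counts = counts, metadata = metadata, clones = clones,
                 ref = ref, out_dir = out_dir, fold_thresh = fold_thresh,
                 a2_fold_thresh = a2_fold_thresh, z_thresh = z_thresh,
                 window_frac = window_frac, alpha = alpha,
                 pseudocount = pseudocount, min_identity = min_identity,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the configured analysis stages and write outputs plus a run report
#'
#' Runs the BioID consensus stage (when count files are configured) and the
#' hypermutation-spectrum stage (when a clone FASTA is configured). All stage
#' computation happens before any stage file is written, so a hard error
#' leaves no partial output. A JSON run report (package version, parameters,
#' seed, collected warnings, output files) is written last.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run report list (`status` 0 on success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_seen <- character()
  outputs <- character()
  results <- list()

  withCallingHandlers({
    if (!is.null(config$counts)) {
      sc <- read_spectral_counts(config$counts, config$metadata)
      results$bioid <- bioid_diff(
        sc$counts, sc$meta, birA = sc$birA_prey_id,
        fold_thresh = config$fold_thresh,
        a2_fold_thresh = config$a2_fold_thresh,
        z_thresh = config$z_thresh, window_frac = config$window_frac,
        alpha = config$alpha, pseudocount = config$pseudocount)
    }
    if (!is.null(config$clones)) {
      cs <- read_clone_fasta(config$clones, config$ref)
      results$shm <- shm_analyze(cs$clones, cs$reference,
                                 min_identity = config$min_identity)
    }
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  if (!is.null(results$bioid)) {
    b <- results$bioid
    readr::write_tsv(b$fold, out("bioid_fold.tsv"))
    readr::write_tsv(
      purrr::imap(b$normz, ~ dplyr::mutate(.x, mutant = .y)) |> purrr::list_rbind(),
      out("bioid_normz.tsv"))
    readr::write_tsv(
      purrr::imap(b$maz, ~ dplyr::mutate(.x, mutant = .y)) |> purrr::list_rbind(),
      out("bioid_maz.tsv"))
    readr::write_tsv(b$nb, out("bioid_deseq.tsv"))
    readr::write_tsv(b$consensus, out("bioid_consensus.tsv"))
    outputs <- c(outputs, "bioid_fold.tsv", "bioid_normz.tsv", "bioid_maz.tsv",
                 "bioid_deseq.tsv", "bioid_consensus.tsv")
  }
  if (!is.null(results$shm)) {
    s <- results$shm
    readr::write_tsv(s$records, out("shm_records.tsv"))
    readr::write_tsv(s$spectrum$load_histogram, out("shm_load_histogram.tsv"))
    readr::write_tsv(s$spectrum$class_table, out("shm_classes.tsv"))
    readr::write_tsv(
      tibble::tibble(n_sequences = s$spectrum$n_sequences,
                     total_bp = s$spectrum$total_bp,
                     n_mutations = s$spectrum$n_mutations,
                     frequency = s$spectrum$frequency,
                     n_rejected_clones = length(s$rejected)),
      out("shm_summary.tsv"))
    outputs <- c(outputs, "shm_records.tsv", "shm_load_histogram.tsv",
                 "shm_classes.tsv", "shm_summary.tsv")
  }

  report <- list(
    package = "aidquant",
    version = as.character(utils::packageVersion("aidquant")),
    r_version = as.character(getRversion()),
    parameters = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    warnings = warnings_seen,
    outputs = outputs,
    status = 0L
  )
  jsonlite::write_json(report, out("run_report.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(c(report, list(results = results)))
}
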