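# TSV conventions: header row, UTF-8, '.' decimal, NA for missing values.

#' Read a spectral-count table and its sample metadata
#'
#' @param path TSV with column `prey_id` then one integer column per sample.
#' @param metadata_path TSV with columns `sample_id`, `bait`, `replicate`.
#' @param birA Prey id of the BirA* row (must be present).
#' @param expected_baits Allowed bait labels; anything else is an error.
#' @return List with `counts`, `meta`, `birA_prey_id`.
#' @export
read_spectral_counts <- function(path, metadata_path, birA = "BirA",
                                 expected_baits = c("WT", "MUT1", "MUT2", "A2")) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "bait", "replicate") %in% names(meta)))
  bad <- setdiff(meta$bait, expected_baits)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown bait label(s): ", paste(bad, collapse = ", ")))
  }
  vals <- counts[setdiff(names(counts), "prey_id")]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    rlang::abort("non-numeric count column")
  }
  if (any(as.matrix(vals) != round(as.matrix(vals)))) {
    rlang::abort("non-integer spectral counts")
  }
  counts <- dplyr::mutate(counts, dplyr::across(-"prey_id", as.integer))
  validate_sc(counts, meta, birA = birA)
  list(counts = counts, meta = meta, birA_prey_id = birA)
}

#' Write a spectral-count table and metadata as TSV
#'
#' @param counts,meta As returned by [sim_bioid()].
#' @param path,metadata_path Output TSV paths.
#' @return Invisibly, the counts path.
#' @export
write_spectral_counts <- function(counts, meta, path, metadata_path) {
  readr::write_tsv(counts, path)
  readr::write_tsv(meta, metadata_path)
  invisible(path)
}

#' Read a clone set from FASTA
#'
#' The reference is the record named `REF` (or the single record of
#' `ref_path` when given); all other records are clones. Sequences are
#' uppercased.
#'
#' @param path Clones FASTA.
#' @param ref_path Optional FASTA holding the reference.
#' @return List with `reference` (string) and `clones` (tibble: clone_id,
#'   sequence).
#' @export
read_clone_fasta <- function(path, ref_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) rlang::abort("empty FASTA")
  ids <- sub("\\s.*$", "", names(seqs))
  seqs <- stats::setNames(toupper(as.character(seqs)), ids)
  if (!is.null(ref_path)) {
    ref <- Biostrings::readDNAStringSet(ref_path)
    if (length(ref) == 0) rlang::abort("empty reference FASTA")
    reference <- toupper(as.character(ref[[1]]))
    clones <- seqs
  } else {
    if (!"REF" %in% ids) rlang::abort("no record named 'REF' and no reference file given")
    reference <- unname(seqs[["REF"]])
    clones <- seqs[ids != "REF"]
  }
  list(reference = reference,
       clones = tibble::tibble(clone_id = names(clones), sequence = unname(clones)))
}

#' Write a clone set as FASTA (reference first, id REF)
#'
#' @param clones Tibble: `clone_id`, `sequence`.
#' @param reference Reference DNA string.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_clone_fasta <- function(clones, reference, path) {
  set <- Biostrings::DNAStringSet(c(REF = reference,
                                    stats::setNames(clones$sequence, clones$clone_id)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a fluctuation-assay colony-count table
#'
#' @param path TSV with columns `construct`, `experiment`, `culture`, `rifR`,
#'   `ampR`.
#' @return Tibble.
#' @export
read_fluctuation_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("construct", "rifR", "ampR") %in% names(d)))
  d
}

#' Read a qPCR plate table
#'
#' @param path TSV with columns `amplicon`, `sample_kind`, `dilution`, `ct`.
#' @return Tibble.
#' @export
read_plate_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  stopifnot(all(c("amplicon", "sample_kind", "ct") %in% names(d)))
  d
}
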