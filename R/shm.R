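#' Classify every reference position by hotspot context
#'
#' AID preferentially deaminates cytosines in WRC motifs (W = A/T, R = A/G,
#' then the mutated C). On the top strand the bottom-strand hotspot appears as
#' GYW (Y = C/T). Positions are classified as `CG_WRC` (C in WRC or G in GYW),
#' `CG_nonWRC` (any other C or G, including C/G whose motif context runs off
#' the sequence end) or `AT`.
#'
#' @param reference A single DNA string over A/C/G/T.
#' @return Character vector of length `nchar(reference)` with the class of
#'   each position.
#' @export
shm_site_classes <- function(reference) {
  reference <- toupper(reference)
  bases <- strsplit(reference, "")[[1]]
  n <- length(bases)
  if (n == 0L) rlang::abort("reference must be non-empty")
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    rlang::abort(paste0("reference contains non-ACGT characters: ",
                        paste(bad, collapse = ", ")))
  }
  cls <- rep("AT", n)
  is_c <- bases == "C"
  is_g <- bases == "G"
  cls[is_c | is_g] <- "CG_nonWRC"

  w <- bases %in% c("A", "T")
  r <- bases %in% c("A", "G")
  y <- bases %in% c("C", "T")
  # C at p is hot iff (p-2, p-1) = (W, R); G at p is hot iff (p+1, p+2) = (Y, W)
  idx <- seq_len(n)
  c_hot <- is_c & idx >= 3L & c(FALSE, FALSE, w[seq_len(n - 2L)]) &
    c(FALSE, r[seq_len(n - 1L)])
  g_hot <- is_g & idx <= n - 2L & c(y[-1L], FALSE) & c(w[-(1:2)], FALSE, FALSE)
  cls[c_hot | g_hot] <- "CG_WRC"
  cls
}

#' Classify a mutated reference position
#'
#' @param reference DNA string over A/C/G/T.
#' @param position 1-based position(s) on the reference (vectorised).
#' @return Character vector: `CG_WRC`, `CG_nonWRC` or `AT`.
#' @details A C or G whose motif context runs off either end of the sequence
#'   is classified `CG_nonWRC` with a warning.
#' @export
classify_mutation <- function(reference, position) {
  n <- nchar(reference)
  if (any(position < 1L | position > n)) {
    rlang::abort("position out of range of the reference")
  }
  cls <- shm_site_classes(reference)
  bases <- strsplit(toupper(reference), "")[[1]]
  edge <- (bases[position] == "C" & position < 3L) |
    (bases[position] == "G" & position > n - 2L)
  if (any(edge)) {
    rlang::warn("motif context runs off the sequence for some positions; classified CG_nonWRC")
  }
  cls[position]
}

#' Globally align a clone against the reference
#'
#' Needleman-Wunsch global alignment (via Biostrings) with affine gap
#' penalties. Clones whose alignment identity falls below `min_identity` are
#' rejected (likely wrong amplicon) rather than mutation-called.
#'
#' @param reference,clone DNA strings; the clone may contain N.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +1 / -2 / -5 / -1).
#' @param min_identity Minimum fraction of identical aligned columns, over
#'   columns where both sequences have a base; below it the clone is rejected.
#' @return A list of class `clone_alignment` with elements `ref_aln`,
#'   `clone_aln` (gapped strings), `identity`, and `rejected`.
#' @export
align_clone <- function(reference, clone, match = 1, mismatch = -2,
                        gap_open = -5, gap_extend = -1, min_identity = 0.8) {
  if (nchar(reference) == 0L || nchar(clone) == 0L) {
    rlang::abort("reference and clone must be non-empty")
  }
  reference <- toupper(reference)
  clone <- toupper(clone)
  # Equal-length, near-identical pairs need no gaps: with these scores a
  # deletion/insertion pair costs more than the mismatches it could save, so
  # the gapless alignment is optimal. This covers the common Sanger case.
  if (nchar(reference) == nchar(clone)) {
    rc <- strsplit(reference, "")[[1]]
    cc <- strsplit(clone, "")[[1]]
    ident <- mean(rc == cc)
    if (ident >= 0.95) {
      return(structure(
        list(ref_aln = reference, clone_aln = clone,
             identity = ident, rejected = ident < min_identity),
        class = "clone_alignment"
      ))
    }
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA"
  )
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(clone),
    subject = Biostrings::DNAString(reference),
    type = "global",
    substitutionMatrix = submat,
    gapOpening = abs(gap_open),
    gapExtension = abs(gap_extend)
  )
  ref_aln <- as.character(Biostrings::alignedSubject(al))
  clone_aln <- as.character(Biostrings::alignedPattern(al))
  rc <- strsplit(ref_aln, "")[[1]]
  cc <- strsplit(clone_aln, "")[[1]]
  both <- rc != "-" & cc != "-"
  identity <- if (any(both)) mean(rc[both] == cc[both]) else 0
  structure(
    list(ref_aln = ref_aln, clone_aln = clone_aln,
         identity = identity, rejected = identity < min_identity),
    class = "clone_alignment"
  )
}

#' Call substitutions from an aligned clone
#'
#' One record per mismatch column (both bases in A/C/G/T and different).
#' Gap columns are counted as indel events, reported separately and excluded
#' from the substitution frequency; columns where the clone has N are excluded
#' and tallied so the per-clone denominator can be corrected.
#'
#' @param alignment A `clone_alignment` from [align_clone()].
#' @param clone_id Identifier carried into the records.
#' @return A list with `records` (tibble: clone_id, position, ref_base,
#'   obs_base, mut_class), `n_indel_events`, and `n_excluded` (N columns).
#' @export
call_mutations <- function(alignment, clone_id = "clone") {
  stopifnot(inherits(alignment, "clone_alignment"))
  if (alignment$rejected) {
    rlang::abort(sprintf(
      "clone '%s' rejected: alignment identity %.1f%% below threshold",
      clone_id, 100 * alignment$identity))
  }
  rc <- strsplit(alignment$ref_aln, "")[[1]]
  cc <- strsplit(alignment$clone_aln, "")[[1]]
  ref_pos <- cumsum(rc != "-")
  acgt <- c("A", "C", "G", "T")
  is_sub <- rc %in% acgt & cc %in% acgt & rc != cc
  gap_cols <- rc == "-" | cc == "-"
  # indel events: runs of gap columns, not individual columns
  n_indel <- sum(rle(gap_cols)$values)
  n_excluded <- sum(cc == "N" & rc != "-")
  reference <- gsub("-", "", alignment$ref_aln, fixed = TRUE)
  pos <- ref_pos[is_sub]
  records <- tibble::tibble(
    clone_id = rep(clone_id, length(pos)),
    position = as.integer(pos),
    ref_base = rc[is_sub],
    obs_base = cc[is_sub],
    mut_class = if (length(pos)) classify_mutation(reference, pos) else character()
  )
  list(records = records, n_indel_events = n_indel, n_excluded = n_excluded)
}

#' Summarise a mutation spectrum
#'
#' Aggregate frequency (substitutions per base pair sequenced), the per-clone
#' mutation-load histogram, and the proportion of mutations in each hotspot
#' class.
#'
#' @param records Tibble of mutation records as from [call_mutations()].
#' @param clone_ids Identifiers of all analysed clones (including those with
#'   zero mutations); defines `n_sequences`.
#' @param analyzed_length Length (bp) of the analysed reference region.
#' @param n_bases_excluded Total N bases excluded across clones; subtracted
#'   from the denominator when they exceed 1% of it.
#' @return A list of class `shm_spectrum`: `n_sequences`, `total_bp`,
#'   `n_mutations`, `frequency`, `load_histogram` (tibble), and
#'   `class_counts` / `class_proportions` (tibble).
#' @export
summarize_spectrum <- function(records, clone_ids, analyzed_length,
                               n_bases_excluded = 0) {
  n_seq <- length(clone_ids)
  if (n_seq == 0L) rlang::abort("no sequences to summarise")
  if (nrow(records) > 0 && any(records$position > analyzed_length)) {
    rlang::abort("mutation record beyond analyzed_length")
  }
  total_bp <- n_seq * analyzed_length
  if (n_bases_excluded / total_bp > 0.01) total_bp <- total_bp - n_bases_excluded
  n_mut <- nrow(records)

  per_clone <- table(factor(records$clone_id, levels = clone_ids))
  load_histogram <- tibble::tibble(n_mutations = as.integer(names(table(per_clone))),
                                   n_sequences = as.integer(unname(table(per_clone)))) |>
    dplyr::mutate(proportion = .data$n_sequences / n_seq)

  classes <- c("CG_WRC", "CG_nonWRC", "AT")
  cc <- table(factor(records$mut_class, levels = classes))
  class_table <- tibble::tibble(
    mut_class = classes,
    count = as.integer(cc),
    proportion = if (n_mut > 0) as.integer(cc) / n_mut else rep(NA_real_, 3)
  )
  structure(
    list(n_sequences = n_seq, total_bp = total_bp, n_mutations = n_mut,
         frequency = n_mut / total_bp,
         load_histogram = load_histogram,
         class_table = class_table),
    class = "shm_spectrum"
  )
}

#' @export
print.shm_spectrum <- function(x, ...) {
  cat(sprintf("Mutation spectrum: %d mutations in %d sequences (%g bp analysed)\n",
              x$n_mutations, x$n_sequences, x$total_bp))
  cat(sprintf("  frequency: %.3g mutations/bp\n", x$frequency))
  print(x$class_table)
  invisible(x)
}

#' Run the full hypermutation-spectrum analysis on a clone set
#'
#' Aligns each clone to the reference, calls substitutions, classifies them by
#' WRC/GYW hotspot context and summarises frequency, load histogram and class
#' proportions. Clones rejected at alignment (identity below `min_identity`)
#' are excluded from the summary and listed in the result.
#'
#' @param clones Tibble with columns `clone_id`, `sequence`, or a named
#'   character vector of sequences.
#' @param reference DNA string over A/C/G/T.
#' @inheritParams align_clone
#' @return A list of class `shm_result`: `records`, `indels` (per-clone indel
#'   event counts), `rejected` (clone ids), and `spectrum` (`shm_spectrum`).
#' @export
shm_analyze <- function(clones, reference, match = 1, mismatch = -2,
                        gap_open = -5, gap_extend = -1, min_identity = 0.8) {
  if (is.character(clones) && !is.null(names(clones))) {
    clones <- tibble::tibble(clone_id = names(clones), sequence = unname(clones))
  }
  stopifnot(all(c("clone_id", "sequence") %in% names(clones)))
  if (anyDuplicated(clones$clone_id)) rlang::abort("duplicate clone ids")

  res <- purrr::map(seq_len(nrow(clones)), function(i) {
    al <- align_clone(reference, clones$sequence[i], match, mismatch,
                      gap_open, gap_extend, min_identity)
    if (al$rejected) {
      return(list(rejected = TRUE, clone_id = clones$clone_id[i],
                  identity = al$identity))
    }
    c(list(rejected = FALSE, clone_id = clones$clone_id[i]),
      call_mutations(al, clones$clone_id[i]))
  })
  rejected <- purrr::map_chr(purrr::keep(res, "rejected"), "clone_id")
  kept <- purrr::discard(res, "rejected")
  records <- purrr::map(kept, "records") |> purrr::list_rbind()
  if (nrow(records) == 0) {
    records <- tibble::tibble(clone_id = character(), position = integer(),
                              ref_base = character(), obs_base = character(),
                              mut_class = character())
  }
  indels <- tibble::tibble(
    clone_id = purrr::map_chr(kept, "clone_id"),
    n_indel_events = purrr::map_int(kept, "n_indel_events")
  )
  n_excluded <- sum(purrr::map_int(kept, "n_excluded"))
  spectrum <- if (length(kept) > 0) {
    summarize_spectrum(records, indels$clone_id, nchar(reference),
                       n_bases_excluded = n_excluded)
  } else {
    structure(list(n_sequences = 0L, total_bp = 0, n_mutations = 0L,
                   frequency = NA_real_,
                   load_histogram = tibble::tibble(n_mutations = integer(),
                                                   n_sequences = integer(),
                                                   proportion = numeric()),
                   class_table = tibble::tibble(mut_class = c("CG_WRC", "CG_nonWRC", "AT"),
                                                count = 0L, proportion = NA_real_)),
              class = "shm_spectrum")
  }
  structure(list(records = records, indels = indels, rejected = rejected,
                 spectrum = spectrum, reference = toupper(reference)),
            class = "shm_result")
}

#' @export
print.shm_result <- function(x, ...) {
  cat(sprintf("SHM analysis: %d clones analysed, %d rejected\n",
              x$spectrum$n_sequences, length(x$rejected)))
  print(x$spectrum)
  invisible(x)
}

#' Reverse-complement a DNA string (plain character interface)
#' @param x DNA string(s) over A/C/G/T/N.
#' @return Reverse-complemented string(s).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}
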