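#' Construct a TE copy alignment
#'
#' A `te_alignment` is a tibble with one row per element copy and columns
#' `copy_id`, `population`, `group` (optional labels, `NA` allowed) and
#' `residues` (the gapped sequence over `A`, `C`, `G`, `T`, `N`, `-`).
#' All copies must have identical (aligned) length. An optional
#' `reference_id` designates a member copy as the ancestral element
#' (an "A01"-style reference copy) used to anchor ancestral-state calls.
#'
#' @param copies A data frame with columns `copy_id`, `population`,
#'   `residues` and optionally `group`.
#' @param reference_id Optional `copy_id` of the designated ancestral copy.
#' @return A `te_alignment` tibble with attributes `n_columns` and
#'   `reference_id`.
#' @examples
#' te_alignment(tibble::tibble(
#'   copy_id = c("a", "b"), population = "P1",
#'   residues = c("ACGT", "ACGA")
#' ))
#' @export
te_alignment <- function(copies, reference_id = NULL) {
  stopifnot(is.data.frame(copies))
  needed <- c("copy_id", "population", "residues")
  missing_cols <- setdiff(needed, names(copies))
  if (length(missing_cols) > 0) {
    stop("metadata error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  copies <- tibble::as_tibble(copies)
  if (!"group" %in% names(copies)) copies$group <- NA_character_
  copies$group <- as.character(copies$group)
  copies$group[!is.na(copies$group) & copies$group == ""] <- NA_character_
  copies <- dplyr::select(copies, "copy_id", "population", "group", "residues")
  if (nrow(copies) == 0) stop("input error: no copies", call. = FALSE)
  if (anyDuplicated(copies$copy_id)) {
    stop("metadata error: duplicated copy_id", call. = FALSE)
  }
  copies$residues <- toupper(copies$residues)
  if (any(nchar(copies$residues) == 0)) {
    stop("input error: empty sequence", call. = FALSE)
  }
  bad <- stringr::str_detect(copies$residues, "[^ACGTN-]")
  if (any(bad)) {
    stop("alphabet error: residues outside {A,C,G,T,N,-} in copy ",
         copies$copy_id[which(bad)[1]], call. = FALSE)
  }
  lens <- nchar(copies$residues)
  if (length(unique(lens)) != 1) {
    stop("alignment-length error: copies have unequal aligned lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(reference_id) && !reference_id %in% copies$copy_id) {
    stop("metadata error: reference_id '", reference_id,
         "' is not a member copy", call. = FALSE)
  }
  structure(copies,
            class = c("te_alignment", class(tibble::tibble())),
            n_columns = unname(lens[1]),
            reference_id = reference_id)
}

#' @export
print.te_alignment <- function(x, ...) {
  cat("<te_alignment> ", nrow(x), " copies x ", attr(x, "n_columns"),
      " columns", sep = "")
  if (!is.null(attr(x, "reference_id"))) {
    cat("; reference:", attr(x, "reference_id"))
  }
  cat("\n")
  NextMethod()
}

#' Number of alignment columns
#' @param aln A `te_alignment`.
#' @return Integer count of aligned columns.
#' @export
n_columns <- function(aln) {
  stopifnot(inherits(aln, "te_alignment"))
  attr(aln, "n_columns")
}

#' Subset an alignment to selected copies
#'
#' Keeps the `te_alignment` class and attributes; the reference is dropped
#' if the subset no longer contains it.
#'
#' @param aln A `te_alignment`.
#' @param copy_ids Character vector of copies to keep.
#' @return A `te_alignment` with the selected copies, in `copy_ids` order.
#' @export
subset_copies <- function(aln, copy_ids) {
  stopifnot(inherits(aln, "te_alignment"))
  missing_ids <- setdiff(copy_ids, aln$copy_id)
  if (length(missing_ids) > 0) {
    stop("metadata error: unknown copy_id: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ref <- attr(aln, "reference_id")
  if (!is.null(ref) && !ref %in% copy_ids) ref <- NULL
  te_alignment(aln[match(copy_ids, aln$copy_id), , drop = FALSE],
               reference_id = ref)
}

# character matrix view (copies x columns); workhorse for the callers
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$residues, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(aln), byrow = TRUE)
  rownames(m) <- aln$copy_id
  m
}

#' Read a gapped aligned FASTA with copy metadata
#'
#' The FASTA must contain equally long gapped nucleotide records (`-` for
#' gaps, `N` for missing); `U` is rejected. Every record id must appear in
#' the metadata table, a tab-separated file with header columns `copy_id`,
#' `population` and optionally `group`.
#'
#' @param path Aligned FASTA file.
#' @param metadata_path Tab-separated metadata file.
#' @param reference_id Optional copy designated as the ancestral element.
#' @return A [te_alignment()].
#' @export
read_aligned_fasta <- function(path, metadata_path, reference_id = NULL) {
  if (!file.exists(path)) stop("input error: no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("input error: empty FASTA: ", path, call. = FALSE)
  residues <- toupper(as.character(seqs))
  if (any(stringr::str_detect(residues, "U"))) {
    stop("alphabet error: 'U' found; RNA alphabets are not supported",
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            colClasses = "character", check.names = FALSE)
  if (!all(c("copy_id", "population") %in% names(meta))) {
    stop("metadata error: metadata needs columns copy_id and population",
         call. = FALSE)
  }
  unknown <- setdiff(ids, meta$copy_id)
  if (length(unknown) > 0) {
    stop("metadata error: FASTA record(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(ids, meta$copy_id), , drop = FALSE]
  copies <- tibble::tibble(
    copy_id = ids,
    population = meta$population,
    group = if ("group" %in% names(meta)) meta$group else NA_character_,
    residues = unname(residues)
  )
  te_alignment(copies, reference_id = reference_id)
}

#' Write an alignment as aligned FASTA plus metadata TSV
#'
#' @param aln A `te_alignment`.
#' @param path Output FASTA file.
#' @param metadata_path Output metadata TSV (`copy_id`, `population`,
#'   `group`).
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(aln, path, metadata_path) {
  stopifnot(inherits(aln, "te_alignment"))
  seqs <- Biostrings::BStringSet(stats::setNames(aln$residues, aln$copy_id))
  Biostrings::writeXStringSet(seqs, path)
  utils::write.table(
    dplyr::select(tibble::as_tibble(aln), "copy_id", "population", "group"),
    metadata_path, sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T); gaps and `N` are excluded from both
#' numerator and denominator, and the result is case-insensitive, so the
#' value is unchanged by alignment gaps.
#'
#' @param residues Character vector of (possibly gapped) sequences.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(residues) {
  stopifnot(is.character(residues), length(residues) > 0)
  up <- toupper(residues)
  gc <- stringr::str_count(up, "[GC]")
  acgt <- stringr::str_count(up, "[ACGT]")
  if (any(acgt == 0)) {
    stop("undefined-content error: sequence with no A/C/G/T bases",
         call. = FALSE)
  }
  gc / acgt
}

#' Ungapped ancestral sequence implied by a profile
#'
#' Concatenates the called ancestral base of every non-insertion column,
#' in ancestral-position order.
#'
#' @param profile An ancestral profile from [call_ancestral_profile()].
#' @return A single ungapped sequence string ('N' at ambiguous columns).
#' @export
ancestral_sequence <- function(profile) {
  stopifnot(inherits(profile, "te_profile"))
  keep <- !is.na(profile$ancestral_position)
  st <- profile$ancestral_state[keep][order(profile$ancestral_position[keep])]
  st[is.na(st) | st == "-"] <- "N"
  paste(st, collapse = "")
}
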