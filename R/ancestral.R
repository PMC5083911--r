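#' Per-column allele counts
#'
#' Counts of `A`, `C`, `G`, `T` and gap (`-`) in the requested alignment
#' column(s); `N` is tallied separately as `missing` and never enters
#' frequency denominators.
#'
#' @param aln A [te_alignment()].
#' @param column 1-based column index (vectorized).
#' @return A tibble with one row per requested column: `column`, `A`, `C`,
#'   `G`, `T`, `gap`, `missing`, `n_copies`.
#' @export
column_allele_counts <- function(aln, column) {
  stopifnot(inherits(aln, "te_alignment"))
  nc <- n_columns(aln)
  if (any(column < 1 | column > nc)) {
    stop("index error: column out of range 1..", nc, call. = FALSE)
  }
  m <- aln_matrix(aln)[, column, drop = FALSE]
  tab <- function(ch) colSums(m == ch)
  tibble::tibble(
    column = as.integer(column),
    A = as.integer(tab("A")), C = as.integer(tab("C")),
    G = as.integer(tab("G")), T = as.integer(tab("T")),
    gap = as.integer(tab("-")), missing = as.integer(tab("N")),
    n_copies = nrow(aln)
  )
}

#' Call an ancestral profile by the majority-rule threshold
#'
#' For every alignment column the allele (base or gap) whose frequency among
#' non-missing characters reaches `major_threshold` is called ancestral;
#' minority characters at frequency at most `minor_threshold` are the
#' derived (mutated) state. Columns where no allele reaches the threshold
#' are `ambiguous` and yield no mutation calls. If a `reference_id` is
#' designated (the element's "A01" ancestral copy), its allele wins
#' whenever it itself reaches the threshold, which also settles exact
#' boundary ties in the reference's favour.
#'
#' Column classes: `fixed` (no minority), `substitution` (ancestral base,
#' minority bases), `deletion` (ancestral base, minority gaps), `insertion`
#' (ancestral gap, minority bases), `ambiguous`. A column carrying both
#' minority bases and minority gaps is labelled `substitution`; the callers
#' scan per-copy characters, so gap runs through such columns are still
#' detected.
#'
#' The threshold comparison is `>=` rather than strict `>`: with the small
#' per-group copy numbers used here a strict reading would make e.g. 17/20
#' twice the nominal 85% majority uncallable, so the boundary is
#' included and the threshold is exposed as a knob.
#'
#' @param aln A [te_alignment()] with at least 2 copies.
#' @param major_threshold Majority frequency needed to call the ancestral
#'   allele (default 0.85).
#' @param minor_threshold Maximum derived-allele frequency (default
#'   `1 - major_threshold`).
#' @param reference_id Designated ancestral copy; defaults to the
#'   alignment's `reference_id` attribute.
#' @return A `te_profile` tibble with one row per column: allele counts,
#'   `ancestral_state`, `ancestral_frequency`, `column_class`,
#'   `ancestral_position` (`NA` on insertion columns).
#' @export
call_ancestral_profile <- function(aln, major_threshold = 0.85,
                                   minor_threshold = 1 - major_threshold,
                                   reference_id = attr(aln, "reference_id")) {
  stopifnot(inherits(aln, "te_alignment"))
  if (nrow(aln) < 2) stop("input error: need >= 2 copies", call. = FALSE)
  if (!(major_threshold > 0.5 && major_threshold <= 1)) {
    stop("parameter error: major_threshold must be in (0.5, 1]", call. = FALSE)
  }
  if (minor_threshold >= major_threshold) {
    stop("parameter error: minor_threshold must be < major_threshold",
         call. = FALSE)
  }
  m <- aln_matrix(aln)
  alleles <- c("A", "C", "G", "T", "-")
  counts <- vapply(alleles, function(ch) colSums(m == ch),
                   numeric(ncol(m)))           # n_columns x 5
  if (ncol(m) == 1) counts <- matrix(counts, nrow = 1,
                                     dimnames = list(NULL, alleles))
  miss <- colSums(m == "N")
  denom <- rowSums(counts)                      # non-missing characters
  top_idx <- max.col(counts, ties.method = "first")
  top_count <- counts[cbind(seq_len(nrow(counts)), top_idx)]
  top_freq <- ifelse(denom > 0, top_count / denom, 0)
  anc <- alleles[top_idx]
  anc_freq <- top_freq
  called <- denom > 0 & top_freq >= major_threshold

  if (!is.null(reference_id)) {
    ref_chars <- m[match(reference_id, aln$copy_id), ]
    ref_idx <- match(ref_chars, alleles)        # NA where reference has N
    ok <- !is.na(ref_idx)
    ref_count <- rep(0, length(denom))
    ref_count[ok] <- counts[cbind(which(ok), ref_idx[ok])]
    ref_freq <- ifelse(denom > 0, ref_count / denom, 0)
    use_ref <- ok & denom > 0 & ref_freq >= major_threshold
    anc[use_ref] <- ref_chars[use_ref]
    anc_freq[use_ref] <- ref_freq[use_ref]
    called <- called | use_ref
  }

  anc[!called] <- NA_character_
  anc_freq[!called] <- NA_real_

  n_base_minor <- rowSums(counts[, c("A", "C", "G", "T"), drop = FALSE]) -
    ifelse(!is.na(anc) & anc != "-",
           counts[cbind(seq_len(nrow(counts)),
                        pmax(match(anc, alleles), 1, na.rm = TRUE))], 0)
  n_base_minor[is.na(anc)] <- NA_real_
  n_gap_minor <- ifelse(!is.na(anc) & anc != "-", counts[, "-"], NA_real_)

  cls <- rep("ambiguous", length(anc))
  is_base <- !is.na(anc) & anc != "-"
  is_gap <- !is.na(anc) & anc == "-"
  cls[is_base & n_base_minor > 0] <- "substitution"
  cls[is_base & n_base_minor == 0 & n_gap_minor > 0] <- "deletion"
  cls[is_base & n_base_minor == 0 & n_gap_minor == 0] <- "fixed"
  ins_minor <- rowSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  cls[is_gap & ins_minor > 0] <- "insertion"
  cls[is_gap & ins_minor == 0] <- "fixed"

  # insertion columns do not consume an ancestral position; ambiguous
  # columns do unless their plurality character is a gap
  is_insertion_col <- is_gap |
    (is.na(anc) & counts[, "-"] > rowSums(counts[, 1:4, drop = FALSE]))
  pos <- rep(NA_integer_, length(anc))
  pos[!is_insertion_col] <- seq_len(sum(!is_insertion_col))

  out <- tibble::tibble(
    column = seq_len(ncol(m)),
    A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"]),
    gap = as.integer(counts[, "-"]), missing = as.integer(miss),
    ancestral_state = anc,
    ancestral_frequency = anc_freq,
    column_class = cls,
    ancestral_position = pos
  )
  structure(out,
            class = c("te_profile", class(tibble::tibble())),
            n_copies = nrow(aln),
            major_threshold = major_threshold,
            minor_threshold = minor_threshold,
            reference_id = reference_id)
}

#' @export
print.te_profile <- function(x, ...) {
  cat("<te_profile> ", nrow(x), " columns; thresholds ",
      attr(x, "major_threshold"), "/", attr(x, "minor_threshold"), "\n",
      sep = "")
  NextMethod()
}

#' Write a profile dump for inspection
#'
#' @param profile A `te_profile`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(inherits(profile, "te_profile"))
  utils::write.table(tibble::as_tibble(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
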