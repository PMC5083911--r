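#' Per-copy single-column substitution calls
#'
#' One call is emitted for every (copy, column) where the column has a
#' called ancestral base, the copy carries a different `A/C/G/T` base, and
#' that base is a minority allele (frequency at most the profile's minor
#' threshold). Ambiguous columns and `N` characters yield no calls.
#'
#' @param aln A [te_alignment()].
#' @param profile The matching `te_profile` built from the same scope.
#' @return A tibble of calls: `copy_id`, `column`, `position` (ancestral),
#'   `anc`, `der`.
#' @export
call_substitutions <- function(aln, profile) {
  stopifnot(inherits(aln, "te_alignment"), inherits(profile, "te_profile"))
  if (n_columns(aln) != nrow(profile) || nrow(aln) != attr(profile, "n_copies")) {
    stop("consistency error: profile does not match alignment dimensions",
         call. = FALSE)
  }
  minor <- attr(profile, "minor_threshold")
  m <- aln_matrix(aln)
  denom <- profile$A + profile$C + profile$G + profile$T + profile$gap
  base_cols <- which(!is.na(profile$ancestral_state) &
                       profile$ancestral_state != "-")
  out <- vector("list", length(base_cols))
  for (k in seq_along(base_cols)) {
    j <- base_cols[k]
    chars <- unname(m[, j])
    anc <- profile$ancestral_state[j]
    hit <- chars %in% c("A", "C", "G", "T") & chars != anc
    if (!any(hit)) next
    cnt <- c(A = profile$A[j], C = profile$C[j], G = profile$G[j],
             T = profile$T[j])
    ok <- hit & (cnt[chars] / denom[j] <= minor)
    if (!any(ok)) next
    out[[k]] <- tibble::tibble(
      copy_id = aln$copy_id[ok],
      column = j,
      position = profile$ancestral_position[j],
      anc = anc,
      der = chars[ok]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(copy_id = character(), column = integer(),
                          position = integer(), anc = character(),
                          der = character())
  }
  res
}

# empty events skeleton shared by the callers
empty_events <- function() {
  tibble::tibble(
    event_kind = character(), copy_id = character(),
    interval_start = integer(), interval_end = integer(),
    anc_alleles = character(), der_alleles = character(),
    length = integer()
  )
}

#' Merge adjacent substitution calls into multi-base events
#'
#' Within each copy, maximal runs of consecutive ancestral positions that
#' are all substituted become one event whose ancestral/derived alleles are
#' the concatenated bases of the run; isolated calls become single-base
#' events. Substitution intervals are inclusive ancestral positions
#' (`interval_start` = first, `interval_end` = last substituted base).
#'
#' @param calls Output of [call_substitutions()].
#' @param profile The profile the calls were made against (unused beyond
#'   validation; kept for interface symmetry).
#' @return An events tibble (`event_kind = "substitution"`), one row per
#'   (copy, run).
#' @export
merge_adjacent_calls <- function(calls, profile = NULL) {
  if (nrow(calls) == 0) return(empty_events())
  calls <- dplyr::arrange(calls, .data$copy_id, .data$position)
  calls |>
    dplyr::group_by(.data$copy_id) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$position) != 1L))) |>
    dplyr::group_by(.data$copy_id, .data$run) |>
    dplyr::summarise(
      event_kind = "substitution",
      interval_start = min(.data$position),
      interval_end = max(.data$position),
      anc_alleles = paste(.data$anc, collapse = ""),
      der_alleles = paste(.data$der, collapse = ""),
      length = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-"run") |>
    dplyr::relocate("event_kind")
}

#' Call insertion and deletion events
#'
#' Deletions: within each copy, maximal runs of consecutive ancestral
#' positions whose columns have a called ancestral base but a gap in the
#' copy (with gap frequency at most the minor threshold) become one
#' deletion event. Insertions: within each maximal block of insertion
#' columns, a copy's maximal occupied run becomes one insertion event.
#'
#' Intervals use the exclusive-flank dialect: a deletion of ancestral
#' segment `[p, p+L-1]` is reported as `interval_start = p - 1`,
#' `interval_end = p + L` (so `length = end - start - 1`), and an insertion
#' between ancestral positions `i` and `i + 1` as `i`, `i + 1`.
#'
#' @param aln A [te_alignment()] (pooled scope recommended: indels are rare,
#'   so they are called on all copies together).
#' @param profile The matching `te_profile`.
#' @return An events tibble, one row per (copy, indel run).
#' @export
call_indels <- function(aln, profile) {
  stopifnot(inherits(aln, "te_alignment"), inherits(profile, "te_profile"))
  if (n_columns(aln) != nrow(profile) || nrow(aln) != attr(profile, "n_copies")) {
    stop("consistency error: profile does not match alignment dimensions",
         call. = FALSE)
  }
  minor <- attr(profile, "minor_threshold")
  m <- aln_matrix(aln)
  denom <- profile$A + profile$C + profile$G + profile$T + profile$gap
  out <- list()

  ## deletions: called-base columns, per-copy gaps, in ancestral-position order
  del_ok <- !is.na(profile$ancestral_state) & profile$ancestral_state != "-" &
    (profile$gap / pmax(denom, 1)) <= minor
  anc_cols <- which(!is.na(profile$ancestral_position))
  anc_cols <- anc_cols[order(profile$ancestral_position[anc_cols])]
  gap_ok <- m[, anc_cols, drop = FALSE] == "-" &
    rep(del_ok[anc_cols], each = nrow(m))
  anc_state <- profile$ancestral_state[anc_cols]
  for (i in seq_len(nrow(m))) {
    g <- gap_ok[i, ]
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      p1 <- starts[k]; p2 <- ends[k]      # indices into ancestral positions
      out[[length(out) + 1]] <- tibble::tibble(
        event_kind = "deletion",
        copy_id = aln$copy_id[i],
        interval_start = p1 - 1L,
        interval_end = p2 + 1L,
        anc_alleles = paste(anc_state[p1:p2], collapse = ""),
        der_alleles = "",
        length = p2 - p1 + 1L
      )
    }
  }

  ## insertions: per contiguous block of insertion columns
  ins_col <- is.na(profile$ancestral_position) &
    !is.na(profile$ancestral_state) & profile$ancestral_state == "-"
  if (any(ins_col)) {
    # left flank = ancestral position of nearest non-insertion column to the left
    left_flank <- cumsum(!is.na(profile$ancestral_position))
    blocks <- rle(ins_col)
    bends <- cumsum(blocks$lengths)
    bstarts <- bends - blocks$lengths + 1L
    for (k in which(blocks$values)) {
      cols <- bstarts[k]:bends[k]
      flank <- left_flank[bstarts[k]]
      sub <- m[, cols, drop = FALSE]
      occupied <- sub %in% c("A", "C", "G", "T")
      occupied <- matrix(occupied, nrow = nrow(m))
      for (i in seq_len(nrow(m))) {
        o <- occupied[i, ]
        if (!any(o)) next
        r <- rle(o)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (q in which(r$values)) {
          out[[length(out) + 1]] <- tibble::tibble(
            event_kind = "insertion",
            copy_id = aln$copy_id[i],
            interval_start = as.integer(flank),
            interval_end = as.integer(flank) + 1L,
            anc_alleles = "",
            der_alleles = paste(sub[i, starts[q]:ends[q]], collapse = ""),
            length = ends[q] - starts[q] + 1L
          )
        }
      }
    }
  }

  if (length(out) == 0) return(empty_events())
  dplyr::arrange(dplyr::bind_rows(out), .data$interval_start,
                 .data$event_kind, .data$copy_id)
}

#' Exclusive-flank interval of an indel placement
#'
#' Renders the reported interval for an indel from its concrete ancestral
#' placement: a deletion of segment `[p, p+L-1]` gets flanks `(p-1, p+L)`;
#' an insertion after ancestral position `i` gets `(i, i+1)`. The printed
#' form is `"start_end"`, so the deleted length is always
#' `end - start - 1`.
#'
#' @param event_kind `"deletion"` or `"insertion"`.
#' @param position Deletion segment start `p`, or insertion left flank `i`
#'   (0 = before the first base).
#' @param length Number of deleted ancestral bases (ignored for
#'   insertions).
#' @return A tibble with `interval_start`, `interval_end`, `interval`.
#' @export
indel_interval <- function(event_kind, position, length = 1L) {
  stopifnot(all(event_kind %in% c("deletion", "insertion")))
  start <- ifelse(event_kind == "deletion", position - 1L, position)
  end <- ifelse(event_kind == "deletion", position + length, position + 1L)
  tibble::tibble(interval_start = as.integer(start),
                 interval_end = as.integer(end),
                 interval = paste0(start, "_", end))
}

#' Equivalent placements of an indel in repeated context
#'
#' A deletion (or insertion) inside a homopolymer or tandem repeat can be
#' placed at several ancestral positions that all yield the same derived
#' sequence. This returns the contiguous range of equivalent segment
#' starts, which quantifies the placement ambiguity; the reported interval
#' itself always uses the aligned placement (see [indel_interval()]).
#'
#' @param ancestral Ungapped ancestral sequence.
#' @param position Deletion segment start, or insertion left flank.
#' @param length Length of the deleted segment (deletions).
#' @param bases Inserted bases (insertions).
#' @param event_kind `"deletion"` or `"insertion"`.
#' @return A list with `min_start`, `max_start`, `n_placements`.
#' @export
indel_placement_range <- function(ancestral, position, length = 1L,
                                  bases = NULL,
                                  event_kind = c("deletion", "insertion")) {
  event_kind <- match.arg(event_kind)
  s <- strsplit(toupper(ancestral), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (event_kind == "deletion") {
    L <- length
    stopifnot(position >= 1, position + L - 1 <= n)
    lo <- position
    while (lo > 1 && s[lo - 1] == s[lo + L - 1]) lo <- lo - 1
    hi <- position
    while (hi + L <= n && s[hi] == s[hi + L]) hi <- hi + 1
  } else {
    ins <- strsplit(toupper(bases), "", fixed = TRUE)[[1]]
    L <- length(ins)
    stopifnot(position >= 0, position <= n)
    # slide left: insertion after i-1 of rotate-right(ins) is equivalent
    # when the last inserted base equals s[i]
    lo <- position
    cur <- ins
    while (lo > 0 && cur[L] == s[lo]) {
      cur <- c(s[lo], cur[-L])
      lo <- lo - 1
    }
    hi <- position
    cur <- ins
    while (hi < n && cur[1] == s[hi + 1]) {
      cur <- c(cur[-1], s[hi + 1])
      hi <- hi + 1
    }
  }
  list(min_start = lo, max_start = hi, n_placements = hi - lo + 1L)
}

#' Collapse recurrent events into unique events with carrier lists
#'
#' Events sharing (`event_kind`, `interval_start`, `interval_end`,
#' `anc_alleles`, `der_alleles`) are one mutation observed in several
#' copies: a mutation occurring multiple times at the same position is
#' counted once, with the carriers unioned. The derived allele is part of
#' the key, so different changes at one position remain distinct events.
#' Idempotent.
#'
#' @param events Events tibble with a `copy_id` (or `copy_ids`) column.
#' @return Unique events with `copy_ids` (comma-separated, sorted) and
#'   `n_carriers`.
#' @export
deduplicate_events <- function(events) {
  if (nrow(events) == 0) {
    out <- empty_events()[, setdiff(names(empty_events()), "copy_id")]
    out$n_carriers <- integer()
    out$copy_ids <- character()
    return(out)
  }
  if (!"copy_ids" %in% names(events)) {
    events <- dplyr::rename(events, copy_ids = "copy_id")
  }
  events |>
    tidyr::separate_longer_delim("copy_ids", delim = ",") |>
    dplyr::group_by(.data$event_kind, .data$interval_start,
                    .data$interval_end, .data$anc_alleles,
                    .data$der_alleles) |>
    dplyr::summarise(
      length = .data$length[1],
      n_carriers = dplyr::n_distinct(.data$copy_ids),
      copy_ids = paste(sort(unique(.data$copy_ids)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$interval_start, .data$event_kind,
                   .data$der_alleles) |>
    dplyr::relocate("event_kind", "interval_start", "interval_end",
                    "anc_alleles", "der_alleles", "length")
}

#' Full caller: substitutions, multi-base merging, indels, deduplication
#'
#' Convenience wrapper running the whole detection stage at one scope.
#'
#' @param aln A [te_alignment()].
#' @param profile Optional pre-built profile (rebuilt from `aln` if `NULL`).
#' @param major_threshold,minor_threshold Passed to
#'   [call_ancestral_profile()] when the profile is rebuilt.
#' @return Deduplicated events tibble (substitutions of any length plus
#'   indels).
#' @export
call_mutation_events <- function(aln, profile = NULL, major_threshold = 0.85,
                                 minor_threshold = 1 - major_threshold) {
  if (is.null(profile)) {
    profile <- call_ancestral_profile(aln, major_threshold, minor_threshold)
  }
  subs <- merge_adjacent_calls(call_substitutions(aln, profile), profile)
  indels <- call_indels(aln, profile)
  deduplicate_events(dplyr::bind_rows(subs, indels))
}

#' Write an events table
#'
#' Tab-separated, one row per event, with the interval rendered as
#' `"start_end"`; rows ordered by (`interval_start`, `event_kind`, first
#' carrier).
#'
#' @param events Events tibble (deduplicated or per-copy).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events_table <- function(events, path) {
  if (!"copy_ids" %in% names(events) && "copy_id" %in% names(events)) {
    events <- dplyr::rename(events, copy_ids = "copy_id")
  }
  if (!"interval" %in% names(events)) {
    events <- dplyr::mutate(
      events,
      interval = paste0(.data$interval_start, "_", .data$interval_end),
      .after = "interval_end"
    )
  }
  events <- dplyr::arrange(events, .data$interval_start, .data$event_kind,
                           .data$copy_ids)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an events table written by [write_events_table()]
#'
#' @param path Input TSV path.
#' @return Events tibble.
#' @export
read_events_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  df <- tibble::as_tibble(df)
  for (col in intersect(c("interval_start", "interval_end", "length",
                          "n_carriers", "codon_position"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in intersect(c("anc_alleles", "der_alleles"), names(df))) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}
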