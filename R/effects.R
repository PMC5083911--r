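#' The 12 ordered single-base substitution patterns
#'
#' @return Character vector of the 12 patterns in canonical order
#'   (4 transitions, then 8 transversions), written `"A>G"` etc.
#' @export
substitution_patterns <- function() {
  c("A>G", "G>A", "T>C", "C>T",
    "A>T", "T>A", "A>C", "C>A", "G>T", "T>G", "G>C", "C>G")
}

#' Classify a single-base substitution pattern
#'
#' A substitution is a transition when ancestral and derived bases are both
#' purines (`A`, `G`) or both pyrimidines (`C`, `T`); the 4 transition and
#' 8 transversion ordered patterns partition the 12 possible base changes.
#'
#' @param anc,der Ancestral and derived bases (vectorized; must differ).
#' @return A tibble with `anc`, `der`, `pattern` (e.g. `"A>G"`), `ts_tv`
#'   (`"transition"`/`"transversion"`).
#' @examples
#' classify_pattern("A", "G")
#' @export
classify_pattern <- function(anc, der) {
  anc <- toupper(anc); der <- toupper(der)
  ok <- anc %in% c("A", "C", "G", "T") & der %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("invalid-substitution error: bases must be A/C/G/T",
                     call. = FALSE)
  if (any(anc == der)) {
    stop("invalid-substitution error: ancestral and derived base are equal",
         call. = FALSE)
  }
  purine <- function(b) b %in% c("A", "G")
  tibble::tibble(
    anc = anc, der = der,
    pattern = paste0(anc, ">", der),
    ts_tv = ifelse(purine(anc) == purine(der), "transition", "transversion")
  )
}

#' Pool complementary-strand substitution patterns
#'
#' Substitution bias is usually expressed per base pair: a pattern and its
#' complementary-strand partner (e.g. `A>G` with `T>C`) are pooled, giving
#' two transition pairs (`A:T>G:C`, `G:C>A:T`) and four transversion pairs.
#' Pooling conserves totals: the six pair counts sum to the twelve pattern
#' counts.
#'
#' @param pattern_counts A data frame with columns `pattern` and `count`
#'   (or a named numeric vector, names = patterns). Missing patterns count
#'   as zero; counts may be fractional (e.g. per-group means).
#' @return A tibble with `pair` and `count` for the six pooled pairs.
#' @examples
#' pool_complementary(c("A>G" = 15.75, "T>C" = 14.5, "G>A" = 7.25, "C>T" = 7))
#' @export
pool_complementary <- function(pattern_counts) {
  if (is.numeric(pattern_counts)) {
    pattern_counts <- tibble::tibble(pattern = names(pattern_counts),
                                     count = unname(pattern_counts))
  }
  stopifnot(all(c("pattern", "count") %in% names(pattern_counts)))
  bad <- setdiff(pattern_counts$pattern, substitution_patterns())
  if (length(bad) > 0) {
    stop("unknown pattern(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(pattern_counts$count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  cnt <- stats::setNames(rep(0, 12), substitution_patterns())
  cnt[pattern_counts$pattern] <- cnt[pattern_counts$pattern] +
    pattern_counts$count
  pairs <- list(
    "A:T>G:C" = c("A>G", "T>C"),
    "G:C>A:T" = c("G>A", "C>T"),
    "A:T>T:A" = c("A>T", "T>A"),
    "A:T>C:G" = c("A>C", "T>G"),
    "G:C>T:A" = c("G>T", "C>A"),
    "G:C>C:G" = c("G>C", "C>G")
  )
  tibble::tibble(
    pair = names(pairs),
    count = unname(vapply(pairs, function(p) sum(cnt[p]), numeric(1)))
  )
}

# normalize an ORF annotation argument to a validated tibble
as_orf_table <- function(orfs) {
  if (is.null(orfs)) return(tibble::tibble(name = character(),
                                           start = integer(), end = integer()))
  orfs <- tibble::as_tibble(orfs)
  stopifnot(all(c("start", "end") %in% names(orfs)))
  if (!"name" %in% names(orfs)) {
    orfs$name <- paste0("ORF", seq_len(nrow(orfs)))
  }
  bad <- orfs$start < 1 | orfs$start >= orfs$end |
    (orfs$end - orfs$start + 1) %% 3 != 0
  if (any(bad)) {
    stop("ORF annotation error: need 1 <= start < end and length divisible ",
         "by 3 (", paste(orfs$name[bad], collapse = ", "), ")", call. = FALSE)
  }
  o <- orfs[order(orfs$start), c("name", "start", "end")]
  if (nrow(o) > 1 && any(o$start[-1] <= o$end[-nrow(o)])) {
    stop("ORF annotation error: ORFs overlap", call. = FALSE)
  }
  o
}

#' Read an ORF annotation table
#'
#' Tab-separated with header columns `name`, `start`, `end`; 1-based
#' inclusive coordinates on the ungapped ancestral sequence.
#'
#' @param path TSV path.
#' @return A validated ORF tibble.
#' @export
read_orf_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  as_orf_table(df)
}

# ancestral base span actually affected by an event:
# substitutions cover [start, end] inclusively; deletions cover the
# removed segment (start+1, end-1); insertions affect the point between
# the flanks and are "inside" only when both flanks sit in one ORF.
event_span <- function(events) {
  del <- events$event_kind == "deletion"
  ins <- events$event_kind == "insertion"
  lo <- events$interval_start + ifelse(del, 1L, 0L)
  hi <- events$interval_end - ifelse(del, 1L, 0L)
  lo[ins] <- events$interval_start[ins]
  hi[ins] <- events$interval_end[ins]
  list(lo = lo, hi = hi)
}

#' Assign events to ORF regions
#'
#' `inside_orf` when the whole affected span lies within a single annotated
#' ORF, `outside_orf` when it is disjoint from all ORFs, `spanning`
#' otherwise (e.g. a long deletion removing ORF and flank together). For
#' insertions the two flanking positions are used, so an insertion is
#' inside when both flanks fall in one ORF.
#'
#' @param events Events tibble.
#' @param orfs ORF annotation (data frame with `start`, `end`, optional
#'   `name`), or `NULL` for none (everything `outside_orf`).
#' @return `events` with a `region` column (and `orf_name` of the
#'   containing ORF for inside events).
#' @export
assign_region <- function(events, orfs) {
  orfs <- as_orf_table(orfs)
  if (nrow(events) == 0) {
    events$region <- character(0); events$orf_name <- character(0)
    return(events)
  }
  sp <- event_span(events)
  region <- rep("outside_orf", nrow(events))
  orf_name <- rep(NA_character_, nrow(events))
  if (nrow(orfs) > 0) {
    for (i in seq_len(nrow(events))) {
      inside <- which(orfs$start <= sp$lo[i] & sp$hi[i] <= orfs$end)
      overlaps <- which(orfs$start <= sp$hi[i] & sp$lo[i] <= orfs$end)
      if (length(inside) > 0) {
        region[i] <- "inside_orf"
        orf_name[i] <- orfs$name[inside[1]]
      } else if (length(overlaps) > 0) {
        region[i] <- "spanning"
      }
    }
  }
  events$region <- region
  events$orf_name <- orf_name
  events
}

#' Codon position of an ancestral site
#'
#' @param pos Ancestral position(s) inside the ORF.
#' @param orf A single ORF (data frame row or list with `start`, `end`).
#' @return 1, 2 or 3: `((pos - start) mod 3) + 1`.
#' @export
codon_position <- function(pos, orf) {
  if (any(pos < orf$start | pos > orf$end)) {
    stop("domain error: position outside the ORF", call. = FALSE)
  }
  ((pos - orf$start) %% 3) + 1L
}

#' Protein effect of a single-base coding substitution
#'
#' Substitutes the derived base into the ancestral codon and compares
#' translations under the standard nuclear genetic code: `synonymous`
#' (amino acid unchanged, including stop-to-stop), `nonsense` (sense codon
#' becomes a stop), `no_stop` (stop codon becomes sense), `missense`
#' otherwise.
#'
#' @param ancestral Ungapped ancestral sequence.
#' @param orf The containing ORF (`start`, `end`).
#' @param pos Ancestral position of the substituted base (vectorized).
#' @param der Derived base(s).
#' @param code Genetic code table (named character vector codon -> amino
#'   acid, `*` = stop); defaults to the standard code.
#' @return Character vector of effect classes.
#' @export
classify_effect <- function(ancestral, orf, pos, der,
                            code = Biostrings::GENETIC_CODE) {
  s <- strsplit(toupper(ancestral), "", fixed = TRUE)[[1]]
  der <- toupper(der)
  stopifnot(length(pos) == length(der))
  if (any(pos < orf$start | pos > orf$end)) {
    stop("domain error: position outside the ORF", call. = FALSE)
  }
  vapply(seq_along(pos), function(i) {
    p <- pos[i]
    cp <- codon_position(p, orf)
    c0 <- p - cp + 1L
    codon <- s[c0:(c0 + 2L)]
    if (any(!codon %in% c("A", "C", "G", "T"))) {
      stop("unclassifiable error: ancestral codon contains N or gap",
           call. = FALSE)
    }
    if (codon[cp] == der[i]) {
      stop("invalid-substitution error: derived equals ancestral base",
           call. = FALSE)
    }
    aa0 <- unname(code[paste(codon, collapse = "")])
    codon[cp] <- der[i]
    aa1 <- unname(code[paste(codon, collapse = "")])
    if (aa0 == aa1) "synonymous"
    else if (aa0 != "*" && aa1 == "*") "nonsense"
    else if (aa0 == "*" && aa1 != "*") "no_stop"
    else "missense"
  }, character(1))
}

#' Frame effect of a coding indel
#'
#' An indel inside (or spanning into) the ORF region causes a frameshift
#' when the number of ORF bases inserted or deleted is not a multiple of 3,
#' and an in-frame change otherwise. For a spanning deletion only the
#' removed bases that overlap annotated ORFs count.
#'
#' @param events Indel events with `region` assigned.
#' @param orfs ORF annotation.
#' @return Character vector: `"frameshift"`, `"in_frame"`, or `NA` for
#'   events not touching an ORF.
#' @export
classify_indel_frame <- function(events, orfs) {
  orfs <- as_orf_table(orfs)
  if (nrow(events) == 0) return(character(0))
  sp <- event_span(events)
  vapply(seq_len(nrow(events)), function(i) {
    kind <- events$event_kind[i]
    if (!kind %in% c("insertion", "deletion")) return(NA_character_)
    if (kind == "insertion") {
      inside <- any(orfs$start <= events$interval_start[i] &
                      events$interval_end[i] <= orfs$end)
      if (!inside) return(NA_character_)
      n_orf <- events$length[i]
    } else {
      n_orf <- sum(pmax(0, pmin(sp$hi[i], orfs$end) -
                          pmax(sp$lo[i], orfs$start) + 1))
      if (n_orf == 0) return(NA_character_)
    }
    if (n_orf %% 3 == 0) "in_frame" else "frameshift"
  }, character(1))
}

#' Annotate events with pattern, region, codon and protein-effect fields
#'
#' Adds `region`/`orf_name` for all events; `pattern` and `ts_tv` for
#' single-base substitutions; `codon_position` and `effect` for
#' single-base substitutions inside an ORF; `frame_effect` for
#' ORF-affecting indels. Multi-base substitutions keep `NA` pattern fields
#' and are reported as their own category.
#'
#' @param events Deduplicated events tibble.
#' @param ancestral Ungapped ancestral sequence (needed for protein
#'   effects; may be `NULL` to skip them).
#' @param orfs ORF annotation (or `NULL`).
#' @return Annotated events tibble.
#' @export
annotate_events <- function(events, ancestral = NULL, orfs = NULL) {
  events <- assign_region(events, orfs)
  n <- nrow(events)
  events$pattern <- rep(NA_character_, n)
  events$ts_tv <- rep(NA_character_, n)
  events$codon_position <- rep(NA_integer_, n)
  events$effect <- rep(NA_character_, n)
  events$frame_effect <- rep(NA_character_, n)
  if (n == 0) return(events)

  sb <- events$event_kind == "substitution" & events$length == 1L
  if (any(sb)) {
    cls <- classify_pattern(events$anc_alleles[sb], events$der_alleles[sb])
    events$pattern[sb] <- cls$pattern
    events$ts_tv[sb] <- cls$ts_tv
  }
  orft <- as_orf_table(orfs)
  coding <- sb & events$region == "inside_orf"
  if (any(coding) && nrow(orft) > 0) {
    for (i in which(coding)) {
      orf <- orft[orft$name == events$orf_name[i], ]
      events$codon_position[i] <-
        codon_position(events$interval_start[i], orf)
      if (!is.null(ancestral)) {
        events$effect[i] <- classify_effect(
          ancestral, orf, events$interval_start[i], events$der_alleles[i]
        )
      }
    }
  }
  indel <- events$event_kind %in% c("insertion", "deletion")
  if (any(indel) && nrow(orft) > 0) {
    events$frame_effect[indel] <-
      classify_indel_frame(events[indel, , drop = FALSE], orft)
  }
  events
}
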