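catalog_path <- function(file) {
  system.file("extdata", file, package = "tespectrum", mustWork = TRUE)
}

#' Published indel catalog of the two surveyed elements
#'
#' The complete list of insertion/deletion events reported for the
#' CsuPLE1.1 (piggyBac-like) and Csu-Ty3 (Ty3/gypsy) element families of
#' the rice stem borer, in the exclusive-flank `"start_end"` coordinate
#' dialect (deleted length = end - start - 1). `bases` gives the affected
#' bases where published; longer indels are published as lengths only.
#'
#' @param element Optional filter: `"CsuPLE1.1"` or `"Csu-Ty3"`.
#' @return A tibble: `element`, `region`, `event_kind`, `interval_start`,
#'   `interval_end`, `length`, `bases`.
#' @export
indel_catalog <- function(element = NULL) {
  df <- utils::read.delim(catalog_path("indel_catalog.tsv"), sep = "\t",
                          colClasses = c(interval_start = "integer",
                                         interval_end = "integer",
                                         length = "integer"),
                          na.strings = NULL)
  df <- tibble::as_tibble(df)
  if (!is.null(element)) df <- df[df$element == element, , drop = FALSE]
  df
}

#' Published multi-base substitution catalog
#'
#' The two adjacent 2-base substitutions of CsuPLE1.1 and the five 2-base
#' plus one 3-base substitutions of Csu-Ty3, as ancestral/derived allele
#' runs with their ORF region. Positions were not published; the fixture
#' builder places them at documented synthetic coordinates consistent
#' with the stated regions.
#'
#' @param element Optional filter.
#' @return A tibble: `element`, `anc`, `der`, `region`.
#' @export
multibase_catalog <- function(element = NULL) {
  df <- tibble::as_tibble(utils::read.delim(
    catalog_path("multibase_catalog.tsv"), sep = "\t"))
  if (!is.null(element)) df <- df[df$element == element, , drop = FALSE]
  df
}

#' Published per-group spectrum means
#'
#' Cross-group means and standard errors of single-base substitution
#' counts for the two elements: transition and transversion totals plus
#' the four transition patterns. These printed summaries are the worked
#' inputs for the pooling and total identities (the underlying copy
#' sequences were not deposited).
#'
#' @param element Optional filter.
#' @return A tibble: `element`, `category`, `mean`, `se`.
#' @export
published_spectrum_means <- function(element = NULL) {
  df <- tibble::as_tibble(utils::read.delim(
    catalog_path("substitution_means.tsv"), sep = "\t"))
  if (!is.null(element)) df <- df[df$element == element, , drop = FALSE]
  df
}

# synthetic coordinates for the multi-base substitutions (positions were
# not published; chosen inside/outside the fixture ORFs as stated)
multibase_positions <- function(element) {
  if (element == "CsuPLE1.1") c(900L, 300L)
  else c(1060L, 1075L, 1090L, 1105L, 1120L, 1200L)
}

# fixture ORF coordinates per element: chosen so every catalog row falls
# in its stated region (Csu-Ty3 needs two ORFs so the 963-nt deletion is
# ORF-affecting while positions 696-779 stay intergenic)
catalog_orfs <- function(element) {
  if (element == "CsuPLE1.1") {
    tibble::tibble(name = "transposase", start = 600L, end = 2129L)
  } else {
    tibble::tibble(name = c("gag", "pol"), start = c(240L, 780L),
                   end = c(695L, 1868L))
  }
}

#' Reconstruct a published event catalog as a synthetic alignment
#'
#' Builds a deterministic synthetic family alignment in which every
#' published indel and multi-base substitution of the chosen element is
#' planted in one carrier copy, on a seeded random ancestral sequence
#' constrained to carry the published bases at the published coordinates.
#' Running the caller on the result reproduces the printed event catalog
#' exactly (counts, intervals, alleles).
#'
#' @param element `"CsuPLE1.1"` (84 copies, 21 populations, 2400 bp,
#'   one ORF) or `"Csu-Ty3"` (140 copies, 7 populations, 1900 bp, two
#'   ORFs).
#' @return List: `alignment`, `truth`, `orfs`, `ancestral`, `element`.
#' @export
build_catalog_fixture <- function(element = c("CsuPLE1.1", "Csu-Ty3")) {
  element <- match.arg(element)
  if (element == "CsuPLE1.1") {
    len <- 2400L; n_copies <- 84L; pops <- 21L; gc <- 0.359; seed <- 104729L
  } else {
    len <- 1900L; n_copies <- 140L; pops <- 7L; gc <- 0.373; seed <- 104730L
  }
  s <- withr::with_seed(seed, sample(
    c("A", "C", "G", "T"), len, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))

  indels <- indel_catalog(element)
  mb <- multibase_catalog(element)
  mb$position <- multibase_positions(element)

  # pin published bases onto the ancestral, checking self-consistency
  constraints <- list()
  pin <- function(pos, base) {
    for (k in seq_along(pos)) {
      key <- as.character(pos[k])
      prev <- constraints[[key]]
      if (!is.null(prev) && prev != base[k]) {
        stop("catalog inconsistency at position ", pos[k], call. = FALSE)
      }
      constraints[[key]] <<- base[k]
    }
  }
  del <- indels[indels$event_kind == "deletion" & indels$bases != "", ,
                drop = FALSE]
  for (i in seq_len(nrow(del))) {
    p <- del$interval_start[i] + 1L
    pin(p:(p + del$length[i] - 1L),
        strsplit(del$bases[i], "", fixed = TRUE)[[1]])
  }
  for (i in seq_len(nrow(mb))) {
    p <- mb$position[i]
    pin(p:(p + nchar(mb$anc[i]) - 1L),
        strsplit(mb$anc[i], "", fixed = TRUE)[[1]])
  }
  for (key in names(constraints)) s[as.integer(key)] <- constraints[[key]]
  # keep derived alleles distinct from the (random) ancestral run
  for (i in seq_len(nrow(mb))) {
    p <- mb$position[i]
    der <- strsplit(mb$der[i], "", fixed = TRUE)[[1]]
    anc <- strsplit(mb$anc[i], "", fixed = TRUE)[[1]]
    stopifnot(all(anc != der))
  }

  filler <- function(n) paste(rep(c("A", "C", "G", "T"), length.out = n),
                              collapse = "")
  planted <- dplyr::bind_rows(
    tibble::tibble(
      event_kind = indels$event_kind,
      position = ifelse(indels$event_kind == "deletion",
                        indels$interval_start + 1L, indels$interval_start),
      bases = ifelse(indels$event_kind == "insertion",
                     ifelse(indels$bases == "",
                            vapply(indels$length, filler, character(1)),
                            indels$bases),
                     NA_character_),
      length = indels$length
    ),
    tibble::tibble(
      event_kind = "substitution",
      position = mb$position,
      bases = mb$der,
      length = nchar(mb$der)
    )
  )
  fx <- build_fixture(paste(s, collapse = ""), planted, n_copies = n_copies,
                      populations = pops)
  c(fx, list(orfs = catalog_orfs(element),
             ancestral = paste(s, collapse = ""), element = element))
}
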