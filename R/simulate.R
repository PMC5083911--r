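#' Simulation configuration for a synthetic TE family
#'
#' Defaults emulate the sampling design and observed mutation magnitudes of
#' a piggyBac-like DNA transposon family surveyed across field populations:
#' 21 populations x 4 copies (~2.4 kb element, GC 0.359, one transposase
#' ORF), with per-copy single-base substitution rates whose per-group
#' expected totals match the observed spectrum (transition:transversion
#' about 2.4:1, A:T>G:C about twice G:C>A:T), rare adjacent multi-base
#' substitutions and rare indels with a 1 bp-dominant, long-tailed length
#' mixture.
#'
#' @param ancestral_length Element length in bases.
#' @param gc_fraction Target GC fraction of the ancestral sequence.
#' @param orfs ORF annotation tibble (`name`, `start`, `end`), `NULL` for
#'   none, or `"auto"` (default): one ORF starting at a quarter of the
#'   element and covering ~60% of it, mirroring a transposase ORF inside
#'   terminal repeats (dropped when the element is too short for a clean
#'   frame).
#' @param populations Number of field populations.
#' @param copies_per_population Copies sampled per population.
#' @param pattern_rates Named vector: expected single-base substitution
#'   events per copy for each of the 12 ordered patterns.
#' @param multi_base_rate Expected adjacent multi-base substitution events
#'   per copy.
#' @param multi_base_lengths,multi_base_length_probs Lengths (and mixture
#'   weights) of multi-base substitution runs.
#' @param indel_rate Expected indel events per copy.
#' @param deletion_prob Probability an indel is a deletion.
#' @param indel_length_mix Mixture weights `c(single, short, long)` for
#'   indel lengths: exactly 1 bp; 2-30 bp (truncated geometric); 30-300 bp
#'   (uniform).
#' @param seed Integer seed driving ancestral generation and event
#'   placement.
#' @return A `te_sim_config` list.
#' @export
simulation_config <- function(ancestral_length = 2400,
                              gc_fraction = 0.359,
                              orfs = "auto",
                              populations = 21,
                              copies_per_population = 4,
                              pattern_rates = default_pattern_rates(),
                              multi_base_rate = 0.024,
                              multi_base_lengths = c(2L, 3L),
                              multi_base_length_probs = c(0.8, 0.2),
                              indel_rate = 0.29,
                              deletion_prob = 0.54,
                              indel_length_mix = c(0.55, 0.35, 0.10),
                              seed = 1L) {
  stopifnot(ancestral_length > 0, gc_fraction > 0, gc_fraction < 1,
            populations >= 1, copies_per_population >= 1,
            all(pattern_rates >= 0), multi_base_rate >= 0, indel_rate >= 0,
            deletion_prob >= 0, deletion_prob <= 1,
            length(indel_length_mix) == 3, all(indel_length_mix >= 0))
  if (identical(orfs, "auto")) {
    start <- floor(ancestral_length * 0.25) + 1
    olen <- floor(ancestral_length * 0.6 / 3) * 3
    olen <- min(olen, floor((ancestral_length - start + 1) / 3) * 3)
    orfs <- if (olen >= 9) {
      tibble::tibble(name = "transposase", start = as.integer(start),
                     end = as.integer(start + olen - 1))
    } else NULL
  }
  orfs <- as_orf_table(orfs)
  if (nrow(orfs) > 0 && any(orfs$end > ancestral_length)) {
    stop("config error: ORF extends past the ancestral length", call. = FALSE)
  }
  stopifnot(setequal(names(pattern_rates), substitution_patterns()))
  structure(list(
    ancestral_length = as.integer(ancestral_length),
    gc_fraction = gc_fraction, orfs = orfs,
    populations = as.integer(populations),
    copies_per_population = as.integer(copies_per_population),
    pattern_rates = pattern_rates[substitution_patterns()],
    multi_base_rate = multi_base_rate,
    multi_base_lengths = multi_base_lengths,
    multi_base_length_probs = multi_base_length_probs /
      sum(multi_base_length_probs),
    indel_rate = indel_rate, deletion_prob = deletion_prob,
    indel_length_mix = indel_length_mix / sum(indel_length_mix),
    seed = as.integer(seed)
  ), class = "te_sim_config")
}

#' Default per-copy substitution pattern rates
#'
#' Expected single-base substitution events per copy, scaled so that a
#' group of 21 copies accumulates on the order of 60 unique events with
#' the observed pattern proportions (A>G most frequent, then T>C, a
#' transition:transversion ratio near 2.4, and A:T>G:C about twice
#' G:C>A:T).
#'
#' @return Named numeric vector over the 12 patterns.
#' @export
default_pattern_rates <- function() {
  group_totals <- c(
    "A>G" = 15.75, "G>A" = 7.25, "T>C" = 14.5, "C>T" = 7,
    "A>T" = 2.28, "T>A" = 2.28, "A>C" = 2.28, "C>A" = 2.28,
    "G>T" = 2.28, "T>G" = 2.28, "G>C" = 2.28, "C>G" = 2.28
  )
  (group_totals / 21)[substitution_patterns()]
}

#' Simulate an ungapped ancestral element sequence
#'
#' Bases are drawn i.i.d. with the configured GC fraction; each annotated
#' ORF is then made a clean reading frame: it starts with `ATG`, ends with
#' `TAA`, and internal in-frame stop codons are patched at their third
#' position.
#'
#' @param config A [simulation_config()].
#' @return List with `ancestral` (string) and `orfs`.
#' @export
simulate_ancestral <- function(config) {
  stopifnot(inherits(config, "te_sim_config"))
  if (nrow(config$orfs) > 0 && any(config$orfs$end - config$orfs$start + 1 < 9)) {
    stop("config error: ORF too short for start + internal + stop codon",
         call. = FALSE)
  }
  withr::with_seed(config$seed, {
    gc <- config$gc_fraction
    s <- sample(c("A", "C", "G", "T"), config$ancestral_length,
                replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    for (k in seq_len(nrow(config$orfs))) {
      a <- config$orfs$start[k]; b <- config$orfs$end[k]
      s[a:(a + 2)] <- c("A", "T", "G")
      s[(b - 2):b] <- c("T", "A", "A")
      starts <- seq(a + 3, b - 5, by = 3)
      for (c0 in starts) {
        codon <- paste(s[c0:(c0 + 2)], collapse = "")
        if (codon %in% c("TAA", "TAG", "TGA")) {
          s[c0 + 2] <- if (codon == "TGA") "G" else "T"   # TAA/TAG -> TAT
        }
      }
    }
    list(ancestral = paste(s, collapse = ""), orfs = config$orfs)
  })
}

# --- alignment assembly from a planted-event plan ------------------------
# plan: tibble with kind ("substitution"/"deletion"/"insertion"),
# pos (substitution/deletion segment start; insertion left flank, 0 ok),
# len, bases (derived/inserted; NA for deletions), carriers (list of
# copy_id character vectors)
assemble_alignment <- function(ancestral, plan, copy_meta,
                               reference_id = NULL) {
  s <- strsplit(ancestral, "", fixed = TRUE)[[1]]
  n <- length(s)
  n_copies <- nrow(copy_meta)
  base_chars <- matrix(rep(s, each = n_copies), nrow = n_copies)
  rownames(base_chars) <- copy_meta$copy_id

  ins <- plan[plan$kind == "insertion", , drop = FALSE]
  ins <- ins[order(ins$pos), , drop = FALSE]
  other <- plan[plan$kind != "insertion", , drop = FALSE]

  for (i in seq_len(nrow(other))) {
    p <- other$pos[i]; L <- other$len[i]
    rows <- match(other$carriers[[i]], copy_meta$copy_id)
    if (other$kind[i] == "deletion") {
      base_chars[rows, p:(p + L - 1)] <- "-"
    } else {
      der <- strsplit(other$bases[i], "", fixed = TRUE)[[1]]
      base_chars[rows, p:(p + L - 1)] <- matrix(rep(der, each = length(rows)),
                                                nrow = length(rows))
    }
  }

  ins_len <- if (nrow(ins) > 0) ins$len else integer(0)
  total_cols <- n + sum(ins_len)
  M <- matrix("-", n_copies, total_cols)
  # ancestral column p lands at p + (inserted bases at flanks < p)
  offsets <- if (nrow(ins) > 0) {
    vapply(seq_len(n), function(p) sum(ins_len[ins$pos < p]), numeric(1))
  } else rep(0, n)
  anc_cols <- seq_len(n) + offsets
  M[, anc_cols] <- base_chars
  if (nrow(ins) > 0) {
    before <- c(0, cumsum(ins_len))[seq_len(nrow(ins))]
    for (i in seq_len(nrow(ins))) {
      cols <- ins$pos[i] + before[i] + seq_len(ins$len[i])
      rows <- match(ins$carriers[[i]], copy_meta$copy_id)
      M[rows, cols] <- matrix(
        rep(strsplit(ins$bases[i], "", fixed = TRUE)[[1]],
            each = length(rows)),
        nrow = length(rows))
    }
  }
  copies <- tibble::tibble(
    copy_id = copy_meta$copy_id,
    population = copy_meta$population,
    group = if ("group" %in% names(copy_meta)) copy_meta$group else NA,
    residues = apply(M, 1, paste, collapse = "")
  )
  te_alignment(copies, reference_id = reference_id)
}

# canonical truth rows (caller schema) from a plan
plan_to_truth <- function(plan, ancestral) {
  s <- strsplit(ancestral, "", fixed = TRUE)[[1]]
  if (nrow(plan) == 0) {
    out <- empty_events()
    out$copy_id <- NULL
    out$n_carriers <- integer()
    out$copy_ids <- character()
    return(out)
  }
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    kind <- plan$kind[i]; p <- plan$pos[i]; L <- plan$len[i]
    carriers <- sort(plan$carriers[[i]])
    if (kind == "substitution") {
      tibble::tibble(event_kind = kind, interval_start = p,
                     interval_end = p + L - 1L,
                     anc_alleles = paste(s[p:(p + L - 1)], collapse = ""),
                     der_alleles = plan$bases[i], length = L,
                     copy_ids = paste(carriers, collapse = ","),
                     n_carriers = length(carriers))
    } else if (kind == "deletion") {
      tibble::tibble(event_kind = kind, interval_start = p - 1L,
                     interval_end = p + L,
                     anc_alleles = paste(s[p:(p + L - 1)], collapse = ""),
                     der_alleles = "", length = L,
                     copy_ids = paste(carriers, collapse = ","),
                     n_carriers = length(carriers))
    } else {
      tibble::tibble(event_kind = kind, interval_start = p,
                     interval_end = p + 1L, anc_alleles = "",
                     der_alleles = plan$bases[i], length = L,
                     copy_ids = paste(carriers, collapse = ","),
                     n_carriers = length(carriers))
    }
  })
  dplyr::bind_rows(rows) |>
    tidyr::separate_longer_delim("copy_ids", delim = ",") |>
    dplyr::group_by(.data$event_kind, .data$interval_start,
                    .data$interval_end, .data$anc_alleles,
                    .data$der_alleles) |>
    dplyr::summarise(length = .data$length[1],
                     n_carriers = dplyr::n_distinct(.data$copy_ids),
                     copy_ids = paste(sort(unique(.data$copy_ids)),
                                      collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$interval_start, .data$event_kind,
                   .data$der_alleles)
}

#' Simulate a TE family alignment with a planted-event ledger
#'
#' Draws, per copy, single-base substitution events per pattern (Poisson
#' with the configured means, placed uniformly on ancestral sites carrying
#' the pattern's source base), rare adjacent multi-base substitutions, and
#' rare indels; emits the gapped family alignment (each insertion event
#' opens its own column block) together with the exact list of planted
#' events in the caller's schema. Within a copy events never overlap, and
#' the per-column carrier count is capped so every planted event stays
#' below the minor-allele threshold when there are at least
#' `ceiling(1/minor)` copies.
#'
#' @param config A [simulation_config()].
#' @param minor_cap Maximum derived-carrier fraction per column (default
#'   0.15, the caller's minor threshold).
#' @return List: `alignment` (a [te_alignment()]), `truth` (planted events
#'   tibble), `ancestral`, `orfs`, `config`.
#' @export
simulate_family <- function(config, minor_cap = 0.15) {
  stopifnot(inherits(config, "te_sim_config"))
  anc <- simulate_ancestral(config)
  s <- strsplit(anc$ancestral, "", fixed = TRUE)[[1]]
  n <- length(s)
  n_copies <- config$populations * config$copies_per_population
  copy_meta <- tibble::tibble(
    copy_id = sprintf("pop%02d_c%02d",
                      rep(seq_len(config$populations),
                          each = config$copies_per_population),
                      rep(seq_len(config$copies_per_population),
                          config$populations)),
    population = sprintf("pop%02d",
                         rep(seq_len(config$populations),
                             each = config$copies_per_population))
  )
  site_budget <- max(1L, floor(minor_cap * n_copies))
  sites_by_base <- lapply(c(A = "A", C = "C", G = "G", T = "T"),
                          function(b) which(s == b))

  plan <- withr::with_seed(config$seed + 1L, {
    used_by_copy <- vector("list", n_copies)      # occupied ancestral sites
    carriers_at <- integer(n)                     # derived carriers per site
    ins_flanks_by_copy <- vector("list", n_copies)
    rows <- list()

    reserve <- function(ci, sites) {
      used_by_copy[[ci]] <<- c(used_by_copy[[ci]], sites)
      carriers_at[sites] <<- carriers_at[sites] + 1L
    }
    # events in one copy keep a 1-base margin so independently planted
    # events never touch: adjacent substitutions (or gap runs) in the same
    # copy are indistinguishable from one longer event after run merging
    free_for <- function(ci, sites) {
      margin <- unique(pmin(pmax(c(sites - 1L, sites, sites + 1L), 1L), n))
      !any(margin %in% used_by_copy[[ci]]) &&
        all(carriers_at[sites] < site_budget)
    }

    for (ci in seq_len(n_copies)) {
      cid <- copy_meta$copy_id[ci]
      ## single-base substitutions per pattern
      for (pat in substitution_patterns()) {
        k <- stats::rpois(1, config$pattern_rates[[pat]])
        if (k == 0) next
        src <- substr(pat, 1, 1); der <- substr(pat, 3, 3)
        for (q in seq_len(k)) {
          pool <- sites_by_base[[src]]
          pool <- pool[!(pool %in% used_by_copy[[ci]] |
                           (pool - 1L) %in% used_by_copy[[ci]] |
                           (pool + 1L) %in% used_by_copy[[ci]])]
          pool <- pool[carriers_at[pool] < site_budget]
          if (length(pool) == 0) break
          p <- if (length(pool) == 1) pool else sample(pool, 1)
          rows[[length(rows) + 1]] <- tibble::tibble(
            kind = "substitution", pos = p, len = 1L, bases = der,
            carriers = list(cid))
          reserve(ci, p)
        }
      }
      ## multi-base substitutions
      k <- stats::rpois(1, config$multi_base_rate)
      for (q in seq_len(k)) {
        L <- sample(config$multi_base_lengths, 1,
                    prob = config$multi_base_length_probs)
        for (try in 1:50) {
          p <- sample.int(n - L + 1L, 1)
          sites <- p:(p + L - 1L)
          if (!free_for(ci, sites)) next
          der <- vapply(sites, function(j)
            sample(setdiff(c("A", "C", "G", "T"), s[j]), 1), character(1))
          rows[[length(rows) + 1]] <- tibble::tibble(
            kind = "substitution", pos = p, len = L,
            bases = paste(der, collapse = ""), carriers = list(cid))
          reserve(ci, sites)
          break
        }
      }
      ## indels
      k <- stats::rpois(1, config$indel_rate)
      for (q in seq_len(k)) {
        L <- sample_indel_length(config$indel_length_mix)
        if (stats::runif(1) < config$deletion_prob) {
          if (L >= n) next
          for (try in 1:50) {
            p <- sample.int(n - L + 1L, 1)
            sites <- p:(p + L - 1L)
            if (!free_for(ci, sites)) next
            rows[[length(rows) + 1]] <- tibble::tibble(
              kind = "deletion", pos = p, len = L, bases = NA_character_,
              carriers = list(cid))
            reserve(ci, sites)
            break
          }
        } else {
          for (try in 1:50) {
            f <- sample.int(n + 1L, 1) - 1L     # flank 0..n
            if (f %in% ins_flanks_by_copy[[ci]]) next
            ins_flanks_by_copy[[ci]] <- c(ins_flanks_by_copy[[ci]], f)
            gcf <- config$gc_fraction
            bases <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                                  prob = c((1 - gcf) / 2, gcf / 2, gcf / 2,
                                           (1 - gcf) / 2)), collapse = "")
            rows[[length(rows) + 1]] <- tibble::tibble(
              kind = "insertion", pos = f, len = L, bases = bases,
              carriers = list(cid))
            break
          }
        }
      }
    }
    if (length(rows) == 0) {
      tibble::tibble(kind = character(), pos = integer(), len = integer(),
                     bases = character(), carriers = list())
    } else {
      dplyr::bind_rows(rows)
    }
  })

  aln <- assemble_alignment(anc$ancestral, plan, copy_meta)
  list(alignment = aln,
       truth = plan_to_truth(plan, anc$ancestral),
       ancestral = anc$ancestral, orfs = anc$orfs, config = config)
}

# length mixture: 1 bp / short geometric 2-30 / long uniform 30-300
sample_indel_length <- function(mix) {
  u <- sample.int(3, 1, prob = mix)
  if (u == 1) 1L
  else if (u == 2) min(30L, 1L + stats::rgeom(1, 0.35) + 1L)
  else sample(30:300, 1)
}

#' Build a deterministic fixture alignment from planted events
#'
#' Places a stated list of mutation events on an ancestral sequence, each
#' in its stated carrier copies and nowhere else, so printed event
#' catalogs can be reconstructed exactly. Carriers may be given as copy
#' ids or as counts (copies are then assigned automatically, one set per
#' event, avoiding per-copy overlap).
#'
#' @param ancestral Ungapped ancestral sequence.
#' @param planted Tibble with `event_kind`, `position` (substitution or
#'   deletion segment start; insertion left flank), `bases` (derived or
#'   inserted; `NA` for deletions), `length` (deletions; inferred from
#'   `bases` otherwise), and optionally `carriers` (counts, default 1) or
#'   `copy_ids`.
#' @param n_copies Total copies in the fixture alignment.
#' @param populations Number of populations to spread copies over.
#' @param minor_cap Maximum carrier fraction allowed per event.
#' @return List: `alignment`, `truth`.
#' @export
build_fixture <- function(ancestral, planted, n_copies, populations = 1,
                          minor_cap = 0.15) {
  s <- strsplit(toupper(ancestral), "", fixed = TRUE)[[1]]
  n <- length(s)
  planted <- tibble::as_tibble(planted)
  stopifnot(all(c("event_kind", "position") %in% names(planted)))
  if (!"bases" %in% names(planted)) planted$bases <- NA_character_
  if (!"length" %in% names(planted)) planted$length <- NA_integer_
  if (!"carriers" %in% names(planted)) planted$carriers <- 1L
  len <- ifelse(is.na(planted$length), nchar(planted$bases), planted$length)
  if (any(is.na(len) | len < 1)) {
    stop("fixture error: events need bases or length", call. = FALSE)
  }
  kinds <- planted$event_kind
  stopifnot(all(kinds %in% c("substitution", "insertion", "deletion")))
  if (any(kinds != "insertion" &
          (planted$position < 1 | planted$position + len - 1 > n)) ||
      any(kinds == "insertion" &
          (planted$position < 0 | planted$position > n))) {
    stop("fixture error: event outside the ancestral sequence", call. = FALSE)
  }
  sub <- which(kinds == "substitution")
  for (i in sub) {
    seg <- s[planted$position[i]:(planted$position[i] + len[i] - 1)]
    der <- strsplit(planted$bases[i], "", fixed = TRUE)[[1]]
    if (any(seg == der)) {
      stop("fixture error: substitution equal to ancestral base at some ",
           "position (event ", i, ")", call. = FALSE)
    }
  }
  n_carry <- if (is.numeric(planted$carriers)) planted$carriers
             else vapply(planted$carriers, length, 1L)
  if (any(n_carry / n_copies > minor_cap)) {
    stop("fixture error: carrier fraction above the minor threshold",
         call. = FALSE)
  }

  copy_meta <- tibble::tibble(
    copy_id = sprintf("copy%03d", seq_len(n_copies)),
    population = sprintf("pop%02d",
                         rep_len(seq_len(populations), n_copies))
  )
  # assign carriers: given ids, or distinct copies per event round-robin,
  # checking per-copy overlap of affected ancestral sites / insertion flanks
  used_sites <- lapply(seq_len(n_copies), function(i) integer(0))
  used_flanks <- lapply(seq_len(n_copies), function(i) integer(0))
  carriers <- vector("list", nrow(planted))
  nxt <- 2L %% n_copies  # keep copy001 pristine when possible
  if (nxt == 0L) nxt <- 1L
  for (i in seq_len(nrow(planted))) {
    sites <- if (kinds[i] == "insertion") integer(0)
             else planted$position[i]:(planted$position[i] + len[i] - 1L)
    flank <- if (kinds[i] == "insertion") planted$position[i] else NA
    if (is.numeric(planted$carriers)) {
      chosen <- character(0)
      tries <- 0
      while (length(chosen) < n_carry[i] && tries < 2 * n_copies) {
        ci <- nxt
        nxt <- if (nxt == n_copies) 2L else nxt + 1L
        if (n_copies == 1L) ci <- 1L
        tries <- tries + 1
        cid <- copy_meta$copy_id[ci]
        if (cid %in% chosen) next
        if (length(sites) > 0 && any(sites %in% used_sites[[ci]])) next
        if (!is.na(flank) && flank %in% used_flanks[[ci]]) next
        chosen <- c(chosen, cid)
        used_sites[[ci]] <- c(used_sites[[ci]], sites)
        if (!is.na(flank)) used_flanks[[ci]] <- c(used_flanks[[ci]], flank)
      }
      if (length(chosen) < n_carry[i]) {
        stop("fixture error: cannot place event ", i,
             " without per-copy overlap", call. = FALSE)
      }
      carriers[[i]] <- chosen
    } else {
      ids <- planted$carriers[[i]]
      rows <- match(ids, copy_meta$copy_id)
      if (anyNA(rows)) stop("fixture error: unknown carrier id", call. = FALSE)
      for (ci in rows) {
        if (length(sites) > 0 && any(sites %in% used_sites[[ci]])) {
          stop("fixture error: overlapping events in copy ",
               copy_meta$copy_id[ci], call. = FALSE)
        }
        used_sites[[ci]] <- c(used_sites[[ci]], sites)
        if (!is.na(flank)) {
          if (flank %in% used_flanks[[ci]]) {
            stop("fixture error: two insertions at one flank in copy ",
                 copy_meta$copy_id[ci], call. = FALSE)
          }
          used_flanks[[ci]] <- c(used_flanks[[ci]], flank)
        }
      }
      carriers[[i]] <- ids
    }
  }
  plan <- tibble::tibble(kind = kinds, pos = as.integer(planted$position),
                         len = as.integer(len), bases = planted$bases,
                         carriers = carriers)
  aln <- assemble_alignment(paste(s, collapse = ""), plan, copy_meta,
                            reference_id = copy_meta$copy_id[1])
  list(alignment = aln, truth = plan_to_truth(plan, paste(s, collapse = "")))
}
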