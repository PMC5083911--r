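aln_with_rows <- function(...) {
  rows <- c(...)
  te_alignment(tibble::tibble(
    copy_id = sprintf("c%02d", seq_along(rows)),
    population = "P1", residues = rows))
}

test_that("substitution calls record the mutation direction per copy", {
  aln <- aln_with_rows(rep("AAAA", 18), "AGAA", "AAAA")
  prof <- call_ancestral_profile(aln)
  calls <- call_substitutions(aln, prof)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$anc, "A")
  expect_equal(calls$der, "G")
  expect_equal(calls$position, 2)
  expect_equal(calls$copy_id, "c19")

  # copy identical to the ancestor contributes no calls
  expect_false("c01" %in% calls$copy_id)
  # ambiguous columns yield nothing
  aln2 <- aln_with_rows(rep("A", 10), rep("G", 10))
  expect_equal(nrow(call_substitutions(aln2, call_ancestral_profile(aln2))), 0)
  # dimension mismatch is refused
  expect_error(call_substitutions(aln2, prof), "consistency")
})

test_that("adjacent calls merge into multi-base events, non-adjacent stay
           single", {
  calls <- tibble::tibble(
    copy_id = c("x", "x", "x"), column = c(100, 101, 103),
    position = c(100L, 101L, 103L), anc = c("A", "G", "T"),
    der = c("G", "A", "C"))
  ev <- merge_adjacent_calls(calls)
  expect_equal(nrow(ev), 2)
  two <- ev[ev$length == 2, ]
  expect_equal(two$anc_alleles, "AG")
  expect_equal(two$der_alleles, "GA")
  expect_equal(c(two$interval_start, two$interval_end), c(100, 101))
  expect_equal(ev$length[ev$interval_start == 103], 1)

  # run-length-encoding oracle on random planted runs
  withr::with_seed(91, {
    for (r in 1:25) {
      pos <- sort(sample(1:60, 12))
      calls <- tibble::tibble(copy_id = "x", column = pos, position = pos,
                              anc = "A", der = "G")
      ev <- merge_adjacent_calls(calls)
      runs <- rle(diff(pos) == 1)
      expected_events <- sum(diff(pos) != 1) + 1
      expect_equal(nrow(ev), expected_events)
      expect_equal(sum(ev$length), length(pos))
    }
  })
})

test_that("indel runs become single events with exclusive-flank intervals", {
  anc <- strsplit(paste(rep("ACGT", 10), collapse = ""), "")[[1]]  # 40 bp
  gapped <- anc; gapped[11:20] <- "-"                              # 10-nt del
  rows <- c(replicate(19, paste(anc, collapse = "")),
            paste(gapped, collapse = ""))
  aln <- aln_with_rows(rows)
  ev <- call_indels(aln, call_ancestral_profile(aln))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_kind, "deletion")
  expect_equal(ev$length, 10)
  expect_equal(c(ev$interval_start, ev$interval_end), c(10, 21))
  expect_equal(ev$anc_alleles, paste(anc[11:20], collapse = ""))
  # the printed dialect preserves length = end - start - 1
  expect_equal(ev$interval_end - ev$interval_start - 1L, ev$length)

  # 7 bases carried in insertion columns by one copy -> one insertion
  base <- paste(anc, collapse = "")
  with_ins <- paste0(substr(base, 1, 20), "AGGTATA", substr(base, 21, 40))
  rows <- c(replicate(19, paste0(substr(base, 1, 20), "-------",
                                 substr(base, 21, 40))), with_ins)
  aln <- aln_with_rows(rows)
  ev <- call_indels(aln, call_ancestral_profile(aln))
  expect_equal(ev$event_kind, "insertion")
  expect_equal(ev$der_alleles, "AGGTATA")
  expect_equal(c(ev$interval_start, ev$interval_end), c(20, 21))

  # gap-free alignment: no indels
  aln <- aln_with_rows(replicate(5, base))
  expect_equal(nrow(call_indels(aln, call_ancestral_profile(aln))), 0)
})

test_that("indel_interval renders the start_end dialect", {
  iv <- indel_interval("deletion", position = 1416, length = 1)
  expect_equal(iv$interval, "1415_1417")
  iv <- indel_interval("deletion", position = 751, length = 10)
  expect_equal(iv$interval, "750_761")
  iv <- indel_interval("insertion", position = 1532)
  expect_equal(iv$interval, "1532_1533")
})

test_that("placement ambiguity in repeated context is quantified", {
  # one T deleted from the TTT run of ACTTTG: three equivalent placements
  for (p in 3:5) {
    r <- indel_placement_range("ACTTTG", p, 1, event_kind = "deletion")
    expect_equal(c(r$min_start, r$max_start, r$n_placements), c(3, 5, 3))
  }
  # unique context: a single placement
  r <- indel_placement_range("ACGTAC", 3, 1, event_kind = "deletion")
  expect_equal(r$n_placements, 1)
  # dinucleotide slide: deleting AC from ACACG can slide by one
  r <- indel_placement_range("ACACG", 1, 2, event_kind = "deletion")
  expect_equal(c(r$min_start, r$max_start), c(1, 3))
  # insertion of A next to an A run slides across it
  r <- indel_placement_range("CAAG", 3, bases = "A", event_kind = "insertion")
  expect_equal(c(r$min_start, r$max_start), c(1, 3))
  # equivalence oracle: every placement in the range yields the same
  # derived sequence
  withr::with_seed(13, {
    for (rep in 1:20) {
      s <- paste(sample(c("A", "T"), 12, TRUE), collapse = "")
      L <- sample(1:2, 1)
      p <- sample(seq_len(nchar(s) - L), 1)
      rng <- indel_placement_range(s, p, L, event_kind = "deletion")
      del_at <- function(q) paste0(substr(s, 1, q - 1),
                                   substr(s, q + L, nchar(s)))
      derived <- vapply(rng$min_start:rng$max_start, del_at, character(1))
      expect_equal(length(unique(derived)), 1)
      if (rng$min_start > 1) {
        expect_false(del_at(rng$min_start - 1) == del_at(p))
      }
    }
  })
})

test_that("recurrent events deduplicate on (kind, interval, alleles) with
           carrier union; distinct derived alleles stay distinct", {
  ev <- tibble::tibble(
    event_kind = "substitution",
    copy_id = c("a", "b", "c", "d"),
    interval_start = 500L, interval_end = 500L,
    anc_alleles = "A", der_alleles = c("G", "G", "G", "C"),
    length = 1L)
  dd <- deduplicate_events(ev)
  expect_equal(nrow(dd), 2)
  g <- dd[dd$der_alleles == "G", ]
  expect_equal(g$n_carriers, 3)
  expect_equal(g$copy_ids, "a,b,c")
  expect_equal(dd$n_carriers[dd$der_alleles == "C"], 1)
  # idempotence
  expect_equal(deduplicate_events(dd), dd)
})

test_that("full caller equals the brute-force oracle on random small
           alignments", {
  withr::with_seed(2024, {
    n_inst <- 400
    for (r in seq_len(n_inst)) {
      aln <- random_alignment(n_copies = sample(4:10, 1),
                              n_anc = sample(20:50, 1))
      got <- call_mutation_events(aln)
      want <- oracle_call(aln)
      expect_identical(event_key(got), event_key(want))
    }
  })
})

test_that("every (copy, column) pair is explained exactly once", {
  sim <- simulate_family(simulation_config(ancestral_length = 500,
                                           populations = 10,
                                           copies_per_population = 2,
                                           seed = 3))
  aln <- sim$alignment
  prof <- call_ancestral_profile(aln)
  calls <- call_substitutions(aln, prof)
  indels <- call_indels(aln, prof)
  m <- tespectrum:::aln_matrix(aln)
  explained <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  # matches / missing / ambiguous columns
  for (j in seq_len(ncol(m))) {
    anc <- prof$ancestral_state[j]
    if (is.na(anc)) { explained[, j] <- explained[, j] + 1L; next }
    explained[m[, j] == anc, j] <- explained[m[, j] == anc, j] + 1L
    explained[m[, j] == "N", j] <- explained[m[, j] == "N", j] + 1L
  }
  for (i in seq_len(nrow(calls))) {
    explained[calls$copy_id[i], calls$column[i]] <-
      explained[calls$copy_id[i], calls$column[i]] + 1L
  }
  # indel runs: map ancestral positions / insertion blocks back to columns
  col_of_pos <- which(!is.na(prof$ancestral_position))
  for (i in seq_len(nrow(indels))) {
    cid <- indels$copy_id[i]
    if (indels$event_kind[i] == "deletion") {
      cols <- col_of_pos[(indels$interval_start[i] + 1):(indels$interval_end[i] - 1)]
    } else {
      flank <- indels$interval_start[i]
      after <- if (flank == 0) 0L else col_of_pos[flank]
      block <- which(seq_len(ncol(m)) > after & is.na(prof$ancestral_position))
      block <- block[block <= (if (flank < max(prof$ancestral_position, na.rm = TRUE))
        col_of_pos[flank + 1] else ncol(m) + 1)]
      cols <- block[m[cid, block] %in% c("A", "C", "G", "T")]
    }
    explained[cid, cols] <- explained[cid, cols] + 1L
  }
  expect_true(all(explained == 1L))
})

test_that("single-base substitution events split exactly into transitions
           plus transversions", {
  sim <- simulate_family(simulation_config(ancestral_length = 800,
                                           populations = 21,
                                           copies_per_population = 1,
                                           seed = 12))
  ev <- annotate_events(call_mutation_events(sim$alignment),
                        ancestral = sim$ancestral, orfs = sim$orfs)
  sb <- ev[ev$event_kind == "substitution" & ev$length == 1, ]
  expect_gt(nrow(sb), 0)
  expect_equal(sum(sb$ts_tv == "transition") +
                 sum(sb$ts_tv == "transversion"), nrow(sb))
})
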