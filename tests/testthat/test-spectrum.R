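test_that("group assignment balances populations and is seed-reproducible", {
  copies <- tibble::tibble(
    copy_id = sprintf("c%03d", 1:84),
    population = rep(sprintf("p%02d", 1:21), each = 4))
  g <- assign_groups(copies, copies_per_population = 1, n_groups = 4,
                     seed = 10)
  tab <- table(g$group)
  expect_equal(as.vector(tab), rep(21L, 4))
  per_pop <- table(g$group, g$population)
  expect_true(all(per_pop == 1))

  copies2 <- tibble::tibble(
    copy_id = sprintf("t%03d", 1:140),
    population = rep(sprintf("p%02d", 1:7), each = 20))
  g2 <- assign_groups(copies2, copies_per_population = 5, n_groups = 4,
                      seed = 10)
  expect_equal(as.vector(table(g2$group)), rep(35L, 4))
  expect_true(all(table(g2$group, g2$population) == 5))

  expect_identical(assign_groups(copies, 1, 4, seed = 99)$group,
                   assign_groups(copies, 1, 4, seed = 99)$group)
  expect_error(assign_groups(copies, 2, 4, seed = 1), "sampling error")
})

test_that("spectrum summary: means, SEs and the partition identity", {
  mk_events <- function(counts_ts, counts_tv) {
    purrr::imap(counts_ts, function(k, g) {
      ts <- if (k > 0) tibble::tibble(
        event_kind = "substitution", interval_start = seq_len(k),
        interval_end = seq_len(k), anc_alleles = "A", der_alleles = "G",
        length = 1L, copy_ids = "x", n_carriers = 1L,
        region = "outside_orf", orf_name = NA, pattern = "A>G",
        ts_tv = "transition", codon_position = NA_integer_,
        effect = NA_character_, frame_effect = NA_character_, group = g)
      kv <- counts_tv[[g]]
      tv <- if (kv > 0) tibble::tibble(
        event_kind = "substitution", interval_start = 1000 + seq_len(kv),
        interval_end = 1000 + seq_len(kv), anc_alleles = "A",
        der_alleles = "T", length = 1L, copy_ids = "x", n_carriers = 1L,
        region = "outside_orf", orf_name = NA, pattern = "A>T",
        ts_tv = "transversion", codon_position = NA_integer_,
        effect = NA_character_, frame_effect = NA_character_, group = g)
      dplyr::bind_rows(ts, tv)
    }) |> purrr::list_rbind()
  }
  ev <- mk_events(c(G1 = 44, G2 = 45, G3 = 44, G4 = 45),
                  c(G1 = 18, G2 = 18, G3 = 19, G4 = 17))
  sp <- summarize_spectrum(ev)
  expect_equal(sp$mean[sp$category == "transition"], 44.5)
  expect_equal(sp$se[sp$category == "transition"],
               stats::sd(c(44, 45, 44, 45)) / 2)
  # identical groups -> SE 0
  ev0 <- mk_events(c(G1 = 10, G2 = 10), c(G1 = 4, G2 = 4))
  expect_equal(summarize_spectrum(ev0)$se, rep(0, nrow(sp)))
  # totals = transitions + transversions in every group and in the means
  groups <- attr(sp, "groups")
  for (g in groups) {
    expect_equal(spectrum_counts(sp, "total")[[g]],
                 spectrum_counts(sp, "transition")[[g]] +
                   spectrum_counts(sp, "transversion")[[g]])
  }
  expect_equal(sp$mean[sp$category == "total"],
               sp$mean[sp$category == "transition"] +
                 sp$mean[sp$category == "transversion"])
  # pooled pairs stay consistent with pattern counts
  expect_equal(sp$mean[sp$category == "A:T>G:C"],
               sp$mean[sp$category == "A>G"] + sp$mean[sp$category == "T>C"])
})

test_that("pooled t-test matches the closed form and its conventions", {
  st <- t_test_independent(c(1, 2, 3), c(2, 3, 4))
  expect_equal(st$statistic, -1.2247, tolerance = 1e-3)
  expect_equal(st$df, 4)
  st0 <- t_test_independent(c(2, 2), c(2, 2))
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p_value, 1)
  # closed-form pooled t on random samples
  withr::with_seed(41, {
    for (r in 1:10) {
      a <- stats::rnorm(5); b <- stats::rnorm(7, 1)
      st <- t_test_independent(a, b)
      sp2 <- ((5 - 1) * stats::var(a) + (7 - 1) * stats::var(b)) / 10
      tman <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 7))
      expect_equal(st$statistic, tman, tolerance = 1e-12)
      expect_equal(st$p_value, 2 * stats::pt(-abs(tman), 10),
                   tolerance = 1e-12)
    }
  })
  expect_equal(glance(st0)$p_value, 1)
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  withr::with_seed(42, {
    for (r in 1:10) {
      a <- stats::rnorm(4, 10, 2); b <- stats::rnorm(4, 12, 2)
      tt <- t_test_independent(a, b)
      av <- anova_tukey(list(a = a, b = b))
      expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-9)
      expect_equal(av$p_value, tt$p_value, tolerance = 1e-9)
      # with two groups the single Tukey pair reduces to the ANOVA p
      # (ptukey vs pf agree to their numerical accuracy)
      expect_equal(av$pairwise$p_value, av$p_value, tolerance = 1e-4)
    }
  })
})

test_that("one-way ANOVA F and Tukey p agree with the closed form and an
           independent reference implementation", {
  samples <- list(g1 = c(44, 45, 44, 45), g2 = c(18, 18, 19, 17),
                  g3 = c(30, 29, 31, 33), g4 = c(28, 31, 30, 29))
  st <- anova_tukey(samples)
  # closed-form one-way F
  all_v <- unlist(samples)
  gm <- mean(all_v)
  ssb <- sum(vapply(samples, function(s) length(s) * (mean(s) - gm)^2, 1))
  ssw <- sum(vapply(samples, function(s) sum((s - mean(s))^2), 1))
  fman <- (ssb / 3) / (ssw / 12)
  expect_equal(st$statistic, fman, tolerance = 1e-9)
  expect_equal(st$p_value, stats::pf(fman, 3, 12, lower.tail = FALSE),
               tolerance = 1e-12)
  # Tukey pairwise p from the studentized range, computed directly
  mse <- ssw / 12
  for (i in seq_len(nrow(st$pairwise))) {
    gs <- strsplit(st$pairwise$pair[i], "-")[[1]]
    q <- abs(mean(samples[[gs[1]]]) - mean(samples[[gs[2]]])) /
      sqrt(mse / 4)
    expect_equal(st$pairwise$p_value[i],
                 stats::ptukey(q, 4, 12, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  # degenerate: identical observations
  flat <- anova_tukey(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_true(all(flat$letters$alpha_0.05 == "a"))
})

test_that("compact letter display: sharing a letter iff non-significant", {
  m <- matrix(FALSE, 3, 3, dimnames = list(1:3, 1:3))
  m[1, 3] <- m[3, 1] <- TRUE
  cld <- compact_letter_display(m)
  expect_equal(unname(cld), c("a", "ab", "b"))
  expect_true(all(compact_letter_display(
    matrix(FALSE, 3, 3, dimnames = list(1:3, 1:3))) == "a"))

  share <- function(x, y) length(intersect(strsplit(x, "")[[1]],
                                           strsplit(y, "")[[1]])) > 0
  withr::with_seed(7, {
    for (r in 1:40) {
      k <- 5
      m <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        m[i, j] <- m[j, i] <- stats::runif(1) < 0.4
      }
      cld <- compact_letter_display(m)
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        expect_equal(share(cld[i], cld[j]), !m[i, j])
      }
    }
  })
})

test_that("letters at alpha 0.01 are never finer than at 0.05, and agree
           with multcomp's letter assignment", {
  withr::with_seed(19, {
    for (r in 1:10) {
      samples <- lapply(1:4, function(i) stats::rnorm(4, i * stats::runif(1, 0, 3)))
      names(samples) <- paste0("g", 1:4)
      st <- anova_tukey(samples)
      l05 <- st$letters$alpha_0.05
      l01 <- st$letters$alpha_0.01
      share <- function(l, x, y) length(intersect(strsplit(l[x], "")[[1]],
                                                  strsplit(l[y], "")[[1]])) > 0
      for (i in 1:3) for (j in (i + 1):4) {
        gi <- paste0("g", i); gj <- paste0("g", j)
        if (share(l05, gi, gj)) expect_true(share(l01, gi, gj))
        # cross-check the sharing relation against multcomp::cld
        sig <- st$pairwise$p_value[st$pairwise$pair %in%
                                     c(paste(gj, gi, sep = "-"),
                                       paste(gi, gj, sep = "-"))] <= 0.05
        expect_equal(share(l05, gi, gj), !sig)
      }
      df <- data.frame(value = unlist(samples),
                       grp = factor(rep(names(samples), each = 4)))
      fit <- stats::aov(value ~ grp, data = df)
      mc <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(grp = "Tukey")),
                          level = 0.05)$mcletters$Letters
      for (i in 1:3) for (j in (i + 1):4) {
        gi <- paste0("g", i); gj <- paste0("g", j)
        expect_equal(share(l05, gi, gj), share(mc, gi, gj))
      }
    }
  })
})

test_that("a strong simulated GC bias is detected at the printed level", {
  # Monte-Carlo power check in a large-effect regime: the observed
  # pattern proportions (A:T>G:C about twice G:C>A:T) at twice the
  # per-copy event rate, so the bias is unambiguous in every group
  reject <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    sim <- simulate_family(simulation_config(
      pattern_rates = default_pattern_rates() * 2, seed = 1000 + r))
    grouped <- assign_groups(tibble::as_tibble(sim$alignment), 1, 4,
                             seed = r)
    sim$alignment$group <- grouped$group
    groups <- sort(unique(stats::na.omit(grouped$group)))
    ev <- purrr::map(groups, function(g) {
      sub <- subset_copies(sim$alignment,
                           sim$alignment$copy_id[!is.na(grouped$group) &
                                                   grouped$group == g])
      gp <- call_ancestral_profile(sub)
      e <- deduplicate_events(
        merge_adjacent_calls(call_substitutions(sub, gp), gp))
      e <- annotate_events(e, ancestral = sim$ancestral, orfs = sim$orfs)
      e$group <- g
      e
    }) |> purrr::list_rbind()
    sp <- summarize_spectrum(ev)
    st <- t_test_independent(spectrum_counts(sp, "A:T>G:C"),
                             spectrum_counts(sp, "G:C>A:T"))
    if (st$p_value <= 0.01) reject <- reject + 1
  }
  expect_gte(reject / n_rep, 0.95)
})

test_that("tidy and glance return broom-shaped tibbles", {
  st <- anova_tukey(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(1, 3, 2)))
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("pair", "p_value", "stars") %in% names(td)))
  gl <- glance(st)
  expect_equal(nrow(gl), 1)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
})
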