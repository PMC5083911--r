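#' Partition copies into analysis groups
#'
#' Reproduces the sampling scheme used for per-group spectra: from every
#' population, `copies_per_population * n_groups` copies are drawn without
#' replacement and dealt into `n_groups` disjoint groups, so each group
#' holds exactly `copies_per_population` copies from every population
#' (e.g. 21 populations x 1 copy = groups of 21; 7 populations x 5 copies
#' = groups of 35).
#'
#' @param copies A data frame with `copy_id` and `population` (e.g. a
#'   [te_alignment()]).
#' @param copies_per_population Copies drawn per population per group.
#' @param n_groups Number of groups.
#' @param seed Integer seed; the partition is reproducible under it.
#' @return The input with a `group` column (`"G1"`, ..., unsampled copies
#'   get `NA`).
#' @export
assign_groups <- function(copies, copies_per_population, n_groups,
                          seed = NULL) {
  stopifnot(is.data.frame(copies),
            all(c("copy_id", "population") %in% names(copies)))
  need <- copies_per_population * n_groups
  short <- copies |>
    dplyr::count(.data$population) |>
    dplyr::filter(.data$n < need)
  if (nrow(short) > 0) {
    stop("sampling error: population(s) with fewer than ", need,
         " copies: ", paste(short$population, collapse = ", "),
         call. = FALSE)
  }
  draw <- function() {
    assign_one <- function(ids) {
      picked <- sample(ids, need)
      g <- rep(paste0("G", seq_len(n_groups)), each = copies_per_population)
      stats::setNames(c(g, rep(NA_character_, length(ids) - need)),
                      c(picked, setdiff(ids, picked)))
    }
    labels <- do.call(c, unname(lapply(split(copies$copy_id,
                                             copies$population),
                                       assign_one)))
    unname(labels[copies$copy_id])
  }
  grp <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- copies
  out$group <- grp
  out
}

# the category layout of a spectrum summary, in report order
spectrum_categories <- function() {
  c("total", "transition", "transversion",
    substitution_patterns(),
    "A:T>G:C", "G:C>A:T", "A:T>T:A", "A:T>C:G", "G:C>T:A", "G:C>C:G",
    "pos1", "pos2", "pos3",
    "synonymous", "missense", "nonsense", "no_stop",
    "inside_orf", "outside_orf")
}

#' Summarize a single-base substitution spectrum across groups
#'
#' Counts unique single-base substitution events per group in every
#' category (total, transition/transversion, the 12 patterns and their 6
#' strand-pooled pairs, codon positions 1-3, the four protein-effect
#' classes, inside/outside ORF) and reports the cross-group mean and
#' standard error of the mean (sample SD / sqrt(number of groups)).
#'
#' @param events Annotated events (see [annotate_events()]) carrying a
#'   `group` column; events must already be deduplicated within group.
#' @return A `te_spectrum` tibble: `category`, `mean`, `se`, plus one
#'   count column per group; attribute `n_groups`.
#' @export
summarize_spectrum <- function(events) {
  stopifnot(is.data.frame(events), "group" %in% names(events))
  groups <- sort(unique(stats::na.omit(events$group)))
  if (length(groups) == 0) stop("input error: no groups", call. = FALSE)
  sb <- events[events$event_kind == "substitution" & events$length == 1L, ,
               drop = FALSE]
  count_cat <- function(g) {
    e <- sb[!is.na(sb$group) & sb$group == g, , drop = FALSE]
    pat <- table(factor(e$pattern, levels = substitution_patterns()))
    pooled <- pool_complementary(tibble::tibble(
      pattern = names(pat), count = as.numeric(pat)))
    c(
      total = nrow(e),
      transition = sum(e$ts_tv == "transition", na.rm = TRUE),
      transversion = sum(e$ts_tv == "transversion", na.rm = TRUE),
      as.numeric(pat) |> stats::setNames(names(pat)),
      stats::setNames(pooled$count, pooled$pair),
      pos1 = sum(e$codon_position == 1, na.rm = TRUE),
      pos2 = sum(e$codon_position == 2, na.rm = TRUE),
      pos3 = sum(e$codon_position == 3, na.rm = TRUE),
      synonymous = sum(e$effect == "synonymous", na.rm = TRUE),
      missense = sum(e$effect == "missense", na.rm = TRUE),
      nonsense = sum(e$effect == "nonsense", na.rm = TRUE),
      no_stop = sum(e$effect == "no_stop", na.rm = TRUE),
      inside_orf = sum(e$region == "inside_orf", na.rm = TRUE),
      outside_orf = sum(e$region == "outside_orf", na.rm = TRUE)
    )[spectrum_categories()]
  }
  counts <- vapply(groups, count_cat, numeric(length(spectrum_categories())))
  mean_v <- rowMeans(counts)
  se_v <- if (length(groups) > 1) {
    apply(counts, 1, stats::sd) / sqrt(length(groups))
  } else {
    rep(NA_real_, nrow(counts))
  }
  out <- tibble::tibble(category = spectrum_categories(),
                        mean = unname(mean_v), se = unname(se_v))
  for (g in groups) out[[g]] <- unname(counts[, g])
  structure(out,
            class = c("te_spectrum", class(tibble::tibble())),
            n_groups = length(groups),
            groups = groups)
}

#' Per-group counts of one spectrum category
#'
#' @param spectrum A `te_spectrum`.
#' @param category Category name (see `summarize_spectrum()`).
#' @return Named numeric vector of per-group counts.
#' @export
spectrum_counts <- function(spectrum, category) {
  stopifnot(inherits(spectrum, "te_spectrum"))
  row <- spectrum[spectrum$category == category, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown category: ", category, call. = FALSE)
  groups <- attr(spectrum, "groups")
  stats::setNames(as.numeric(unlist(row[1, groups])), groups)
}

significance_stars <- function(p) {
  dplyr::case_when(p <= 0.01 ~ "**", p <= 0.05 ~ "*", .default = "")
}

#' Independent-sample pooled t-test
#'
#' Two-sided Student t-test with pooled variance (the equal-variance
#' independent-sample test); Welch's correction is available via
#' `var_equal = FALSE`. When both samples are constant and equal,
#' `t = 0`, `p = 1` by convention. Significance stars: `*` at p <= 0.05,
#' `**` at p <= 0.01.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A `te_stat` object; see [tidy.te_stat()] and
#'   [glance.te_stat()].
#' @export
t_test_independent <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, p.value = 1,
                  df = length(a) + length(b) - 2)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0,
                  df = length(a) + length(b) - 2)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                df = unname(tt$parameter))
  }
  structure(list(
    test = if (var_equal) "pooled t-test" else "Welch t-test",
    statistic = res$statistic, p_value = res$p.value, df = res$df,
    stars = significance_stars(res$p.value),
    means = c(a = mean(a), b = mean(b)),
    pairwise = NULL, letters = NULL
  ), class = "te_stat")
}

#' One-way ANOVA with Tukey HSD and compact letter displays
#'
#' Fits a one-way ANOVA across the given samples, computes all pairwise
#' Tukey honestly-significant-difference p-values (studentized range), and
#' derives a compact letter display at each alpha level (groups sharing a
#' letter are not significantly different). If all observations are
#' identical, `F = 0`, `p = 1` and all pairs are non-significant.
#'
#' @param samples Named list of numeric vectors (>= 2 samples, each of
#'   size >= 2).
#' @param alpha Significance levels for the letter displays.
#' @return A `te_stat` object with `pairwise` (tibble of pair, diff,
#'   p_value) and `letters` (list of letter vectors per alpha).
#' @export
anova_tukey <- function(samples, alpha = c(0.05, 0.01)) {
  stopifnot(is.list(samples), length(samples) >= 2,
            all(vapply(samples, length, 1L) >= 2))
  if (is.null(names(samples))) {
    names(samples) <- paste0("g", seq_along(samples))
  }
  df <- tibble::tibble(
    value = unlist(samples, use.names = FALSE),
    grp = factor(rep(names(samples), vapply(samples, length, 1L)),
                 levels = names(samples))
  )
  pair_names <- utils::combn(names(samples), 2,
                             FUN = function(x) paste(x[2], x[1], sep = "-"))
  if (stats::var(df$value) == 0) {
    fstat <- 0; pval <- 1
    pw <- tibble::tibble(pair = pair_names, diff = 0, p_value = 1)
  } else {
    fit <- stats::aov(value ~ grp, data = df)
    an <- summary(fit)[[1]]
    fstat <- an[["F value"]][1]
    pval <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$grp
    pw <- tibble::tibble(pair = rownames(tk), diff = unname(tk[, "diff"]),
                         p_value = unname(tk[, "p adj"]))
  }
  letters <- lapply(alpha, function(a) {
    sig <- pairwise_signif_matrix(pw, names(samples), a)
    compact_letter_display(sig)
  })
  names(letters) <- paste0("alpha_", alpha)
  structure(list(
    test = "one-way ANOVA + Tukey HSD",
    statistic = fstat, p_value = pval,
    df = c(between = length(samples) - 1,
           within = nrow(df) - length(samples)),
    stars = significance_stars(pval),
    means = vapply(samples, mean, numeric(1)),
    pairwise = pw, letters = letters, alpha = alpha
  ), class = "te_stat")
}

# symmetric logical matrix: TRUE where the pair is significant at alpha
pairwise_signif_matrix <- function(pairwise, group_names, alpha) {
  m <- matrix(FALSE, length(group_names), length(group_names),
              dimnames = list(group_names, group_names))
  for (i in seq_len(nrow(pairwise))) {
    gs <- strsplit(pairwise$pair[i], "-", fixed = TRUE)[[1]]
    if (pairwise$p_value[i] <= alpha) {
      m[gs[1], gs[2]] <- TRUE
      m[gs[2], gs[1]] <- TRUE
    }
  }
  m
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb letter assignment: two groups share at least one
#' letter if and only if their pair is non-significant. Intransitive
#' significance patterns are representable because a group may carry
#' several letters.
#'
#' @param signif A symmetric logical matrix with group names; `TRUE`
#'   marks a significantly different pair.
#' @return Named character vector: letter string per group.
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(1:3, 1:3))
#' m[1, 3] <- m[3, 1] <- TRUE
#' compact_letter_display(m)  # "a", "ab", "b"
#' @export
compact_letter_display <- function(signif) {
  stopifnot(is.matrix(signif), nrow(signif) == ncol(signif),
            isTRUE(all(signif == t(signif))))
  groups <- rownames(signif)
  stopifnot(!is.null(groups))
  sets <- list(groups)                      # start: one letter for everyone
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !signif[i, j]) next
      gi <- groups[i]; gj <- groups[j]
      new_sets <- list()
      for (s in sets) {
        if (gi %in% s && gj %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets wholly contained in another
      keep <- rep(TRUE, length(new_sets))
      for (u in seq_along(new_sets)) {
        for (v in seq_along(new_sets)) {
          if (u != v && keep[u] &&
              all(new_sets[[u]] %in% new_sets[[v]]) &&
              (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v)) {
            keep[u] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  sets <- sets[vapply(sets, length, 1L) > 0]
  # order letters by the first group they contain
  first <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' @export
print.te_stat <- function(x, ...) {
  cat("<te_stat> ", x$test, ": statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 5), " ", x$stars, "\n", sep = "")
  if (!is.null(x$letters)) {
    for (nm in names(x$letters)) {
      cat("  ", nm, ": ",
          paste(names(x$letters[[nm]]), x$letters[[nm]], sep = "=",
                collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy a `te_stat`
#'
#' For ANOVA results, one row per Tukey pair; for t-tests, a single row.
#'
#' @param x A `te_stat`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.te_stat <- function(x, ...) {
  if (is.null(x$pairwise)) {
    tibble::tibble(test = x$test, statistic = x$statistic,
                   p_value = x$p_value, df = x$df, stars = x$stars)
  } else {
    dplyr::mutate(x$pairwise, stars = significance_stars(.data$p_value))
  }
}

#' Glance at a `te_stat`
#'
#' @param x A `te_stat`.
#' @param ... Unused.
#' @return One-row tibble with the headline statistic and p-value.
#' @export
glance.te_stat <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 p_value = x$p_value, stars = x$stars)
}

#' @export
tidy.te_spectrum <- function(x, ...) {
  groups <- attr(x, "groups")
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::all_of(groups),
                      names_to = "group", values_to = "count")
}

#' @export
glance.te_spectrum <- function(x, ...) {
  tibble::tibble(
    n_groups = attr(x, "n_groups"),
    total_mean = x$mean[x$category == "total"],
    transition_mean = x$mean[x$category == "transition"],
    transversion_mean = x$mean[x$category == "transversion"]
  )
}
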