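#' Run the full mutation-spectrum pipeline
#'
#' Orchestrates alignment loading (or simulation), group assignment,
#' two-scope mutation calling (per-group profiles for the single-base
#' spectrum; the pooled copy set for indels and multi-base substitutions,
#' which are too rare to resolve per group), annotation, the spectrum
#' summary and the headline statistics, and writes a TSV report bundle.
#'
#' The configuration is a list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{input}{`fasta`, `metadata`, optional `orfs` (TSV path),
#'     optional `reference_id` — or instead}
#'   \item{simulation}{arguments for [simulation_config()]}
#'   \item{thresholds}{`major` (default 0.85), optional `minor`}
#'   \item{grouping}{`copies_per_population`, `n_groups`, optional `seed`;
#'     omitted = use the metadata's `group` column}
#'   \item{out_dir}{where to write `events.tsv`, `spectrum.tsv`,
#'     `stats.tsv`, `run.log` (omitted = no files)}
#'   \item{seed}{fallback seed for grouping}
#' }
#'
#' @param config List or YAML file path.
#' @return Invisibly, a list: `alignment`, `profile` (pooled scope),
#'   `spectrum`, `stats` (list of `te_stat`), `events` (pooled-scope
#'   deduplicated, annotated), `group_events`, `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }

  major <- config$thresholds$major %||% 0.85
  minor <- config$thresholds$minor %||% (1 - major)
  say("thresholds: major=", major, " minor=", minor)

  orfs <- NULL; ancestral <- NULL
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    if (!is.null(sim_args$orfs)) sim_args$orfs <- as_orf_table(sim_args$orfs)
    sim <- simulate_family(do.call(simulation_config, sim_args),
                           minor_cap = minor)
    aln <- sim$alignment
    orfs <- sim$orfs
    ancestral <- sim$ancestral
    say("stage simulate: ", nrow(aln), " copies x ", n_columns(aln),
        " columns, seed=", sim$config$seed)
  } else if (!is.null(config$input)) {
    inp <- config$input
    aln <- read_aligned_fasta(inp$fasta, inp$metadata,
                              reference_id = inp$reference_id)
    if (!is.null(inp$orfs)) {
      orfs <- if (is.character(inp$orfs)) read_orf_table(inp$orfs)
              else as_orf_table(inp$orfs)
    }
    say("stage input: ", nrow(aln), " copies x ", n_columns(aln), " columns")
  } else {
    stop("configuration error [stage input]: need an 'input' or ",
         "'simulation' block", call. = FALSE)
  }

  profile <- call_ancestral_profile(aln, major, minor)
  if (is.null(ancestral)) ancestral <- ancestral_sequence(profile)

  if (!is.null(config$grouping)) {
    g <- config$grouping
    seed <- g$seed %||% config$seed
    grouped <- assign_groups(tibble::as_tibble(aln),
                             g$copies_per_population, g$n_groups,
                             seed = seed)
    aln$group <- grouped$group
    say("stage group: scheme (", g$copies_per_population, ", ", g$n_groups,
        "), seed=", seed %||% "none")
  }
  groups <- sort(unique(stats::na.omit(aln$group)))
  if (length(groups) < 2) {
    stop("configuration error [stage group]: need >= 2 groups (give a ",
         "'grouping' block or group labels in the metadata)", call. = FALSE)
  }

  ## per-group scope: single-base substitution spectrum
  group_events <- purrr::map(groups, function(g) {
    sub <- subset_copies(aln, aln$copy_id[!is.na(aln$group) & aln$group == g])
    gprof <- call_ancestral_profile(sub, major, minor)
    ev <- merge_adjacent_calls(call_substitutions(sub, gprof), gprof) |>
      deduplicate_events() |>
      annotate_events(ancestral = ancestral, orfs = orfs)
    ev$group <- g
    ev
  }) |> purrr::list_rbind()
  say("stage call/group: ", nrow(group_events),
      " unique substitution events across ", length(groups), " groups")

  spectrum <- summarize_spectrum(group_events)

  ## pooled scope: indels and multi-base substitutions
  events <- call_mutation_events(aln, profile) |>
    annotate_events(ancestral = ancestral, orfs = orfs)
  say("stage call/pooled: ",
      sum(events$event_kind == "substitution" & events$length > 1),
      " multi-base substitutions, ",
      sum(events$event_kind == "deletion"), " deletions, ",
      sum(events$event_kind == "insertion"), " insertions")

  stats_list <- list(
    transition_vs_transversion = anova_tukey(list(
      transition = spectrum_counts(spectrum, "transition"),
      transversion = spectrum_counts(spectrum, "transversion"))),
    at_gc_vs_gc_at = t_test_independent(
      spectrum_counts(spectrum, "A:T>G:C"),
      spectrum_counts(spectrum, "G:C>A:T")),
    codon_positions = anova_tukey(list(
      pos1 = spectrum_counts(spectrum, "pos1"),
      pos2 = spectrum_counts(spectrum, "pos2"),
      pos3 = spectrum_counts(spectrum, "pos3"))),
    protein_effects = anova_tukey(list(
      synonymous = spectrum_counts(spectrum, "synonymous"),
      missense = spectrum_counts(spectrum, "missense"),
      nonsense = spectrum_counts(spectrum, "nonsense"),
      no_stop = spectrum_counts(spectrum, "no_stop")))
  )
  for (nm in names(stats_list)) {
    say("stat ", nm, ": statistic=", signif(stats_list[[nm]]$statistic, 5),
        " p=", signif(stats_list[[nm]]$p_value, 5),
        " ", stats_list[[nm]]$stars)
  }

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      events = file.path(config$out_dir, "events.tsv"),
      spectrum = file.path(config$out_dir, "spectrum.tsv"),
      stats = file.path(config$out_dir, "stats.tsv"),
      log = file.path(config$out_dir, "run.log")
    )
    write_events_table(events, paths$events)
    utils::write.table(tibble::as_tibble(spectrum), paths$spectrum,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats_tbl <- purrr::imap(stats_list, function(st, nm) {
      letters05 <- st$letters[["alpha_0.05"]]
      tibble::tibble(
        comparison = nm, test = st$test, statistic = st$statistic,
        p_value = st$p_value, stars = st$stars,
        letters = if (is.null(letters05)) "" else
          paste(names(letters05), letters05, sep = "=", collapse = " ")
      )
    }) |> purrr::list_rbind()
    utils::write.table(stats_tbl, paths$stats, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(c(paste0("timestamp: ", format(Sys.time())), log_lines),
               paths$log)
  }

  invisible(list(alignment = aln, profile = profile, spectrum = spectrum,
                 stats = stats_list, events = events,
                 group_events = group_events, paths = paths,
                 log = log_lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
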