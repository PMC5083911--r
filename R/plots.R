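#' Plot a spectrum summary
#'
#' Bar chart of cross-group mean counts with standard-error bars for one
#' family of categories.
#'
#' @param object A `te_spectrum` from [summarize_spectrum()].
#' @param which Category family: `"patterns"` (12 ordered changes),
#'   `"ts_tv"`, `"pooled"` (strand-pooled pairs), `"codon"` (positions
#'   1-3), `"effects"` (protein-effect classes), `"region"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_spectrum <- function(object, which = c("patterns", "ts_tv",
                                                   "pooled", "codon",
                                                   "effects", "region"),
                                 ...) {
  which <- match.arg(which)
  cats <- switch(which,
    patterns = substitution_patterns(),
    ts_tv = c("transition", "transversion"),
    pooled = c("A:T>G:C", "G:C>A:T", "A:T>T:A", "A:T>C:G", "G:C>T:A",
               "G:C>C:G"),
    codon = c("pos1", "pos2", "pos3"),
    effects = c("synonymous", "missense", "nonsense", "no_stop"),
    region = c("inside_orf", "outside_orf")
  )
  df <- tibble::as_tibble(object)
  df <- df[match(cats, df$category), , drop = FALSE]
  df$category <- factor(df$category, levels = cats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.25) +
    ggplot2::labs(x = NULL,
                  y = sprintf("substitutions (mean ± SE, %d groups)",
                              attr(object, "n_groups"))) +
    ggplot2::theme_minimal()
}

#' Plot group means of a comparison with its letter display
#'
#' @param object A `te_stat` (ANOVA results carry compact letters; t-test
#'   results plot the two means with significance stars).
#' @param alpha Which letter display to annotate (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_stat <- function(object, alpha = 0.05, ...) {
  df <- tibble::tibble(group = names(object$means),
                       mean = unname(object$means))
  df$group <- factor(df$group, levels = df$group)
  lab <- if (!is.null(object$letters)) {
    lt <- object$letters[[paste0("alpha_", alpha)]]
    unname(lt[as.character(df$group)])
  } else {
    c(object$stars, rep("", nrow(df) - 1))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = lab),
                       vjust = -0.4, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "mean count",
                  subtitle = sprintf("%s: p = %.3g %s", object$test,
                                     object$p_value, object$stars)) +
    ggplot2::theme_minimal()
}

#' Histogram of indel lengths in an event set
#'
#' @param events Events tibble (e.g. from [call_mutation_events()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_indel_lengths <- function(events, ...) {
  df <- events[events$event_kind %in% c("insertion", "deletion"), ,
               drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length,
                                   fill = .data$event_kind)) +
    ggplot2::geom_histogram(bins = 30, position = "dodge") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "indel length (bases)", y = "events", fill = NULL) +
    ggplot2::theme_minimal()
}
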