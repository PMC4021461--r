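#' Filter cascade configuration
#'
#' The three sequential filters of the differential-expression analysis:
#' proteins identified by fewer than `min_peptides` peptides are rejected as
#' unreliable for quantification; proteins whose mean ratio lies strictly
#' inside the fold-change band `(fc_down, fc_up)` are deemed unchanged and
#' removed (thresholds inclusive: a mean of exactly 1.25 or 0.75 survives);
#' finally only proteins with raw `p < alpha` (strict) are kept. Defaults are
#' the study's values: 3 peptides, a +/- 1.25x band with the down threshold
#' read literally as 0.75 (not 1/1.25), and alpha 0.05.
#'
#' @param min_peptides minimum peptide count, `>= 1`.
#' @param fc_up upper fold-change threshold, `> 1`.
#' @param fc_down lower fold-change threshold, in `(0, 1)`.
#' @param alpha significance level, in `(0, 1)`.
#' @return A `filter_config` object (named list).
#' @export
filter_config <- function(min_peptides = 3, fc_up = 1.25, fc_down = 0.75,
                          alpha = 0.05) {
  stopifnot(
    min_peptides >= 1,
    fc_down > 0, fc_down < 1, fc_up > 1,
    alpha > 0, alpha < 1
  )
  structure(
    list(
      min_peptides = as.integer(min_peptides),
      fc_up = fc_up, fc_down = fc_down, alpha = alpha
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(
    "<filter_config> min peptides %d | fold-change band (%.4g, %.4g) | alpha %.4g\n",
    x$min_peptides, x$fc_down, x$fc_up, x$alpha
  ))
  invisible(x)
}

#' Individual cascade filters
#'
#' Each filter takes a protein summary tibble and returns the subset passing
#' its predicate; [run_cascade()] composes them in the analysis order.
#' `apply_significance()` excludes (with a warning) summaries that carry no
#' p-value — a protein quantified by a single peptide cannot be tested and is
#' never silently kept.
#'
#' @param summaries a protein summary tibble (see [summarize_proteins()]).
#' @param config a [filter_config()].
#' @return the filtered summary tibble.
#' @export
apply_min_peptides <- function(summaries, config = filter_config()) {
  dplyr::filter(summaries, .data$n_peptides >= config$min_peptides)
}

#' @rdname apply_min_peptides
#' @export
apply_fold_change <- function(summaries, config = filter_config()) {
  dplyr::filter(
    summaries,
    .data$mean_ratio >= config$fc_up | .data$mean_ratio <= config$fc_down
  )
}

#' @rdname apply_min_peptides
#' @export
apply_significance <- function(summaries, config = filter_config()) {
  n_missing <- sum(is.na(summaries$p_value))
  if (n_missing > 0) {
    warning(
      n_missing, " summarie(s) lack a p-value (single-peptide proteins) ",
      "and are excluded from the significance filter",
      call. = FALSE
    )
  }
  dplyr::filter(summaries, !is.na(.data$p_value), .data$p_value < config$alpha)
}

#' Run the three-stage differential-expression filter cascade
#'
#' Applies, independently per contrast and in the analysis order: the minimum
#' peptide-count filter, the fold-change band filter, and the raw-p
#' significance filter. Stage survivor counts are non-increasing and each
#' stage's survivors are a subset of the previous stage's; because the three
#' predicates are independent, the final survivor set does not depend on the
#' order (only the intermediate counts do).
#'
#' @param summaries a protein summary tibble for one or more contrasts.
#' @param config a [filter_config()].
#' @return A `cascade_report`: list with `counts` (per-contrast tibble of
#'   `n_detected`, `n_after_peptide_filter`, `n_after_fc_filter`,
#'   `n_after_significance`, `n_up`, `n_down`), `survivors` (the summaries
#'   passing all three filters), and `config`. Use [generics::tidy()] for the
#'   survivors, [generics::glance()] for the counts, and
#'   [ggplot2::autoplot()] for a stage-count chart.
#' @export
run_cascade <- function(summaries, config = filter_config()) {
  contrasts <- unique(summaries$contrast)
  stage1 <- apply_min_peptides(summaries, config)
  stage2 <- apply_fold_change(stage1, config)
  stage3 <- suppressWarnings(apply_significance(stage2, config))
  count_by <- function(s) {
    vapply(contrasts, function(cc) sum(s$contrast == cc), integer(1))
  }
  counts <- tibble::tibble(
    contrast = contrasts,
    timepoint = contrast_timepoint(contrasts),
    n_detected = count_by(summaries),
    n_after_peptide_filter = count_by(stage1),
    n_after_fc_filter = count_by(stage2),
    n_after_significance = count_by(stage3),
    n_up = vapply(
      contrasts,
      function(cc) sum(stage3$contrast == cc & stage3$direction == "up"),
      integer(1)
    ),
    n_down = vapply(
      contrasts,
      function(cc) sum(stage3$contrast == cc & stage3$direction == "down"),
      integer(1)
    )
  )
  structure(
    list(counts = counts, survivors = stage3, config = config),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(x$config)
  print(x$counts)
  invisible(x)
}

#' Tidy the survivors of a cascade report
#'
#' @param x a `cascade_report`.
#' @param ... unused.
#' @return the survivor summary tibble.
#' @method tidy cascade_report
#' @export
tidy.cascade_report <- function(x, ...) {
  x$survivors
}

#' One row per contrast of cascade stage counts
#'
#' @param x a `cascade_report`.
#' @param ... unused.
#' @return the per-contrast counts tibble.
#' @method glance cascade_report
#' @export
glance.cascade_report <- function(x, ...) {
  x$counts
}

#' Stage-count chart for a cascade report
#'
#' @param object a `cascade_report`.
#' @param ... unused.
#' @return a ggplot object: survivor counts at each cascade stage, one panel
#'   group per contrast.
#' @method autoplot cascade_report
#' @export
autoplot.cascade_report <- function(object, ...) {
  stages <- c(
    "n_detected", "n_after_peptide_filter",
    "n_after_fc_filter", "n_after_significance"
  )
  long <- tidyr::pivot_longer(
    object$counts[, c("timepoint", stages)],
    cols = dplyr::all_of(stages),
    names_to = "stage", values_to = "n"
  )
  long$stage <- factor(long$stage, levels = stages,
    labels = c("detected", ">= min peptides", "fold-change band", "p < alpha")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$n,
    fill = .data$timepoint)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "proteins remaining",
      title = "Differential-expression filter cascade"
    ) +
    ggplot2::theme_minimal()
}
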