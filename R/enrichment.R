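#' Keywords flagging neuronal-connectivity annotations
#'
#' The six keywords used to narrow enriched functional annotations to those
#' reflecting changes in neuronal connectivity after deafferentation.
#'
#' @return character vector of keywords.
#' @export
neurite_keywords <- function() {
  c("axon", "dendrite", "dendritic", "synapse", "synaptic", "neurite")
}

#' Right-tailed Fisher's exact enrichment over annotation term sets
#'
#' For each term, tests whether the selected proteins overlap the term's
#' member set more than expected by chance: the p-value is the hypergeometric
#' upper tail `P(X >= n_overlap)` with population `n_background`, successes
#' `n_term` and draws `n_selected` — the right-tailed Fisher's exact test
#' commercial annotation tools rank by. This module is a transparent stand-in
#' for such tools: the term sets come from the user (GMT), not from a curated
#' knowledge base.
#'
#' @param selected character vector of selected accessions (e.g. the
#'   up-regulated survivors of [run_cascade()]); must be a subset of the
#'   annotation background.
#' @param annotations an [annotation_sets()] collection.
#' @param keywords keyword set used to fill the `keyword_hit` flag (default
#'   [neurite_keywords()]); the flag is informational until
#'   [keyword_filter()] is applied.
#' @return A tibble sorted ascending by p-value: `term`, `n_term`,
#'   `n_selected`, `n_overlap`, `n_background`, `p_value`,
#'   `fraction_selected` (share of the selected list annotated to the term),
#'   `keyword_hit`.
#' @seealso [filter_terms()], [keyword_filter()]
#' @export
fisher_enrichment <- function(selected, annotations,
                              keywords = neurite_keywords()) {
  background <- annotation_background(annotations)
  selected <- unique(selected)
  stray <- setdiff(selected, background)
  if (length(stray) > 0) {
    stop(
      "selected accessions outside the background: ",
      paste(utils::head(stray, 10), collapse = ", "),
      call. = FALSE
    )
  }
  n_bg <- length(background)
  n_sel <- length(selected)
  overlap <- vapply(
    annotations$members,
    function(m) length(intersect(m, selected)),
    integer(1)
  )
  p <- stats::phyper(
    overlap - 1L, annotations$n_term, n_bg - annotations$n_term, n_sel,
    lower.tail = FALSE
  )
  out <- tibble::tibble(
    term = annotations$term,
    n_term = annotations$n_term,
    n_selected = n_sel,
    n_overlap = overlap,
    n_background = n_bg,
    p_value = p,
    fraction_selected = if (n_sel > 0) overlap / n_sel else NA_real_,
    keyword_hit = keyword_match(annotations$term, keywords)
  )
  dplyr::arrange(out, .data$p_value)
}

keyword_match <- function(terms, keywords) {
  if (length(keywords) == 0) {
    return(rep(FALSE, length(terms)))
  }
  lowered <- tolower(terms)
  Reduce(`|`, lapply(tolower(keywords), function(k) {
    stringr::str_detect(lowered, stringr::fixed(k))
  }))
}

#' Remove unreliable enrichment terms
#'
#' Drops a term when its p-value exceeds `alpha` *or* its overlap with the
#' selection is below `min_proteins` — a small-overlap annotation is
#' unreliable regardless of its p-value. Note the p cut is `> alpha`
#' (a term at exactly 0.05 survives), matching the stated removal rule.
#'
#' @param results an enrichment tibble from [fisher_enrichment()].
#' @param alpha removal threshold on the p-value (default 0.05).
#' @param min_proteins minimum overlap count (default 3).
#' @return the filtered enrichment tibble.
#' @export
filter_terms <- function(results, alpha = 0.05, min_proteins = 3) {
  dplyr::filter(
    results,
    .data$p_value <= alpha, .data$n_overlap >= min_proteins
  )
}

#' Keep only terms whose name matches a keyword
#'
#' Case-insensitive substring match of any keyword against the term name;
#' the default set flags annotations about neuronal connectivity (axons,
#' dendrites, synapses, neurites).
#'
#' @param results an enrichment tibble from [fisher_enrichment()].
#' @param keywords character vector of keywords (default
#'   [neurite_keywords()]).
#' @return the rows of `results` whose term matches at least one keyword.
#' @export
keyword_filter <- function(results, keywords = neurite_keywords()) {
  dplyr::filter(results, keyword_match(.data$term, keywords))
}

#' Bar chart of enrichment results
#'
#' @param results an enrichment tibble from [fisher_enrichment()].
#' @param max_terms show at most this many terms (smallest p first).
#' @return a ggplot object of -log10 p per term, keyword hits highlighted.
#' @export
plot_enrichment <- function(results, max_terms = 20) {
  d <- utils::head(dplyr::arrange(results, .data$p_value), max_terms)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = -log10(.data$p_value), y = .data$term,
      fill = .data$keyword_hit
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = expression(-log[10] ~ p), y = NULL,
      fill = "keyword hit",
      title = "Right-tailed Fisher's exact enrichment"
    ) +
    ggplot2::theme_minimal()
}
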