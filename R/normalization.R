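#' Global median normalization of reporter-ion ratios
#'
#' Divides every non-missing peptide ratio of a contrast by the median of all
#' non-missing ratios of that contrast across the whole table
#' (`ratio / median(all found ratios)`), independently per contrast. This is
#' the normalization the quantification software applies globally: after it,
#' the median ratio of each processed channel is exactly 1, so channel-wide
#' loading or labelling bias cancels while relative differences between
#' proteins are untouched.
#'
#' The median of an even number of values is the arithmetic mean of the two
#' middle order statistics, making the operation bit-reproducible. Missing
#' ratios stay missing and take no part in the median. A contrast with no
#' usable ratios at all is skipped and flagged (`n_found = 0`) in the report
#' rather than raising an error.
#'
#' @param peptides a peptide tibble (see [read_peptide_table()]).
#' @param contrasts contrast labels to normalize; defaults to all three.
#' @return The normalized peptide tibble. The per-channel divisors are
#'   attached as a `median_report` attribute — read it with [median_report()]
#'   immediately after this call (later dplyr verbs may drop attributes).
#' @examples
#' p <- simulate_peptides(sim_config(n_proteins = 20, seed = 1))
#' norm <- normalize_ratios(p)
#' median_report(norm)
#' @export
normalize_ratios <- function(peptides, contrasts = contrast_labels()) {
  report <- tibble::tibble(
    contrast = contrasts,
    timepoint = contrast_timepoint(contrasts),
    raw_median = NA_real_,
    n_found = 0L
  )
  out <- peptides
  for (i in seq_along(contrasts)) {
    cc <- ratio_col(contrasts[i])
    v <- out[[cc]]
    found <- !is.na(v)
    report$n_found[i] <- sum(found)
    if (any(found)) {
      m <- stats::median(v[found])
      report$raw_median[i] <- m
      out[[cc]] <- v / m
    }
  }
  attr(out, "median_report") <- report
  out
}

#' @param x a tibble returned by [normalize_ratios()].
#' @rdname normalize_ratios
#' @export
median_report <- function(x) {
  rep <- attr(x, "median_report")
  if (is.null(rep)) {
    stop("no median_report attribute; was the table produced by normalize_ratios()?",
      call. = FALSE
    )
  }
  rep
}

#' Plot per-channel raw medians
#'
#' Bar chart of the normalization divisors, one bar per contrast; a divisor
#' far from 1 indicates global channel bias that normalization removed.
#'
#' @param report a median report tibble from [median_report()].
#' @return a ggplot object.
#' @export
plot_channel_medians <- function(report) {
  ggplot2::ggplot(
    report,
    ggplot2::aes(x = .data$contrast, y = .data$raw_median)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "contrast", y = "raw channel median",
      title = "Median-ratio normalization divisors"
    ) +
    ggplot2::theme_minimal()
}
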