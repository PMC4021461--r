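#' iTRAQ contrast labels and timepoints
#'
#' The 4-plex design labels the unlesioned control with reporter 114 and the
#' lesioned striatum at 3, 7 and 14 days post-lesion with reporters 115, 116
#' and 117. All quantification is carried as reporter-ion ratios over the
#' control channel, so the three contrasts are `"115/114"`, `"116/114"` and
#' `"117/114"`.
#'
#' @return `contrast_labels()` returns the three contrast labels in channel
#'   order. `contrast_timepoint()` maps labels to the timepoints `"3d"`,
#'   `"7d"`, `"14d"`.
#' @examples
#' contrast_labels()
#' contrast_timepoint("116/114")
#' @export
contrast_labels <- function() {
  c("115/114", "116/114", "117/114")
}

#' @param contrast character vector of contrast labels.
#' @rdname contrast_labels
#' @export
contrast_timepoint <- function(contrast) {
  map <- c("115/114" = "3d", "116/114" = "7d", "117/114" = "14d")
  bad <- setdiff(contrast, names(map))
  if (length(bad) > 0) {
    stop("unknown contrast label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(map[contrast])
}

# column name in the wide peptide table holding a contrast's ratios
ratio_col <- function(contrast) {
  paste0("ratio_", sub("/", "_", contrast, fixed = TRUE))
}

ratio_cols <- function() ratio_col(contrast_labels())

# wide peptide table -> one row per non-missing (peptide, contrast) ratio
peptides_long <- function(peptides, contrasts = contrast_labels()) {
  cols <- ratio_col(contrasts)
  out <- tidyr::pivot_longer(
    peptides,
    cols = dplyr::all_of(cols),
    names_to = "contrast",
    values_to = "ratio"
  )
  out$contrast <- contrasts[match(out$contrast, cols)]
  dplyr::filter(out, !is.na(.data$ratio))
}
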