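#' Read a peptide-level iTRAQ quantification table
#'
#' Reads the tab-separated peptide table exported from search-engine software:
#' one row per identified peptide with its protein accession and the three
#' reporter-ion ratios over the control channel. Identification-quality
#' filtering is applied at read time: only peptides with total ion score
#' confidence interval of at least `min_ci` percent and peptide rank at most
#' `max_rank` are returned (the stringent settings used for the original
#' search were 95% and rank 1).
#'
#' The expected header is
#' `accession  protein_name  peptide_sequence  ion_score_ci  peptide_rank
#' ratio_115_114  ratio_116_114  ratio_117_114` (tab-separated, UTF-8).
#' Empty or unparseable ratio cells are kept as missing values (`NA`), never
#' coerced to zero; a ratio that parses to a non-positive number is a
#' validation error.
#'
#' @param path path to a tab-separated peptide table.
#' @param min_ci minimum ion score confidence interval, percent in `[0, 100]`.
#' @param max_rank maximum peptide rank to retain.
#' @return A tibble with one row per retained peptide, in file order, with
#'   columns `accession`, `protein_name`, `peptide_sequence`, `ion_score_ci`,
#'   `peptide_rank`, `ratio_115_114`, `ratio_116_114`, `ratio_117_114`.
#' @seealso [write_peptide_table()], [normalize_ratios()], [summarize_proteins()]
#' @export
read_peptide_table <- function(path, min_ci = 95, max_rank = 1) {
  if (!file.exists(path)) {
    stop("peptide table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    na = character()
  )
  required <- c(
    "accession", "protein_name", "peptide_sequence",
    "ion_score_ci", "peptide_rank", ratio_cols()
  )
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0) {
    stop(
      "peptide table is missing required column(s): ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    accession = raw$accession,
    protein_name = raw$protein_name,
    peptide_sequence = raw$peptide_sequence,
    ion_score_ci = suppressWarnings(as.numeric(raw$ion_score_ci)),
    peptide_rank = suppressWarnings(as.integer(raw$peptide_rank))
  )
  for (cc in ratio_cols()) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    v[trimws(raw[[cc]]) == ""] <- NA_real_
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad) > 0) {
      stop(
        sprintf(
          "non-positive ratio %g in column %s at data row %d",
          v[bad[1]], cc, bad[1]
        ),
        call. = FALSE
      )
    }
    out[[cc]] <- v
  }
  validate_peptides(out)
  dplyr::filter(out, .data$ion_score_ci >= min_ci, .data$peptide_rank <= max_rank)
}

validate_peptides <- function(peptides) {
  if (any(is.na(peptides$accession) | peptides$accession == "")) {
    stop("accession must be non-empty for every peptide row", call. = FALSE)
  }
  ci <- peptides$ion_score_ci
  if (any(is.na(ci) | ci < 0 | ci > 100)) {
    stop("ion_score_ci must be a percentage in [0, 100]", call. = FALSE)
  }
  rk <- peptides$peptide_rank
  if (any(is.na(rk) | rk < 1)) {
    stop("peptide_rank must be a positive integer", call. = FALSE)
  }
  invisible(peptides)
}

#' Write a peptide table in the canonical dialect
#'
#' Missing ratios are written as empty cells so that a write/read cycle
#' round-trips every record exactly.
#'
#' @param peptides a peptide tibble as returned by [read_peptide_table()] or
#'   [simulate_peptides()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  readr::write_tsv(peptides, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a protein summary table in the published layout
#'
#' Renders protein-level summaries for a single contrast the way the study's
#' differential-expression tables are printed: the down-regulated block first,
#' sorted ascending by mean ratio, then the up-regulated block, again
#' ascending by mean ratio. Means and SDs are printed with 2 decimals and
#' p-values with 4 (round-half-even); filtering decisions are always taken on
#' the unrounded values upstream of this writer.
#'
#' @param summaries a protein summary tibble (one contrast only), as produced
#'   by [summarize_proteins()] or [run_cascade()] survivors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(summaries, path) {
  header <- c(
    "protein_name", "accession", "mean_ratio", "sd",
    "n_peptides", "p_value", "direction"
  )
  if (nrow(summaries) == 0) {
    readr::write_lines(paste(header, collapse = "\t"), path)
    return(invisible(path))
  }
  if (length(unique(summaries$contrast)) > 1) {
    stop("write_protein_table() expects summaries for a single contrast",
      call. = FALSE
    )
  }
  dir <- if ("direction" %in% names(summaries)) {
    summaries$direction
  } else {
    ifelse(summaries$mean_ratio < 1, "down", "up")
  }
  ord <- order(dir != "down", summaries$mean_ratio)
  s <- summaries[ord, ]
  fmt2 <- function(x) ifelse(is.na(x), "NA", formatC(round(x, 2), format = "f", digits = 2))
  fmt4 <- function(x) ifelse(is.na(x), "NA", formatC(round(x, 4), format = "f", digits = 4))
  out <- tibble::tibble(
    protein_name = s$protein_name,
    accession = s$accession,
    mean_ratio = fmt2(s$mean_ratio),
    sd = fmt2(s$sd),
    n_peptides = as.character(s$n_peptides),
    p_value = fmt4(s$p_value),
    direction = dir[ord]
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read annotation term sets in GMT format
#'
#' Parses the standard GMT dialect (one term per line: term name, description,
#' then tab-separated member accessions). Member sets are de-duplicated. The
#' background population defaults to the union of all members; a larger
#' background (e.g. the quantifiable proteome) may be supplied explicitly and
#' must contain every member.
#'
#' @param path path to a GMT file.
#' @param background optional character vector of background accessions.
#' @return An `annotation_sets` object: a tibble with columns `term`,
#'   `description`, `members` (list-column) and `n_term`, carrying the
#'   background as an attribute retrievable with [annotation_background()].
#' @seealso [fisher_enrichment()]
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  terms <- vapply(fields, `[[`, character(1), 1L)
  dup <- terms[duplicated(terms)]
  if (length(dup) > 0) {
    stop("duplicate term name in GMT: ", dup[1], call. = FALSE)
  }
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  annotation_sets(
    term = terms,
    description = vapply(fields, `[[`, character(1), 2L),
    members = members,
    background = background
  )
}

#' Construct an annotation set collection
#'
#' @param term character vector of unique term names.
#' @param members list of character vectors of member accessions, parallel to
#'   `term`.
#' @param description optional character vector of term descriptions.
#' @param background optional background accession vector; defaults to the
#'   union of all members. Every member must belong to it.
#' @return An `annotation_sets` tibble.
#' @export
annotation_sets <- function(term, members, description = NULL, background = NULL) {
  stopifnot(length(term) == length(members))
  if (anyDuplicated(term)) {
    stop("term names must be unique", call. = FALSE)
  }
  members <- lapply(members, unique)
  universe <- unique(unlist(members, use.names = FALSE))
  if (is.null(background)) {
    background <- universe
  } else {
    background <- unique(background)
    stray <- setdiff(universe, background)
    if (length(stray) > 0) {
      stop(
        "term members outside the declared background: ",
        paste(utils::head(stray, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  out <- tibble::tibble(
    term = term,
    description = description %||% rep(NA_character_, length(term)),
    members = members,
    n_term = lengths(members)
  )
  attr(out, "background") <- background
  class(out) <- c("annotation_sets", class(out))
  out
}

#' @param x an `annotation_sets` object.
#' @rdname annotation_sets
#' @export
annotation_background <- function(x) {
  bg <- attr(x, "background")
  if (is.null(bg)) {
    stop("object carries no background attribute; is it an annotation_sets?",
      call. = FALSE
    )
  }
  bg
}
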