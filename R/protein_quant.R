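#' Roll peptide ratios up to protein-level summaries
#'
#' Aggregates the non-missing peptide ratios of each protein in one contrast
#' to the protein-level mean, sample standard deviation (divisor `n - 1`) and
#' peptide count — the `mean +/- SD [n]` triple the study's tables print.
#' Proteins with a single usable ratio get `sd = NA` (undefined under the
#' `n - 1` divisor); proteins with no usable ratio in the contrast are absent.
#' Distinct accessions are distinct proteins: no grouping or parsimony
#' inference is attempted, and shared peptide rows are used as given.
#'
#' @param peptides a (normalized) peptide tibble.
#' @param contrast a single contrast label, e.g. `"115/114"`.
#' @return A tibble with columns `accession`, `protein_name`, `contrast`,
#'   `timepoint`, `mean_ratio`, `sd`, `n_peptides`, in order of first
#'   appearance in the input.
#' @seealso [summarize_proteins()] for all contrasts plus significance testing.
#' @export
rollup <- function(peptides, contrast) {
  stopifnot(length(contrast) == 1)
  long <- peptides_long(peptides, contrast)
  out <- dplyr::summarise(
    long,
    protein_name = dplyr::first(.data$protein_name),
    mean_ratio = mean(.data$ratio),
    sd = stats::sd(.data$ratio),
    n_peptides = dplyr::n(),
    .by = "accession"
  )
  out$contrast <- contrast
  out$timepoint <- contrast_timepoint(contrast)
  dplyr::select(
    out, "accession", "protein_name", "contrast", "timepoint",
    "mean_ratio", "sd", "n_peptides"
  )
}

#' One-tailed one-sample t-test of peptide ratios against unity
#'
#' The study's "pairwise" test: each peptide's lesioned and control reporter
#' measurements form a pair whose quotient is the peptide's ratio, so the
#' paired comparison collapses to a one-sample Student t-test of a protein's
#' peptide ratios against the null ratio (default 1). On the linear scale
#' `t = (mean - null_value) / (sd / sqrt(n))` with `n - 1` degrees of
#' freedom; on the log scale the ratios are log-transformed and tested
#' against `log(null_value)`, which symmetrizes the right-skewed ratio
#' distribution.
#'
#' The reported p-value is one-tailed. With `tail = "adaptive"` (the
#' convention of the published analysis) the tail is taken in the direction
#' of the observed mean, so p never exceeds 0.5; note that used as a
#' fixed-level test this doubles the null rejection rate relative to a
#' pre-specified tail (`"upper"` or `"lower"`), where p is uniform under the
#' null. Degenerate inputs: zero spread with mean at the null gives p = 0.5;
#' zero spread with mean away from the null gives the smallest representable
#' positive p with a warning.
#'
#' @param ratios numeric vector of at least 2 positive peptide ratios.
#' @param scale `"linear"` (default) or `"log"`.
#' @param null_value null ratio, default 1.
#' @param tail `"adaptive"` (direction of the observed mean), `"upper"`, or
#'   `"lower"`.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `direction`
#'   (`"up"`, `"down"` or `"null"`, from the observed mean on the test scale).
#' @examples
#' peptide_t_test(c(1.2, 1.4, 1.6)) # t = 3.4641, p ~= 0.0371
#' @export
peptide_t_test <- function(ratios, scale = c("linear", "log"),
                           null_value = 1, tail = c("adaptive", "upper", "lower")) {
  scale <- match.arg(scale)
  tail <- match.arg(tail)
  stopifnot(null_value > 0)
  if (any(is.na(ratios) | !is.finite(ratios) | ratios <= 0)) {
    stop("ratios must be positive and finite", call. = FALSE)
  }
  if (length(ratios) < 2) {
    stop("insufficient peptides for test (need at least 2 ratios)", call. = FALSE)
  }
  x <- if (scale == "log") log(ratios) else ratios
  null <- if (scale == "log") log(null_value) else null_value
  res <- t_tail_prob(mean(x), stats::sd(x), length(x), null, tail)
  tibble::tibble(
    t_statistic = res$t,
    df = length(ratios) - 1,
    p_value = res$p,
    direction = res$direction
  )
}

# vectorized t statistic + one-tailed p from summary moments; shared by
# peptide_t_test() and summarize_proteins()
t_tail_prob <- function(m, s, n, null, tail) {
  df <- n - 1
  direction <- ifelse(m > null, "up", ifelse(m < null, "down", "null"))
  t <- (m - null) / (s / sqrt(n))
  zero_sd <- !is.na(s) & s == 0
  t[zero_sd & direction == "null"] <- 0
  t[zero_sd & direction == "up"] <- Inf
  t[zero_sd & direction == "down"] <- -Inf
  n_degen <- sum(zero_sd & direction != "null")
  if (n_degen > 0) {
    warning(
      n_degen, " test(s) with zero spread and mean away from the null; ",
      "p reported as the smallest representable positive value",
      call. = FALSE
    )
  }
  p <- switch(tail,
    adaptive = ifelse(t >= 0,
      stats::pt(t, df, lower.tail = FALSE),
      stats::pt(t, df)
    ),
    upper = stats::pt(t, df, lower.tail = FALSE),
    lower = stats::pt(t, df)
  )
  # tail probability of an infinite t underflows to 0; report the smallest
  # positive double instead so p stays in (0, 1]
  p[p == 0] <- .Machine$double.xmin
  list(t = t, p = p, direction = direction)
}

#' Protein-level summaries with significance for every contrast
#'
#' Runs [rollup()] and the one-tailed t-test for every protein in every
#' requested contrast. Proteins with a single peptide in a contrast carry
#' `p_value = NA` (no test possible). The printed `mean_ratio`/`sd` are
#' always the linear-scale moments, matching the published table layout,
#' regardless of the test scale; `direction` compares the linear mean against
#' `null_value`. A Benjamini–Hochberg adjusted column `p_adjusted` (per
#' contrast) is included for information only — the filter cascade, like the
#' original analysis, uses raw p-values.
#'
#' @inheritParams peptide_t_test
#' @param peptides a normalized peptide tibble.
#' @param contrasts contrast labels to summarize; defaults to all three.
#' @return A tibble with one row per protein x contrast (`accession`,
#'   `protein_name`, `contrast`, `timepoint`, `mean_ratio`, `sd`,
#'   `n_peptides`, `t_statistic`, `p_value`, `direction`, `p_adjusted`).
#' @export
summarize_proteins <- function(peptides, contrasts = contrast_labels(),
                          scale = c("linear", "log"), null_value = 1,
                          tail = c("adaptive", "upper", "lower")) {
  scale <- match.arg(scale)
  tail <- match.arg(tail)
  stopifnot(null_value > 0)
  long <- peptides_long(peptides, contrasts)
  if (scale == "log") {
    long$test_value <- log(long$ratio)
    null <- log(null_value)
  } else {
    long$test_value <- long$ratio
    null <- null_value
  }
  out <- dplyr::summarise(
    long,
    protein_name = dplyr::first(.data$protein_name),
    mean_ratio = mean(.data$ratio),
    sd = stats::sd(.data$ratio),
    n_peptides = dplyr::n(),
    .test_mean = mean(.data$test_value),
    .test_sd = stats::sd(.data$test_value),
    .by = c("contrast", "accession")
  )
  testable <- out$n_peptides >= 2
  out$t_statistic <- NA_real_
  out$p_value <- NA_real_
  if (any(testable)) {
    res <- t_tail_prob(
      out$.test_mean[testable], out$.test_sd[testable],
      out$n_peptides[testable], null, tail
    )
    out$t_statistic[testable] <- res$t
    out$p_value[testable] <- res$p
  }
  out$direction <- ifelse(out$mean_ratio > null_value, "up",
    ifelse(out$mean_ratio < null_value, "down", "null")
  )
  out$timepoint <- contrast_timepoint(out$contrast)
  out <- dplyr::mutate(out,
    p_adjusted = stats::p.adjust(.data$p_value, method = "BH"),
    .by = "contrast"
  )
  dplyr::select(
    out, "accession", "protein_name", "contrast", "timepoint",
    "mean_ratio", "sd", "n_peptides", "t_statistic", "p_value",
    "direction", "p_adjusted"
  )
}
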