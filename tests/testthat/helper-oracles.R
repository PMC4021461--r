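# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: closed forms, quadrature of a hand-written density,
# and exhaustive combinatorial enumeration.

# Student t CDF at df = 2, closed form: F(t) = 1/2 + t / (2 * sqrt(2 + t^2))
t_cdf_df2 <- function(t) {
  0.5 + t / (2 * sqrt(2 + t^2))
}

# upper tail P(T >= t) by quadrature of the t density written from scratch
t_upper_tail_quad <- function(t, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) /
      sqrt(df * pi) * (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, t, Inf, rel.tol = 1e-13, abs.tol = 0)$value
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration over all
# possible overlap outcomes
hyper_upper_enum <- function(k, n_term, n_background, n_selected) {
  j <- seq(k, min(n_term, n_selected))
  sum(choose(n_term, j) * choose(n_background - n_term, n_selected - j)) /
    choose(n_background, n_selected)
}

# two-pass mean / sample SD, independent of stats::sd
brute_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# n ratios (n even) with exactly the requested mean and sample SD:
# half at mean - d, half at mean + d with d = sd * sqrt((n - 1) / n)
exact_moment_ratios <- function(mean, sd, n) {
  stopifnot(n %% 2 == 0)
  d <- sd * sqrt((n - 1) / n)
  stopifnot(mean - d > 0)
  rep(c(mean - d, mean + d), each = n / 2)
}

# build a peptide tibble from per-accession ratio lists; each element of
# `ratios` is a list with entries named by contrast label, each a numeric
# vector (recycled row-wise; NA allowed)
peptide_tbl <- function(ratios, ion_score_ci = 99, peptide_rank = 1L) {
  rows <- list()
  for (acc in names(ratios)) {
    chans <- ratios[[acc]]
    n <- max(lengths(chans))
    row <- tibble::tibble(
      accession = rep(acc, n),
      protein_name = paste("protein", acc),
      peptide_sequence = sprintf("PEPTIDE%s%d", acc, seq_len(n)),
      ion_score_ci = ion_score_ci,
      peptide_rank = peptide_rank
    )
    for (cc in contrast_labels()) {
      col <- paste0("ratio_", sub("/", "_", cc, fixed = TRUE))
      v <- chans[[cc]]
      row[[col]] <- if (is.null(v)) NA_real_ else c(v, rep(NA_real_, n - length(v)))
    }
    rows[[acc]] <- row
  }
  dplyr::bind_rows(rows)
}

# random small peptide table for property checks
random_peptides <- function(n_proteins, max_peptides = 6, missing_frac = 0.1) {
  ratios <- lapply(seq_len(n_proteins), function(i) {
    n <- sample(seq_len(max_peptides), 1)
    chans <- lapply(contrast_labels(), function(cc) {
      v <- stats::rlnorm(n, 0, 0.4)
      v[stats::runif(n) < missing_frac] <- NA_real_
      v
    })
    names(chans) <- contrast_labels()
    chans
  })
  names(ratios) <- sprintf("P%03d", seq_len(n_proteins))
  peptide_tbl(ratios)
}
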