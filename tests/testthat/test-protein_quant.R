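test_that("rollup computes mean, sample SD and peptide count per protein", {
  p <- peptide_tbl(list(
    A = list("115/114" = c(1.2, 1.4, 1.6)),
    B = list("115/114" = c(2.0))
  ))
  got <- rollup(p, "115/114")
  a <- got[got$accession == "A", ]
  expect_equal(a$mean_ratio, 1.4)
  expect_equal(a$sd, 0.2)
  expect_equal(a$n_peptides, 3L)
  b <- got[got$accession == "B", ]
  expect_equal(b$mean_ratio, 2.0)
  expect_equal(b$n_peptides, 1L)
  expect_true(is.na(b$sd)) # n - 1 divisor undefined at n = 1
})

test_that("rollup reproduces the printed GFAP summary from a supplementary-shaped fixture", {
  # synthetic peptide ratios constructed to carry the published protein-level
  # moments exactly (mean 3.44, SD 2.58, 8 peptides at 3 days)
  gfap <- exact_moment_ratios(3.44, 2.58, 8)
  p <- peptide_tbl(list("158186732" = list("115/114" = gfap)))
  got <- rollup(p, "115/114")
  expect_equal(round(got$mean_ratio, 2), 3.44)
  expect_equal(round(got$sd, 2), 2.58)
  expect_equal(got$n_peptides, 8L)
})

test_that("rollup mean/SD agree with a brute-force two-pass oracle", {
  set.seed(7)
  p <- random_peptides(40)
  for (cc in contrast_labels()) {
    got <- rollup(p, cc)
    col <- paste0("ratio_", sub("/", "_", cc, fixed = TRUE))
    for (i in seq_len(nrow(got))) {
      v <- p[[col]][p$accession == got$accession[i]]
      v <- v[!is.na(v)]
      oracle <- brute_mean_sd(v)
      expect_equal(got$mean_ratio[i], oracle$mean, tolerance = 1e-12)
      expect_equal(got$n_peptides[i], length(v))
      if (length(v) >= 2) expect_equal(got$sd[i], oracle$sd, tolerance = 1e-12)
    }
  }
})

test_that("the one-tailed t-test matches the closed form at df = 2", {
  got <- peptide_t_test(c(1.2, 1.4, 1.6))
  expect_equal(got$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(got$df, 2)
  expect_equal(got$p_value, 1 - t_cdf_df2(got$t_statistic), tolerance = 1e-10)
  expect_equal(round(got$p_value, 4), 0.0371)
  expect_equal(got$direction, "up")
})

test_that("the one-tailed p matches an independent quadrature oracle", {
  # the printed GFAP moments under the plain linear convention give
  # t = 2.6752 at df 7 (note: this does not reproduce the printed 0.0118)
  gfap <- exact_moment_ratios(3.44, 2.58, 8)
  got <- peptide_t_test(gfap)
  expect_equal(got$t_statistic, 2.6752, tolerance = 1e-4)
  expect_equal(got$p_value, t_upper_tail_quad(got$t_statistic, 7), tolerance = 1e-10)

  set.seed(12)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    x <- stats::rlnorm(n, stats::rnorm(1, 0, 0.3), 0.4)
    for (scale in c("linear", "log")) {
      got <- peptide_t_test(x, scale = scale)
      y <- if (scale == "log") log(x) else x
      null <- if (scale == "log") 0 else 1
      t_ref <- (mean(y) - null) / (stats::sd(y) / sqrt(n))
      p_ref <- if (n - 1 == 2) {
        if (t_ref >= 0) 1 - t_cdf_df2(t_ref) else t_cdf_df2(t_ref)
      } else if (t_ref >= 0) {
        t_upper_tail_quad(t_ref, n - 1)
      } else {
        1 - t_upper_tail_quad(t_ref, n - 1)
      }
      expect_equal(got$p_value, p_ref, tolerance = 1e-10)
      expect_gt(got$p_value, 0)
      expect_lte(got$p_value, 1)
    }
  }
})

test_that("p is monotone in effect size and in peptide count", {
  # strictly decreasing in |mean - null| at fixed sd and n
  base <- c(1.0, 1.2, 1.4)
  p1 <- peptide_t_test(base)$p_value
  p2 <- peptide_t_test(base + 0.3)$p_value
  expect_lt(p2, p1)
  # strictly decreasing in n at fixed mean and sd (mean != null)
  p_n3 <- peptide_t_test(exact_moment_ratios(1.4, 0.2, 4))$p_value
  p_n8 <- peptide_t_test(exact_moment_ratios(1.4, 0.2, 8))$p_value
  expect_lt(p_n8, p_n3)
})

test_that("reciprocal ratios flip the direction with identical p on the log scale", {
  set.seed(3)
  for (i in 1:10) {
    x <- stats::rlnorm(sample(3:8, 1), 0.3, 0.4)
    up <- peptide_t_test(x, scale = "log")
    down <- peptide_t_test(1 / x, scale = "log")
    expect_equal(up$p_value, down$p_value, tolerance = 1e-12)
    expect_equal(up$t_statistic, -down$t_statistic, tolerance = 1e-12)
    expect_true(up$direction != down$direction || up$direction == "null")
  }
})

test_that("degenerate inputs follow the stated conventions", {
  expect_equal(peptide_t_test(c(1.0, 1.0, 1.0))$p_value, 0.5) # mean at null
  expect_equal(peptide_t_test(c(0.8, 1.2))$p_value, 0.5) # mean exactly 1
  expect_warning(
    got <- peptide_t_test(c(2, 2, 2)),
    "zero spread"
  )
  expect_equal(got$p_value, .Machine$double.xmin)
  expect_equal(got$direction, "up")
  expect_error(peptide_t_test(c(1.5)), "insufficient peptides")
  expect_error(peptide_t_test(c(1.5, -1)), "positive")
})

test_that("a pre-specified tail gives the fixed one-sided tail probability", {
  x <- c(0.6, 0.7, 0.8)
  up <- peptide_t_test(x, tail = "upper")
  lo <- peptide_t_test(x, tail = "lower")
  expect_equal(up$p_value + lo$p_value, 1, tolerance = 1e-12)
  expect_gt(up$p_value, 0.5) # mean below null: upper tail is large
  expect_equal(lo$p_value, peptide_t_test(x)$p_value) # adaptive picked the lower tail
})

test_that("summarize_proteins covers every protein x contrast with data", {
  p <- peptide_tbl(list(
    A = list(
      "115/114" = c(1.2, 1.4), "116/114" = c(0.9, 1.0), "117/114" = c(1.1, 1.3)
    ),
    B = list(
      "115/114" = c(2.0, 2.2), "116/114" = c(1.5, 1.6), "117/114" = c(0.5, 0.6)
    ),
    C = list("115/114" = c(1.8, 2.0, 2.2)) # one contrast only
  ))
  got <- summarize_proteins(p)
  expect_equal(nrow(got), 7) # 2 proteins x 3 contrasts + 1
  expect_equal(sum(got$accession == "C"), 1)
  expect_equal(got$contrast[got$accession == "C"], "115/114")
  expect_true(all(c("p_value", "p_adjusted", "direction", "timepoint") %in% names(got)))
  expect_true(all(got$direction %in% c("up", "down", "null")))
})

test_that("summarize_proteins p-values agree with the scalar test and the t oracle", {
  set.seed(21)
  p <- random_peptides(10, max_peptides = 8, missing_frac = 0)
  for (scale in c("linear", "log")) {
    got <- summarize_proteins(p, scale = scale)
    col <- "ratio_115_114"
    for (acc in unique(p$accession)) {
      row <- got[got$accession == acc & got$contrast == "115/114", ]
      v <- p[[col]][p$accession == acc]
      if (length(v) < 2) {
        expect_true(is.na(row$p_value))
      } else {
        ref <- peptide_t_test(v, scale = scale)
        expect_equal(row$p_value, ref$p_value, tolerance = 1e-12)
        t_ref <- ref$t_statistic
        p_ref <- if (t_ref >= 0) {
          t_upper_tail_quad(t_ref, length(v) - 1)
        } else {
          1 - t_upper_tail_quad(t_ref, length(v) - 1)
        }
        expect_equal(row$p_value, p_ref, tolerance = 1e-10)
      }
    }
  }
})

test_that("single-peptide proteins carry no p-value but keep their rollup", {
  p <- peptide_tbl(list(A = list("115/114" = 2.0)))
  got <- summarize_proteins(p)
  expect_equal(got$mean_ratio, 2.0)
  expect_true(is.na(got$p_value))
  expect_equal(got$direction, "up")
})
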