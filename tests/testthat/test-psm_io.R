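write_toy_table <- function(lines, path = withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())) {
  header <- paste(
    c(
      "accession", "protein_name", "peptide_sequence", "ion_score_ci",
      "peptide_rank", "ratio_115_114", "ratio_116_114", "ratio_117_114"
    ),
    collapse = "\t"
  )
  writeLines(c(header, lines), path)
  path
}

test_that("read_peptide_table applies the ion-score and rank thresholds", {
  path <- write_toy_table(c(
    "A\tprot A\tPEPK\t99\t1\t1.2\t1.0\t0.8",
    "B\tprot B\tPEPR\t80\t1\t1.1\t1.0\t0.9", # below default min_ci 95
    "C\tprot C\tPEPA\t95\t1\t2.0\t1.5\t0.5", # boundary: kept
    "D\tprot D\tPEPL\t99\t2\t1.3\t1.1\t0.7", # rank 2: dropped at max_rank 1
    "E\tprot E\tPEPM\t96\t1\t0.9\t1.2\t1.1"
  ))
  got <- read_peptide_table(path)
  expect_equal(got$accession, c("A", "C", "E")) # file order preserved
  # relaxing the thresholds returns supersets; tightening returns subsets
  all_rows <- read_peptide_table(path, min_ci = 0, max_rank = 99)
  expect_equal(nrow(all_rows), 5)
  for (ci in c(0, 80, 95, 96, 99)) {
    expect_true(all(
      read_peptide_table(path, min_ci = ci + 1, max_rank = 99)$accession %in%
        read_peptide_table(path, min_ci = ci, max_rank = 99)$accession
    ))
  }
})

test_that("missing or unparseable ratio cells become NA, never zero", {
  path <- write_toy_table(c(
    "A\tprot A\tPEPK\t99\t1\t1.2\t\t0.8",
    "B\tprot B\tPEPR\t99\t1\t1.1\tnot-a-number\t0.9"
  ))
  got <- read_peptide_table(path)
  expect_equal(nrow(got), 2)
  expect_true(all(is.na(got$ratio_116_114)))
  expect_false(any(got$ratio_116_114 %in% 0))
})

test_that("format and validation errors name the offending column / row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tprotein_name\tratio_115_114", "A\tp\t1.0"), path)
  expect_error(read_peptide_table(path), "peptide_sequence")

  bad <- write_toy_table(c(
    "A\tprot A\tPEPK\t99\t1\t1.2\t1.0\t0.8",
    "B\tprot B\tPEPR\t99\t1\t-0.5\t1.0\t0.9"
  ))
  expect_error(read_peptide_table(bad), "ratio_115_114.*row 2")
})

test_that("peptide tables round-trip exactly through write/read", {
  p <- peptide_tbl(list(
    ACC1 = list("115/114" = c(2.0, 1.0, 0.5), "116/114" = c(1.25, NA, 0.3))
  ))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(p, f1)
  back <- read_peptide_table(f1, min_ci = 0, max_rank = 99)
  expect_equal(back$ratio_115_114, c(2.0, 1.0, 0.5))
  expect_equal(back$ratio_116_114, c(1.25, NA, 0.3))
  # byte-identical on re-serialization (idempotent writer)
  write_peptide_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("write_protein_table renders the published row format", {
  s <- tibble::tibble(
    accession = c("158186732", "9506535"),
    protein_name = c("Glial fibrillary acidic protein", "Diacylglycerol kinase beta"),
    contrast = "115/114",
    mean_ratio = c(3.44, 0.57),
    sd = c(2.58, 0.2),
    n_peptides = c(8L, 4L),
    p_value = c(0.0118, 0.0192),
    direction = c("up", "down")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(s, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  # down block precedes up block
  expect_match(lines[2], "^Diacylglycerol")
  expect_match(lines[3], "3\\.44\t2\\.58\t8\t0\\.0118\tup$")
})

test_that("write_protein_table sorts down then up, each ascending by mean", {
  s <- tibble::tibble(
    accession = sprintf("A%d", 1:6),
    protein_name = sprintf("protein %d", 1:6),
    contrast = "116/114",
    mean_ratio = c(1.9, 0.6, 1.3, 0.7, 0.5, 1.5),
    sd = 0.1, n_peptides = 4L, p_value = 0.01,
    direction = c("up", "down", "up", "down", "down", "up")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(s, path)
  got <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(got$mean_ratio, c(0.5, 0.6, 0.7, 1.3, 1.5, 1.9))
  expect_equal(got$direction, c(rep("down", 3), rep("up", 3)))
  # round trip recovers every field at the stated rounding
  expect_equal(got$accession, s$accession[order(s$direction == "up", s$mean_ratio)])
  expect_equal(got$p_value, rep(0.01, 6))
})

test_that("an empty summary collection writes the header only", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(tibble::tibble(), path)
  expect_equal(
    readLines(path),
    "protein_name\taccession\tmean_ratio\tsd\tn_peptides\tp_value\tdirection"
  )
})

test_that("read_gmt parses terms, de-duplicates members and unions the background", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "growth of neurites\tna\tP1\tP2\tP3",
    "synaptic transmission\tna\tP2\tP2\tP4"
  ), path)
  ann <- read_gmt(path)
  expect_equal(ann$n_term, c(3L, 2L)) # second term's P2 duplicate collapsed
  expect_setequal(annotation_background(ann), c("P1", "P2", "P3", "P4"))
})

test_that("read_gmt rejects duplicate terms and out-of-background members", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("term A\tna\tP1", "term A\tna\tP2"), path)
  expect_error(read_gmt(path), "term A")

  path2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("term B\tna\tP1\tP9", path2)
  expect_error(read_gmt(path2, background = c("P1", "P2")), "P9")
  ok <- read_gmt(path2, background = c("P1", "P9", "P5"))
  expect_length(annotation_background(ok), 3)
})
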