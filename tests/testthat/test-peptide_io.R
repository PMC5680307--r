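test_that("peptide table round-trips through TSV with groups resolved", {
  tab <- toy_peptide_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tab, path)
  dat <- read_peptide_table(path, list(case_ids = c("s1", "s2"),
                                       control_ids = c("s3", "s4")))
  expect_equal(dat$peptides, tab)
  expect_length(dat$groups$case_ids, 2)
  expect_length(dat$groups$control_ids, 2)

  # full-precision abundances survive a write/read cycle
  tab$s1 <- c(1 / 3, pi, exp(-20))
  write_peptide_table(tab, path)
  back <- read_peptide_table(path, toy_groups())
  expect_identical(back$peptides$s1, tab$s1)
  expect_identical(back$peptides$start, tab$start) # no silent renumbering
})

test_that("blank abundance cells are read as zero (absent signal)", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\tsequence\taccession\tstart\tstop\ts1\ts2",
               "p1\tACDEF\tP00001\t2\t6\t\t4.5"), path)
  dat <- read_peptide_table(path, list(case_ids = "s1", control_ids = "s2"))
  expect_identical(dat$peptides$s1, 0)
  expect_identical(dat$peptides$s2, 4.5)
})

test_that("malformed tables are rejected with the offending row named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\tsequence\taccession\tstart\tstop\ts1\ts2",
               "bad_pep\tACD\tP00001\t5\t3\t1\t2"), path)
  expect_error(read_peptide_table(path, list(case_ids = "s1", control_ids = "s2")),
               "bad_pep")

  writeLines(c("peptide_id\tsequence\taccession\tstart\tstop\ts1\ts2",
               "p1\tACD\tP00001\t1\t3\t1\t2",
               "p1\tACD\tP00001\t1\t3\t1\t2"), path)
  expect_error(read_peptide_table(path, list(case_ids = "s1", control_ids = "s2")),
               "duplicate peptide_id")

  # sequence length inconsistent with the coordinate span
  writeLines(c("peptide_id\tsequence\taccession\tstart\tstop\ts1\ts2",
               "p9\tACDE\tP00001\t1\t3\t1\t2"), path)
  expect_error(read_peptide_table(path, list(case_ids = "s1", control_ids = "s2")),
               "p9")
})

test_that("unknown samples in the group config are a hard error", {
  tab <- toy_peptide_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tab, path)
  expect_error(
    read_peptide_table(path, list(case_ids = c("s1", "ghost"),
                                  control_ids = c("s3", "s4"))),
    "ghost"
  )
})

test_that("groups can come from a two-column file or YAML", {
  tab <- toy_peptide_table()
  pep_path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tab, pep_path)

  gpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "s1\tcase", "s2\tcase",
               "s3\tcontrol", "s4\tcontrol"), gpath)
  dat <- read_peptide_table(pep_path, gpath)
  expect_setequal(dat$groups$case_ids, c("s1", "s2"))

  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("case_ids: [s1, s2]", "control_ids: [s3, s4]"), ypath)
  dat2 <- read_peptide_table(pep_path, ypath)
  expect_setequal(dat2$groups$control_ids, c("s3", "s4"))
})

test_that("sample_groups enforces disjoint non-empty groups", {
  expect_error(sample_groups(character(0), "a"), "non-empty")
  expect_error(sample_groups(c("a", "b"), c("b", "c")), "disjoint")
  expect_s3_class(sample_groups("a", "b"), "sample_groups")
})

test_that("FASTA accessions follow the first-token and UniProt dialects", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P01009|A1AT_HUMAN some description", "MPSSV"), path)
  expect_identical(read_fasta(path), c(P01009 = "MPSSV"))

  writeLines(c(">P02452", "GAPG"), path)
  expect_identical(read_fasta(path), c(P02452 = "GAPG"))

  writeLines(c(">sp|P01009|A1AT_HUMAN", "MPSSV", ">P01009", "GAPG"), path)
  expect_error(read_fasta(path), "duplicate accession")

  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")

  writeLines(c(">P1", "MPZQ"), path)
  expect_error(read_fasta(path), "non-standard")
})

test_that("cleavage DB keeps only observed evidence classes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protease\tsubstrate_accession\tp1_position\tevidence",
    "MMP9\tP02452\t775\tobserved",
    "MMP9\tP02452\t780\tObserved in different substrate",
    "CTSD\tP01009\t44\tOBSERVED",
    "CTSD\tP01009\t60\tobserved_different_substrate",
    "KLK4\tP01009\t10\thigh_probability"
  ), path)
  expect_warning(db <- read_cleavage_db(path), "dropped 1")
  expect_equal(nrow(db), 4)
  expect_setequal(unique(db$evidence),
                  c("observed", "observed_different_substrate"))

  writeLines("protease\tsubstrate_accession\tp1_position\tevidence", path)
  expect_warning(empty <- read_cleavage_db(path), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("evidence table reader normalizes and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protease\tsource\tdirection",
               "CTSD\tTranscriptomics\tIncrease",
               "MMP-9\tprotein_expression\tno change"), path)
  ev <- read_evidence(path)
  expect_identical(ev$direction, c("increase", "no_change"))
  writeLines(c("protease\tsource\tdirection",
               "CTSD\ttranscriptomics\tsideways"), path)
  expect_error(read_evidence(path), "direction")
})
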