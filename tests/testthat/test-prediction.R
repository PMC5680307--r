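seqs_fixture <- c(
  P10 = "ABCDEFGHIJ", # only used via extract_site_context in examples below
  PA = paste(rep("ACDEFGHIKL", 10), collapse = ""),
  PB = paste(rep("MNPQRSTVWY", 10), collapse = "")
)

test_that("cleavage events follow the terminus conventions", {
  seqs <- c(PX = strrep("A", 100))
  pep <- function(start, stop, id = "p") {
    tibble::tibble(peptide_id = id, sequence = "", accession = "PX",
                   start = as.integer(start), stop = as.integer(stop))
  }
  # whole-protein fragment records no cleavage at all
  expect_equal(nrow(derive_cleavage_events(pep(1, 100), seqs)), 0)

  ev <- derive_cleavage_events(pep(10, 20), seqs)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$p1_position[ev$terminus == "N"], 9L)
  expect_equal(ev$p1_position[ev$terminus == "C"], 20L)

  ev1 <- derive_cleavage_events(pep(1, 20), seqs)
  expect_equal(nrow(ev1), 1)
  expect_identical(ev1$terminus, "C")
  expect_equal(ev1$p1_position, 20L)

  expect_error(derive_cleavage_events(pep(10, 150, id = "too_long"), seqs),
               "too_long")
  expect_warning(
    none <- derive_cleavage_events(
      tibble::tibble(peptide_id = "p", sequence = "", accession = "GHOST",
                     start = 2L, stop = 5L), seqs),
    "GHOST"
  )
  expect_equal(nrow(none), 0)
})

test_that("site context octamer extraction pads protein ends with dashes", {
  s <- "ABCDEFGHIJ"
  expect_identical(extract_site_context(s, 5), "BCDEFGHI")
  expect_identical(extract_site_context(s, 2), "--ABCDEF")
  expect_identical(extract_site_context(s, 9), "FGHIJ---")
  expect_error(extract_site_context(s, 10), "p1_position")
  expect_error(extract_site_context(s, 0), "p1_position")
  # configurable window
  expect_identical(extract_site_context(s, 5, window = 2), "DEFG")
})

test_that("same-substrate and cross-substrate matches behave per definition", {
  # PA and PB repeat 10-mers, so identical octamers exist across substrates
  seqs <- c(PA = seqs_fixture[["PA"]], PB = seqs_fixture[["PB"]],
            PC = seqs_fixture[["PA"]]) # PC duplicates PA's sequence
  db <- tibble::tibble(
    protease = c("MMP9", "CTSD"),
    substrate_accession = c("PA", "PC"),
    p1_position = c(20L, 35L),
    evidence = "observed"
  )
  peptides <- tibble::tibble(
    peptide_id = c("pep_same", "pep_cross"),
    sequence = "", accession = c("PA", "PA"),
    start = c(21L, 36L), stop = c(30L, 45L)
  )
  ev <- derive_cleavage_events(peptides, seqs)
  hits <- match_proteases(ev, db, seqs)

  same <- hits[hits$peptide_id == "pep_same" & hits$protease == "MMP9", ]
  expect_equal(nrow(same), 1)
  expect_identical(same$match_mode, "same_substrate")

  # pep_cross N-terminal event at PA:35 matches CTSD's site on PC (same
  # octamer, different substrate)
  cross <- hits[hits$peptide_id == "pep_cross" & hits$protease == "CTSD", ]
  expect_equal(nrow(cross), 1)
  expect_identical(cross$match_mode, "cross_substrate")
})

test_that("both termini matching one protease deduplicate to one association", {
  set.seed(1)
  seqs <- c(PX = paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 60,
                              replace = TRUE), collapse = ""))
  db <- tibble::tibble(
    protease = "CTSD",
    substrate_accession = "PX",
    p1_position = c(9L, 20L),
    evidence = "observed"
  )
  pep <- tibble::tibble(peptide_id = "p", sequence = "", accession = "PX",
                        start = 10L, stop = 20L)
  hits <- match_proteases(derive_cleavage_events(pep, seqs), db, seqs)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$match_mode, "same_substrate")
})

test_that("matcher agrees with the nested-loop oracle on random fixtures", {
  set.seed(303)
  for (rep in 1:10) {
    n_prot <- 4
    accs <- sprintf("RP%02d", seq_len(n_prot))
    seqs <- vapply(accs, function(a) {
      paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 120,
                   replace = TRUE), collapse = "")
    }, character(1))
    db <- tibble::tibble(
      protease = sample(c("MMP9", "CTSD", "KLK4"), 12, replace = TRUE),
      substrate_accession = sample(accs, 12, replace = TRUE),
      p1_position = sample(10:90, 12),
      evidence = "observed"
    )
    peptides <- tibble::tibble(
      peptide_id = sprintf("pep%02d", 1:15),
      sequence = "",
      accession = sample(accs, 15, replace = TRUE),
      start = sample(5:80, 15, replace = TRUE)
    )
    peptides$stop <- peptides$start + sample(8:20, 15, replace = TRUE)
    # steer some termini onto DB sites so same-substrate hits actually occur
    for (k in 1:5) {
      peptides$accession[k] <- db$substrate_accession[k]
      peptides$start[k] <- db$p1_position[k] + 1L
      peptides$stop[k] <- peptides$start[k] + 10L
    }
    ev <- derive_cleavage_events(peptides, seqs)
    got <- match_proteases(ev, db, seqs)
    want <- match_brute(ev, db, seqs)
    got_keys <- sort(paste(got$protease, got$peptide_id, got$match_mode))
    want_keys <- sort(paste(want$protease, want$peptide_id, want$match_mode))
    expect_identical(got_keys, want_keys)
  }
})

test_that("restricting the DB restricts associations monotonically", {
  set.seed(404)
  accs <- sprintf("RP%02d", 1:3)
  seqs <- vapply(accs, function(a) {
    paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 150,
                 replace = TRUE), collapse = "")
  }, character(1))
  db <- tibble::tibble(
    protease = rep(c("MMP9", "CTSD", "KLK4"), each = 4),
    substrate_accession = sample(accs, 12, replace = TRUE),
    p1_position = sample(20:120, 12),
    evidence = "observed"
  )
  peptides <- tibble::tibble(
    peptide_id = sprintf("pep%02d", 1:12), sequence = "",
    accession = db$substrate_accession,
    start = db$p1_position + 1L,
    stop = db$p1_position + 11L
  )
  ev <- derive_cleavage_events(peptides, seqs)
  full <- match_proteases(ev, db, seqs)
  sub <- match_proteases(ev, db[db$protease != "MMP9", ], seqs)
  expect_false("MMP9" %in% sub$protease)
  expect_true(all(paste(sub$protease, sub$peptide_id) %in%
                    paste(full$protease, full$peptide_id)))
})
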