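#' Packaged reference fixture: published protease score table
#'
#' The package ships the published diabetic-nephropathy protease table as
#' plain-text fixtures: per-protease counts of down-/up-regulated associated
#' urinary peptides for the 17 proteases that passed the >= 3-peptide
#' reporting threshold, the association totals over all 30 pre-threshold
#' proteases (n_up = 93, n_down = 42, summing to the 135 regulated
#' associations), the printed %freq/score values, and the transcript- and
#' protein-level direction evidence columns.
#'
#' @return `table3_counts()`: tibble `protease`, `occ_down`, `occ_up`.
#'   `table3_totals()`: list with `n_up`, `n_down`.
#'   `table3_printed()`: tibble `protease`, `pct_freq`, `score`.
#'   `table3_evidence()`: tibble `protease`, `source`, `direction`.
#' @name table3_fixture
NULL

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "proteact")
  if (!nzchar(path)) abort(paste0("packaged fixture not found: ", file))
  path
}

#' @rdname table3_fixture
#' @export
table3_counts <- function() {
  readr::read_tsv(extdata_path("table3_counts.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname table3_fixture
#' @export
table3_totals <- function() {
  tab <- readr::read_tsv(extdata_path("table3_totals.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  as.list(stats::setNames(as.integer(tab$value), tab$quantity))
}

#' @rdname table3_fixture
#' @export
table3_printed <- function() {
  readr::read_tsv(extdata_path("table3_printed.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname table3_fixture
#' @export
table3_evidence <- function() {
  read_evidence(extdata_path("table3_evidence.tsv"))
}

#' Recompute the published score table and diff against the printed values
#'
#' Recomputes every activity score from the packaged per-protease occurrence
#' counts and association totals, applies display rounding (score to 2
#' decimals, %freq to the nearest integer) and compares row by row with the
#' printed values.
#'
#' @param counts Occurrence tibble (`protease`, `occ_down`, `occ_up`);
#'   defaults to the packaged fixture.
#' @param totals List with `n_up`, `n_down`; defaults to the packaged
#'   fixture.
#' @param printed Printed reference (`protease`, `pct_freq`, `score`);
#'   defaults to the packaged fixture.
#' @return Tibble with recomputed and printed values plus logical
#'   `score_match` / `pct_freq_match` per protease; attribute `all_match`
#'   gives the overall verdict.
#' @export
recompute_table3 <- function(counts = table3_counts(),
                             totals = table3_totals(),
                             printed = table3_printed()) {
  scores <- activity_score(counts$occ_up, counts$occ_down,
                           totals$n_up, totals$n_down,
                           protease = counts$protease)
  recomputed <- format_score_table(scores)
  diff <- dplyr::inner_join(
    recomputed,
    dplyr::select(printed, "protease", printed_pct_freq = "pct_freq",
                  printed_score = "score"),
    by = "protease"
  )
  diff$pct_freq_match <- diff$pct_freq == diff$printed_pct_freq
  diff$score_match <- diff$score == diff$printed_score
  attr(diff, "all_match") <- all(diff$pct_freq_match & diff$score_match) &&
    nrow(diff) == nrow(printed)
  diff
}
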