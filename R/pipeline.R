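#' Run the full protease-activity pipeline on files
#'
#' Chains the stages: read inputs, differential peptide testing, cleavage
#' event derivation, protease matching, activity scoring with the reporting
#' threshold, and (when evidence is supplied) cross-omics concordance.
#' Writes `differential.tsv`, `associations.tsv`, `scores.tsv`,
#' `scores.json`, `concordance.tsv`/`concordance.json` and `report.json`
#' (stage counts, package version, full config echo) under `out_dir`.
#' All outputs are deterministic functions of the inputs.
#'
#' @param peptide_table Path to the peptide abundance table.
#' @param fasta Path to the parent-protein FASTA.
#' @param cleavage_db Path to the cleavage-site table.
#' @param groups Group specification (see [read_peptide_table()]).
#' @param evidence Optional path to an evidence-direction table.
#' @param out_dir Output directory, created if needed.
#' @param alpha,fc_up,fc_down Differential thresholds.
#' @param min_peptides Reporting threshold on associated regulated peptides.
#' @param window Site-context half-width for cross-substrate matching.
#' @return The run report, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(peptide_table, fasta, cleavage_db, groups,
                         evidence = NULL, out_dir = ".",
                         alpha = 0.05, fc_up = 1.5, fc_down = 0.66,
                         min_peptides = 3, window = 4) {
  for (p in c(peptide_table, fasta, cleavage_db,
              if (is.character(groups)) groups,
              evidence)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  dat <- stage("read", read_peptide_table(peptide_table, groups))
  sequences <- stage("read", read_fasta(fasta))
  db <- stage("read", read_cleavage_db(cleavage_db))
  ev <- if (!is.null(evidence)) stage("read", read_evidence(evidence))

  diffs <- stage("differential",
                 select_regulated(dat$peptides, dat$groups,
                                  alpha = alpha, fc_up = fc_up,
                                  fc_down = fc_down))
  write_differential(diffs, file.path(out_dir, "differential.tsv"))

  events <- stage("predict", derive_cleavage_events(dat$peptides, sequences))
  reg_ids <- diffs$peptide_id[diffs$direction %in% c("up", "down")]
  assoc <- stage("predict",
                 match_proteases(events[events$peptide_id %in% reg_ids, ],
                                 db, sequences, window = window))
  write_associations(assoc, file.path(out_dir, "associations.tsv"))

  scores <- NULL
  if (nrow(assoc) > 0) {
    scores <- stage("score", score_proteases(assoc, diffs,
                                             min_peptides = min_peptides))
    write_scores(scores,
                 tsv_path = file.path(out_dir, "scores.tsv"),
                 json_path = file.path(out_dir, "scores.json"))
  } else {
    write_scores(list(table = activity_score(integer(0), integer(0), 1, 1,
                                             protease = character(0)),
                      n_up = 0L, n_down = 0L),
                 tsv_path = file.path(out_dir, "scores.tsv"),
                 json_path = file.path(out_dir, "scores.json"))
  }

  conc <- NULL
  if (!is.null(ev) && !is.null(scores)) {
    conc <- stage("concordance", concordance(scores$table, ev))
    write_concordance(conc,
                      tsv_path = file.path(out_dir, "concordance.tsv"),
                      json_path = file.path(out_dir, "concordance.json"))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("proteact")),
    config = list(alpha = alpha, fc_up = fc_up, fc_down = fc_down,
                  min_peptides = min_peptides, window = window,
                  inputs = list(peptide_table = peptide_table, fasta = fasta,
                                cleavage_db = cleavage_db,
                                evidence = evidence)),
    counts = list(
      peptides_detected = nrow(dat$peptides),
      samples_case = length(dat$groups$case_ids),
      samples_control = length(dat$groups$control_ids),
      regulated_up = sum(diffs$direction == "up"),
      regulated_down = sum(diffs$direction == "down"),
      cleavage_events = nrow(events),
      associations = nrow(assoc),
      n_up = if (is.null(scores)) 0L else scores$n_up,
      n_down = if (is.null(scores)) 0L else scores$n_down,
      proteases_predicted = if (is.null(scores)) 0L else nrow(scores$all),
      proteases_reported = if (is.null(scores)) 0L else nrow(scores$table)
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
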