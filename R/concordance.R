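#' Cross-omics concordance of predicted protease activity
#'
#' Compares the predicted activity direction of each scored protease
#' (activated when score > 0, otherwise deactivated) with external direction
#' evidence per source. Verdicts: `agree` when activated meets `increase` or
#' deactivated meets `decrease`; `oppose` when crossed; `no_change` and
#' `inconclusive` evidence pass through; absent evidence yields `missing`.
#' Evidence on proteases absent from the score table is kept with a
#' `missing` predicted direction and a warning.
#'
#' @param score_table Ranked score tibble (e.g. `score_proteases()$table`).
#' @param evidence Evidence tibble from [read_evidence()].
#' @return List with `records` (tibble: `protease`, `predicted`, `source`,
#'   `evidence_direction`, `verdict`) and `summary` (tibble of verdict
#'   counts per source, excluding `missing`-evidence rows).
#' @export
concordance <- function(score_table, evidence) {
  predicted <- tibble(
    protease = score_table$protease,
    predicted = ifelse(score_table$score > 0, "activated", "deactivated")
  )
  unscored <- setdiff(unique(evidence$protease), predicted$protease)
  if (length(unscored) > 0) {
    warn(paste0("evidence for protease(s) not in the score table: ",
                paste(unscored, collapse = ", ")))
  }

  grid <- tidyr::expand_grid(
    protease = predicted$protease,
    source = EVIDENCE_SOURCES
  )
  grid <- dplyr::left_join(grid, predicted, by = "protease")
  extra <- dplyr::distinct(
    evidence[evidence$protease %in% unscored, c("protease", "source")]
  )
  if (nrow(extra) > 0) {
    extra$predicted <- "missing"
    grid <- dplyr::bind_rows(grid, extra)
  }
  grid <- dplyr::left_join(
    grid,
    dplyr::select(evidence, "protease", "source",
                  evidence_direction = "direction"),
    by = c("protease", "source")
  )
  grid$evidence_direction[is.na(grid$evidence_direction)] <- "missing"
  grid$verdict <- verdict_of(grid$predicted, grid$evidence_direction)

  informative <- grid[grid$evidence_direction != "missing" &
                        grid$predicted != "missing", , drop = FALSE]
  summary <- dplyr::summarise(
    dplyr::group_by(informative, .data$source),
    agree = sum(.data$verdict == "agree"),
    oppose = sum(.data$verdict == "oppose"),
    inconclusive = sum(.data$verdict == "inconclusive"),
    no_change = sum(.data$verdict == "no_change"),
    .groups = "drop"
  )
  list(records = grid, summary = summary)
}

verdict_of <- function(predicted, direction) {
  out <- character(length(predicted))
  out[direction == "missing" | predicted == "missing"] <- "missing"
  out[direction == "inconclusive" & predicted != "missing"] <- "inconclusive"
  out[direction == "no_change" & predicted != "missing"] <- "no_change"
  act <- predicted == "activated"
  deact <- predicted == "deactivated"
  out[act & direction == "increase"] <- "agree"
  out[deact & direction == "decrease"] <- "agree"
  out[act & direction == "decrease"] <- "oppose"
  out[deact & direction == "increase"] <- "oppose"
  out
}

#' Write concordance output (TSV records plus JSON summary)
#'
#' @param result List from [concordance()].
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the list of written paths.
#' @export
write_concordance <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    readr::write_tsv(result$records, tsv_path, progress = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(result$summary, json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
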