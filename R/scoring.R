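#' Count up/down-regulated associated peptides per protease
#'
#' For each protease, the number of unique associated peptides called `up`
#' and the number called `down`. Associations to `unchanged` peptides are
#' ignored; proteases without any up/down association are absent from the
#' output.
#'
#' @param associations Tibble from [match_proteases()].
#' @param differential_results Tibble from [select_regulated()] covering
#'   every associated peptide (an association to an unknown peptide is an
#'   error).
#' @return Tibble with `protease`, `occ_up`, `occ_down`.
#' @export
count_occurrences <- function(associations, differential_results) {
  unknown <- setdiff(associations$peptide_id, differential_results$peptide_id)
  if (length(unknown) > 0) {
    abort(paste0("association references peptide(s) absent from results: ",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    dplyr::distinct(associations, .data$protease, .data$peptide_id),
    dplyr::select(differential_results, "peptide_id", "direction"),
    by = "peptide_id"
  )
  joined <- joined[joined$direction %in% c("up", "down"), , drop = FALSE]
  counts <- dplyr::summarise(
    dplyr::group_by(joined, .data$protease),
    occ_up = sum(.data$direction == "up"),
    occ_down = sum(.data$direction == "down"),
    .groups = "drop"
  )
  dplyr::arrange(counts, .data$protease)
}

#' Association totals across all predicted proteases
#'
#' `n_up` is the total number of up-regulated protease-peptide associations
#' summed over all predicted proteases before any reporting threshold, with
#' multiplicity (a peptide associated with k proteases contributes k);
#' `n_down` likewise. These are the score denominators.
#'
#' @param occurrence_counts Tibble from [count_occurrences()].
#' @return Named list with `n_up` and `n_down`.
#' @export
association_totals <- function(occurrence_counts) {
  n_up <- sum(occurrence_counts$occ_up)
  n_down <- sum(occurrence_counts$occ_down)
  if (n_up + n_down == 0) {
    abort("no regulated protease-peptide associations; cannot score")
  }
  list(n_up = n_up, n_down = n_down)
}

#' Per-protease activity score
#'
#' Computes, for each protease with occurrence counts `(occ_up, occ_down)`
#' against association totals `(n_up, n_down)`:
#' \deqn{weight = occ_{down}/n_{down} + occ_{up}/n_{up}}
#' \deqn{freq\%(up) = occ_{up}/n_{total} \cdot 100,\quad
#'       freq\%(down) = occ_{down}/n_{total} \cdot 100}
#' \deqn{\%freq = \frac{freq\%(up) - freq\%(down)}
#'                     {freq\%(up) + freq\%(down)} \cdot 100}
#' \deqn{Score = \%freq \cdot weight}
#' with `n_total = n_up + n_down`. A positive score predicts increased
#' proteolytic activity, a negative score predicts inhibition. All fields
#' are returned at full precision; display rounding (score to 2 decimals,
#' %freq to the nearest integer) is applied only when formatting output.
#'
#' @param occ_up,occ_down Integer vectors (same length), each pair with
#'   `occ_up + occ_down >= 1`.
#' @param n_up,n_down Scalar association totals with `n_up + n_down >= 1`,
#'   `n_up >= max(occ_up)` and `n_down >= max(occ_down)`. A total of 0 in
#'   one direction (no associations of that sign anywhere) zeroes that
#'   weight term.
#' @param protease Optional character vector of protease names carried
#'   through to the output.
#' @return Tibble with `protease` (if given), `occ_up`, `occ_down`,
#'   `weight`, `freq_up_pct`, `freq_down_pct`, `pct_freq`, `score`.
#' @export
activity_score <- function(occ_up, occ_down, n_up, n_down, protease = NULL) {
  if (length(occ_up) != length(occ_down)) {
    abort("occ_up and occ_down must have equal length")
  }
  if (n_up + n_down < 1) abort("association totals must be >= 1")
  if (any(occ_up + occ_down < 1)) {
    abort("each protease needs at least one regulated associated peptide")
  }
  if (any(occ_up > n_up) || any(occ_down > n_down)) {
    abort("occurrence counts cannot exceed the association totals")
  }
  n_total <- n_up + n_down
  # a direction with no associations at all contributes a zero weight term
  frac <- function(occ, n) if (n > 0) occ / n else occ * 0
  weight <- frac(occ_down, n_down) + frac(occ_up, n_up)
  freq_up_pct <- occ_up / n_total * 100
  freq_down_pct <- occ_down / n_total * 100
  pct_freq <- (freq_up_pct - freq_down_pct) / (freq_up_pct + freq_down_pct) * 100
  score <- pct_freq * weight
  out <- tibble(
    occ_up = as.integer(occ_up),
    occ_down = as.integer(occ_down),
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    weight = weight,
    freq_up_pct = freq_up_pct,
    freq_down_pct = freq_down_pct,
    pct_freq = pct_freq,
    score = score
  )
  if (!is.null(protease)) out <- dplyr::bind_cols(tibble(protease = protease), out)
  out
}

#' Apply the minimum-peptide reporting threshold and rank
#'
#' Retains proteases with at least `min_peptides` regulated associated
#' peptides (`occ_up + occ_down >= min_peptides`), then ranks: predicted
#' activated proteases (score > 0) first, descending by score; predicted
#' inhibited proteases after, ascending by score (strongest inhibition
#' first). Equal scores are ordered alphabetically by protease name.
#'
#' @param scores Tibble from [activity_score()] with a `protease` column.
#' @param min_peptides Minimum number of regulated associated peptides.
#' @return The filtered, ranked score tibble.
#' @export
filter_min_peptides <- function(scores, min_peptides = 3) {
  kept <- scores[scores$occ_up + scores$occ_down >= min_peptides, , drop = FALSE]
  activated <- kept[kept$score > 0, , drop = FALSE]
  rest <- kept[kept$score <= 0, , drop = FALSE]
  activated <- dplyr::arrange(activated, dplyr::desc(.data$score), .data$protease)
  rest <- dplyr::arrange(rest, .data$score, .data$protease)
  dplyr::bind_rows(activated, rest)
}

#' Score all predicted proteases from associations and differential calls
#'
#' Convenience chain: [count_occurrences()], [association_totals()],
#' [activity_score()], [filter_min_peptides()].
#'
#' @inheritParams count_occurrences
#' @inheritParams filter_min_peptides
#' @return List with `table` (ranked, thresholded score tibble), `all`
#'   (pre-threshold scores), `n_up`, `n_down`.
#' @export
score_proteases <- function(associations, differential_results, min_peptides = 3) {
  counts <- count_occurrences(associations, differential_results)
  totals <- association_totals(counts)
  scores <- activity_score(counts$occ_up, counts$occ_down,
                           totals$n_up, totals$n_down,
                           protease = counts$protease)
  list(
    table = filter_min_peptides(scores, min_peptides),
    all = scores,
    n_up = totals$n_up,
    n_down = totals$n_down
  )
}

#' Format a score table for reporting
#'
#' Applies the display rounding used in reports: `pct_freq` to the nearest
#' integer and `score` to 2 decimals.
#'
#' @param scores Score tibble.
#' @return Tibble with `protease`, `occ_down`, `occ_up`, `pct_freq`, `score`.
#' @export
format_score_table <- function(scores) {
  tibble(
    protease = scores$protease,
    occ_down = scores$occ_down,
    occ_up = scores$occ_up,
    pct_freq = round(scores$pct_freq),
    score = round(scores$score, 2)
  )
}

#' Write score output (display TSV plus full-precision JSON)
#'
#' @param result List from [score_proteases()].
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the list of written paths.
#' @export
write_scores <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    readr::write_tsv(format_score_table(result$table), tsv_path, progress = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_up = result$n_up, n_down = result$n_down,
           proteases = result$table),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
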