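#' Two-sided Mann-Whitney (rank-sum) p-value
#'
#' Compares two groups of abundances with the Wilcoxon-Mann-Whitney U test.
#' When the pooled sample size is at most `exact_max` and there are no ties,
#' the exact null distribution of U (enumeration over all labelings) is used;
#' otherwise the normal approximation with the midrank tie correction is
#' applied, without continuity correction.
#'
#' @param case_values,control_values Numeric vectors, both non-empty.
#' @param exact_max Largest pooled sample size for the exact branch.
#' @return Two-sided p-value in (0, 1].
#' @export
mann_whitney_p <- function(case_values, control_values, exact_max = 12) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    abort("mann_whitney_p: both groups must be non-empty")
  }
  pooled <- c(case_values, control_values)
  if (anyNA(pooled)) abort("mann_whitney_p: NA abundances not allowed")
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- (length(pooled) <= exact_max) && !has_ties
  res <- suppressWarnings(stats::wilcox.test(
    case_values, control_values,
    alternative = "two.sided", exact = use_exact, correct = FALSE
  ))
  min(res$p.value, 1)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Returns FDR-adjusted p-values in the input order: sort ascending, take
#' `p_(i) * m / i`, enforce monotonicity by a cumulative minimum from the
#' largest rank down, and cap at 1.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Group-mean fold change
#'
#' Ratio of case mean to control mean of raw (not log) abundances.
#' Returns `Inf` when the control mean is 0 and the case mean positive, and
#' `NA` (undefined; excluded from regulation calls) when both means are 0.
#'
#' @param case_values,control_values Non-negative numeric vectors.
#' @return Positive real, `Inf`, or `NA`.
#' @export
fold_change <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0) {
    abort("fold_change: both groups must be non-empty")
  }
  m_case <- mean(case_values)
  m_ctrl <- mean(control_values)
  if (m_ctrl == 0 && m_case == 0) return(NA_real_)
  if (m_ctrl == 0) return(Inf)
  m_case / m_ctrl
}

#' Differential peptide analysis between two sample groups
#'
#' Scores every peptide with the Mann-Whitney test, adjusts p-values by
#' Benjamini-Hochberg, computes the case/control fold change on group means,
#' and calls the regulation direction: `up` when `adjusted_p < alpha` and
#' `fold_change > fc_up`; `down` when `adjusted_p < alpha` and
#' `fold_change < fc_down`; `unchanged` otherwise. Gates are applied to the
#' adjusted p-value only, never the raw one. The asymmetric default gate pair
#' (1.5, 0.66) is deliberate and not symmetrized.
#'
#' @param peptides Peptide tibble (see [read_peptide_table()]).
#' @param groups A [sample_groups] object.
#' @param alpha Adjusted-p significance threshold.
#' @param fc_up Fold-change threshold for up-regulation (exclusive).
#' @param fc_down Fold-change threshold for down-regulation (exclusive).
#' @return Tibble with `peptide_id`, `p_value`, `adjusted_p`, `fold_change`,
#'   `direction`.
#' @export
select_regulated <- function(peptides, groups, alpha = 0.05,
                             fc_up = 1.5, fc_down = 0.66) {
  stopifnot(inherits(groups, "sample_groups"))
  if (fc_down >= 1 || fc_up <= 1) abort("need fc_down < 1 < fc_up")
  if (length(groups$case_ids) < 3 || length(groups$control_ids) < 3) {
    warn("fewer than 3 samples in a group; rank-sum p-values will be coarse")
  }
  case_mat <- as.matrix(peptides[, groups$case_ids, drop = FALSE])
  ctrl_mat <- as.matrix(peptides[, groups$control_ids, drop = FALSE])
  n <- nrow(peptides)
  p <- numeric(n)
  fc <- numeric(n)
  for (i in seq_len(n)) {
    p[i] <- mann_whitney_p(case_mat[i, ], ctrl_mat[i, ])
    fc[i] <- fold_change(case_mat[i, ], ctrl_mat[i, ])
  }
  padj <- benjamini_hochberg(p)
  direction <- rep("unchanged", n)
  sig <- padj < alpha & !is.na(fc)
  direction[sig & fc > fc_up] <- "up"
  direction[sig & fc < fc_down] <- "down"
  tibble(
    peptide_id = peptides$peptide_id,
    p_value = p,
    adjusted_p = padj,
    fold_change = fc,
    direction = direction
  )
}

#' Write differential results to TSV
#'
#' @param results Tibble from [select_regulated()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
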