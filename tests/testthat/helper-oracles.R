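# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# Step-up FDR adjustment built directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(sorted[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact two-sided rank-sum p-value by full enumeration of all C(n+m, n)
# group labelings of the pooled values. Tie-free inputs only.
mw_exact_brute <- function(case_values, control_values) {
  pooled <- c(case_values, control_values)
  n <- length(case_values)
  u_stat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- u_stat(seq_len(n))
  all_u <- apply(utils::combn(length(pooled), n), 2, u_stat)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Nested-loop protease matcher: every event against every DB row, then
# naive deduplication preferring same-substrate matches.
match_brute <- function(events, db, sequences, window = 4) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    ev_ctx <- extract_site_context(sequences[[ev$substrate_accession]],
                                   ev$p1_position, window)
    for (j in seq_len(nrow(db))) {
      entry <- db[j, ]
      mode <- NULL
      if (entry$substrate_accession == ev$substrate_accession &&
          entry$p1_position == ev$p1_position) {
        mode <- "same_substrate"
      } else if (entry$substrate_accession %in% names(sequences) &&
                 entry$substrate_accession != ev$substrate_accession) {
        db_ctx <- extract_site_context(sequences[[entry$substrate_accession]],
                                       entry$p1_position, window)
        if (db_ctx == ev_ctx) mode <- "cross_substrate"
      }
      if (!is.null(mode)) {
        rows[[length(rows) + 1]] <- data.frame(
          peptide_id = ev$peptide_id, protease = entry$protease,
          match_mode = mode, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(peptide_id = character(), protease = character(),
                      match_mode = character()))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$protease, hits$peptide_id,
                     hits$match_mode != "same_substrate"), ]
  hits[!duplicated(hits[, c("protease", "peptide_id")]), ]
}

# Small valid peptide table shared across io/pipeline tests.
toy_peptide_table <- function() {
  tibble::tibble(
    peptide_id = c("p1", "p2", "p3"),
    sequence = c("ACDEF", "GHIKL", "MNPQR"),
    accession = c("P00001", "P00001", "P00002"),
    start = c(2L, 10L, 5L),
    stop = c(6L, 14L, 9L),
    s1 = c(10, 0, 3.5),
    s2 = c(12.25, 1, 0),
    s3 = c(1, 8, 2),
    s4 = c(0.5, 9, 1)
  )
}

toy_groups <- function() sample_groups(c("s1", "s2"), c("s3", "s4"))
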