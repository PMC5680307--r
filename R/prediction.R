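#' Derive cleavage events from peptide termini
#'
#' A naturally occurring peptide records up to two in vivo cleavage events:
#' an N-terminal event at `p1 = start - 1` (absent when the peptide starts
#' at the parent's first residue) and a C-terminal event at `p1 = stop`
#' (absent when the peptide ends at the parent's last residue). `p1` is the
#' 1-based position of the residue immediately N-terminal to the scissile
#' bond.
#'
#' @param peptides Peptide tibble with `peptide_id`, `accession`, `start`,
#'   `stop`.
#' @param sequences Named character vector of parent sequences
#'   (see [read_fasta()]). Peptides on accessions absent from `sequences`
#'   are skipped with a warning.
#' @return Tibble with `peptide_id`, `terminus` (`"N"`/`"C"`),
#'   `substrate_accession`, `p1_position`.
#' @export
derive_cleavage_events <- function(peptides, sequences) {
  known <- peptides$accession %in% names(sequences)
  if (any(!known)) {
    warn(sprintf("skipping %d peptide(s) on accession(s) absent from FASTA: %s",
                 sum(!known),
                 paste(utils::head(unique(peptides$accession[!known]), 5),
                       collapse = ", ")))
    peptides <- peptides[known, , drop = FALSE]
  }
  parent_len <- nchar(sequences[peptides$accession])
  over <- peptides$stop > parent_len
  if (any(over)) {
    abort(paste0(
      "peptide stop exceeds parent length for peptide_id: ",
      paste(peptides$peptide_id[utils::head(which(over), 5)], collapse = ", ")
    ))
  }
  n_ev <- tibble(
    peptide_id = peptides$peptide_id,
    terminus = "N",
    substrate_accession = peptides$accession,
    p1_position = peptides$start - 1L
  )[peptides$start > 1L, ]
  c_ev <- tibble(
    peptide_id = peptides$peptide_id,
    terminus = "C",
    substrate_accession = peptides$accession,
    p1_position = peptides$stop
  )[peptides$stop < parent_len, ]
  dplyr::bind_rows(n_ev, c_ev)
}

#' Extract the cleavage-site context octamer
#'
#' Returns the standard P4..P1 | P1'..P4' context of a scissile bond:
#' residues `p1 - window + 1 .. p1` followed by `p1 + 1 .. p1 + window`,
#' padded with `-` where the window runs past a protein end.
#'
#' @param sequence Parent protein sequence (single string).
#' @param p1_position 1-based position of the P1 residue;
#'   must satisfy `1 <= p1 < nchar(sequence)`.
#' @param window Residues on each side of the bond (default 4, the octamer).
#' @return Character string of length `2 * window`.
#' @export
extract_site_context <- function(sequence, p1_position, window = 4) {
  len <- nchar(sequence)
  if (any(p1_position < 1 | p1_position >= len)) {
    abort("extract_site_context: need 1 <= p1_position < length(sequence)")
  }
  padded <- paste0(strrep("-", window), sequence, strrep("-", window))
  # p1 maps to index p1 + window in the padded string
  substr_v <- function(s, from, to) substring(s, from, to)
  substr_v(padded, p1_position + 1, p1_position + 2 * window)
}

#' Match cleavage events against a curated cleavage-site table
#'
#' An event matches a database entry either on the same substrate
#' (`substrate_accession` and `p1_position` equal; `same_substrate`) or
#' through identical site context on a different substrate: the event's
#' octamer equals the octamer of a database entry on another accession
#' (`cross_substrate`). Matches are deduplicated to one association per
#' (protease, peptide) pair — even when both termini match — with
#' `same_substrate` preferred as the recorded mode.
#'
#' @param events Event tibble from [derive_cleavage_events()].
#' @param db Cleavage-site tibble from [read_cleavage_db()].
#' @param sequences Named character vector of parent sequences; used to
#'   compute site contexts. Database entries on substrates without a known
#'   sequence cannot take part in cross-substrate matching.
#' @param window Context half-width passed to [extract_site_context()].
#' @return Tibble with `peptide_id`, `protease`, `terminus`, `match_mode`,
#'   `site_context`, one row per (protease, peptide) association.
#' @export
match_proteases <- function(events, db, sequences, window = 4) {
  empty <- tibble(peptide_id = character(), protease = character(),
                  terminus = character(), match_mode = character(),
                  site_context = character())
  if (nrow(events) == 0 || nrow(db) == 0) return(empty)

  events <- dplyr::mutate(
    events,
    site_context = extract_site_context(
      unname(sequences[.data$substrate_accession]), .data$p1_position, window
    )
  )

  same <- dplyr::inner_join(
    events, db,
    by = c("substrate_accession", "p1_position"),
    relationship = "many-to-many"
  )
  same$match_mode <- "same_substrate"

  db_known <- db[db$substrate_accession %in% names(sequences), , drop = FALSE]
  cross <- empty
  if (nrow(db_known) > 0) {
    db_known <- dplyr::mutate(
      db_known,
      site_context = extract_site_context(
        unname(sequences[.data$substrate_accession]), .data$p1_position, window
      )
    )
    cross <- dplyr::inner_join(
      events,
      dplyr::select(db_known, db_accession = "substrate_accession",
                    "protease", "site_context"),
      by = "site_context",
      relationship = "many-to-many"
    )
    cross <- cross[cross$substrate_accession != cross$db_accession, , drop = FALSE]
    cross$match_mode <- "cross_substrate"
  }

  hits <- dplyr::bind_rows(
    dplyr::select(same, "peptide_id", "protease", "terminus",
                  "match_mode", "site_context"),
    dplyr::select(cross, "peptide_id", "protease", "terminus",
                  "match_mode", "site_context")
  )
  if (nrow(hits) == 0) return(empty)
  # one association per (protease, peptide); same_substrate wins the record
  hits <- dplyr::arrange(
    hits, .data$protease, .data$peptide_id,
    .data$match_mode != "same_substrate", .data$terminus
  )
  dplyr::distinct(hits, .data$protease, .data$peptide_id, .keep_all = TRUE)
}

#' Write protease-peptide associations to TSV
#'
#' @param associations Tibble from [match_proteases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(associations, path) {
  readr::write_tsv(
    dplyr::select(associations, "peptide_id", "protease", "terminus",
                  "match_mode", "site_context"),
    path, progress = FALSE
  )
  invisible(path)
}
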