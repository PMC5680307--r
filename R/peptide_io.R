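#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# the 20 standard residues; X tolerated as an unknown placeholder
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_ALLOWED <- c(AA_STANDARD, "X")

RESERVED_PEPTIDE_COLS <- c("peptide_id", "sequence", "accession", "start", "stop", "modifications")

#' Construct a sample-group assignment
#'
#' Holds the case/control split of the cohort's sample identifiers.
#' Groups must be disjoint and both non-empty.
#'
#' @param case_ids Character vector of case (e.g. nephropathy) sample ids.
#' @param control_ids Character vector of control sample ids.
#' @return A `sample_groups` object (a named list with `case_ids` and
#'   `control_ids`).
#' @export
sample_groups <- function(case_ids, control_ids) {
  case_ids <- as.character(case_ids)
  control_ids <- as.character(control_ids)
  if (length(case_ids) == 0 || length(control_ids) == 0) {
    abort("both sample groups must be non-empty")
  }
  if (anyDuplicated(case_ids) || anyDuplicated(control_ids)) {
    abort("duplicated sample ids within a group")
  }
  overlap <- intersect(case_ids, control_ids)
  if (length(overlap) > 0) {
    abort(paste0(
      "sample groups must be disjoint; shared ids: ",
      paste(utils::head(overlap, 5), collapse = ", ")
    ))
  }
  structure(list(case_ids = case_ids, control_ids = control_ids),
            class = "sample_groups")
}

#' @export
print.sample_groups <- function(x, ...) {
  cat(sprintf("<sample_groups> %d case / %d control samples\n",
              length(x$case_ids), length(x$control_ids)))
  invisible(x)
}

validate_peptide_table <- function(peptides, sample_cols) {
  if (anyDuplicated(peptides$peptide_id)) {
    dup <- unique(peptides$peptide_id[duplicated(peptides$peptide_id)])
    abort(paste0("duplicate peptide_id: ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad <- which(!is.finite(peptides$start) | !is.finite(peptides$stop) |
                 peptides$start < 1 | peptides$start > peptides$stop)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed coordinates (need 1 <= start <= stop) for peptide_id: ",
      paste(peptides$peptide_id[utils::head(bad, 5)], collapse = ", ")
    ))
  }
  has_seq <- !is.na(peptides$sequence) & nzchar(peptides$sequence)
  span <- peptides$stop - peptides$start + 1L
  mism <- which(has_seq & nchar(peptides$sequence) != span)
  if (length(mism) > 0) {
    abort(paste0(
      "sequence length does not match stop - start + 1 for peptide_id: ",
      paste(peptides$peptide_id[utils::head(mism, 5)], collapse = ", ")
    ))
  }
  for (s in sample_cols) {
    v <- peptides[[s]]
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("negative abundance in sample column '", s, "'"))
    }
  }
  invisible(peptides)
}

#' Read a peptide abundance table
#'
#' Reads a delimited table with one row per detected peptide: `peptide_id`,
#' `sequence`, `accession`, `start`, `stop`, an optional `modifications`
#' column, and one numeric column per sample. Coordinates are 1-based
#' inclusive positions in the parent protein and pass through unchanged.
#' Blank or missing abundance cells denote a peptide not detected in that
#' sample and are read as 0 (no imputation).
#'
#' @param path Path to a TSV (default) or CSV file with a header row.
#' @param groups Sample group assignment: a [sample_groups] object, a named
#'   list with `case_ids`/`control_ids`, or the path of a two-column
#'   delimited file (`sample_id`, `group` with values `case`/`control`) or a
#'   YAML/JSON file with keys `case_ids` and `control_ids`.
#' @param delim Field delimiter; `"\t"` by default.
#' @return A list with `peptides` (a tibble) and `groups` (a
#'   [sample_groups] object).
#' @export
read_peptide_table <- function(path, groups, delim = "\t") {
  peptides <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                                progress = FALSE)
  required <- c("peptide_id", "sequence", "accession", "start", "stop")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols) > 0) {
    abort(paste0("peptide table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  peptides$peptide_id <- as.character(peptides$peptide_id)
  peptides$sequence <- toupper(as.character(peptides$sequence))
  peptides$accession <- as.character(peptides$accession)
  peptides$start <- as.integer(peptides$start)
  peptides$stop <- as.integer(peptides$stop)
  sample_cols <- setdiff(names(peptides), RESERVED_PEPTIDE_COLS)
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(peptides[[s]]))
    v[is.na(v)] <- 0 # absent signal convention
    peptides[[s]] <- v
  }
  validate_peptide_table(peptides, sample_cols)

  groups <- resolve_groups(groups)
  unknown <- setdiff(c(groups$case_ids, groups$control_ids), sample_cols)
  if (length(unknown) > 0) {
    abort(paste0("group config names sample(s) absent from the table: ",
                 paste(unknown, collapse = ", ")))
  }
  list(peptides = as_tibble(peptides), groups = groups)
}

resolve_groups <- function(groups) {
  if (inherits(groups, "sample_groups")) return(groups)
  if (is.list(groups)) {
    return(sample_groups(groups$case_ids, groups$control_ids))
  }
  if (is.character(groups) && length(groups) == 1) {
    if (grepl("\\.(ya?ml|json)$", groups, ignore.case = TRUE)) {
      cfg <- if (grepl("\\.json$", groups, ignore.case = TRUE)) {
        jsonlite::read_json(groups, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(groups)
      }
      return(sample_groups(cfg$case_ids, cfg$control_ids))
    }
    tab <- readr::read_tsv(groups, show_col_types = FALSE, progress = FALSE)
    if (!all(c("sample_id", "group") %in% names(tab))) {
      abort("groups file must have columns sample_id, group")
    }
    grp <- tolower(tab$group)
    if (!all(grp %in% c("case", "control"))) {
      abort("groups file 'group' values must be 'case' or 'control'")
    }
    return(sample_groups(tab$sample_id[grp == "case"],
                         tab$sample_id[grp == "control"]))
  }
  abort("unrecognized groups specification")
}

#' Write a peptide abundance table
#'
#' Inverse of [read_peptide_table()]; abundances round-trip at full double
#' precision.
#'
#' @param peptides Peptide tibble as produced by [read_peptide_table()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path, delim = "\t") {
  readr::write_delim(peptides, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read parent-protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of each header;
#' the UniProt `sp|ACC|NAME` / `tr|ACC|NAME` dialect is also recognized and
#' the accession field extracted. Sequences must use the 20 standard amino
#' acids plus `X`.
#'
#' @param path FASTA file path.
#' @return Named character vector mapping accession to amino-acid sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(paste0("empty FASTA file: ", path))
  acc <- vapply(names(seqs), parse_fasta_accession, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    abort(paste0("duplicate accession in FASTA: ", paste(dup, collapse = ", ")))
  }
  out <- toupper(as.character(seqs))
  names(out) <- acc
  if (any(!nzchar(out))) abort("empty sequence in FASTA")
  letters_used <- unique(strsplit(paste(out, collapse = ""), "")[[1]])
  bad <- setdiff(letters_used, AA_ALLOWED)
  if (length(bad) > 0) {
    abort(paste0("non-standard residue(s) in FASTA: ", paste(bad, collapse = ", ")))
  }
  out
}

parse_fasta_accession <- function(header) {
  token <- strsplit(trimws(header), "\\s+")[[1]][1]
  if (grepl("^(sp|tr)\\|", token)) {
    parts <- strsplit(token, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && nzchar(parts[2])) return(parts[2])
  }
  token
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector (accession -> sequence).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

EVIDENCE_OBSERVED <- c("observed", "observed_different_substrate")

normalize_cs_evidence <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ -]+", "_", x)
  x[x == "observed_in_different_substrate"] <- "observed_different_substrate"
  x
}

#' Read a curated cleavage-site table
#'
#' Expects a delimited file with columns `protease`, `substrate_accession`,
#' `p1_position` (1-based index of the residue immediately N-terminal to the
#' scissile bond) and `evidence`. Only experimentally observed associations
#' are retained: evidence values are normalized case-insensitively and rows
#' outside `observed` / `observed_different_substrate` (e.g. probability-based
#' predictions) are dropped with a warning reporting the count.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return Tibble with columns `protease`, `substrate_accession`,
#'   `p1_position`, `evidence`.
#' @export
read_cleavage_db <- function(path, delim = "\t") {
  db <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  required <- c("protease", "substrate_accession", "p1_position", "evidence")
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols) > 0) {
    abort(paste0("cleavage DB lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  db$evidence <- normalize_cs_evidence(db$evidence)
  keep <- db$evidence %in% EVIDENCE_OBSERVED
  if (sum(!keep) > 0) {
    warn(sprintf("dropped %d cleavage-site entr%s with non-observed evidence",
                 sum(!keep), if (sum(!keep) == 1) "y" else "ies"))
  }
  db <- db[keep, required]
  if (nrow(db) == 0) warn("cleavage DB is empty after evidence filtering")
  db$protease <- as.character(db$protease)
  db$substrate_accession <- as.character(db$substrate_accession)
  db$p1_position <- as.integer(db$p1_position)
  if (any(db$p1_position < 1, na.rm = TRUE) || anyNA(db$p1_position)) {
    abort("cleavage DB: p1_position must be an integer >= 1")
  }
  as_tibble(db)
}

EVIDENCE_SOURCES <- c("transcriptomics", "protein_expression")
EVIDENCE_DIRECTIONS <- c("increase", "decrease", "no_change", "inconclusive", "missing")

#' Read an external evidence-direction table
#'
#' One row per (protease, source): `source` is `transcriptomics` or
#' `protein_expression`; `direction` one of `increase`, `decrease`,
#' `no_change`, `inconclusive`, `missing`.
#'
#' @param path File path (TSV).
#' @return Tibble with columns `protease`, `source`, `direction`.
#' @export
read_evidence <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("protease", "source", "direction")
  if (!all(required %in% names(ev))) {
    abort("evidence table must have columns protease, source, direction")
  }
  ev$source <- tolower(trimws(ev$source))
  ev$direction <- gsub("[ -]+", "_", tolower(trimws(ev$direction)))
  if (!all(ev$source %in% EVIDENCE_SOURCES)) {
    abort(paste0("unknown evidence source; allowed: ",
                 paste(EVIDENCE_SOURCES, collapse = ", ")))
  }
  if (!all(ev$direction %in% EVIDENCE_DIRECTIONS)) {
    abort(paste0("unknown evidence direction; allowed: ",
                 paste(EVIDENCE_DIRECTIONS, collapse = ", ")))
  }
  if (anyDuplicated(ev[, c("protease", "source")])) {
    abort("evidence table: one row per (protease, source) required")
  }
  as_tibble(ev[, required])
}
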