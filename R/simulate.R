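#' Default planted-protease truth table
#'
#' Six proteases planted as activated, six as inhibited, five as null
#' (present in the cleavage-site table but with unregulated peptides),
#' five cleavage sites each.
#'
#' @return Tibble with `name`, `true_direction`, `n_sites`.
#' @export
default_proteases <- function() {
  tibble(
    name = c(sprintf("ACTP%d", 1:6), sprintf("INHP%d", 1:6), sprintf("NULP%d", 1:5)),
    true_direction = c(rep("activated", 6), rep("deactivated", 6), rep("null", 5)),
    n_sites = 5L
  )
}

#' Simulation configuration for a synthetic urinary-peptide cohort
#'
#' Defines a two-group cohort of log-normally distributed peptide
#' abundances in which peptides are genuine fragments of randomly drawn
#' parent proteins, each planted protease owns a set of cleavage sites
#' recorded in the emitted cleavage-site table, and every peptide spawned
#' from a site abuts that site with one terminus. Peptides of an activated
#' protease receive a multiplicative case-group shift of `effect_size`,
#' peptides of an inhibited protease a shift of `1/effect_size`, peptides
#' of a null protease none. Background peptides share the parent proteins
#' but none of their termini coincide with a recorded cleavage site.
#'
#' @param seed Integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @param n_case,n_control Samples per group.
#' @param n_proteins Number of parent proteins.
#' @param protein_length_range Integer pair, inclusive length range.
#' @param proteases Tibble with `name`, `true_direction`
#'   (`activated`/`deactivated`/`null`) and `n_sites`.
#' @param peptides_per_site Peptides spawned per cleavage site.
#' @param effect_size Multiplicative case/control fold (> 1) for peptides
#'   of non-null proteases.
#' @param noise_sigma Log-scale standard deviation of per-sample abundance
#'   noise.
#' @param background_peptides Number of unassociated peptides; their
#'   regulation cycles up / down / none in equal parts.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_case = 30L, n_control = 30L,
                              n_proteins = 20L,
                              protein_length_range = c(200L, 400L),
                              proteases = default_proteases(),
                              peptides_per_site = 2L,
                              effect_size = 4,
                              noise_sigma = 0.5,
                              background_peptides = 60L) {
  stopifnot(
    n_case >= 1, n_control >= 1, n_proteins >= 1,
    length(protein_length_range) == 2,
    protein_length_range[1] <= protein_length_range[2],
    all(c("name", "true_direction", "n_sites") %in% names(proteases)),
    all(proteases$true_direction %in% c("activated", "deactivated", "null")),
    all(proteases$n_sites >= 0), peptides_per_site >= 0,
    effect_size > 1, noise_sigma > 0, background_peptides >= 0
  )
  structure(
    list(seed = as.integer(seed), n_case = as.integer(n_case),
         n_control = as.integer(n_control), n_proteins = as.integer(n_proteins),
         protein_length_range = as.integer(protein_length_range),
         proteases = proteases,
         peptides_per_site = as.integer(peptides_per_site),
         effect_size = effect_size, noise_sigma = noise_sigma,
         background_peptides = as.integer(background_peptides)),
    class = "simulation_config"
  )
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# margin kept clear of protein ends so every spawned peptide (<= 25 aa)
# fits with both termini interior
SITE_MARGIN <- 30L
PEPTIDE_LENGTH_RANGE <- c(8L, 25L)

#' Generate a synthetic cohort
#'
#' Draws parent proteins, plants cleavage sites and peptides per
#' [simulation_config()], and samples per-peptide abundances as
#' `exp(mu + N(0, sigma))` with the group fold applied multiplicatively to
#' case samples. The same config always yields the identical cohort.
#'
#' @param config A [simulation_config()].
#' @return A list (class `peptide_cohort`) with `peptides` (wide tibble),
#'   `groups`, `sequences`, `cleavage_db`, `evidence`, `truth` (list of
#'   `proteases` and `peptides` truth tibbles), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_preserved_seed(config$seed, build_cohort(config))
}

build_cohort <- function(config) {
  lens <- sample(seq(config$protein_length_range[1],
                     config$protein_length_range[2]),
                 config$n_proteins, replace = TRUE)
  accs <- sprintf("SYNP%03d", seq_len(config$n_proteins))
  sequences <- vapply(lens, function(l) {
    paste(sample(AA_STANDARD, l, replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- accs

  # site pool: interior positions, unique (accession, p1) across the DB
  pool <- dplyr::bind_rows(lapply(seq_along(accs), function(i) {
    tibble(substrate_accession = accs[i],
           p1_position = seq(SITE_MARGIN, lens[i] - SITE_MARGIN))
  }))
  need <- sum(config$proteases$n_sites)
  if (need > nrow(pool)) {
    abort(sprintf("config requests %d cleavage sites but only %d positions available",
                  need, nrow(pool)))
  }
  picked <- pool[sample.int(nrow(pool), need), , drop = FALSE]
  picked$protease <- rep(config$proteases$name, times = config$proteases$n_sites)
  cleavage_db <- tibble(
    protease = picked$protease,
    substrate_accession = picked$substrate_accession,
    p1_position = as.integer(picked$p1_position),
    evidence = "observed"
  )
  site_keys <- paste(cleavage_db$substrate_accession, cleavage_db$p1_position)

  dir_of <- stats::setNames(config$proteases$true_direction, config$proteases$name)
  reg_of <- c(activated = "up", deactivated = "down", null = "none")

  planted <- list()
  used_coords <- character(0)
  pid <- 0L
  for (k in seq_len(nrow(cleavage_db))) {
    acc <- cleavage_db$substrate_accession[k]
    p1 <- cleavage_db$p1_position[k]
    plen <- nchar(sequences[[acc]])
    for (j in seq_len(config$peptides_per_site)) {
      anchor_n <- (j %% 2L) == 1L # alternate which terminus abuts the site
      coords <- draw_anchored_peptide(acc, p1, plen, anchor_n,
                                      site_keys, used_coords)
      used_coords <- c(used_coords, paste(acc, coords[1], coords[2]))
      pid <- pid + 1L
      planted[[length(planted) + 1L]] <- tibble(
        peptide_id = sprintf("PEP%04d", pid),
        accession = acc, start = coords[1], stop = coords[2],
        protease = cleavage_db$protease[k],
        regulation = reg_of[[dir_of[[cleavage_db$protease[k]]]]]
      )
    }
  }
  planted <- dplyr::bind_rows(planted)

  background <- list()
  bg_reg <- rep(c("up", "down", "none"), length.out = config$background_peptides)
  for (b in seq_len(config$background_peptides)) {
    coords <- draw_background_peptide(accs, lens, site_keys, used_coords)
    used_coords <- c(used_coords, paste(coords$acc, coords$start, coords$stop))
    background[[b]] <- tibble(
      peptide_id = sprintf("BG%04d", b),
      accession = coords$acc, start = coords$start, stop = coords$stop,
      protease = NA_character_, regulation = bg_reg[b]
    )
  }
  background <- dplyr::bind_rows(background)

  truth_peptides <- dplyr::bind_rows(planted, background)
  truth_peptides$start <- as.integer(truth_peptides$start)
  truth_peptides$stop <- as.integer(truth_peptides$stop)

  case_ids <- sprintf("DN%03d", seq_len(config$n_case))
  control_ids <- sprintf("CTRL%03d", seq_len(config$n_control))
  n_samples <- length(case_ids) + length(control_ids)
  shift <- c(up = 1, down = -1, none = 0)[truth_peptides$regulation]
  abund <- matrix(0, nrow = nrow(truth_peptides), ncol = n_samples,
                  dimnames = list(NULL, c(case_ids, control_ids)))
  for (i in seq_len(nrow(truth_peptides))) {
    mu <- stats::runif(1, log(500), log(5000))
    row <- exp(mu + stats::rnorm(n_samples, 0, config$noise_sigma))
    row[seq_along(case_ids)] <- row[seq_along(case_ids)] *
      config$effect_size^shift[i]
    abund[i, ] <- row
  }

  peptides <- dplyr::bind_cols(
    tibble(
      peptide_id = truth_peptides$peptide_id,
      sequence = unname(substring(sequences[truth_peptides$accession],
                                  truth_peptides$start, truth_peptides$stop)),
      accession = truth_peptides$accession,
      start = truth_peptides$start,
      stop = truth_peptides$stop
    ),
    as_tibble(abund)
  )

  nonnull <- config$proteases[config$proteases$true_direction != "null", ]
  evidence <- tidyr::expand_grid(
    protease = nonnull$name, source = EVIDENCE_SOURCES
  )
  evidence$direction <- unname(ifelse(
    dir_of[evidence$protease] == "activated", "increase", "decrease"
  ))

  structure(
    list(
      peptides = peptides,
      groups = sample_groups(case_ids, control_ids),
      sequences = sequences,
      cleavage_db = cleavage_db,
      evidence = as_tibble(evidence),
      truth = list(
        proteases = tibble(protease = config$proteases$name,
                           true_direction = config$proteases$true_direction),
        peptides = truth_peptides
      ),
      config = config
    ),
    class = "peptide_cohort"
  )
}

draw_anchored_peptide <- function(acc, p1, plen, anchor_n, site_keys, used) {
  for (try in 1:100) {
    len <- sample(seq(PEPTIDE_LENGTH_RANGE[1], PEPTIDE_LENGTH_RANGE[2]), 1)
    if (anchor_n) { # N terminus abuts the site: start - 1 == p1
      start <- p1 + 1L; stop <- start + len - 1L
      free_p1 <- stop # the C-terminal event this peptide would also record
    } else {        # C terminus abuts the site: stop == p1
      stop <- p1; start <- stop - len + 1L
      free_p1 <- start - 1L
    }
    if (start <= 1L || stop >= plen) next
    if (paste(acc, free_p1) %in% site_keys) next
    if (paste(acc, start, stop) %in% used) next
    return(c(as.integer(start), as.integer(stop)))
  }
  abort("could not place a site-anchored peptide; widen the protein margins")
}

draw_background_peptide <- function(accs, lens, site_keys, used) {
  for (try in 1:200) {
    i <- sample.int(length(accs), 1)
    len <- sample(seq(PEPTIDE_LENGTH_RANGE[1], PEPTIDE_LENGTH_RANGE[2]), 1)
    start <- sample(seq(2L, lens[i] - len), 1)
    stop <- start + len - 1L
    if (stop >= lens[i]) next
    if (paste(accs[i], start - 1L) %in% site_keys) next
    if (paste(accs[i], stop) %in% site_keys) next
    if (paste(accs[i], start, stop) %in% used) next
    return(list(acc = accs[i], start = as.integer(start), stop = as.integer(stop)))
  }
  abort("could not place a background peptide clear of all cleavage sites")
}

#' Write a cohort to the file dialects the readers consume
#'
#' @param cohort A `peptide_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "peptide_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    peptides = file.path(dir, "peptides.tsv"),
    fasta = file.path(dir, "proteins.fasta"),
    cleavage_db = file.path(dir, "cleavage_db.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth_proteases = file.path(dir, "truth_proteases.tsv"),
    truth_peptides = file.path(dir, "truth_peptides.tsv")
  )
  write_peptide_table(cohort$peptides, paths$peptides)
  write_fasta(cohort$sequences, paths$fasta)
  readr::write_tsv(cohort$cleavage_db, paths$cleavage_db, progress = FALSE)
  readr::write_tsv(cohort$evidence, paths$evidence, progress = FALSE)
  readr::write_tsv(
    tibble(sample_id = c(cohort$groups$case_ids, cohort$groups$control_ids),
           group = c(rep("case", length(cohort$groups$case_ids)),
                     rep("control", length(cohort$groups$control_ids)))),
    paths$groups, progress = FALSE
  )
  readr::write_tsv(cohort$truth$proteases, paths$truth_proteases, progress = FALSE)
  readr::write_tsv(cohort$truth$peptides, paths$truth_peptides, progress = FALSE)
  paths
}

#' Run the full pipeline on a generated cohort and check direction recovery
#'
#' Generates a cohort, runs differential testing, protease matching and
#' activity scoring, and reports per planted protease whether the sign of
#' its score matches the planted direction.
#'
#' @param config A [simulation_config()].
#' @param alpha,fc_up,fc_down,min_peptides Analysis thresholds (defaults as
#'   in [select_regulated()] / [filter_min_peptides()]).
#' @return List with `report` (per non-null protease: planted direction,
#'   recovered score or NA, `correct`), `summary` (recovery fraction,
#'   counts, whether the final table was empty) and the intermediate
#'   `scores` result.
#' @export
recover_and_check <- function(config, alpha = 0.05, fc_up = 1.5,
                              fc_down = 0.66, min_peptides = 3) {
  cohort <- generate_cohort(config)
  diffs <- select_regulated(cohort$peptides, cohort$groups,
                            alpha = alpha, fc_up = fc_up, fc_down = fc_down)
  events <- derive_cleavage_events(cohort$peptides, cohort$sequences)
  assoc <- match_proteases(events, cohort$cleavage_db, cohort$sequences)
  reg_ids <- diffs$peptide_id[diffs$direction %in% c("up", "down")]
  assoc_reg <- assoc[assoc$peptide_id %in% reg_ids, , drop = FALSE]
  scores <- if (nrow(assoc_reg) == 0) {
    NULL
  } else {
    score_proteases(assoc_reg, diffs, min_peptides = min_peptides)
  }
  final <- if (is.null(scores)) {
    tibble(protease = character(), score = numeric())
  } else {
    scores$table
  }

  truth <- cohort$truth$proteases
  nonnull <- truth[truth$true_direction != "null", , drop = FALSE]
  recovered <- final$score[match(nonnull$protease, final$protease)]
  expected_sign <- ifelse(nonnull$true_direction == "activated", 1, -1)
  report <- tibble(
    protease = nonnull$protease,
    true_direction = nonnull$true_direction,
    score = recovered,
    correct = !is.na(recovered) & sign(recovered) == expected_sign
  )
  null_in_table <- intersect(
    truth$protease[truth$true_direction == "null"], final$protease
  )
  summary <- list(
    n_nonnull = nrow(nonnull),
    n_correct = sum(report$correct),
    recovery_rate = if (nrow(nonnull) > 0) mean(report$correct) else NA_real_,
    n_null_flagged = length(null_in_table),
    final_table_empty = nrow(final) == 0
  )
  list(report = report, summary = summary, scores = scores)
}
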