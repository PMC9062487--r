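# ---- in-silico proteolytic digestion and cross-species ambiguity -----------

#' Digestion configuration
#'
#' @param rule `"trypsin"` (cleave after K/R unless followed by P) or
#'   `"trypsin_p"` (cleave after K/R regardless of a following proline).
#' @param missed_cleavages Maximum internal uncleaved sites per peptide
#'   (0..5).
#' @param min_length,max_length Peptide length window in residues, applied
#'   after missed-cleavage enumeration.
#' @return A `digest_config` list.
#' @export
digest_config <- function(rule = c("trypsin_p", "trypsin"),
                          missed_cleavages = 0L,
                          min_length = 6L, max_length = 52L) {
  rule <- match.arg(rule)
  missed_cleavages <- as.integer(missed_cleavages)
  if (missed_cleavages < 0L || missed_cleavages > 5L)
    stop("missed_cleavages must be in 0..5")
  if (min_length > max_length) stop("min_length > max_length")
  structure(list(rule = rule, missed_cleavages = missed_cleavages,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_config")
}

#' Digest one protein sequence in silico
#'
#' Cleaves C-terminally of K or R; under `"trypsin"` no cleavage occurs when
#' the next residue is proline. Peptides with up to `missed_cleavages`
#' internal uncleaved sites are emitted, the length filter is applied last,
#' and the C-terminal peptide is always produced. Unknown residues are
#' non-cleavage sites. Coordinates are 1-based inclusive.
#'
#' @param sequence Amino-acid string.
#' @param config A [digest_config()].
#' @return `data.frame` with columns `peptide`, `start`, `end`, ordered by
#'   `start` then `end`.
#' @export
digest_protein <- function(sequence, config = digest_config()) {
  if (!nzchar(sequence)) stop("empty sequence")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_kr <- chars %in% c("K", "R")
  cut_after <- is_kr
  if (config$rule == "trypsin") {
    next_p <- c(chars[-1] == "P", FALSE)
    cut_after <- cut_after & !next_p
  }
  cut_after[n] <- FALSE  # no cleavage needed after the last residue
  bounds <- c(0L, which(cut_after), n)   # fragment boundaries
  nfrag <- length(bounds) - 1L
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + config$missed_cleavages)
    for (j in i:jmax) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j + 1L])
    }
  }
  len <- ends - starts + 1L
  keep <- len >= config$min_length & len <= config$max_length
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  data.frame(peptide = substring(sequence, starts, ends),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Build a peptide-to-protein index by digesting a database
#'
#' @param records Protein records as returned by [read_fasta()] or
#'   [generate_proteome()].
#' @param config A [digest_config()].
#' @return A `peptide_index`: a `data.frame` with one row per
#'   (peptide, protein) mapping, columns `peptide`, `accession`, `species`,
#'   `is_contaminant`, `start`, `has_nonstandard`.
#' @export
build_peptide_index <- function(records, config = digest_config()) {
  if (!nrow(records)) stop("empty record list")
  pieces <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    d <- digest_protein(records$sequence[i], config)
    if (!nrow(d)) next
    pieces[[i]] <- data.table::data.table(
      peptide = d$peptide,
      accession = records$accession[i],
      species = records$species[i],
      is_contaminant = records$is_contaminant[i],
      start = d$start)
  }
  idx <- as.data.frame(data.table::rbindlist(pieces))
  idx <- idx[!duplicated(idx[, c("peptide", "accession", "start")]), ]
  idx$has_nonstandard <- grepl("[XUBZ]", idx$peptide)
  rownames(idx) <- NULL
  structure(idx, class = c("peptide_index", "data.frame"),
            config = config)
}

#' Fraction of tryptic peptides ambiguous between two species
#'
#' The proportion of unique non-contaminant peptide sequences that map to at
#' least one HUMAN and at least one MOUSE protein. Peptides mapping only to
#' contaminant entries are excluded from the denominator.
#'
#' @param index A [build_peptide_index()] result spanning at least two
#'   species.
#' @return Proportion in \[0, 1\].
#' @export
fraction_ambiguous_peptides <- function(index) {
  nc <- index[!index$is_contaminant, ]
  if (length(unique(nc$species)) < 2)
    stop("peptide index spans a single species; ambiguity is undefined")
  human <- unique(nc$peptide[nc$species == "HUMAN"])
  mouse <- unique(nc$peptide[nc$species == "MOUSE"])
  length(intersect(human, mouse)) / length(unique(nc$peptide))
}

#' Classify observed protein groups by species evidence
#'
#' A group is `contaminant` when any protein mapped by its peptides is a
#' contaminant entry; `human_unique` when at least one observed peptide maps
#' only to HUMAN proteins; `mouse_unique` symmetrically; `ambiguous` when
#' every observed peptide maps to both species. Ambiguous groups are retained
#' (treated as human downstream); mouse-unique and contaminant groups are
#' flagged for exclusion. Peptides containing nonstandard residues
#' (X/U/B/Z) never count as species-unique evidence.
#'
#' @param groups Character vector of protein-group ids
#'   (semicolon-separated accessions).
#' @param observed_peptides A [peptide_observations()] table; a peptide
#'   belongs to a group when it lists any of the group's accessions.
#' @param index A [build_peptide_index()] result covering the observed
#'   peptides.
#' @return An `ambiguity_report`: list with `per_group` (`data.frame` of
#'   `group`, `species_call`, `retain`, `exclude`), `class_fractions`,
#'   `n_unique_peptides`, and `fraction_ambiguous_peptides` (when the index
#'   spans two species).
#' @export
classify_protein_groups <- function(groups, observed_peptides, index) {
  miss <- setdiff(observed_peptides$sequence, index$peptide)
  if (length(miss))
    stop("observed peptide(s) absent from index: ",
         paste(head(miss, 3), collapse = ", "))
  idx_split <- split(index[, c("species", "is_contaminant", "has_nonstandard")],
                     index$peptide)
  calls <- character(length(groups))
  for (g in seq_along(groups)) {
    accs <- split_set(groups[g])
    obs_rows <- vapply(strsplit(observed_peptides$accession, ";", fixed = TRUE),
                       function(a) any(a %in% accs), logical(1))
    peps <- unique(observed_peptides$sequence[obs_rows])
    if (!length(peps)) stop("group with no observed peptide: ", groups[g])
    maps <- idx_split[peps]
    any_cont <- any(vapply(maps, function(m) any(m$is_contaminant), logical(1)))
    std <- vapply(maps, function(m) !any(m$has_nonstandard), logical(1))
    human_only <- vapply(maps, function(m)
      all(m$species[!m$is_contaminant] == "HUMAN") &&
        any(!m$is_contaminant), logical(1))
    mouse_only <- vapply(maps, function(m)
      all(m$species[!m$is_contaminant] == "MOUSE") &&
        any(!m$is_contaminant), logical(1))
    calls[g] <-
      if (any_cont) "contaminant"
      else if (any(human_only & std)) "human_unique"
      else if (any(mouse_only & std)) "mouse_unique"
      else "ambiguous"
  }
  per_group <- data.frame(group = groups, species_call = calls,
                          retain = calls %in% c("human_unique", "ambiguous"),
                          exclude = calls %in% c("mouse_unique", "contaminant"),
                          stringsAsFactors = FALSE)
  frac <- table(factor(calls, levels = c("human_unique", "mouse_unique",
                                         "ambiguous", "contaminant")))
  frac <- as.numeric(frac) / length(calls)
  names(frac) <- c("human_unique", "mouse_unique", "ambiguous", "contaminant")
  fap <- tryCatch(fraction_ambiguous_peptides(index), error = function(e) NA_real_)
  structure(list(per_group = per_group,
                 class_fractions = frac,
                 n_unique_peptides = length(unique(index$peptide)),
                 fraction_ambiguous_peptides = fap),
            class = "ambiguity_report")
}

#' @export
print.ambiguity_report <- function(x, ...) {
  cat("<ambiguity_report>\n")
  cat(sprintf("  unique peptides in index: %d\n", x$n_unique_peptides))
  if (!is.na(x$fraction_ambiguous_peptides))
    cat(sprintf("  cross-species ambiguous peptides: %.1f%%\n",
                100 * x$fraction_ambiguous_peptides))
  cf <- x$class_fractions
  cat(sprintf("  groups: %.1f%% human-unique, %.1f%% mouse-unique, %.1f%% ambiguous (retained), %.1f%% contaminant\n",
              100 * cf[["human_unique"]], 100 * cf[["mouse_unique"]],
              100 * cf[["ambiguous"]], 100 * cf[["contaminant"]]))
  invisible(x)
}
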