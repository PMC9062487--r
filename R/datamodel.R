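# ---- shared data containers -------------------------------------------------
# Containers are light S3 wrappers over base structures so that every stage of
# the pipeline can validate its inputs cheaply. Coordinates are 1-based
# inclusive everywhere (UniProt convention); missing intensities are NA, never
# zero -- zero is a legal measured value.

SPECIES_LEVELS <- c("HUMAN", "MOUSE", "OTHER")
REGION_CATEGORIES <- c("extracellular", "transmembrane", "intracellular",
                       "signal", "other")
MARKER_CATEGORIES <- c("apoptosis", "organelle", "ev", "beta_cell", "other")

#' Construct a protein-group intensity matrix
#'
#' Wraps a numeric matrix of protein-group by sample abundances, tagging the
#' scale it lives on. Raw-scale matrices must be non-negative linear
#' intensities; missing values are `NA`.
#'
#' @param values Numeric matrix; rows are protein groups (semicolon-separated
#'   accessions allowed in rownames), columns are samples.
#' @param scale Either `"raw"` (linear intensities) or `"log2_normalized"`.
#' @return The matrix with class `intensity_matrix` and a `scale` attribute.
#' @export
intensity_matrix <- function(values, scale = c("raw", "log2_normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity matrix needs row (protein) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein-group identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("negative values are not legal raw intensities")
  structure(values, scale = scale,
            class = c("intensity_matrix", class(values)))
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d protein groups x %d samples [%s], %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "scale"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @export
as.matrix.intensity_matrix <- function(x, ...) {
  matrix(as.vector(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

im_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "raw" else s
}

stopifnot_raw <- function(x) {
  if (im_scale(x) != "raw")
    stop("this operation requires a raw-scale intensity matrix")
}

#' Construct a sample metadata table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param condition Character vector of condition labels.
#' @param compartment `"lysate"` or `"secretome"` per sample.
#' @param pair_id Optional pairing label linking a lysate sample to its
#'   secretome sample; each pair id must occur exactly once per compartment.
#' @param plex Optional TMT plex (batch) label.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, condition, compartment,
                            pair_id = NA_character_, plex = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = as.character(condition),
                   compartment = as.character(compartment),
                   pair_id = as.character(pair_id),
                   plex = as.character(plex),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$compartment %in% c("lysate", "secretome")))
    stop("compartment must be 'lysate' or 'secretome'")
  paired <- df[!is.na(df$pair_id), ]
  if (nrow(paired)) {
    tab <- table(paired$pair_id, paired$compartment)
    if (any(tab > 1))
      stop("a pair_id occurs more than once within a compartment")
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct a marker set
#'
#' @param name Set name, unique within a collection.
#' @param members Non-empty character vector of gene symbols or accessions.
#' @param category One of apoptosis, organelle, ev, beta_cell, other.
#' @return A `marker_set` object.
#' @export
marker_set <- function(name, members, category = "other") {
  if (!length(members)) stop(sprintf("marker set '%s' has no members", name))
  if (!category %in% MARKER_CATEGORIES)
    stop("unknown marker category: ", category)
  structure(list(name = name, category = category,
                 members = unique(as.character(members))),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s [%s]: %d members\n",
              x$name, x$category, length(x$members)))
  invisible(x)
}

#' Construct a membrane topology annotation
#'
#' Regions are 1-based inclusive, non-overlapping and ordered by start.
#'
#' @param accession Protein accession.
#' @param regions `data.frame` with columns `start`, `end`, `category`.
#' @param protein_length Protein length in residues.
#' @return A `topology_annotation` object.
#' @export
topology_annotation <- function(accession, regions, protein_length) {
  regions <- regions[order(regions$start), c("start", "end", "category")]
  if (any(regions$start < 1) || any(regions$end > protein_length) ||
      any(regions$start > regions$end))
    stop(sprintf("%s: region outside 1..%d or start > end",
                 accession, protein_length))
  if (nrow(regions) > 1 &&
      any(regions$start[-1] <= regions$end[-nrow(regions)]))
    stop(sprintf("%s: overlapping topology regions", accession))
  if (!all(regions$category %in% REGION_CATEGORIES))
    stop(sprintf("%s: unknown region category", accession))
  rownames(regions) <- NULL
  structure(list(accession = accession, regions = regions,
                 protein_length = as.integer(protein_length)),
            class = "topology_annotation")
}

#' Construct a per-protein annotation table
#'
#' One row per accession. Set-valued columns (`subcellular_locations`,
#' `go_terms`, `marker_flags`) are semicolon-separated strings; empty sets are
#' empty strings.
#'
#' @param accession Character vector of unique accessions.
#' @param gene_symbol Gene symbols (may be `NA`).
#' @param has_signal_peptide Logical flag per accession.
#' @param subcellular_locations,go_terms,marker_flags Semicolon-separated
#'   set-valued annotation strings.
#' @return A `data.frame` of class `annotation_table`.
#' @export
annotation_table <- function(accession, gene_symbol = NA_character_,
                             has_signal_peptide = FALSE,
                             subcellular_locations = "",
                             go_terms = "", marker_flags = "") {
  if (anyDuplicated(accession)) stop("duplicate accession in annotation table")
  df <- data.frame(accession = as.character(accession),
                   gene_symbol = as.character(gene_symbol),
                   has_signal_peptide = as.logical(has_signal_peptide),
                   subcellular_locations = as.character(subcellular_locations),
                   go_terms = as.character(go_terms),
                   marker_flags = as.character(marker_flags),
                   stringsAsFactors = FALSE)
  class(df) <- c("annotation_table", "data.frame")
  df
}

# split a semicolon-joined set column into a character vector
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Construct a peptide observation table
#'
#' @param sequence Peptide amino-acid sequences.
#' @param accession Semicolon-separated accession list per peptide.
#' @param start,end 1-based inclusive coordinates on each listed accession.
#' @param check_length Verify `end - start + 1 == nchar(sequence)`.
#' @return A `data.frame` of class `peptide_observations`.
#' @export
peptide_observations <- function(sequence, accession, start, end,
                                 check_length = TRUE) {
  df <- data.frame(sequence = as.character(sequence),
                   accession = as.character(accession),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (check_length && any(df$end - df$start + 1L != nchar(df$sequence)))
    stop("peptide span does not match sequence length")
  class(df) <- c("peptide_observations", "data.frame")
  df
}
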