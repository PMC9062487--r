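# ---- detection filtering and secretion-mode classification -----------------

# default GO identifiers standing for the extracellular-vesicle branch
DEFAULT_EV_GO_TERMS <- c("GO:0070062",  # extracellular exosome
                         "GO:1903561",  # extracellular vesicle
                         "GO:0065010")  # extracellular membrane-bounded organelle

#' Detection filter per condition
#'
#' A protein counts as detected in a condition when it is quantified
#' (non-missing) in at least the condition's minimum number of samples,
#' e.g. two of three day-0 samples or three of twelve 72-h samples.
#'
#' @param matrix An [intensity_matrix()].
#' @param groups Named list mapping condition -> sample ids.
#' @param min_per_group Named integer vector of per-condition thresholds.
#' @return Named list of detected protein-group id vectors per condition.
#' @export
detection_filter <- function(matrix, groups, min_per_group) {
  v <- unclass(matrix)
  out <- list()
  for (cond in names(groups)) {
    ids <- groups[[cond]]
    if (!all(ids %in% colnames(v)))
      stop("unknown sample id in group '", cond, "'")
    thr <- min_per_group[[cond]]
    if (is.null(thr) || is.na(thr)) stop("no threshold for condition ", cond)
    if (thr > length(ids))
      stop(sprintf("threshold %d exceeds group size %d for '%s'",
                   thr, length(ids), cond))
    counts <- rowSums(!is.na(v[, ids, drop = FALSE]))
    out[[cond]] <- rownames(v)[counts >= thr]
  }
  out
}

#' Classify proteins by mode of secretion
#'
#' Modes may overlap. `signal_peptide`: the annotation carries a signal
#' peptide (classical secretion). `ev_associated`: any GO term in the
#' configured extracellular-vesicle set, an `EV_marker` flag, or membership
#' in a marker set of category `ev`. `hormone_granin`: a `hormone` or
#' `granin` flag or membership in a `beta_cell` marker set. `shed`: the
#' protein has a topology annotation with an extracellular region, i.e. an
#' ectodomain a sheddase could release -- a heuristic call, flagged as such
#' in the evidence. Unannotated proteins get empty modes with a
#' `"no annotation"` evidence string.
#'
#' @param accessions Character vector of protein accessions.
#' @param annotations An [annotation_table()].
#' @param markers Optional `marker_set_collection` (or list of
#'   [marker_set()]).
#' @param topologies Optional named list of [topology_annotation()] for the
#'   sheddome heuristic.
#' @param ev_go_terms GO identifiers defining the EV branch.
#' @return A `secretion_classification` `data.frame`: `accession`, `modes`
#'   (semicolon-joined), `evidence` (semicolon-joined).
#' @export
classify_secretion_mode <- function(accessions, annotations, markers = NULL,
                                    topologies = NULL,
                                    ev_go_terms = DEFAULT_EV_GO_TERMS) {
  ann_idx <- match(accessions, annotations$accession)
  ev_members <- character(0)
  bc_members <- character(0)
  if (!is.null(markers)) {
    for (s in markers) {
      if (s$category == "ev") ev_members <- c(ev_members, s$members)
      if (s$category == "beta_cell") bc_members <- c(bc_members, s$members)
    }
  }
  modes <- character(length(accessions))
  evidence <- character(length(accessions))
  for (i in seq_along(accessions)) {
    j <- ann_idx[i]
    if (is.na(j)) {
      modes[i] <- ""
      evidence[i] <- "no annotation"
      next
    }
    m <- character(0); e <- character(0)
    sym <- annotations$gene_symbol[j]
    flags <- split_set(annotations$marker_flags[j])
    gos <- split_set(annotations$go_terms[j])
    if (isTRUE(annotations$has_signal_peptide[j])) {
      m <- c(m, "signal_peptide"); e <- c(e, "signal peptide annotation")
    }
    in_ev_set <- accessions[i] %in% ev_members ||
      (!is.na(sym) && sym %in% ev_members)
    if (any(gos %in% ev_go_terms) || "EV_marker" %in% flags || in_ev_set) {
      m <- c(m, "ev_associated")
      e <- c(e, "EV GO term/marker")
    }
    in_bc_set <- accessions[i] %in% bc_members ||
      (!is.na(sym) && sym %in% bc_members)
    if (any(c("hormone", "granin") %in% flags) || in_bc_set) {
      m <- c(m, "hormone_granin"); e <- c(e, "hormone/granin flag")
    }
    topo <- topologies[[accessions[i]]]
    if (!is.null(topo) &&
        any(topo$regions$category == "extracellular")) {
      m <- c(m, "shed")
      e <- c(e, "extracellular domain present (sheddome heuristic)")
    }
    modes[i] <- paste(m, collapse = ";")
    evidence[i] <- paste(e, collapse = ";")
  }
  out <- data.frame(accession = accessions, modes = modes,
                    evidence = evidence, stringsAsFactors = FALSE)
  class(out) <- c("secretion_classification", "data.frame")
  out
}

#' Signal-peptide and EV proportions of a detected set versus background
#'
#' Compares the percentage of proteins with a signal peptide (conventional
#' secretion) and the percentage of EV-associated proteins (nonconventional
#' secretion) in a detected set against a background proteome annotated
#' with the same scheme, attaching two-proportion z-test p-values.
#'
#' @param detected Character vector of detected accessions (non-empty).
#' @param annotations [annotation_table()] covering the detected set.
#' @param background [annotation_table()] for the background proteome.
#' @param ev_go_terms GO identifiers defining the EV branch.
#' @return List with `detected` and `background` percentage pairs, their
#'   differences, counts, and p-values.
#' @export
ev_proportion_vs_background <- function(detected, annotations, background,
                                        ev_go_terms = DEFAULT_EV_GO_TERMS) {
  if (!length(detected)) stop("empty detected set")
  pcts <- function(acc, ann) {
    cls <- classify_secretion_mode(acc, ann, ev_go_terms = ev_go_terms)
    has <- function(mode) vapply(cls$modes, function(m)
      mode %in% split_set(m), logical(1), USE.NAMES = FALSE)
    c(sp = 100 * mean(has("signal_peptide")),
      ev = 100 * mean(has("ev_associated")))
  }
  d <- pcts(detected, annotations)
  b <- pcts(background$accession, background)
  n_d <- length(detected); n_b <- nrow(background)
  ztest <- function(p1, p2) {
    x <- c(round(p1 / 100 * n_d), round(p2 / 100 * n_b))
    suppressWarnings(prop.test(x, c(n_d, n_b), correct = FALSE)$p.value)
  }
  list(pct_signal_peptide = unname(d["sp"]),
       pct_ev = unname(d["ev"]),
       background_pct_signal_peptide = unname(b["sp"]),
       background_pct_ev = unname(b["ev"]),
       diff_signal_peptide = unname(d["sp"] - b["sp"]),
       diff_ev = unname(d["ev"] - b["ev"]),
       n_detected = n_d, n_background = n_b,
       p_signal_peptide = ztest(d["sp"], b["sp"]),
       p_ev = ztest(d["ev"], b["ev"]))
}

#' Rank a secretome by median normalized abundance
#'
#' Orders protein groups by decreasing median log2-normalized abundance
#' across the given samples; ties break by accession lexicographic order so
#' the ranking is deterministic.
#'
#' @param matrix A `normalized_matrix`.
#' @param samples Sample ids to take medians over.
#' @param annotations Optional [annotation_table()] to attach gene symbols.
#' @return A `ranked_secretome` `data.frame`: `rank`, `accession`,
#'   `gene_symbol`, `median_abundance`.
#' @export
rank_secretome <- function(matrix, samples, annotations = NULL) {
  if (!length(samples)) stop("need >= 1 sample")
  v <- unclass(matrix)[, samples, drop = FALSE]
  med <- apply(v, 1, median, na.rm = TRUE)
  o <- order(-med, rownames(v))
  sym <- if (!is.null(annotations))
    annotations$gene_symbol[match(rownames(v)[o], annotations$accession)]
  else NA_character_
  out <- data.frame(rank = seq_along(o), accession = rownames(v)[o],
                    gene_symbol = sym, median_abundance = unname(med[o]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_secretome", "data.frame")
  out
}
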