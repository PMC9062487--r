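# ---- peptide-to-membrane-topology QC ---------------------------------------

# merge adjacent same-category regions (end + 1 == next start)
merge_regions <- function(regions) {
  if (nrow(regions) < 2) return(regions)
  out <- regions[1, , drop = FALSE]
  for (i in 2:nrow(regions)) {
    last <- nrow(out)
    if (regions$category[i] == out$category[last] &&
        regions$start[i] == out$end[last] + 1L) {
      out$end[last] <- regions$end[i]
    } else {
      out <- rbind(out, regions[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

classify_span <- function(start, end, topo) {
  if (end > topo$protein_length)
    stop(sprintf("%s: peptide end %d beyond protein length %d",
                 topo$accession, end, topo$protein_length))
  if (start < 1) stop("peptide start < 1")
  reg <- merge_regions(topo$regions)
  inside <- reg$start <= start & end <= reg$end
  if (any(inside)) return(reg$category[which(inside)[1]])
  touches <- reg$start <= end & start <= reg$end
  if (any(touches)) return("boundary")
  "unmapped"  # peptide falls entirely in an unannotated gap
}

#' Classify one peptide against a protein's membrane topology
#'
#' The peptide takes a region's category when its span lies entirely within
#' regions of that single category (contiguous same-category regions are
#' merged first); `boundary` when the span crosses categories; `unmapped`
#' when the accession carries no topology annotation. For peptides shared by
#' several annotated proteins the highest-priority mapping wins
#' (extracellular > intracellular > transmembrane; conflicting boundary
#' mappings stay boundary).
#'
#' @param peptide One row of a [peptide_observations()] table (or a list with
#'   `accession`, `start`, `end`).
#' @param topologies Named list of [topology_annotation()] objects.
#' @return One of `"extracellular"`, `"intracellular"`, `"transmembrane"`,
#'   `"signal"`, `"other"`, `"boundary"`, `"unmapped"`.
#' @export
classify_peptide_region <- function(peptide, topologies) {
  accs <- split_set(peptide$accession)
  annotated <- accs[accs %in% names(topologies)]
  if (!length(annotated)) return("unmapped")
  cats <- vapply(annotated, function(a)
    classify_span(peptide$start, peptide$end, topologies[[a]]), character(1))
  cats <- cats[cats != "unmapped"]
  if (!length(cats)) return("unmapped")
  priority <- c("extracellular", "intracellular", "transmembrane",
                "signal", "other", "boundary")
  unname(cats[order(match(cats, priority))][1])
}

#' Map identified peptides onto membrane topology and summarize purity
#'
#' Percentages are computed over unique peptide sequences with a
#' non-unmapped classification. `expected_ratio` is the summed length of
#' extracellular regions over intracellular regions in the topology set
#' (signal-peptide regions excluded from both); `observed_ratio` is
#' `pct_extracellular / pct_intracellular`. In a clean secretome,
#' peptides concentrate in extracellular (shed or cleaved-off) regions;
#' a lysate reproduces the database's length ratio.
#'
#' @param peptides A [peptide_observations()] table.
#' @param topologies Named list of [topology_annotation()] objects.
#' @return A `topology_qc_result` list: `n_peptides_mapped`,
#'   `pct_extracellular`, `pct_intracellular`, `pct_transmembrane`,
#'   `pct_boundary`, `expected_ratio`, `observed_ratio`, and the per-peptide
#'   `classifications`.
#' @export
summarize_topology <- function(peptides, topologies) {
  uniq <- peptides[!duplicated(peptides$sequence), , drop = FALSE]
  cats <- vapply(seq_len(nrow(uniq)), function(i)
    classify_peptide_region(uniq[i, ], topologies), character(1))
  mapped <- cats[cats != "unmapped"]
  if (!length(mapped)) stop("no classifiable peptide")
  pct <- function(k) 100 * sum(mapped == k) / length(mapped)
  # signal/other regions counted with boundary-free remainder: the four
  # reported classes cover extracellular/intracellular/transmembrane/boundary;
  # signal- or other-region peptides are folded into boundary-free "other"
  # which the percentages below simply do not claim.
  pct_extr <- pct("extracellular")
  pct_intr <- pct("intracellular")
  pct_tm <- pct("transmembrane")
  pct_bnd <- 100 - pct_extr - pct_intr - pct_tm
  lens <- lapply(topologies, function(t) {
    r <- t$regions
    c(extr = sum(r$end[r$category == "extracellular"] -
                   r$start[r$category == "extracellular"] + 1L),
      intr = sum(r$end[r$category == "intracellular"] -
                   r$start[r$category == "intracellular"] + 1L))
  })
  lens <- do.call(rbind, lens)
  expected <- sum(lens[, "extr"]) / sum(lens[, "intr"])
  structure(list(n_peptides_mapped = length(mapped),
                 pct_extracellular = pct_extr,
                 pct_intracellular = pct_intr,
                 pct_transmembrane = pct_tm,
                 pct_boundary = pct_bnd,
                 expected_ratio = expected,
                 observed_ratio = pct_extr / pct_intr,
                 classifications = data.frame(sequence = uniq$sequence,
                                              category = cats,
                                              stringsAsFactors = FALSE)),
            class = "topology_qc_result")
}

#' @export
print.topology_qc_result <- function(x, ...) {
  cat("<topology_qc_result>\n")
  cat(sprintf("  peptides mapped: %d\n", x$n_peptides_mapped))
  cat(sprintf("  extracellular %.1f%% | intracellular %.1f%% | transmembrane %.1f%% | boundary %.1f%%\n",
              x$pct_extracellular, x$pct_intracellular,
              x$pct_transmembrane, x$pct_boundary))
  cat(sprintf("  expected extra:intra length ratio %.2f, observed %.2f\n",
              x$expected_ratio, x$observed_ratio))
  invisible(x)
}

#' Verdict on a topology QC result
#'
#' `"secretome-like"` when the extracellular percentage reaches
#' `secretome_threshold`; `"lysate-like"` when the observed
#' extracellular:intracellular ratio is within `ratio_tolerance` (relative)
#' of the expected database ratio; `"intermediate"` otherwise.
#'
#' @param result A [summarize_topology()] result.
#' @param ratio_tolerance Relative tolerance on the ratio (default 0.25).
#' @param secretome_threshold Extracellular percentage cut-off (default 90).
#' @return List with `verdict` and the quantities it used.
#' @export
compare_to_expectation <- function(result, ratio_tolerance = 0.25,
                                   secretome_threshold = 90) {
  rel <- abs(result$observed_ratio - result$expected_ratio) /
    result$expected_ratio
  verdict <- if (result$pct_extracellular >= secretome_threshold)
    "secretome-like"
  else if (is.finite(rel) && rel <= ratio_tolerance) "lysate-like"
  else "intermediate"
  list(verdict = verdict,
       pct_extracellular = result$pct_extracellular,
       observed_ratio = result$observed_ratio,
       expected_ratio = result$expected_ratio,
       relative_ratio_deviation = rel,
       ratio_tolerance = ratio_tolerance,
       secretome_threshold = secretome_threshold)
}
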