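# ---- marker signal fractions and lysate-vs-secretome leakage ---------------

# resolve marker members to matrix rows: accession exact match against the
# accessions inside protein-group ids, then gene-symbol match via annotations
resolve_marker_rows <- function(matrix, markers, annotations = NULL) {
  ids <- rownames(matrix)
  accs <- strsplit(ids, ";", fixed = TRUE)
  hit <- vapply(accs, function(a) any(a %in% markers$members), logical(1))
  if (!is.null(annotations)) {
    sym_of <- setNames(annotations$gene_symbol, annotations$accession)
    hit <- hit | vapply(accs, function(a) {
      s <- sym_of[a]
      any(!is.na(s) & s %in% markers$members)
    }, logical(1))
  }
  which(hit)
}

#' Marker-set signal fraction per sample
#'
#' Relative abundance of a marker set, computed on raw (linear) intensities
#' as the sum of marker protein-group intensities over the sample's total
#' intensity. Missing values contribute zero to both sums. Used with
#' apoptosis and organelle negative-control sets: a clean secretome keeps
#' these fractions low (conventionally under 2%).
#'
#' @param matrix Raw-scale [intensity_matrix()].
#' @param markers A [marker_set()].
#' @param annotations Optional [annotation_table()] for gene-symbol
#'   resolution of marker members.
#' @param threshold Pass threshold on the fraction (default 0.02).
#' @return A `marker_fraction_result` `data.frame` with one row per sample:
#'   `sample`, `fraction`, `threshold`, `passes`.
#' @export
marker_signal_fraction <- function(matrix, markers, annotations = NULL,
                                   threshold = 0.02) {
  stopifnot_raw(matrix)
  v <- unclass(matrix)
  totals <- colSums(v, na.rm = TRUE)
  if (any(totals == 0)) stop("sample with zero total intensity")
  rows <- resolve_marker_rows(matrix, markers, annotations)
  if (!length(rows)) {
    warning(sprintf("no member of marker set '%s' resolves to a matrix row",
                    markers$name))
    frac <- rep(0, ncol(v))
  } else {
    frac <- colSums(v[rows, , drop = FALSE], na.rm = TRUE) / totals
  }
  out <- data.frame(sample = colnames(v), marker_set = markers$name,
                    fraction = unname(frac), threshold = threshold,
                    passes = unname(frac) < threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_fraction_result", "data.frame")
  out
}

#' Cytoplasmic-protein leakage screen across paired lysate/secretome samples
#'
#' If intracellular proteins appear in conditioned medium through cell death
#' or membrane damage, their abundances should track the paired lysate.
#' For each lysate/secretome pair this computes the Spearman rank
#' correlation (average ranks on ties) over proteins annotated as
#' cytoplasmic and quantified in both members; a pair with fewer than
#' `min_shared` such proteins is skipped with a flag. The summary reports
#' the median and IQR across pairs and a verdict `"leakage unlikely"` when
#' the median absolute correlation stays at or below `bound`.
#'
#' @param lysate,secretome Raw or normalized [intensity_matrix()] objects
#'   whose columns are linked through `metadata$pair_id`.
#' @param metadata A [sample_metadata()] with `compartment` and `pair_id`.
#' @param annotations An [annotation_table()]; cytoplasmic means
#'   `subcellular_locations` contains `"Cytoplasm"`.
#' @param min_shared Minimum shared cytoplasmic proteins per pair
#'   (default 10).
#' @param bound Verdict bound on the median absolute rho (default 0.3).
#' @return A `leakage_result` list: `per_pair` `data.frame`
#'   (`pair_id`, `rho`, `n_proteins`, `skipped`), `median_rho`, `iqr`
#'   (length-2), `verdict`.
#' @export
leakage_correlation <- function(lysate, secretome, metadata, annotations,
                                min_shared = 10, bound = 0.3) {
  cyto <- annotations$accession[vapply(annotations$subcellular_locations,
                                       function(s) "Cytoplasm" %in% split_set(s),
                                       logical(1))]
  if (!length(cyto)) stop("no cytoplasmic annotation available")
  lys_meta <- metadata[metadata$compartment == "lysate" &
                         !is.na(metadata$pair_id), ]
  sec_meta <- metadata[metadata$compartment == "secretome" &
                         !is.na(metadata$pair_id), ]
  pairs <- intersect(lys_meta$pair_id, sec_meta$pair_id)
  if (!length(pairs)) stop("no lysate/secretome pair via pair_id")
  rows_l <- intersect(rownames(lysate), cyto)
  rows_s <- intersect(rownames(secretome), cyto)
  shared_rows <- intersect(rows_l, rows_s)
  res <- data.frame(pair_id = pairs, rho = NA_real_, n_proteins = 0L,
                    skipped = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(pairs)) {
    ls <- lys_meta$sample_id[lys_meta$pair_id == pairs[k]]
    ss <- sec_meta$sample_id[sec_meta$pair_id == pairs[k]]
    x <- unclass(lysate)[shared_rows, ls]
    y <- unclass(secretome)[shared_rows, ss]
    ok <- !is.na(x) & !is.na(y)
    res$n_proteins[k] <- sum(ok)
    if (sum(ok) < min_shared) {
      res$skipped[k] <- TRUE
      next
    }
    res$rho[k] <- cor(x[ok], y[ok], method = "spearman")
  }
  valid <- res$rho[!res$skipped]
  if (!length(valid)) stop("every pair was skipped (too few shared cytoplasmic proteins)")
  med <- median(valid)
  iqr <- unname(quantile(valid, c(0.25, 0.75)))
  structure(list(per_pair = res, median_rho = med, iqr = iqr,
                 verdict = if (abs(med) <= bound) "leakage unlikely"
                           else "possible leakage",
                 bound = bound),
            class = "leakage_result")
}

#' @export
print.leakage_result <- function(x, ...) {
  cat("<leakage_result>\n")
  cat(sprintf("  pairs: %d (%d skipped)\n", nrow(x$per_pair),
              sum(x$per_pair$skipped)))
  cat(sprintf("  median Spearman rho %.2f (IQR %.2f to %.2f) -> %s\n",
              x$median_rho, x$iqr[1], x$iqr[2], x$verdict))
  invisible(x)
}
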