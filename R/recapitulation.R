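# ---- recapitulation of reference expression profiles -----------------------

new_expression_profile <- function(feature, summary_value, expressed, rule) {
  if (anyDuplicated(feature)) stop("duplicate feature ids")
  df <- data.frame(feature = as.character(feature),
                   summary = summary_value,
                   expressed = as.logical(expressed),
                   stringsAsFactors = FALSE)
  structure(df, rule = rule,
            class = c("expression_profile", "data.frame"))
}

#' Expressed-gene profile from a TPM matrix
#'
#' A gene is expressed when its median TPM across samples reaches the
#' cut-off (inclusive; default 1 TPM).
#'
#' @param tpm_matrix An [intensity_matrix()] (or named matrix) of gene-level
#'   TPM values.
#' @param cutoff Median-TPM cut-off (default 1).
#' @return An `expression_profile` `data.frame` (`feature`, `summary`,
#'   `expressed`) with the applied rule recorded in the `rule` attribute.
#' @export
expressed_gene_set <- function(tpm_matrix, cutoff = 1) {
  v <- unclass(tpm_matrix)
  if (any(v < 0, na.rm = TRUE)) stop("negative TPM value")
  med <- apply(v, 1, median, na.rm = TRUE)
  new_expression_profile(rownames(v), med, med >= cutoff,
                         rule = sprintf("median TPM >= %g", cutoff))
}

#' Expressed-protein profile from an intensity matrix
#'
#' A protein is expressed when it is quantified (non-missing) in at least
#' `min_samples` samples and its species call is unambiguous: groups called
#' `ambiguous` or `contaminant` are excluded here even though
#' cross-species-ambiguous groups are retained as human upstream.
#'
#' @param matrix An [intensity_matrix()].
#' @param min_samples Minimum quantified samples (default 3).
#' @param ambiguity Optional [classify_protein_groups()] report covering the
#'   matrix rows; rows absent from the report count as unambiguous.
#' @return An `expression_profile` `data.frame`.
#' @export
expressed_protein_set <- function(matrix, min_samples = 3, ambiguity = NULL) {
  v <- unclass(matrix)
  n_quant <- rowSums(!is.na(v))
  ok_species <- rep(TRUE, nrow(v))
  if (!is.null(ambiguity)) {
    pg <- ambiguity$per_group
    call <- pg$species_call[match(rownames(v), pg$group)]
    ok_species <- is.na(call) | !call %in% c("ambiguous", "contaminant")
  }
  new_expression_profile(rownames(v), n_quant,
                         n_quant >= min_samples & ok_species,
                         rule = sprintf(
                           "quantified in >= %d samples, unambiguous",
                           min_samples))
}

#' Recapitulation of a reference expression profile
#'
#' Percentage of the reference's expressed features also expressed in the
#' query, plus the Venn triple (reference-only, shared, query-only). The
#' denominator is fixed by the reference, so query-only features never
#' change the percentage.
#'
#' @param reference,query `expression_profile` objects in the same id
#'   namespace.
#' @param id_map Optional named character vector translating query feature
#'   ids into the reference namespace.
#' @return A `recapitulation_result` list: `n_reference`, `n_query`,
#'   `n_shared`, `pct_recapitulated`, `venn`, and the rules applied.
#' @export
recapitulation <- function(reference, query, id_map = NULL) {
  ref_set <- reference$feature[reference$expressed]
  qry_set <- query$feature[query$expressed]
  if (!is.null(id_map)) {
    mapped <- id_map[qry_set]
    qry_set <- unique(mapped[!is.na(mapped)])
  }
  if (!length(ref_set)) stop("empty reference expressed set")
  shared <- intersect(ref_set, qry_set)
  structure(list(n_reference = length(ref_set),
                 n_query = length(qry_set),
                 n_shared = length(shared),
                 pct_recapitulated = 100 * length(shared) / length(ref_set),
                 venn = c(reference_only = length(setdiff(ref_set, qry_set)),
                          shared = length(shared),
                          query_only = length(setdiff(qry_set, ref_set))),
                 reference_rule = attr(reference, "rule"),
                 query_rule = attr(query, "rule")),
            class = "recapitulation_result")
}

#' @export
print.recapitulation_result <- function(x, ...) {
  cat("<recapitulation_result>\n")
  cat(sprintf("  reference expressed: %d | query expressed: %d | shared: %d\n",
              x$n_reference, x$n_query, x$n_shared))
  cat(sprintf("  recapitulated: %.1f%% (rules: reference '%s'; query '%s')\n",
              x$pct_recapitulated, x$reference_rule, x$query_rule))
  invisible(x)
}
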