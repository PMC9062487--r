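# ---- readers and writers for the standard formats the pipeline touches -----

#' Read a protein FASTA database
#'
#' Parses UniProt-style (`>sp|ACC|NAME_SPECIES desc`) or generic headers.
#' Species is taken from the entry-name suffix (`_HUMAN`, `_MOUSE`, anything
#' else is `OTHER`); contaminants are recognized by an accession prefix
#' and/or an explicit accession list.
#'
#' @param path FASTA file path.
#' @param header_dialect `"uniprot"` or `"generic"` (first whitespace token is
#'   the accession).
#' @param contaminant_prefix Accession prefix marking contaminant entries
#'   (default `"Cont_"`, the common contaminant-library dialect).
#' @param contaminant_accessions Optional character vector of additional
#'   contaminant accessions.
#' @return A `data.frame` with columns `accession`, `entry_name`, `species`,
#'   `is_contaminant`, `sequence`.
#' @export
read_fasta <- function(path, header_dialect = c("uniprot", "generic"),
                       contaminant_prefix = "Cont_",
                       contaminant_accessions = NULL) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  first_tok <- sub("\\s.*$", "", headers)
  acc <- character(length(headers))
  entry <- character(length(headers))
  malformed <- logical(length(headers))
  if (header_dialect == "uniprot") {
    parts <- strsplit(first_tok, "|", fixed = TRUE)
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) >= 3 && p[1] %in% c("sp", "tr")) {
        acc[i] <- p[2]; entry[i] <- p[3]
      } else if (length(p) == 2) {
        # contaminant-library style "Cont_P00761|TRYP_PIG"
        acc[i] <- p[1]; entry[i] <- p[2]
      } else {
        acc[i] <- first_tok[i]; entry[i] <- first_tok[i]
        malformed[i] <- TRUE
      }
    }
    if (any(malformed))
      warning(sum(malformed), " malformed header(s); species set to OTHER")
  } else {
    acc <- first_tok
    entry <- first_tok
  }
  if (any(!nzchar(acc))) stop("empty accession in FASTA header")
  if (anyDuplicated(acc))
    stop("duplicate accession: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  suffix <- sub("^.*_", "", entry)
  species <- ifelse(malformed, "OTHER",
                    ifelse(suffix == "HUMAN", "HUMAN",
                           ifelse(suffix == "MOUSE", "MOUSE", "OTHER")))
  is_cont <- startsWith(acc, contaminant_prefix) |
    acc %in% (contaminant_accessions %||% character(0))
  data.frame(accession = acc, entry_name = entry, species = species,
             is_contaminant = is_cont,
             sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]; non-contaminant records get `sp|ACC|ENTRY`
#' headers, contaminant records keep their prefixed accession as
#' `ACC|ENTRY`.
#'
#' @param records A `data.frame` as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(records$is_contaminant,
                paste0(records$accession, "|", records$entry_name),
                paste0("sp|", records$accession, "|", records$entry_name))
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read marker gene sets from a GMT file
#'
#' Standard GMT: `name TAB description TAB member...`. The description field
#' is interpreted as the marker category when it matches one of
#' `apoptosis`, `organelle`, `ev`, `beta_cell`; anything else maps to
#' `other`. Duplicate members are deduplicated.
#'
#' @param path GMT file path.
#' @return A named list of [marker_set()] objects
#'   (class `marker_set_collection`).
#' @export
read_marker_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    category <- if (f[2] %in% MARKER_CATEGORIES) f[2] else "other"
    sets[[i]] <- marker_set(f[1], members = f[-(1:2)], category = category)
    nms[i] <- f[1]
  }
  if (anyDuplicated(nms)) stop("duplicate marker set name in GMT")
  names(sets) <- nms
  structure(sets, class = "marker_set_collection")
}

#' Write a marker set collection to GMT
#'
#' @param sets A `marker_set_collection` or list of [marker_set()] objects.
#' @param path Output path.
#' @export
write_marker_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$category, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-group intensity matrix from TSV
#'
#' First column is the protein-group identifier (kept verbatim, semicolons
#' allowed); remaining columns are samples. Empty cells and `NA` parse as
#' missing, never zero.
#'
#' @param path TSV file path.
#' @param metadata Optional [sample_metadata()]; when given, every sample
#'   column must be covered.
#' @return A raw-scale [intensity_matrix()].
#' @export
read_protein_matrix <- function(path, metadata = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("matrix file needs an id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(metadata)) {
    missing_meta <- setdiff(colnames(m), metadata$sample_id)
    if (length(missing_meta))
      stop("sample column(s) without metadata: ",
           paste(missing_meta, collapse = ", "))
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity value in ", path)
  intensity_matrix(m, scale = "raw")
}

#' Write an intensity matrix to TSV
#'
#' @param matrix An [intensity_matrix()] (or plain named matrix).
#' @param path Output path.
#' @param id_column Name of the identifier column (default `"protein_group"`).
#' @export
write_protein_matrix <- function(matrix, path, id_column = "protein_group") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read membrane topology annotations from TSV
#'
#' Expects columns `accession`, `start`, `end`, `category`, `protein_length`.
#' Regions are grouped per accession, sorted and validated (no overlap,
#' within protein bounds). Unknown categories map to `other` with a warning.
#'
#' @param path TSV file path.
#' @return A named list of [topology_annotation()] objects.
#' @export
read_topology_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "start", "end", "category", "protein_length")
  if (!all(need %in% colnames(df)))
    stop("topology table must have columns: ", paste(need, collapse = ", "))
  unknown <- !df$category %in% REGION_CATEGORIES
  if (any(unknown)) {
    warning("unknown topology categories mapped to 'other': ",
            paste(unique(df$category[unknown]), collapse = ", "))
    df$category[unknown] <- "other"
  }
  out <- lapply(split(df, df$accession), function(d) {
    if (length(unique(d$protein_length)) != 1)
      stop(d$accession[1], ": inconsistent protein_length")
    topology_annotation(d$accession[1],
                        d[, c("start", "end", "category")],
                        d$protein_length[1])
  })
  out[order(names(out))]
}

#' Write topology annotations to TSV
#'
#' @param topologies A (named) list of [topology_annotation()] objects.
#' @param path Output path.
#' @export
write_topology_table <- function(topologies, path) {
  rows <- lapply(topologies, function(t)
    data.frame(accession = t$accession, t$regions,
               protein_length = t$protein_length,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
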