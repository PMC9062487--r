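# ---- seeded synthetic fixtures with planted ground truth -------------------

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# tryptic-peptide alphabet: canonical residues minus K/R (internal cleavage)
# and minus P (so trypsin and trypsin_p digest identically on fixtures)
PEPTIDE_BODY_ALPHABET <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]

random_tryptic_peptides <- function(n, len_range) {
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out) + 50L
    lens <- sample(seq(len_range[1], len_range[2]), k, replace = TRUE)
    bodies <- vapply(lens, function(L)
      paste(sample(PEPTIDE_BODY_ALPHABET, L - 1L, replace = TRUE),
            collapse = ""), character(1))
    peps <- paste0(bodies, sample(c("K", "R"), k, replace = TRUE))
    out <- unique(c(out, peps))
  }
  out[seq_len(n)]
}

#' Generate a two-species proteome with a planted shared-peptide fraction
#'
#' Builds human and mouse protein sets as concatenations of distinct
#' tryptic peptides (each ending in K/R with no internal K/R/P, so the
#' package's default digest recovers them exactly). A controllable fraction
#' of the unique peptide inventory is shared verbatim between the species'
#' orthologs, emulating cross-species sequence identity; contaminant
#' entries are always included so exclusion paths are exercised.
#'
#' @param n_proteins Total proteins across both species (split evenly).
#' @param shared_fraction Target fraction of unique tryptic peptides shared
#'   between the species, in \[0, 1\].
#' @param peptides_per_protein Tryptic peptides per protein.
#' @param peptide_length Length-2 range of peptide lengths (residues).
#' @param n_contaminants Number of contaminant entries.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return List with `records` (a `data.frame` in [read_fasta()] layout) and
#'   `truth` (`shared_fraction_target`, `shared_fraction_realized`,
#'   `species` per accession).
#' @export
generate_proteome <- function(n_proteins = 1000, shared_fraction = 0.3,
                              peptides_per_protein = 12,
                              peptide_length = c(8, 12),
                              n_contaminants = 3, seed = 1) {
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  if (n_proteins < 10) stop("need >= 10 proteins")
  with_seed(seed, {
    n_per_species <- n_proteins %/% 2L
    P <- n_per_species * peptides_per_protein
    q <- shared_fraction
    s <- round(2 * P * q / (1 + q))
    n_needed <- s + 2L * (P - s) + n_contaminants * peptides_per_protein
    inventory <- random_tryptic_peptides(n_needed, peptide_length)
    shared <- inventory[seq_len(s)]
    human_only <- inventory[s + seq_len(P - s)]
    mouse_only <- inventory[s + (P - s) + seq_len(P - s)]
    cont_peps <- inventory[seq.int(2L * P - s + 1L, n_needed)]

    place <- function(shared, own) {
      slots <- character(P)
      pos <- sample.int(P, length(shared))
      slots[pos] <- shared
      slots[slots == ""] <- own
      slots
    }
    h_slots <- place(shared, human_only)
    m_slots <- place(shared, mouse_only)
    to_prot <- function(slots) {
      vapply(split(slots, rep(seq_len(n_per_species),
                              each = peptides_per_protein)),
             paste, character(1), collapse = "")
    }
    h_seq <- to_prot(h_slots)
    m_seq <- to_prot(m_slots)
    cont_seq <- vapply(split(cont_peps, rep(seq_len(max(n_contaminants, 1L)),
                                            each = peptides_per_protein)),
                       paste, character(1), collapse = "")
    if (!n_contaminants) cont_seq <- character(0)
    records <- data.frame(
      accession = c(sprintf("HQ%05d", seq_len(n_per_species)),
                    sprintf("MQ%05d", seq_len(n_per_species)),
                    if (n_contaminants) sprintf("Cont_C%03d", seq_len(n_contaminants))),
      entry_name = c(sprintf("HP%d_HUMAN", seq_len(n_per_species)),
                     sprintf("MP%d_MOUSE", seq_len(n_per_species)),
                     if (n_contaminants) sprintf("CP%d_PIG", seq_len(n_contaminants))),
      species = c(rep("HUMAN", n_per_species), rep("MOUSE", n_per_species),
                  rep("OTHER", n_contaminants)),
      is_contaminant = c(rep(FALSE, 2L * n_per_species),
                         rep(TRUE, n_contaminants)),
      sequence = c(h_seq, m_seq, cont_seq),
      stringsAsFactors = FALSE, row.names = NULL)
    truth <- list(shared_fraction_target = q,
                  shared_fraction_realized = s / (2 * P - s),
                  n_shared_peptides = s,
                  species = setNames(records$species, records$accession))
    list(records = records, truth = truth)
  })
}

#' Generate surfaceome-like topology annotations
#'
#' Each protein gets a signal peptide, then alternating
#' extracellular/transmembrane/intracellular passes with region lengths
#' drawn so the combined extracellular:intracellular length ratio sits near
#' the 2.4:1 seen for annotated surface proteins.
#'
#' @param n_proteins Number of annotated proteins.
#' @param ext_len,int_len Length-2 uniform ranges for extracellular and
#'   intracellular region lengths (residues).
#' @param tm_len Transmembrane helix length (residues).
#' @param passes_range Range of membrane passes per protein.
#' @param seed RNG seed.
#' @return Named list of [topology_annotation()] objects.
#' @export
generate_topology_fixture <- function(n_proteins = 200,
                                      ext_len = c(180, 300),
                                      int_len = c(60, 140),
                                      tm_len = 21, passes_range = c(1, 3),
                                      seed = 1) {
  with_seed(seed, {
    out <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      k <- sample(seq(passes_range[1], passes_range[2]), 1)
      cats <- "signal"; lens <- 20L
      for (p in seq_len(k)) {
        cats <- c(cats, "extracellular", "transmembrane", "intracellular")
        lens <- c(lens,
                  sample(seq(ext_len[1], ext_len[2]), 1), tm_len,
                  sample(seq(int_len[1], int_len[2]), 1))
        if (p < k) { cats <- c(cats, "transmembrane"); lens <- c(lens, tm_len) }
      }
      ends <- cumsum(lens)
      starts <- c(1L, head(ends, -1) + 1L)
      acc <- sprintf("TP%05d", i)
      out[[i]] <- topology_annotation(
        acc, data.frame(start = starts, end = ends, category = cats,
                        stringsAsFactors = FALSE),
        protein_length = ends[length(ends)])
    }
    names(out) <- vapply(out, `[[`, character(1), "accession")
    out
  })
}

#' Place peptides on annotated proteins
#'
#' With `frac_extracellular = NULL` peptide start positions are uniform
#' along the proteins (lysate-like); otherwise that fraction of peptides is
#' placed fully inside extracellular regions and the remainder uniformly
#' (secretome-like).
#'
#' @param topologies Named list of [topology_annotation()].
#' @param n_peptides Number of peptides to place.
#' @param peptide_length Peptide length (residues).
#' @param frac_extracellular `NULL` for uniform placement, else proportion
#'   forced into extracellular regions.
#' @param seed RNG seed.
#' @return A [peptide_observations()] table (synthetic sequences).
#' @export
generate_topology_peptides <- function(topologies, n_peptides = 5000,
                                       peptide_length = 10,
                                       frac_extracellular = NULL, seed = 1) {
  with_seed(seed, {
    L <- as.integer(peptide_length)
    lens <- vapply(topologies, `[[`, integer(1), "protein_length")
    w <- pmax(lens - L + 1L, 0L)
    acc <- names(topologies)
    pick <- sample(seq_along(acc), n_peptides, replace = TRUE, prob = w)
    starts <- integer(n_peptides)
    forced <- if (is.null(frac_extracellular)) rep(FALSE, n_peptides)
      else runif(n_peptides) < frac_extracellular
    for (i in seq_len(n_peptides)) {
      topo <- topologies[[pick[i]]]
      if (forced[i]) {
        reg <- topo$regions
        reg <- reg[reg$category == "extracellular" &
                     reg$end - reg$start + 1L >= L, , drop = FALSE]
        j <- sample.int(nrow(reg), 1,
                        prob = reg$end - reg$start - L + 2L)
        starts[i] <- reg$start[j] +
          sample.int(reg$end[j] - reg$start[j] - L + 2L, 1) - 1L
      } else {
        starts[i] <- sample.int(topo$protein_length - L + 1L, 1)
      }
    }
    seqs <- vapply(seq_len(n_peptides), function(i)
      paste(sample(PEPTIDE_BODY_ALPHABET, L, replace = TRUE), collapse = ""),
      character(1))
    peptide_observations(sequence = seqs, accession = acc[pick],
                         start = starts, end = starts + L - 1L)
  })
}

#' Generate a paired lysate/secretome experiment with planted ground truth
#'
#' Log-normal protein intensities for paired lysate and secretome samples.
#' On the linear scale each secretome sample is
#' `(1 - leakage) * independent secretome signal + leakage * paired lysate`,
#' one planted (apoptosis) marker set carries exactly `marker_fraction` of
#' every secretome sample's total before missingness, and missing values
#' are introduced MCAR or biased toward low intensities. A membrane-protein
#' subset carries topology annotations, with detected peptides placed
#' predominantly in extracellular regions as in a clean secretome.
#'
#' @param n_proteins Number of protein groups.
#' @param n_pairs Number of lysate/secretome sample pairs.
#' @param leakage Mixing level lambda in \[0, 1\].
#' @param marker_fraction Planted marker signal fraction f (must be < 1).
#' @param n_marker_proteins Size of the planted marker set.
#' @param cyto_fraction Fraction of proteins annotated cytoplasmic.
#' @param missing_rate Expected fraction of missing cells.
#' @param missing_mechanism `"MCAR"` or `"low_intensity_biased"` (logistic
#'   in latent log2 intensity).
#' @param meanlog,sdlog Protein baseline distribution on the log2 scale.
#' @param noise_sd Per-sample residual SD on the log2 scale.
#' @param signal_peptide_prob,ev_prob,hormone_prob Planted secretion-mode
#'   label probabilities.
#' @param n_membrane Number of proteins given topology annotations.
#' @param n_peptides Peptides placed on the membrane subset.
#' @param frac_extracellular Fraction of those peptides forced into
#'   extracellular regions.
#' @param seed RNG seed.
#' @return List: `lysate`, `secretome` (raw [intensity_matrix()]s),
#'   `metadata`, `markers`, `annotations`, `topologies`, `peptides`,
#'   `truth` (planted lambda, f, masked true values, mode labels, ...).
#' @export
generate_secretome_experiment <- function(n_proteins = 500, n_pairs = 6,
                                          leakage = 0,
                                          marker_fraction = 0.015,
                                          n_marker_proteins = 50,
                                          cyto_fraction = 0.4,
                                          missing_rate = 0.01,
                                          missing_mechanism = c("MCAR", "low_intensity_biased"),
                                          meanlog = 20, sdlog = 1.2,
                                          noise_sd = 0.4,
                                          signal_peptide_prob = 0.5,
                                          ev_prob = 0.3,
                                          hormone_prob = 0.05,
                                          n_membrane = 100,
                                          n_peptides = 2000,
                                          frac_extracellular = 0.95,
                                          seed = 1) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (marker_fraction >= 1) stop("marker_fraction must be < 1")
  if (leakage < 0 || leakage > 1) stop("leakage must be in [0, 1]")
  if (n_marker_proteins >= n_proteins)
    stop("n_marker_proteins must be smaller than n_proteins")
  with_seed(seed, {
    acc <- sprintf("SP%05d", seq_len(n_proteins))
    lys_ids <- sprintf("L%02d", seq_len(n_pairs))
    sec_ids <- sprintf("S%02d", seq_len(n_pairs))
    b <- rnorm(n_proteins, meanlog, sdlog)       # lysate baseline
    cvec <- rnorm(n_proteins, meanlog, sdlog)    # independent secretome baseline
    lys <- 2^(b + matrix(rnorm(n_proteins * n_pairs, 0, noise_sd),
                         n_proteins, n_pairs))
    sec_ind <- 2^(cvec + matrix(rnorm(n_proteins * n_pairs, 0, noise_sd),
                                n_proteins, n_pairs))
    sec <- (1 - leakage) * sec_ind + leakage * lys
    dimnames(lys) <- list(acc, lys_ids)
    dimnames(sec) <- list(acc, sec_ids)

    marker_rows <- sort(sample.int(n_proteins, n_marker_proteins))
    f <- marker_fraction
    for (j in seq_len(n_pairs)) {
      m_sum <- sum(sec[marker_rows, j])
      o_sum <- sum(sec[-marker_rows, j])
      sec[marker_rows, j] <- sec[marker_rows, j] * (f * o_sum) / ((1 - f) * m_sum)
    }

    add_missing <- function(m) {
      p <- if (missing_mechanism == "MCAR") {
        matrix(missing_rate, nrow(m), ncol(m))
      } else {
        lx <- log2(m)
        w <- stats::plogis(stats::quantile(lx, 0.2) - lx)
        missing_rate * w / mean(w)
      }
      mask <- matrix(runif(length(m)) < p, nrow(m), ncol(m))
      list(values = ifelse(mask, NA_real_, m), mask = mask)
    }
    lys_m <- add_missing(lys)
    sec_m <- add_missing(sec)
    dimnames(lys_m$values) <- dimnames(lys)
    dimnames(sec_m$values) <- dimnames(sec)

    metadata <- sample_metadata(
      sample_id = c(lys_ids, sec_ids),
      condition = "siCTRL_72h",
      compartment = rep(c("lysate", "secretome"), each = n_pairs),
      pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2))

    cyto <- runif(n_proteins) < cyto_fraction
    cyto[marker_rows] <- FALSE  # planted markers are secreted signal, not leakage
    sp_label <- runif(n_proteins) < signal_peptide_prob
    ev_label <- runif(n_proteins) < ev_prob
    hor_label <- runif(n_proteins) < hormone_prob
    membrane_rows <- sort(sample.int(n_proteins, min(n_membrane, n_proteins)))
    topo_raw <- generate_topology_fixture(length(membrane_rows),
                                          seed = seed + 1L)
    topologies <- setNames(topo_raw, acc[membrane_rows])
    for (i in seq_along(topologies))
      topologies[[i]]$accession <- names(topologies)[i]
    shed_label <- seq_len(n_proteins) %in% membrane_rows

    annotations <- annotation_table(
      accession = acc,
      gene_symbol = sprintf("GENE%04d", seq_len(n_proteins)),
      has_signal_peptide = sp_label,
      subcellular_locations = ifelse(cyto, "Cytoplasm", "Secreted"),
      go_terms = ifelse(ev_label, "GO:0070062", ""),
      marker_flags = ifelse(hor_label, "hormone", ""))

    markers <- marker_set("planted_apoptosis", members = acc[marker_rows],
                          category = "apoptosis")
    peptides <- generate_topology_peptides(topologies, n_peptides = n_peptides,
                                           frac_extracellular = frac_extracellular,
                                           seed = seed + 2L)

    truth <- list(leakage = leakage,
                  marker_fraction = marker_fraction,
                  marker_accessions = acc[marker_rows],
                  cytoplasmic_accessions = acc[cyto],
                  lysate_true = lys, secretome_true = sec,
                  lysate_mask = lys_m$mask, secretome_mask = sec_m$mask,
                  modes = data.frame(
                    accession = acc,
                    signal_peptide = sp_label, ev_associated = ev_label,
                    hormone_granin = hor_label, shed = shed_label,
                    stringsAsFactors = FALSE))
    list(lysate = intensity_matrix(lys_m$values, "raw"),
         secretome = intensity_matrix(sec_m$values, "raw"),
         metadata = metadata, markers = markers,
         annotations = annotations, topologies = topologies,
         peptides = peptides, truth = truth)
  })
}

#' Generate a reference/query expression-profile pair with planted overlap
#'
#' Builds gene-level TPM matrices whose expressed sets (median TPM >= 1)
#' realize an exact planted overlap: the query expresses
#' `round(overlap * n_reference)` of the reference's expressed genes plus
#' `n_query_extra` genes of its own. Median TPMs sit safely away from the
#' cut-off unless `margin_noise` pulls them toward it.
#'
#' @param n_features Universe size (shared gene id namespace).
#' @param n_reference Reference expressed-set size.
#' @param overlap Planted overlap proportion in \[0, 1\].
#' @param n_query_extra Query-only expressed genes.
#' @param margin_noise SD of log-normal jitter applied to medians near the
#'   cut-off (0 = noise-free, overlap recovered exactly).
#' @param seed RNG seed.
#' @return List: `reference`, `query` ([expressed_gene_set()] profiles),
#'   `reference_tpm`, `query_tpm` (matrices), `truth`.
#' @export
generate_reference_pair <- function(n_features = 10000, n_reference = 1000,
                                    overlap = 0.9, n_query_extra = 200,
                                    margin_noise = 0, seed = 1) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  with_seed(seed, {
    feats <- sprintf("G%06d", seq_len(n_features))
    ref_idx <- sort(sample.int(n_features, n_reference))
    n_shared <- round(overlap * n_reference)
    shared_idx <- sort(sample(ref_idx, n_shared))
    extra_idx <- sort(sample(setdiff(seq_len(n_features), ref_idx),
                             n_query_extra))
    qry_idx <- sort(c(shared_idx, extra_idx))
    build_tpm <- function(expr_idx) {
      med <- runif(n_features, 0, 0.5)
      med[expr_idx] <- runif(length(expr_idx), 2, 100)
      if (margin_noise > 0)
        med <- med * exp(rnorm(n_features, 0, margin_noise))
      m <- cbind(med * 0.9, med, med * 1.1)
      dimnames(m) <- list(feats, paste0("R", 1:3))
      m
    }
    ref_tpm <- build_tpm(ref_idx)
    qry_tpm <- build_tpm(qry_idx)
    colnames(qry_tpm) <- paste0("Q", 1:3)
    list(reference = expressed_gene_set(ref_tpm),
         query = expressed_gene_set(qry_tpm),
         reference_tpm = ref_tpm, query_tpm = qry_tpm,
         truth = list(overlap_target = overlap,
                      overlap_realized = n_shared / n_reference,
                      n_reference = n_reference, n_shared = n_shared))
  })
}
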