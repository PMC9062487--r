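# Independent oracles used to check pipeline operations on small instances.

# Brute-force tryptic digest: enumerate every substring [i, j] and keep it
# iff both boundaries are cleavage points (or sequence ends) and the number
# of internal cleavage sites does not exceed the missed-cleavage budget.
brute_digest <- function(sequence, rule, missed, min_len = 1L,
                         max_len = 100000L) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(ch)
  site <- ch %in% c("K", "R")
  if (rule == "trypsin") site <- site & c(ch[-1] != "P", TRUE)
  peps <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- i == 1L || site[i - 1L]
      right_ok <- j == n || site[j]
      if (!left_ok || !right_ok) next
      internal <- if (j > i) sum(site[i:(j - 1L)]) else 0L
      if (internal > missed) next
      len <- j - i + 1L
      if (len < min_len || len > max_len) next
      peps[[length(peps) + 1L]] <- c(i, j)
    }
  }
  if (!length(peps)) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0)))
  }
  m <- do.call(rbind, peps)
  o <- order(m[, 1], m[, 2])
  data.frame(peptide = substring(sequence, m[o, 1], m[o, 2]),
             start = m[o, 1], end = m[o, 2], stringsAsFactors = FALSE)
}

random_aa_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# Brute-force quantile normalization with average-rank ties: every sample is
# mapped onto the vector of per-rank means via interpolation at its average
# ranks.
brute_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(x) {
    r <- rank(x, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = r)$y
  })
}

# Brute-force Benjamini-Hochberg step-up: q_i = min over ranks >= rank(i) of
# p_(j) * n / j, capped at 1.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * n / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# small fixture builders -----------------------------------------------------

tiny_topology <- function() {
  list(P1 = topology_annotation(
    "P1",
    data.frame(start = c(1, 51, 72), end = c(50, 71, 100),
               category = c("extracellular", "transmembrane",
                            "intracellular"),
               stringsAsFactors = FALSE),
    protein_length = 100))
}

tiny_records <- function() {
  # HQ1 and MQ1 share peptide ELVISLIVESK; HQ2 is human-only; Cont_T is a
  # contaminant sharing nothing.
  data.frame(
    accession = c("HQ1", "MQ1", "HQ2", "Cont_T1"),
    entry_name = c("H1_HUMAN", "M1_MOUSE", "H2_HUMAN", "T1_PIG"),
    species = c("HUMAN", "MOUSE", "HUMAN", "OTHER"),
    is_contaminant = c(FALSE, FALSE, FALSE, TRUE),
    sequence = c("ELVISLIVESKAAAAAGK",
                 "ELVISLIVESKCCCCCCK",
                 "DDDDDDKEEEEEEK",
                 "FFFFFFKGGGGGGK"),
    stringsAsFactors = FALSE)
}
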