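---
title: "Methods behind secretomeQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind secretomeQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomeQC)
```

# The problem

Secretome proteomics of cultured cells asks a deceptively simple question:
of the proteins measured in conditioned medium, which were genuinely
secreted? Three artifact classes confound the answer.

1. **Cross-species database ambiguity.** Cells grown on a xenogeneic matrix
   (e.g. human cells on a mouse-derived basement-membrane preparation) must
   be searched against a combined human + mouse + contaminant database.
   Many tryptic peptides are sequence-identical between orthologs, so a
   substantial fraction of identifications cannot be assigned to a species.
2. **Leakage.** Dying or damaged cells release cytoplasmic content; an
   intracellular protein found in the medium may reflect lysis rather than
   secretion.
3. **Matrix and reagent contaminants**, handled by a contaminant accession
   library.

`secretomeQC` implements the computational QC battery for this setting plus
the downstream characterization steps: preprocessing, secretion-mode
classification, and recapitulation scoring of a cell line against reference
transcriptomes/proteomes.

# Models and procedures

## In-silico digestion and ambiguity

`digest_protein()` cleaves C-terminally of K/R; the `trypsin` rule
suppresses cleavage before proline while `trypsin_p` (the default, matching
common DIA quantification settings) cleaves regardless. Peptides with up to
`missed_cleavages` internal sites are enumerated and the length window is
applied last. The ambiguity statistic is the fraction of unique
non-contaminant peptides mapping to at least one human *and* one mouse
protein. Defaults are 0 missed cleavages and a 6–52 residue window: a
conservative choice, because adding missed-cleavage variants mostly adds
longer, rarer, more species-specific peptides and deflates the estimate.
Groups whose only species-unique evidence carries wildcard residues
(X/U/B/Z) stay ambiguous; I and L are kept distinct (an equivalencing
option would only raise ambiguity and is off by default).

Observed protein groups are classified `human_unique` / `mouse_unique` /
`ambiguous` / `contaminant`. Ambiguous groups are *retained* (treated as
human) for abundance-level analyses — their intensity and missingness
behavior tracks human-unique proteins — but are *excluded* from
expressed-set definitions (`expressed_protein_set()`), where identity
matters more than signal.

## Topology QC

For membrane proteins with per-residue topology (signal peptide /
extracellular / transmembrane / intracellular), a genuine secretome should
contain peptides from extracellular regions — the parts that can be shed or
cleaved off — whereas lysis contributes intracellular and transmembrane
peptides in proportion to their sequence length. `summarize_topology()`
counts **unique peptide sequences** (not PSMs or intensities: deterministic
and order-free; an intensity-weighted variant would couple the statistic to
normalization choices). A peptide wholly inside one merged same-category
region takes that category; spans crossing categories form a separate
`boundary` class, which is why the main percentages can sum below the
extracellular + intracellular total of a boundary-free scheme. Peptides
shared by several annotated proteins take the highest-priority mapping
(extracellular > intracellular > transmembrane).

The reference statistic is the ratio of combined extracellular to
intracellular region lengths in the topology database (signal-peptide
regions excluded from both, since they are absent from the mature chain).
A lysate-like sample reproduces this ratio; a secretome-like sample instead
shows a high extracellular percentage (default verdict threshold 90%,
relative ratio tolerance 0.25 — both configurable, and both reported
alongside the verdict rather than replacing the numbers).

## Marker fractions and leakage

`marker_signal_fraction()` computes, per sample, the summed **raw linear**
intensity of a marker set over the sample's total; normalized or log-scale
values would break the interpretation as a signal share. Missing values
contribute zero to both sums. The conventional pass threshold for
apoptosis-marker signal is 2% of total intensity. Fractions are invariant
to per-sample rescaling and additive over disjoint sets.

`leakage_correlation()` tests a sharper prediction: if intracellular
proteins reach the medium through lysis, their abundances should *track the
paired lysate*. Per lysate/secretome pair it computes the Spearman
correlation (average ranks) over proteins annotated cytoplasmic and
quantified in both members; pairs with fewer than 10 such proteins are
skipped. The summary is the median and IQR across pairs — pairs, not pooled
samples, are the unit, because pooling would mix between-pair abundance
structure into the correlation.

## Preprocessing

* **Quantile normalization** (DIA-style near-complete matrices) maps every
  sample onto the distribution of per-rank means; ties receive the mean of
  the reference values at their tied ranks. The implementation delegates to
  `limma::normalizeQuantiles(ties = TRUE)` and is cross-checked in the test
  suite against a brute-force rank-mean construction.
* **Scaling-factor normalization** (TMT-style) multiplies each sample by
  `median(totals)/total`, equalizing totals while preserving within-sample
  ratios.
* Both are followed by `log2(x + offset)`; the pseudo-count defaults to 1
  (raw intensities are ≫ 1, so the offset is inert except at true zeros).
* **Sequential imputation**: rows are processed in increasing order of
  missing count; each missing cell is filled with the conditional mean of a
  multivariate normal over samples, estimated from the currently complete
  rows and updated as rows complete. This is a conditional-mean sequential
  scheme chosen for determinism and testability (it equals the OLS
  prediction from complete rows, which the tests exploit as an independent
  oracle); equivalence with any particular published sequential-imputation
  variant is not claimed. It is intended for the low missingness (~1–2% per
  sample) of DIA protein matrices, where the complete-row pool is large.
* **Differential expression** fits, per protein, log2 intensity on
  condition with the TMT plex as an additive fixed block term. A random
  intercept for plex is weakly identified with the 2–5 plexes typical of
  these designs; the fixed-block approximation is deterministic and
  yields identical contrasts in the balanced case. With one plex the term
  is dropped. p-values are two-sided; BH adjustment is applied within one
  experiment at a time, never pooled across experiments.
* **Power design**: `corrected_alpha()` is the Bonferroni division;
  `sample_size_two_sample_t()` scans integer group sizes against the exact
  noncentral-t power function (floor 2 per group).

## Secretion-mode classification

Modes may overlap. Signal-peptide and hormone/granin calls come directly
from annotation flags. The EV (extracellular-vesicle) call is
annotation-based — membership in the extracellular-exosome/vesicle GO
branch or an EV marker set — rather than a re-implementation of any
external EV-prediction model; it is an orthogonal, auditable analog. The
sheddome call is explicitly a *heuristic* (flagged as such in the evidence
string): a protein with an annotated extracellular domain could have that
ectodomain proteolytically released. Detection filtering follows the
min-samples-per-condition rule (e.g. 2 of 3, or 3 of 12) and is monotone in
the threshold. Abundance ranking uses per-protein medians with
lexicographic-accession tie-breaks so output is reproducible across runs.

## Recapitulation

Expressed sets use inclusive cut-offs: median TPM ≥ 1 for genes;
quantified in ≥ 3 samples *and* unambiguously annotated for proteins. The
recapitulation percentage is computed over the reference's expressed set,
so query-only features never move it. The result records the rule applied
on each side, because reference datasets may ship their own expressed-set
definitions.

# The synthetic-data generator

The generator produces fixtures with the statistical structure every stage
assumes, plus stored ground truth:

* **Proteomes** are concatenations of globally distinct tryptic peptides
  (terminal K/R, no internal K/R/P), with an exactly planted shared
  fraction between human and mouse orthologs and contaminant entries always
  present. Choosing `s` shared peptides among `P` per-species slots with
  `s = 2Pq/(1+q)` makes the unique-peptide shared fraction exactly `q`.
* **Topologies** follow a signal peptide + alternating
  extracellular (180–300 aa) / transmembrane (21 aa) / intracellular
  (60–140 aa) pass structure, 1–3 passes, giving a combined length ratio
  near the ~2.4:1 typical of annotated surface proteins. Uniformly placed
  peptides recover the database ratio with a small upward edge-effect bias
  (a peptide of length L cannot start in the last L−1 residues of a region,
  which costs short intracellular regions proportionally more); the bias is
  bounded well inside the ±10% convergence band at 5,000 peptides.
* **Paired experiments** draw per-protein log2 baselines from
  N(20, 1.2) with N(0, 0.4) per-sample noise — synthetic conventions on a
  log2-like intensity scale, not estimates from any dataset. On the linear
  scale, `secretome = (1−λ)·independent + λ·lysate`; one marker set is
  rescaled to carry exactly fraction `f` of each sample's total before
  missingness. Planted markers are annotated as secreted, not cytoplasmic,
  so marker planting and the leakage screen stay orthogonal. Missingness is
  MCAR by default, or logistic in latent log2 intensity
  (`low_intensity_biased`) to mimic DIA missingness lore.
* **Reference pairs** realize an exact expressed-set overlap through TPM
  matrices whose per-gene medians sit safely away from the 1-TPM cut-off
  (optionally jittered toward it with `margin_noise`).

What the generator does *not* emulate: peptide-to-protein roll-up,
intensity-dependent identification, retention-time structure, shared-peptide
quantification bias, or search-engine FDR behavior. Passing recovery tests
therefore demonstrate the estimators' correctness on data satisfying their
assumptions, not robustness to every pathology of real acquisitions.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere; conversions happen only at
  I/O boundaries.
* Missing intensity is `NA`, never 0; zero is a legal measured value.
* Protein-group ids are kept verbatim; accession lists split on ";".
* The imputation covariance inversion adds a relative ridge of 1e-8 to the
  observed block, so perfectly collinear sample pairs do not break it.
* All generators accept a single integer seed and restore the caller's RNG
  state; equal seeds give byte-identical fixtures.
* Problem sizes used by the test suite and the acceptance script (1,000
  proteins for ambiguity recovery, 5,000 placed peptides for topology
  convergence, 550 proteins × 6 pairs for leakage, 1,000-protein null and
  100-protein effect simulations for differential expression, 10,000
  features for recapitulation) were chosen so each estimator's sampling
  error is several times smaller than the property bounds being checked.

# Known limitations

* The ambiguity estimate depends on digestion settings; with databases
  differing from the fixture construction (isoforms, signal peptides kept,
  nonstandard residues) the estimate is approximate by nature.
* The sheddome call is annotation-driven unless peptide evidence is
  supplied; it overlaps deliberately with the EV and signal-peptide
  classes.
* The fixed-block plex term is an approximation to a random-intercept
  model; with many plexes and unbalanced designs a true mixed model would
  differ.
* `expressed_protein_set()` treats rows absent from the ambiguity report as
  unambiguous, so the report should cover the matrix when exclusion
  matters.
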