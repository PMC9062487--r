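det_fixture <- function() {
  v <- matrix(NA_real_, 3, 15,
              dimnames = list(c("A", "B", "C"),
                              c(paste0("d0_", 1:3), paste0("h72_", 1:12))))
  v["A", c(1, 2)] <- 10          # 2 of 3 at day 0
  v["A", 4:9] <- 10              # 6 of 12 at 72 h
  v["B", c(4, 5)] <- 10          # 2 of 12 at 72 h only
  intensity_matrix(v, "raw")
}

test_that("detection requires the per-condition minimum number of quantified samples", {
  m <- det_fixture()
  groups <- list(day0 = paste0("d0_", 1:3), h72 = paste0("h72_", 1:12))
  det <- detection_filter(m, groups, c(day0 = 2, h72 = 3))
  expect_equal(det$day0, "A")        # 2 of 3 detected
  expect_equal(det$h72, "A")         # B has only 2 of 12
  expect_false("C" %in% unlist(det)) # all-missing protein never detected

  # lowering a threshold never removes a detected protein
  det_lo <- detection_filter(m, groups, c(day0 = 1, h72 = 2))
  expect_true(all(det$day0 %in% det_lo$day0))
  expect_true(all(det$h72 %in% det_lo$h72))
  expect_true("B" %in% det_lo$h72)

  expect_error(detection_filter(m, groups, c(day0 = 4, h72 = 3)),
               "exceeds group size")
})

test_that("secretion modes fire from signal peptide, EV, hormone and sheddome evidence and may overlap", {
  ann <- annotation_table(
    c("INS", "CD63", "PLAIN"),
    gene_symbol = c("INS", "CD63", "PLAIN"),
    has_signal_peptide = c(TRUE, FALSE, FALSE),
    marker_flags = c("hormone", "EV_marker", ""))
  cls <- classify_secretion_mode(c("INS", "CD63", "PLAIN", "UNKNOWN"), ann)
  modes <- strsplit(cls$modes, ";", fixed = TRUE)
  expect_setequal(modes[[1]], c("signal_peptide", "hormone_granin"))
  expect_equal(modes[[2]], "ev_associated")
  expect_equal(cls$modes[3], "")
  expect_equal(cls$evidence[4], "no annotation")

  # EV via GO term and via an ev-category marker set
  ann2 <- annotation_table(c("P1", "P2"), gene_symbol = c("G1", "G2"),
                           go_terms = c("GO:0070062", ""))
  markers <- structure(list(ev = marker_set("ev_set", "G2", "ev")),
                       class = "marker_set_collection")
  cls2 <- classify_secretion_mode(c("P1", "P2"), ann2, markers = markers)
  expect_equal(cls2$modes, c("ev_associated", "ev_associated"))

  # sheddome heuristic from an extracellular topology region
  topo <- tiny_topology()
  ann3 <- annotation_table("P1")
  cls3 <- classify_secretion_mode("P1", ann3, topologies = topo)
  expect_equal(cls3$modes, "shed")
  expect_match(cls3$evidence, "heuristic")
})

test_that("classification is a pure function of annotations, stable under row order", {
  exp <- generate_secretome_experiment(n_proteins = 200, seed = 19)
  acc <- exp$annotations$accession
  cls1 <- classify_secretion_mode(acc, exp$annotations,
                                  topologies = exp$topologies)
  shuffled <- exp$annotations[sample(nrow(exp$annotations)), ]
  cls2 <- classify_secretion_mode(acc, shuffled,
                                  topologies = exp$topologies)
  expect_equal(cls1, cls2)
})

test_that("planted secretion-mode labels are recovered exactly", {
  exp <- generate_secretome_experiment(n_proteins = 300, seed = 20)
  cls <- classify_secretion_mode(exp$annotations$accession, exp$annotations,
                                 topologies = exp$topologies)
  has <- function(mode) vapply(strsplit(cls$modes, ";", fixed = TRUE),
                               function(m) mode %in% m, logical(1))
  truth <- exp$truth$modes
  expect_equal(has("signal_peptide"), truth$signal_peptide)
  expect_equal(has("ev_associated"), truth$ev_associated)
  expect_equal(has("hormone_granin"), truth$hormone_granin)
  expect_equal(has("shed"), truth$shed)
})

test_that("signal-peptide and EV percentages compare against the background proteome", {
  set.seed(21)
  bg_acc <- paste0("B", 1:400)
  bg <- annotation_table(bg_acc,
                         has_signal_peptide = rep(c(TRUE, FALSE), c(100, 300)),
                         go_terms = rep(c("GO:0070062", ""), c(100, 300)))
  same <- ev_proportion_vs_background(bg_acc, bg, bg)
  expect_equal(same$diff_signal_peptide, 0)
  expect_equal(same$diff_ev, 0)

  det_acc <- paste0("D", 1:200)
  det_ann <- annotation_table(det_acc,
                              go_terms = rep(c("GO:0070062", ""), c(120, 80)))
  res <- ev_proportion_vs_background(det_acc, det_ann, bg)
  expect_equal(res$pct_ev, 60)
  expect_equal(res$diff_ev, 35)
  expect_lt(res$p_ev, 1e-6)

  expect_error(ev_proportion_vs_background(character(0), det_ann, bg),
               "empty detected set")
})

test_that("secretome ranking is by decreasing median with deterministic ties", {
  v <- matrix(c(9.1, 7.4, 8.8, 9.1, 7.4, 8.8), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  rk <- rank_secretome(structure(v, scale = "log2_normalized"), c("s1", "s2"))
  expect_equal(rk$accession, c("P1", "P3", "P2"))
  expect_equal(rk$rank, 1:3)
  expect_true(all(diff(rk$median_abundance) <= 0))

  # equal medians break by accession lexicographic order
  v2 <- matrix(c(5, 5, 5, 5), 2, 2,
               dimnames = list(c("PB", "PA"), c("s1", "s2")))
  rk2 <- rank_secretome(structure(v2, scale = "log2_normalized"),
                        c("s1", "s2"))
  expect_equal(rk2$accession, c("PA", "PB"))

  # rank vector is a permutation; removing the top shifts ranks by -1
  set.seed(22)
  v3 <- matrix(rnorm(30, 20, 2), 10, 3,
               dimnames = list(paste0("P", 1:10), paste0("s", 1:3)))
  rk3 <- rank_secretome(structure(v3, scale = "log2_normalized"),
                        paste0("s", 1:3))
  expect_setequal(rk3$rank, 1:10)
  rk4 <- rank_secretome(structure(v3[rk3$accession[-1], ],
                                  scale = "log2_normalized"),
                        paste0("s", 1:3))
  expect_equal(rk4$accession, rk3$accession[-1])
  expect_equal(rk4$rank, rk3$rank[-1] - 1L)
})
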