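test_that("UniProt FASTA headers parse into species and contaminant flags", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P01308|INS_HUMAN Insulin", "MALWMRLLPLLALLALWGPDPAAA",
               ">sp|P01326|INS2_MOUSE Insulin-2", "MALWMRFLPLLALLVLWEPKPAQA",
               ">Cont_P00761|TRYP_PIG Trypsin", "FPTDDDDKIVGG"), f)
  rec <- read_fasta(f)
  expect_equal(rec$accession, c("P01308", "P01326", "Cont_P00761"))
  expect_equal(rec$species, c("HUMAN", "MOUSE", "OTHER"))
  expect_equal(rec$is_contaminant, c(FALSE, FALSE, TRUE))
  expect_equal(rec$entry_name[1], "INS_HUMAN")
})

test_that("malformed headers warn and fall back to OTHER; duplicates error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">just_a_name", "ACDEFGHIK"), f)
  expect_warning(rec <- read_fasta(f), "malformed")
  expect_equal(rec$species, "OTHER")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|A_HUMAN", "ACDK", ">sp|P1|B_HUMAN", "ACDR"), f2)
  expect_error(read_fasta(f2), "duplicate accession")

  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f3)
  expect_error(read_fasta(f3))
})

test_that("GMT marker sets parse with dedup, categories, and field checks", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("apoptosis_set\tapoptosis\tCASP3\tBAX\tBAX",
               "golgi\torganelle\tGOLGA1\tGOLGB1",
               "custom\tsome description\tGENE1"), f)
  sets <- read_marker_gmt(f)
  expect_equal(sets$apoptosis_set$members, c("CASP3", "BAX"))
  expect_equal(sets$apoptosis_set$category, "apoptosis")
  expect_equal(sets$custom$category, "other")

  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("lonely\tdesc", f2)
  expect_error(read_marker_gmt(f2), "line 1")
  expect_error(marker_set("empty", character(0)), "no members")
})

test_that("protein matrices parse missing cells as missing, reject negatives", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_group\ts1\ts2",
               "P1;P2\t10\t20",
               "P3\t\t5",
               "P4\t1\t2"), f)
  m <- read_protein_matrix(f)
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["P3", "s1"]))
  expect_equal(rownames(m)[1], "P1;P2")
  expect_equal(attr(m, "scale"), "raw")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_group\ts1", "P1\t-5"), f2)
  expect_error(read_protein_matrix(f2), "negative")

  meta <- sample_metadata("s1", "c", "lysate")
  expect_error(read_protein_matrix(f, metadata = meta), "without metadata")
})

test_that("topology tables group, sort and validate regions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tstart\tend\tcategory\tprotein_length",
               "P1\t72\t100\tintracellular\t100",
               "P1\t1\t50\textracellular\t100",
               "P1\t51\t71\ttransmembrane\t100"), f)
  topo <- read_topology_table(f)
  expect_length(topo, 1)
  expect_equal(nrow(topo$P1$regions), 3)
  expect_equal(topo$P1$regions$start, c(1, 51, 72))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tstart\tend\tcategory\tprotein_length",
               "P1\t1\t50\textracellular\t100",
               "P1\t40\t60\ttransmembrane\t100"), f2)
  expect_error(read_topology_table(f2), "overlap")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tstart\tend\tcategory\tprotein_length",
               "P1\t1\t120\textracellular\t100"), f3)
  expect_error(read_topology_table(f3))

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tstart\tend\tcategory\tprotein_length",
               "P1\t1\t100\tlumenal\t100"), f4)
  expect_warning(topo4 <- read_topology_table(f4), "lumenal")
  expect_equal(topo4$P1$regions$category, "other")
})

test_that("write/read round-trips preserve matrices, marker sets, topology and FASTA", {
  set.seed(42)
  v <- matrix(round(abs(rnorm(20, 100, 30)), 3), 5, 4,
              dimnames = list(paste0("P", 1:5), paste0("s", 1:4)))
  v[2, 3] <- NA
  m <- intensity_matrix(v, "raw")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_protein_matrix(m, f)
  m2 <- read_protein_matrix(f)
  expect_equal(unclass(m2), unclass(m))

  sets <- list(a = marker_set("a", c("X", "Y"), "ev"),
               b = marker_set("b", "Z", "apoptosis"))
  g <- withr::local_tempfile(fileext = ".gmt")
  write_marker_gmt(sets, g)
  sets2 <- read_marker_gmt(g)
  expect_equal(lapply(sets2, unclass), lapply(sets, unclass))

  topo <- tiny_topology()
  t <- withr::local_tempfile(fileext = ".tsv")
  write_topology_table(topo, t)
  topo2 <- read_topology_table(t)
  expect_equal(lapply(topo2, unclass), lapply(topo, unclass))

  rec <- tiny_records()
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, fa)
  rec2 <- read_fasta(fa)
  expect_equal(rec2, rec)
})

test_that("container invariants: species partition, pairing, missing is NA not zero", {
  rec <- tiny_records()
  expect_true(all(rec$species %in% c("HUMAN", "MOUSE", "OTHER")))
  expect_error(sample_metadata(c("a", "b"), "c", c("lysate", "lysate"),
                               pair_id = c("p1", "p1")),
               "pair_id")
  v <- matrix(c(0, NA, 2, 3), 2, 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  m <- intensity_matrix(v, "raw")
  expect_equal(m["P1", "s1"], 0)       # zero is a legal measured value
  expect_true(is.na(m["P2", "s1"]))    # missing stays missing
  expect_error(intensity_matrix(-v, "raw"), "negative")
})
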