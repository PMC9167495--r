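# Anchor-table loading, region segmentation, sushi key-residue check.

write_domain_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- "protein_id\tname\tstart\tend"
  writeLines(c(header, rows), path)
  path
}

test_that("load_domain_table reads, validates and sorts", {
  path <- write_domain_tsv("P1\tCLECT\t22\t150")
  tab <- load_domain_table(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$start, 22L)
  expect_equal(tab$end, 150L)

  # overlapping anchors are rejected with both offenders named
  path2 <- write_domain_tsv(c("P1\tEGF\t210\t250", "P1\tEGF\t240\t280"))
  expect_error(load_domain_table(path2), "overlap")

  # truly empty file -> zero rows
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(load_domain_table(empty)), 0L)

  path3 <- write_domain_tsv("P1\tEGF\t250\t210")
  expect_error(load_domain_table(path3), "end")
  path4 <- write_domain_tsv("P1\tEGF\t10\t90")
  expect_error(load_domain_table(path4, protein_lengths = c(P1 = 50L)),
               "beyond protein length")
})

test_that("segment_protein derives sushi, mucin and cytotail intervals", {
  ann <- data.frame(protein_id = "P1",
                    name = c("CLECT", "EGF", "EGF", "TM"),
                    start = c(22L, 210L, 251L, 580L),
                    end = c(150L, 250L, 290L, 602L))
  rs <- segment_protein(ann, protein_length = 650, family = "CD93")
  expect_equal(unname(rs$sushi), c(151L, 209L))
  expect_equal(unname(rs$mucin), c(291L, 579L))
  expect_equal(unname(rs$cytotail), c(603L, 650L))
  expect_equal(rs$sushi_label, "sushi-like")

  # EGF loss: the CTLD-to-TM interval is the sushi-bearing region
  ann2 <- data.frame(protein_id = "P2", name = c("CLECT", "TM"),
                     start = c(22L, 180L), end = c(150L, 202L))
  rs2 <- segment_protein(ann2, protein_length = 230)
  expect_equal(unname(rs2$sushi), c(151L, 179L))
  expect_null(rs2$mucin)
  expect_equal(unname(rs2$cytotail), c(203L, 230L))

  # adjacent anchors: zero-length derived regions are absent
  ann3 <- data.frame(protein_id = "P3", name = c("CLECT", "EGF"),
                     start = c(1L, 101L), end = c(100L, 140L))
  rs3 <- segment_protein(ann3, protein_length = 140)
  expect_null(rs3$sushi)
})

test_that("inconsistent architectures and duplicated anchors error", {
  bad1 <- data.frame(protein_id = "P", name = c("EGF", "CLECT"),
                     start = c(10L, 60L), end = c(50L, 120L))
  expect_error(segment_protein(bad1, 200), "CTLD lies after")
  bad2 <- data.frame(protein_id = "P", name = c("CLECT", "TM", "EGF"),
                     start = c(1L, 60L, 100L), end = c(50L, 80L, 140L))
  expect_error(segment_protein(bad2, 200), "TM lies before")
  bad3 <- data.frame(protein_id = "P", name = c("CLECT", "CLECT"),
                     start = c(1L, 60L), end = c(50L, 120L))
  expect_error(segment_protein(bad3, 200), "more than one CTLD")
})

test_that("segmentation is invariant to annotation row order", {
  ann <- data.frame(protein_id = "P1",
                    name = c("CLECT", "EGF", "EGF", "TM"),
                    start = c(22L, 210L, 251L, 580L),
                    end = c(150L, 250L, 290L, 602L))
  set.seed(7)
  shuffled <- ann[sample(nrow(ann)), , drop = FALSE]
  expect_equal(as.data.frame(segment_protein(ann, 650)),
               as.data.frame(segment_protein(shuffled, 650)))
})

test_that("regions + anchors + leader tile simulated proteins exactly", {
  for (fam in c("CD93", "Clec14A", "CD248", "Thrombomodulin")) {
    sim <- simulate_architecture(architecture_template(fam),
                                 seed = 500 + match(fam, c(
                                   "CD93", "Clec14A", "CD248",
                                   "Thrombomodulin")))
    rs <- segment_protein(sim$annotations, nchar(sim$protein),
                          family = fam, protein_sequence = sim$protein)
    tab <- as.data.frame(rs)
    covered <- unlist(mapply(seq, tab$start, tab$end, SIMPLIFY = FALSE))
    leader_end <- min(tab$start) - 1L
    expect_false(anyDuplicated(covered) > 0)
    expect_setequal(c(seq_len(leader_end), covered),
                    seq_len(nchar(sim$protein)))
  }
})

test_that("sushi key-residue check maps columns through the alignment", {
  ref <- "CAWAGAPAC"
  keys <- data.frame(position = c(1L, 3L, 5L, 7L, 9L),
                     class = c("C", "W", "G", "P", "C"))
  rep1 <- check_sushi_residues(c(ref = ref, ok = ref), "ref",
                               key_columns = keys)
  expect_true(all(rep1$per_sequence$ok$conserved))
  expect_equal(unname(rep1$calls["ok"]), "has_sushi")

  # single substitution at a key column
  rep2 <- check_sushi_residues(c(ref = ref, mut = "CAAAGAPAC"), "ref",
                               key_columns = keys)
  expect_false(rep2$per_sequence$mut$conserved[2])
  expect_equal(sum(!rep2$per_sequence$mut$conserved), 1L)
  expect_equal(unname(rep2$calls["mut"]), "lacks_sushi")
  # ... tolerated when tolerance covers it
  rep2b <- check_sushi_residues(c(ref = ref, mut = "CAAAGAPAC"), "ref",
                                key_columns = keys, tolerance = 1)
  expect_equal(unname(rep2b$calls["mut"]), "has_sushi")

  # a deletion covering the terminal key cysteine counts as lost
  rep3 <- check_sushi_residues(c(ref = ref, del = "CAWAGAPA"), "ref",
                               key_columns = keys)
  expect_false(rep3$per_sequence$del$conserved[5])
  expect_equal(unname(rep3$calls["del"]), "lacks_sushi")
})

test_that("sushi check validates its configuration", {
  expect_error(check_sushi_residues(c(a = "CAW"), "missing"),
               "reference sequence not found")
  expect_error(check_sushi_residues(
    c(ref = "CAWAGAPAC", q = "CAWAGAPAC"), "ref",
    key_columns = data.frame(position = 99L, class = "C")),
    "no position")
  expect_error(check_sushi_residues(
    c(ref = "CAWAGAPAC", q = "CAWAGAPAC"), "ref",
    key_columns = data.frame(position = 2L, class = "C")),
    "not in class")
  # default key columns: first occurrence of each hallmark residue
  keys <- default_sushi_key_columns("ACWAGAPA")
  expect_equal(keys$position[keys$class == "C"], 2L)
  expect_error(default_sushi_key_columns("AAAA"), "lacks hallmark")
})
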