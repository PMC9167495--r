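# Codon alignments and the NG86 / YN00 estimators.

test_that("protein-to-CDS interval mapping is the closed form", {
  expect_equal(unname(map_protein_interval_to_cds(10, 20)), c(28L, 60L))
  expect_equal(unname(map_protein_interval_to_cds(1, 1)), c(1L, 3L))
  expect_error(map_protein_interval_to_cds(200, 210, cds_length = 600),
               "beyond the CDS")
})

test_that("backthread_codons drops gap and stop columns and validates", {
  aln <- backthread_codons("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(length(aln$codons_a), 2L)
  expect_equal(aln$n_dropped[["gap"]], 0L)

  aln2 <- backthread_codons("M-K", "MQK", "ATGAAA", "ATGCAAAAG")
  expect_equal(length(aln2$codons_a), 2L)
  expect_equal(aln2$n_dropped[["gap"]], 1L)

  # an internal stop codon column is dropped and reported
  expect_message(
    aln3 <- codon_alignment("ATGTAAAAA", "ATGCACAAA"),
    "stop")
  expect_equal(length(aln3$codons_a), 2L)
  expect_equal(aln3$n_dropped[["stop"]], 1L)

  # terminal stops are stripped before validation
  aln4 <- codon_alignment("ATGAAATAA", "ATGAAGTGA")
  expect_equal(length(aln4$codons_a), 2L)

  expect_error(backthread_codons("MK", "MM", "ATGAAA", "ATGAAG"),
               "residue 2")
  expect_error(codon_alignment("ATGAA", "ATGAA"), "divisible by 3")
})

test_that("ng86 reproduces hand-enumerated values", {
  # identical sequences: no differences, zero distances, ratio undefined
  set.seed(201)
  cds <- paste(sample(SENSE, 300, replace = TRUE), collapse = "")
  r0 <- ng86(codon_alignment(cds, cds))
  expect_equal(r0$Sd, 0)
  expect_equal(r0$Nd, 0)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$ratio))

  # TTT vs TTA: Phe -> Leu, one nonsynonymous difference; at the third
  # position only TTC is synonymous among {TTC, TTA, TTG}, so S = 0.5
  # averaged over both codons; dN = -3/4 log(1 - 4/3 * 0.4)
  r <- ng86(codon_alignment("TTT", "TTA"))
  expect_equal(r$S, 0.5)
  expect_equal(r$N, 2.5)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 1)
  expect_equal(r$pN, 0.4)
  expect_equal(r$dN, -0.75 * log(1 - 4 / 3 * 0.4), tolerance = 1e-12)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$ratio))
})

test_that("ng86 matches the enumeration oracle on random codon pairs", {
  set.seed(202)
  pairs <- random_codon_pair(400)
  got <- ng86(codon_aln_from_vectors(pairs$a, pairs$b))
  want <- oracle_ng86_counts(pairs$a, pairs$b)
  expect_equal(got$S, want$S, tolerance = 1e-9)
  expect_equal(got$N, want$N, tolerance = 1e-9)
  expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
  expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
})

test_that("S + N equals 3 x retained columns and estimators are symmetric", {
  set.seed(203)
  for (i in 1:10) {
    pairs <- random_codon_pair(60)
    aln_ab <- codon_aln_from_vectors(pairs$a, pairs$b)
    aln_ba <- codon_aln_from_vectors(pairs$b, pairs$a)
    for (est in list(ng86, function(x) yn00(x, kappa = 2))) {
      r1 <- est(aln_ab)
      r2 <- est(aln_ba)
      expect_equal(r1$S + r1$N, 3 * length(aln_ab$codons_a),
                   tolerance = 1e-9)
      expect_equal(r1$S, r2$S, tolerance = 1e-12)
      expect_equal(r1$Sd, r2$Sd, tolerance = 1e-9)
      expect_equal(r1$Nd, r2$Nd, tolerance = 1e-9)
    }
  }
})

test_that("yn00 handles identical sequences and empty alignments", {
  set.seed(204)
  cds <- paste(sample(SENSE, 100, replace = TRUE), collapse = "")
  r <- yn00(codon_alignment(cds, cds))
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$ratio))
  empty <- codon_alignment("", "")
  expect_error(ng86(empty), "no retained columns")
  expect_error(yn00(empty), "no retained columns")
})

test_that("yn00 reduces to ng86 at kappa 1 with uniform frequencies", {
  set.seed(205)
  for (i in 1:15) {
    pairs <- random_codon_pair(80)
    aln <- codon_aln_from_vectors(pairs$a, pairs$b)
    a <- ng86(aln)
    b <- yn00(aln, kappa = 1, codon_freqs = "uniform")
    expect_equal(b$dS, a$dS, tolerance = 1e-6)
    expect_equal(b$dN, a$dN, tolerance = 1e-6)
    expect_equal(b$S, a$S, tolerance = 1e-6)
  }
})

test_that("yn00 recovers the simulated kappa approximately", {
  set.seed(206)
  cds <- paste(sample(SENSE, 800, replace = TRUE), collapse = "")
  ev <- simulate_codon_evolution(cds, omega = 1, kappa = 4, t = 0.4)
  r <- yn00(codon_alignment(ev$cds_a, ev$cds_b))
  expect_true(r$kappa_estimated)
  expect_gt(r$kappa, 2)   # clearly above the no-bias value
})

test_that("mean estimated ratio increases with the generating omega", {
  set.seed(207)
  cds <- paste(sample(SENSE, 300, replace = TRUE), collapse = "")
  mean_ratio <- function(om, est) {
    mean(vapply(1:8, function(i) {
      ev <- simulate_codon_evolution(cds, omega = om, kappa = 2, t = 0.3)
      est(codon_alignment(ev$cds_a, ev$cds_b))$ratio
    }, numeric(1)), na.rm = TRUE)
  }
  for (est in list(ng86, yn00)) {
    ratios <- vapply(c(0.1, 1, 4), mean_ratio, numeric(1), est = est)
    expect_true(all(diff(ratios) > 0))
  }
})

test_that("aggregate_domain_kaks pairs species and summarises per region", {
  co <- simulate_cohort(architecture_template("CD248", t = 0.2),
                        n_species = 3, seed = 208)
  agg <- aggregate_domain_kaks(co, method = "ng86")
  # C(3,2) unordered pairs per region
  expect_true(all(table(agg$table$region) == 3L))
  expect_true(all(c("CTLD", "mucin", "cytotail", "EGF_1") %in%
                    agg$summary$region))
  # identical sequences: every ratio undefined, summary n = 0
  rec_id <- lapply(co, function(r) { r$cds <- co[[1]]$cds
                                     r$protein <- co[[1]]$protein
                                     r$regions <- co[[1]]$regions; r })
  agg_id <- aggregate_domain_kaks(rec_id, method = "ng86")
  expect_true(all(is.na(agg_id$table$ratio)))
  expect_true(all(agg_id$summary$n == 0L))
})

test_that("species lacking a region are skipped with a warning message", {
  co <- simulate_cohort(architecture_template("Clec14A", t = 0.2),
                        n_species = 3, seed = 209)
  # remove the TM anchor from one species: no TM, mucin or cytotail
  ann <- co[[1]]$regions
  ann_tab <- as.data.frame(ann)
  co[[1]]$regions <- segment_protein(
    data.frame(protein_id = "x",
               name = c("CLECT", "EGF"),
               start = ann_tab$start[ann_tab$region %in%
                                       c("CTLD", "EGF_1")],
               end = ann_tab$end[ann_tab$region %in% c("CTLD", "EGF_1")]),
    protein_length = nchar(co[[1]]$protein),
    family = "Clec14A", protein_sequence = co[[1]]$protein)
  expect_message(
    agg <- aggregate_domain_kaks(co, method = "ng86"),
    "absent in species")
  tab <- agg$table
  expect_false(co[[1]]$regions$protein_id %in% character(0))
  expect_equal(sum(tab$region == "cytotail"), 1L)  # only the other pair
  expect_equal(sum(tab$region == "CTLD"), 3L)
})
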