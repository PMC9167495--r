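# Synteny blocks, shared families, and gene-absence classification.

gene_row <- function(family, chr = "chr1", start = 1e6,
                     species = "sp", id = NULL) {
  data.frame(chromosome = chr, start = start, end = start + 2000,
             gene_id = id %||% paste0(family, "_", chr, "_", start),
             family = family, species = species,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("build_block applies the window interval arithmetic", {
  genes <- rbind(gene_row("anchor", start = 30e6),
                 gene_row("far_left", start = 5e6),
                 gene_row("near", start = 25e6),
                 gene_row("far_right", start = 55e6))
  blk <- build_block(genes, "anchor", window_bp = 20e6)
  expect_setequal(blk$members$family, c("anchor", "near"))
  # a window covering the whole chromosome includes every gene
  blk_all <- build_block(genes, "anchor", window_bp = 1e9)
  expect_equal(nrow(blk_all$members), 4L)
  expect_false(is.unsorted(blk_all$members$start))
})

test_that("build_block rejects missing or ambiguous anchors", {
  genes <- rbind(gene_row("f1"), gene_row("f2", start = 2e6))
  expect_error(build_block(genes, "anchor"), "not found")
  two <- rbind(gene_row("anchor", start = 1e6),
               gene_row("anchor", start = 9e6))
  expect_error(build_block(two, "anchor"), "ambiguous")
})

test_that("shared_families intersects family sets and is symmetric", {
  mk_block <- function(fams) {
    genes <- do.call(rbind, lapply(seq_along(fams), function(i) {
      gene_row(fams[i], start = i * 1e6)
    }))
    genes <- rbind(genes, gene_row("anchor", start = 1e5))
    build_block(genes, "anchor", window_bp = 1e9)
  }
  a <- mk_block(paste0("f", 1:20))
  b <- mk_block(c(paste0("f", 1:15), paste0("g", 1:5)))
  rep_ab <- shared_families(a, b)
  rep_ba <- shared_families(b, a)
  expect_equal(rep_ab$count, 16L)  # f1..f15 + the shared anchor family
  expect_true(rep_ab$meets_threshold)
  expect_setequal(rep_ab$shared_families, rep_ba$shared_families)
  # disjoint blocks share nothing but the anchor
  d <- mk_block(paste0("h", 1:5))
  expect_equal(shared_families(a, d)$count, 1L)
  expect_false(shared_families(a, d)$meets_threshold)
  # identical blocks: count = number of distinct families; bounded by
  # the smaller block
  expect_equal(shared_families(a, a)$count,
               length(unique(a$members$family)))
  expect_lte(rep_ab$count,
             min(length(unique(a$members$family)),
                 length(unique(b$members$family))))
})

test_that("classify_absence follows the decision rule", {
  mk_ref <- function(n) {
    genes <- do.call(rbind, lapply(seq_len(n), function(i) {
      gene_row(paste0("f", i), start = 40e6 + i * 1e5)
    }))
    genes <- rbind(genes, gene_row("target", start = 41e6))
    build_block(genes, "target", window_bp = 20e6)
  }
  ref <- mk_ref(15)

  # all 15 neighbours retained in one block, target absent
  qry_keep <- do.call(rbind, lapply(1:15, function(i) {
    gene_row(paste0("f", i), chr = "chrQ", start = 10e6 + i * 1e5)
  }))
  rep1 <- classify_absence("target", ref, qry_keep)
  expect_equal(rep1$absence_call, "locus_preserved_loss")
  expect_equal(unname(rep1$counts["retained"]), 15L)

  # 3 retained, 7 relocated, 5 missing -> disruption
  qry_disrupt <- rbind(
    do.call(rbind, lapply(1:3, function(i) {
      gene_row(paste0("f", i), chr = "chrQ", start = 10e6 + i * 1e5)
    })),
    do.call(rbind, lapply(4:10, function(i) {
      gene_row(paste0("f", i), chr = paste0("chrX", i), start = 3e6)
    })))
  rep2 <- classify_absence("target", ref, qry_disrupt)
  expect_equal(rep2$absence_call, "chromosome_disruption")
  expect_equal(unname(rep2$counts),
               c(3L, 7L, 5L))

  # 8 retained / 7 relocated: retained fraction 0.533 -> preserved
  qry_mixed <- rbind(
    do.call(rbind, lapply(1:8, function(i) {
      gene_row(paste0("f", i), chr = "chrQ", start = 10e6 + i * 1e5)
    })),
    do.call(rbind, lapply(9:15, function(i) {
      gene_row(paste0("f", i), chr = paste0("chrX", i), start = 3e6)
    })))
  rep3 <- classify_absence("target", ref, qry_mixed)
  expect_equal(rep3$absence_call, "locus_preserved_loss")

  # the target present in the candidate block -> "present"
  qry_present <- rbind(qry_keep,
                       gene_row("target", chr = "chrQ", start = 10.5e6))
  expect_equal(classify_absence("target", ref, qry_present)$absence_call,
               "present")
})

test_that("too few assessable neighbours is indeterminate with warning", {
  genes <- rbind(gene_row("f1", start = 40e6), gene_row("f2", start = 41e6),
                 gene_row("target", start = 40.5e6))
  ref <- build_block(genes, "target", window_bp = 20e6)
  expect_warning(rep <- classify_absence("target", ref, gene_row("f1")),
                 "indeterminate")
  expect_equal(rep$absence_call, "indeterminate")
})

test_that("results are invariant to gene table row order", {
  h <- simulate_synteny_history(16, "chromosome_disruption", seed = 420)
  ref_blk <- build_block(h$reference, "CTLDcp")
  r1 <- classify_absence("CTLDcp", ref_blk, h$derived)
  set.seed(1)
  shuffled <- h$derived[sample(nrow(h$derived)), , drop = FALSE]
  r2 <- classify_absence("CTLDcp", ref_blk, shuffled)
  expect_equal(r1$counts, r2$counts)
  expect_equal(r1$absence_call, r2$absence_call)
})

test_that("classify_absence recovers simulated mechanisms", {
  set.seed(421)
  hits <- 0L
  for (i in 1:20) {
    mech <- if (i %% 2 == 0) "chromosome_disruption" else
      "locus_preserved_loss"
    h <- simulate_synteny_history(20, mech, intensity = 0.8)
    ref_blk <- build_block(h$reference, "CTLDcp")
    call <- classify_absence("CTLDcp", ref_blk, h$derived)$absence_call
    hits <- hits + (call == mech)
  }
  expect_gte(hits, 19L)
})

test_that("shared_family_matrix is symmetric with family counts on top", {
  h1 <- simulate_synteny_history(16, "locus_preserved_loss", seed = 422)
  blocks <- list(ref = build_block(h1$reference, "CTLDcp"),
                 ref2 = build_block(h1$reference, "CTLDcp"))
  m <- shared_family_matrix(blocks)
  expect_equal(m["ref", "ref2"], m["ref2", "ref"])
  expect_equal(unname(m["ref", "ref"]), 17L)  # 16 neighbours + target
})
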