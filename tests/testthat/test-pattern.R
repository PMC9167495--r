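# PROSITE-style pattern parsing, matching and EGF subtype calls.

test_that("parsing the shipped signatures gives the expected structure", {
  p22 <- parse_pattern("CxCx(5)Gx(2)C", name = "PS00022")
  # elements C, x, C, x(5), G, x(2), C; positions 1+1+1+5+1+2+1 = 12
  expect_length(p22$elements, 7L)
  expect_equal(unname(pattern_length_range(p22)), c(12L, 12L))

  p86 <- parse_pattern("CxCx(2)[GP][FYW]x(4,8)C")
  # 1+1+1+2+1+1+4+1 = 11 fixed positions + x(4,8) variability
  expect_equal(unname(pattern_length_range(p86)), c(12L, 16L))
  classes <- vapply(p86$elements, function(e) e$kind, character(1))
  expect_equal(sum(classes == "class"), 2L)

  p87 <- egf_signatures()$PS01187
  # 5 + 3 + 1 + 3 + 11 + 1 + 1 + 8 + 1 + 1 fixed minimum
  expect_equal(unname(pattern_length_range(p87))[1], 35L)
  # shorthand classes expand as defined: N = [DEQN], B = [DN], A aromatic
  expect_setequal(p87$elements[[1]]$residues, c("D", "E", "Q", "N"))
})

test_that("malformed patterns fail with a position-naming parse error", {
  expect_error(parse_pattern("Cx("), "position 3")
  expect_error(parse_pattern("C[GF"), "unclosed")
  expect_error(parse_pattern("Cx(2,1)"), "bad repeat")
  expect_error(parse_pattern("C[]C"), "empty residue class")
  expect_error(parse_pattern(""), "empty pattern")
})

test_that("parse -> render -> parse round-trips to an equal element list", {
  for (txt in c("CxCx(5)Gx(2)C", "CxCx(2)[GP][FYW]x(4,8)C",
                "NxNNC-x(3,14)-C-x(3,7)-CxxBxxxxAxC-x(1,6)-C-x(8,13)-Cx",
                "{P}x(2)[DN]W")) {
    p <- parse_pattern(txt)
    p2 <- parse_pattern(render_pattern(p))
    expect_equal(p2$elements, p$elements, info = txt)
  }
})

test_that("match_pattern finds constructed matches and rejects non-matches", {
  sig <- egf_signatures()
  expect_equal(match_pattern(sig$PS00022, "CACAAAAAGAAC"),
               data.frame(start = 1L, end = 12L))
  expect_equal(match_pattern(sig$PS01186, "CACAAGFAAAAC"),
               data.frame(start = 1L, end = 12L))
  expect_equal(nrow(match_pattern(sig$PS00022, "AAAAAAAAAAAA")), 0L)
  # all start positions are reported, shortest match at each start
  two <- match_pattern(sig$PS00022,
                       paste0("CACAAAAAGAAC", "TTT" , "CACAAAAAGAAC"))
  expect_error(two, NA)
  # unknown residue X matches only the x element
  expect_equal(nrow(match_pattern(sig$PS00022, "XACAAAAAGAAC")), 0L)
  expect_equal(match_pattern(sig$PS00022, "CXCAAAAAGAAC")$start, 1L)
  expect_error(match_pattern(sig$PS00022, "CAC1AAAAGAAC"), "non-residue")
})

test_that("match_pattern agrees with the regex window oracle", {
  set.seed(401)
  sigs <- c(PS00022 = "CxCx(5)Gx(2)C",
            PS01186 = "CxCx(2)[GP][FYW]x(4,8)C",
            PS01187 = "NxNNC-x(3,14)-C-x(3,7)-CxxBxxxxAxC-x(1,6)-C-x(8,13)-Cx")
  pats <- lapply(sigs, parse_pattern)
  # bias the alphabet toward signature residues so hits actually occur
  alpha <- c(rep("C", 6), rep(c("G", "F", "D", "N"), 2), AA20)
  n_hits <- 0L
  for (rep in 1:200) {
    s <- paste(sample(alpha, 60, replace = TRUE), collapse = "")
    for (nm in names(sigs)) {
      got <- match_pattern(pats[[nm]], s)
      want <- oracle_match_pattern(sigs[[nm]], s)
      expect_equal(got, want, info = paste(nm, s))
      n_hits <- n_hits + nrow(got)
    }
  }
  expect_gt(n_hits, 0L)  # the comparison exercised real matches
})

test_that("classify_egf follows the subtype decision table", {
  expect_equal(as.character(classify_egf("CACAAAAAGAAC")), "EGF1")
  expect_equal(as.character(classify_egf("CACAAGFAAAAC")), "EGF2")
  expect_equal(as.character(classify_egf("AAAA")), "EGF_like")
  # a domain carrying both the EGF 2 and the calcium-binding
  # consensus is a cbEGF (constructed element-by-element; both
  # signatures verified to fire by the oracle)
  cb <- "CACAAGFAAAACDADDCAAACAAACAADAAAAFACACAAAAAAAACA"
  expect_gt(nrow(oracle_match_pattern("CxCx(2)[GP][FYW]x(4,8)C", cb)), 0L)
  expect_gt(nrow(oracle_match_pattern(
    "NxNNC-x(3,14)-C-x(3,7)-CxxBxxxxAxC-x(1,6)-C-x(8,13)-Cx", cb)), 0L)
  expect_equal(as.character(classify_egf(cb)), "cbEGF")
  expect_error(classify_egf(""), "empty")
})

test_that("dual PS00022/PS01186 hits resolve to EGF2 and are flagged", {
  both <- paste0("CACAAAAAGAAC", "CACAAGFAAAAC")
  expect_message(res <- classify_egf(both), "both")
  expect_equal(as.character(res), "EGF2")
  expect_true(attr(res, "ambiguous"))
})

test_that("PS01187 is tested on the flanked interval only", {
  cb_tail <- "DADDCAAACAAACAADAAAAFACACAAAAAAAACA"
  core <- "CACAAGFAAAAC"
  protein <- paste0("CACAAGFAAAAC", cb_tail)  # consensus spans past core
  # core alone: EGF2; with protein context and a generous flank the
  # calcium-binding consensus (which needs the downstream residues)
  # upgrades the call
  expect_equal(as.character(classify_egf(core)), "EGF2")
  res <- classify_egf(protein_sequence = protein,
                      interval = c(1, nchar(core)), flank = 40)
  expect_equal(as.character(res), "cbEGF")
})
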