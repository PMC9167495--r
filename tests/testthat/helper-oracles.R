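# Independent oracles used by the unit and acceptance tests.  These
# deliberately use different machinery from the package: the pattern
# oracle matches via the PCRE regex engine, the Ka/Ks oracle
# re-derives site/difference counts from the genetic code by explicit
# enumeration, and the alignment oracle enumerates complete alignments
# recursively.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ---- pattern oracle -------------------------------------------------

# translate a compact signature string to an anchored PCRE regex plus
# the min/max match lengths; independent matching engine (regex), the
# element grammar is shared with the package by design
oracle_pattern_regex <- function(text) {
  shorthand <- list(N = "DEQN", B = "DN", A = "FYW")
  chars <- strsplit(text, "")[[1]]
  i <- 1L
  rx <- ""
  lens <- c(0L, 0L)
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "-") { i <- i + 1L; next }
    if (ch == "x") {
      piece <- paste0("[", paste(c(AA20, "X"), collapse = ""), "]")
      i <- i + 1L
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      piece <- paste0("[", paste(chars[(i + 1):(j - 1)], collapse = ""), "]")
      i <- j + 1L
    } else if (ch %in% names(shorthand)) {
      piece <- paste0("[", shorthand[[ch]], "]")
      i <- i + 1L
    } else {
      piece <- ch
      i <- i + 1L
    }
    lo <- 1L; hi <- 1L
    if (i <= length(chars) && chars[i] == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1]
      spec <- paste(chars[(i + 1):(j - 1)], collapse = "")
      parts <- as.integer(strsplit(spec, ",")[[1]])
      lo <- parts[1]; hi <- if (length(parts) == 2) parts[2] else parts[1]
      piece <- sprintf("%s{%d,%d}", piece, lo, hi)
      i <- j + 1L
    }
    rx <- paste0(rx, piece)
    lens <- lens + c(lo, hi)
  }
  list(regex = paste0("^", rx, "$"), min = lens[1], max = lens[2])
}

# all (start, shortest end) matches by testing every window with the
# regex engine; one vectorized grepl per candidate window length
oracle_match_pattern <- function(text, sequence) {
  o <- oracle_pattern_regex(text)
  L <- nchar(sequence)
  if (L < o$min) return(data.frame(start = integer(), end = integer()))
  best_end <- rep(NA_integer_, L)
  for (len in o$min:min(o$max, L)) {
    s <- seq_len(L - len + 1L)
    hit <- grepl(o$regex, substring(sequence, s, s + len - 1L),
                 perl = TRUE)
    upd <- s[hit & is.na(best_end[s])]
    best_end[upd] <- upd + len - 1L
  }
  keep <- which(!is.na(best_end))
  data.frame(start = keep, end = best_end[keep])
}

# ---- NG86 oracle ----------------------------------------------------

GC <- as.list(Biostrings::GENETIC_CODE)
NT <- c("T", "C", "A", "G")
SENSE <- names(GC)[unlist(GC) != "*"]

oracle_mutants <- function(codon, pos) {
  out <- character(0)
  for (nt in setdiff(NT, substr(codon, pos, pos))) {
    m <- codon
    substr(m, pos, pos) <- nt
    out <- c(out, m)
  }
  out
}

# synonymous site count of one codon (stop mutations excluded from
# the per-position denominator; each position contributes one site)
oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    muts <- oracle_mutants(codon, pos)
    non_stop <- muts[unlist(GC[muts]) != "*"]
    if (length(non_stop) > 0) {
      s <- s + sum(unlist(GC[non_stop]) == GC[[codon]]) / length(non_stop)
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over
# all shortest mutation pathways; pathways through stop intermediates
# dropped (all pathways used if every one is blocked)
oracle_codon_diffs <- function(c1, c2) {
  pos_diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos_diff)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(1L) else if (d == 2) {
    list(c(1L, 2L), c(2L, 1L))
  } else {
    list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
         c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  }
  walk <- function(ord) {
    cur <- c1
    syn <- 0; blocked <- FALSE
    for (k in seq_along(ord)) {
      p <- pos_diff[ord[k]]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC[[nxt]] == "*" && k < length(ord)) blocked <- TRUE
      if (GC[[nxt]] == GC[[cur]]) syn <- syn + 1
      cur <- nxt
    }
    c(syn = syn, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(2))
  use <- res["blocked", ] == 0
  if (!any(use)) use <- rep(TRUE, length(perms))
  sd <- mean(res["syn", use])
  c(sd = sd, nd = d - sd)
}

# full NG86 oracle on two codon vectors (no correction)
oracle_ng86_counts <- function(ca, cb) {
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  diffs <- mapply(function(x, y) oracle_codon_diffs(x, y), ca, cb)
  list(S = S, N = 3 * length(ca) - S,
       Sd = sum(diffs["sd", ]), Nd = sum(diffs["nd", ]))
}

# ---- alignment oracle -----------------------------------------------

# exhaustive enumeration of global alignments of two short strings,
# scored with affine gaps (gap of length L costs open + L * ext);
# returns the maximal score
oracle_nw_score <- function(a, b, sub, open = -11, ext = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return()
    }
    if (i <= length(ca) && j <= length(cb)) {
      recurse(i + 1, j + 1, score + sub[ca[i], cb[j]], "m")
    }
    if (i <= length(ca)) {
      pen <- ext + if (last == "a") 0 else open
      recurse(i + 1, j, score + pen, "a")
    }
    if (j <= length(cb)) {
      pen <- ext + if (last == "b") 0 else open
      recurse(i, j + 1, score + pen, "b")
    }
  }
  recurse(1, 1, 0, "none")
  best
}

# ---- misc helpers ---------------------------------------------------

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_codon_pair <- function(n_codons) {
  list(a = sample(SENSE, n_codons, replace = TRUE),
       b = sample(SENSE, n_codons, replace = TRUE))
}

codon_aln_from_vectors <- function(ca, cb) {
  codon_alignment(paste(ca, collapse = ""), paste(cb, collapse = ""))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
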