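# PROSITE-style motif patterns: parsing, matching, EGF subtype calls.

# the twenty standard residues; 'X' (unknown) is handled separately
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one-letter shorthand classes used by the compact signature dialect:
#   N = negatively charged or polar [DEQN], B = beta-hydroxylatable [DN],
#   A = aromatic.  All other uppercase letters are literal residues.
.SHORTHAND <- list(
  N = c("D", "E", "Q", "N"),
  B = c("D", "N"),
  A = c("F", "Y", "W")
)

.pattern_element <- function(kind, residues, rep_min, rep_max) {
  list(kind = kind, residues = residues,
       rep_min = as.integer(rep_min), rep_max = as.integer(rep_max))
}

#' Parse a compact PROSITE-style motif pattern
#'
#' Parses patterns written in the compact dialect used for EGF-domain
#' signatures, e.g. `"CxCx(5)Gx(2)C"` or
#' `"CxCx(2)[GP][FYW]x(4,8)C"`.  Supported syntax: literal residues
#' (uppercase), `x` for any residue, bracketed residue classes
#' `[GP]`, excluded classes `{P}`, repeat suffixes `(n)` and `(n,m)`,
#' and optional `-` separators between elements.  With
#' `shorthand = TRUE` (the default) the bare letters `N`, `B` and `A`
#' denote the classes \[DEQN\] (negatively charged or polar),
#' \[DN\] (possibly beta-hydroxylated) and aromatic \[FYW\]
#' respectively; bracketed letters are always literal.
#'
#' @param text pattern string.
#' @param name optional label stored on the pattern (e.g. `"PS00022"`).
#' @param shorthand expand the `N`/`B`/`A` shorthand classes?
#' @return an object of class `MotifPattern`: a list with `name` and
#'   `elements`, each element holding `kind`
#'   (`"literal"`, `"any"`, `"class"` or `"exclude"`), `residues`,
#'   `rep_min` and `rep_max`.
#' @examples
#' p <- parse_pattern("CxCx(5)Gx(2)C", name = "PS00022")
#' pattern_length_range(p)  # minimal match length 12
#' @seealso [match_pattern()], [classify_egf()]
#' @export
parse_pattern <- function(text, name = NULL, shorthand = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty pattern")
  elements <- list()
  i <- 1L
  bad <- function(pos, why) {
    stop(sprintf("malformed pattern at position %d ('%s'): %s",
                 pos, substr(text, pos, pos), why), call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") { i <- i + 1L; next }
    start_pos <- i
    if (ch == "x") {
      elem <- .pattern_element("any", character(), 1L, 1L)
      i <- i + 1L
    } else if (ch == "[" || ch == "{") {
      closer <- if (ch == "[") "]" else "}"
      j <- i + 1L
      set <- character()
      while (j <= n && chars[j] != closer) {
        if (!chars[j] %in% .AA20) bad(j, "not an amino-acid code in class")
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > n) bad(start_pos, sprintf("unclosed '%s'", ch))
      if (length(set) == 0L) bad(start_pos, "empty residue class")
      set <- unique(set)
      if (ch == "{") {
        elem <- .pattern_element("exclude", set, 1L, 1L)
      } else if (length(set) == 1L) {
        # singleton classes normalize to literals so that
        # parse -> render -> parse round-trips exactly
        elem <- .pattern_element("literal", set, 1L, 1L)
      } else {
        elem <- .pattern_element("class", set, 1L, 1L)
      }
      i <- j + 1L
    } else if (ch %in% LETTERS) {
      if (shorthand && ch %in% names(.SHORTHAND)) {
        elem <- .pattern_element("class", .SHORTHAND[[ch]], 1L, 1L)
      } else if (ch %in% .AA20) {
        elem <- .pattern_element("literal", ch, 1L, 1L)
      } else {
        bad(i, "not an amino-acid code")
      }
      i <- i + 1L
    } else {
      bad(i, "unexpected character")
    }
    # optional repeat suffix (n) or (n,m)
    if (i <= n && chars[i] == "(") {
      j <- i + 1L
      digits <- ""
      while (j <= n && chars[j] != ")") {
        digits <- paste0(digits, chars[j])
        j <- j + 1L
      }
      if (j > n) bad(i, "unclosed repeat parenthesis")
      if (!grepl("^[0-9]+(,[0-9]+)?$", digits)) bad(i + 1L, "bad repeat spec")
      parts <- as.integer(strsplit(digits, ",")[[1]])
      rep_min <- parts[1]
      rep_max <- if (length(parts) == 2L) parts[2] else parts[1]
      if (rep_min < 1L || rep_max < rep_min) bad(i + 1L, "bad repeat range")
      elem$rep_min <- rep_min
      elem$rep_max <- rep_max
      i <- j + 1L
    }
    elements[[length(elements) + 1L]] <- elem
  }
  if (length(elements) == 0L) stop("pattern contains no elements")
  structure(list(name = name, elements = elements), class = "MotifPattern")
}

#' Render a motif pattern back to its compact string form
#'
#' Inverse of [parse_pattern()] up to element-list equality:
#' re-parsing the rendered string yields an identical element list.
#'
#' @param pattern a `MotifPattern`.
#' @return a single pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "MotifPattern"))
  render_one <- function(e) {
    base <- switch(e$kind,
      any     = "x",
      literal = e$residues,
      class   = paste0("[", paste(e$residues, collapse = ""), "]"),
      exclude = paste0("{", paste(e$residues, collapse = ""), "}"),
      stop("unknown element kind: ", e$kind)
    )
    if (e$rep_min == 1L && e$rep_max == 1L) return(base)
    if (e$rep_min == e$rep_max) return(sprintf("%s(%d)", base, e$rep_min))
    sprintf("%s(%d,%d)", base, e$rep_min, e$rep_max)
  }
  paste(vapply(pattern$elements, render_one, character(1)), collapse = "")
}

#' Minimal and maximal match length of a pattern
#'
#' @param pattern a `MotifPattern`.
#' @return integer vector `c(min, max)`: the sums of `rep_min` and
#'   `rep_max` over the elements.
#' @export
pattern_length_range <- function(pattern) {
  stopifnot(inherits(pattern, "MotifPattern"))
  mins <- vapply(pattern$elements, function(e) e$rep_min, integer(1))
  maxs <- vapply(pattern$elements, function(e) e$rep_max, integer(1))
  c(min = sum(mins), max = sum(maxs))
}

#' @export
print.MotifPattern <- function(x, ...) {
  rng <- pattern_length_range(x)
  cat(sprintf("MotifPattern %s: %s (%d elements, match length %d-%d)\n",
              if (is.null(x$name)) "<unnamed>" else x$name,
              render_pattern(x), length(x$elements), rng[1], rng[2]))
  invisible(x)
}

# logical vector: does each sequence position satisfy this element?
# 'X' (unknown residue) matches only the 'any' element -- conservative.
.element_match_vector <- function(elem, chars) {
  switch(elem$kind,
    any     = chars %in% c(.AA20, "X"),
    literal = chars == elem$residues,
    class   = chars %in% elem$residues,
    exclude = !(chars %in% elem$residues) & chars %in% .AA20,
    stop("unknown element kind")
  )
}

.check_protein_string <- function(sequence, allow_x = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "")[[1]]
  ok <- chars %in% c(.AA20, if (allow_x) "X")
  if (!all(ok)) {
    stop(sprintf("sequence contains non-residue character '%s' at position %d",
                 chars[which(!ok)[1]], which(!ok)[1]), call. = FALSE)
  }
  chars
}

#' Find all matches of a motif pattern in a protein sequence
#'
#' Scans every start position; for variable-length repeats the
#' shortest match at each start is reported (sufficient for
#' presence/absence signature calls).  Overlapping matches at distinct
#' starts are all returned.  `X` in the sequence matches only the `x`
#' element, never literals or classes.
#'
#' @param pattern a `MotifPattern` from [parse_pattern()].
#' @param sequence amino-acid string (standard codes; `X` allowed).
#' @return data.frame with columns `start` and `end` (1-based closed
#'   intervals), zero rows when there is no match.
#' @examples
#' ps00022 <- parse_pattern("CxCx(5)Gx(2)C")
#' match_pattern(ps00022, "CACAAAAAGAAC")
#' @export
match_pattern <- function(pattern, sequence) {
  stopifnot(inherits(pattern, "MotifPattern"))
  chars <- .check_protein_string(sequence)
  L <- length(chars)
  rng <- pattern_length_range(pattern)
  if (L < rng[["min"]]) {
    return(data.frame(start = integer(), end = integer()))
  }
  elems <- pattern$elements
  # per element: run-length of consecutive matches starting at each position
  runs <- lapply(elems, function(e) {
    m <- .element_match_vector(e, chars)
    r <- integer(L)
    acc <- 0L
    for (i in L:1) {
      acc <- if (m[i]) acc + 1L else 0L
      r[i] <- acc
    }
    r
  })
  starts <- integer()
  ends <- integer()
  for (s in seq_len(L - rng[["min"]] + 1L)) {
    offsets <- 0L   # residues consumed so far, relative to s
    for (k in seq_along(elems)) {
      e <- elems[[k]]
      run <- runs[[k]]
      new_offsets <- integer()
      for (o in offsets) {
        pos <- s + o
        if (pos > L) next
        avail <- run[pos]
        if (avail >= e$rep_min) {
          hi <- min(e$rep_max, avail)
          new_offsets <- c(new_offsets, o + e$rep_min:hi)
        }
      }
      offsets <- unique(new_offsets)
      if (length(offsets) == 0L) break
    }
    if (length(offsets) > 0L) {
      starts <- c(starts, s)
      ends <- c(ends, s + min(offsets) - 1L)
    }
  }
  data.frame(start = starts, end = ends)
}

#' The EGF subtype signature table shipped with the package
#'
#' Three signatures drive the subtype calls: `PS00022` (EGF 1),
#' `PS01186` (EGF 2) and `PS01187` (the calcium-binding consensus that
#' refines EGF 2 into cbEGF).  The table is a plain-text
#' `name TAB pattern` file under `extdata` and can be replaced via
#' [read_signature_table()].
#'
#' @param path optional path to an alternative signature table.
#' @return named list of `MotifPattern` objects.
#' @export
egf_signatures <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ctldcpevo_cache$signatures)) {
      return(.ctldcpevo_cache$signatures)
    }
    path <- system.file("extdata", "egf_signatures.tsv",
                        package = "ctldcpevo", mustWork = TRUE)
    sig <- read_signature_table(path)
    .ctldcpevo_cache$signatures <- sig
    return(sig)
  }
  read_signature_table(path)
}

#' Read a signature table (name TAB pattern, no header)
#'
#' @param path path to a two-column tab-separated file.
#' @return named list of `MotifPattern`.
#' @export
read_signature_table <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    col.names = c("name", "pattern"),
                    colClasses = "character")
  if (nrow(tab) == 0L) stop("signature table is empty: ", path)
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    parse_pattern(tab$pattern[i], name = tab$name[i])
  })
  names(pats) <- tab$name
  pats
}

#' Classify one EGF-like domain sequence into a subtype
#'
#' Subtypes follow the standard signature logic for these proteins:
#' a domain matching both `PS01186` and the calcium-binding consensus
#' `PS01187` is a `cbEGF`; `PS01186` alone gives `EGF2`; `PS00022`
#' alone gives `EGF1`; no signature gives `EGF_like`.  When both
#' `PS00022` and `PS01186` match, `EGF2` wins (the calcium-binding
#' consensus is conditioned on the EGF 2 signature) and the ambiguity
#' is reported in the `ambiguous` attribute.  `Tme5EGF`
#' (Thrombomodulin's fifth EGF) is never produced here: it is assigned
#' from the `cl07616` anchor annotation by [segment_protein()].
#'
#' `PS01187` commonly extends beyond a tightly annotated EGF core, so
#' it is tested on the domain plus a flank of `flank` residues each
#' side (clipped to the protein) whenever the surrounding protein
#' sequence and interval are supplied; the other two signatures are
#' always tested on the core interval only.
#'
#' @param sequence amino-acid string of the annotated EGF interval.
#'   May be omitted when `protein_sequence` and `interval` are given.
#' @param protein_sequence optional full protein string for flanking.
#' @param interval optional `c(start, end)` of the domain within
#'   `protein_sequence` (1-based closed).
#' @param flank residues of context added on each side for the
#'   `PS01187` test only (default 10).
#' @param signatures named list with `PS00022`, `PS01186`, `PS01187`
#'   patterns; defaults to the shipped table.
#' @return a length-1 character, one of `"cbEGF"`, `"EGF2"`, `"EGF1"`,
#'   `"EGF_like"`, with attributes `hits` (logical per signature) and
#'   `ambiguous`.
#' @examples
#' classify_egf("CACAAAAAGAAC")  # EGF1
#' classify_egf("CACAAGFAAAAC")  # EGF2
#' @export
classify_egf <- function(sequence = NULL, protein_sequence = NULL,
                         interval = NULL, flank = 10,
                         signatures = egf_signatures()) {
  if (is.null(sequence)) {
    if (is.null(protein_sequence) || is.null(interval)) {
      stop("supply either `sequence` or `protein_sequence` + `interval`")
    }
    sequence <- substr(protein_sequence, interval[1], interval[2])
  }
  if (!nzchar(sequence)) stop("empty EGF domain sequence")
  for (need in c("PS00022", "PS01186", "PS01187")) {
    if (is.null(signatures[[need]])) stop("signature table lacks ", need)
  }
  flank_seq <- sequence
  if (!is.null(protein_sequence) && !is.null(interval)) {
    lo <- max(1L, interval[1] - as.integer(flank))
    hi <- min(nchar(protein_sequence), interval[2] + as.integer(flank))
    flank_seq <- substr(protein_sequence, lo, hi)
  }
  hit <- c(
    PS00022 = nrow(match_pattern(signatures$PS00022, sequence)) > 0L,
    PS01186 = nrow(match_pattern(signatures$PS01186, sequence)) > 0L,
    PS01187 = nrow(match_pattern(signatures$PS01187, flank_seq)) > 0L
  )
  ambiguous <- unname(hit["PS00022"] && hit["PS01186"])
  if (ambiguous) {
    .log_warn("EGF domain matches both PS00022 and PS01186; calling EGF2")
  }
  subtype <- if (hit["PS01186"] && hit["PS01187"]) {
    "cbEGF"
  } else if (hit["PS01186"]) {
    "EGF2"
  } else if (hit["PS00022"]) {
    "EGF1"
  } else {
    "EGF_like"
  }
  structure(subtype, hits = hit, ambiguous = ambiguous)
}
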