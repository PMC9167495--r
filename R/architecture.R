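# Region partition of a CTLDcp from anchor domain annotations, and the
# sushi-like domain key-residue conservation check.

.CTLD_NAMES <- c("CLECT", "CTLD")
.TM_NAMES <- c("TM", "transmembrane", "TMhelix")
.TME5_NAME <- "cl07616"

.is_egf_anchor <- function(name) grepl("EGF", name) | name == .TME5_NAME

#' Load a domain anchor annotation table
#'
#' Reads a CD-Search-style hit table: a tab-separated file with a
#' header and (at least) the columns `protein_id`, `name`, `start`,
#' `end` in 1-based closed protein coordinates.  Other column names
#' can be mapped via `column_map` (e.g. the Batch CD-Search dialect
#' `c(protein_id = "Query", name = "Short.name", start = "From",
#' end = "To")`).
#'
#' @param path path to the TSV file (an empty file yields zero rows).
#' @param protein_lengths optional named integer vector; when given,
#'   annotations extending beyond the protein are rejected.
#' @param column_map optional named character vector mapping the
#'   required names to the file's column names.
#' @return data.frame with columns `protein_id`, `name`, `start`,
#'   `end`, `source`, sorted by protein then start.  Overlapping
#'   anchors within a protein, `end < start`, or out-of-range
#'   coordinates raise a validation error listing the offenders.
#' @export
load_domain_table <- function(path, protein_lengths = NULL,
                              column_map = NULL) {
  if (file.info(path)$size == 0) {
    return(data.frame(protein_id = character(), name = character(),
                      start = integer(), end = integer(),
                      source = character()))
  }
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein_id", "name", "start", "end")
  if (!is.null(column_map)) {
    for (nm in need) {
      if (!is.null(column_map[[nm]])) {
        if (!column_map[[nm]] %in% names(raw)) {
          stop("column_map refers to missing column: ", column_map[[nm]])
        }
        raw[[nm]] <- raw[[column_map[[nm]]]]
      }
    }
  }
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("domain table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  tab <- data.frame(
    protein_id = as.character(raw$protein_id),
    name = as.character(raw$name),
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    source = if ("source" %in% names(raw)) as.character(raw$source)
             else basename(path),
    stringsAsFactors = FALSE
  )
  if (nrow(tab) == 0L) return(tab)
  validate_domain_annotations(tab, protein_lengths = protein_lengths)
}

#' Validate and sort domain annotations
#'
#' @param tab data.frame as returned by [load_domain_table()].
#' @param protein_lengths optional named lengths for range checks.
#' @return the table sorted by protein then start; errors list every
#'   offending row.
#' @export
validate_domain_annotations <- function(tab, protein_lengths = NULL) {
  problems <- character()
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$start < 1L)
  for (i in bad) {
    problems <- c(problems, sprintf("%s %s: non-positive or missing coordinate",
                                    tab$protein_id[i], tab$name[i]))
  }
  bad <- which(tab$end < tab$start)
  for (i in bad) {
    problems <- c(problems, sprintf("%s %s: end %d < start %d",
                                    tab$protein_id[i], tab$name[i],
                                    tab$end[i], tab$start[i]))
  }
  if (!is.null(protein_lengths)) {
    for (i in seq_len(nrow(tab))) {
      len <- protein_lengths[[tab$protein_id[i]]]
      if (!is.null(len) && !is.na(tab$end[i]) && tab$end[i] > len) {
        problems <- c(problems,
                      sprintf("%s %s: end %d beyond protein length %d",
                              tab$protein_id[i], tab$name[i], tab$end[i], len))
      }
    }
  }
  tab <- tab[order(tab$protein_id, tab$start, tab$end), , drop = FALSE]
  for (pid in unique(tab$protein_id)) {
    sub <- tab[tab$protein_id == pid, , drop = FALSE]
    if (nrow(sub) > 1L) {
      prev_end <- sub$end[-nrow(sub)]
      next_start <- sub$start[-1L]
      ov <- which(next_start <= prev_end)
      for (k in ov) {
        problems <- c(problems,
                      sprintf("%s: anchors %s (%d,%d) and %s (%d,%d) overlap",
                              pid, sub$name[k], sub$start[k], sub$end[k],
                              sub$name[k + 1], sub$start[k + 1],
                              sub$end[k + 1]))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("invalid domain annotations:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Derive the region partition of a CTLDcp from its anchor domains
#'
#' Applies the standard segmentation rules for these proteins: the
#' sushi-like region spans the interval between the CTLD and the first
#' EGF-like anchor (or the transmembrane anchor when all EGF repeats
#' were lost); the mucin-like region runs from the first residue after
#' the last EGF to the residue before the transmembrane segment; the
#' cytoplasmic tail runs from after the transmembrane segment to the
#' C-terminus.  Zero-length derived regions (adjacent anchors) are
#' reported as absent.  For the Thrombomodulin family the
#' CTLD-to-first-EGF region is labelled `"hydrophobic stretch"` instead
#' of `"sushi-like"`.  EGF subtypes are filled by [classify_egf()]
#' when `protein_sequence` is supplied; anchors named `cl07616` become
#' `Tme5EGF` directly.
#'
#' @param annotations data.frame of anchors for one protein
#'   (`protein_id`, `name`, `start`, `end`); order does not matter.
#'   CTLD anchors are recognised by name `CLECT`/`CTLD`, transmembrane
#'   anchors by `TM`, EGF anchors by a name containing `EGF` or equal
#'   to `cl07616`.
#' @param protein_length protein length in residues.
#' @param family one of `"CD93"`, `"Clec14A"`, `"CD248"`,
#'   `"Thrombomodulin"`, `"other"`.
#' @param protein_sequence optional amino-acid string for subtype calls.
#' @param flank flank passed to [classify_egf()].
#' @param signatures signature list passed to [classify_egf()].
#' @return an object of class `RegionSet`.
#' @examples
#' ann <- data.frame(protein_id = "P1",
#'                   name = c("CLECT", "EGF", "EGF", "TM"),
#'                   start = c(22, 210, 251, 580),
#'                   end = c(150, 250, 290, 602))
#' segment_protein(ann, protein_length = 650, family = "CD93")
#' @export
segment_protein <- function(annotations, protein_length,
                            family = c("other", "CD93", "Clec14A",
                                       "CD248", "Thrombomodulin"),
                            protein_sequence = NULL, flank = 10,
                            signatures = egf_signatures()) {
  family <- match.arg(family)
  protein_length <- as.integer(protein_length)
  stopifnot(nrow(annotations) >= 1L, protein_length >= 1L)
  pid <- unique(annotations$protein_id)
  if (length(pid) != 1L) {
    stop("segment_protein expects annotations for exactly one protein")
  }
  if (!is.null(protein_sequence) &&
      nchar(protein_sequence) != protein_length) {
    stop("protein_sequence length disagrees with protein_length")
  }
  ann <- validate_domain_annotations(
    annotations,
    protein_lengths = setNames(protein_length, pid)
  )
  ctld <- ann[ann$name %in% .CTLD_NAMES, , drop = FALSE]
  tm <- ann[ann$name %in% .TM_NAMES, , drop = FALSE]
  egf <- ann[.is_egf_anchor(ann$name), , drop = FALSE]
  if (nrow(ctld) > 1L) stop("more than one CTLD anchor for ", pid)
  if (nrow(tm) > 1L) stop("more than one TM anchor for ", pid)
  if (nrow(egf) > 0L && nrow(ctld) == 1L &&
      ctld$start[1] > egf$start[1]) {
    stop("inconsistent architecture for ", pid,
         ": CTLD lies after the first EGF anchor")
  }
  if (nrow(egf) > 0L && nrow(tm) == 1L &&
      tm$start[1] < egf$end[nrow(egf)]) {
    stop("inconsistent architecture for ", pid,
         ": TM lies before the last EGF anchor")
  }

  interval_or_null <- function(lo, hi) {
    if (lo > hi) NULL else c(start = as.integer(lo), end = as.integer(hi))
  }

  sushi <- NULL
  if (nrow(ctld) == 1L) {
    nxt <- if (nrow(egf) > 0L) egf$start[1]
           else if (nrow(tm) == 1L) tm$start[1]
           else NA_integer_
    if (!is.na(nxt)) sushi <- interval_or_null(ctld$end[1] + 1L, nxt - 1L)
  }
  mucin <- NULL
  if (nrow(egf) > 0L && nrow(tm) == 1L) {
    mucin <- interval_or_null(egf$end[nrow(egf)] + 1L, tm$start[1] - 1L)
  }
  cytotail <- NULL
  if (nrow(tm) == 1L) {
    cytotail <- interval_or_null(tm$end[1] + 1L, protein_length)
  }

  egf_tab <- NULL
  if (nrow(egf) > 0L) {
    subtype <- character(nrow(egf))
    ambiguous <- logical(nrow(egf))
    for (i in seq_len(nrow(egf))) {
      if (egf$name[i] == .TME5_NAME) {
        subtype[i] <- "Tme5EGF"
      } else if (is.null(protein_sequence)) {
        subtype[i] <- NA_character_
      } else {
        cls <- classify_egf(protein_sequence = protein_sequence,
                            interval = c(egf$start[i], egf$end[i]),
                            flank = flank, signatures = signatures)
        subtype[i] <- as.character(cls)
        ambiguous[i] <- attr(cls, "ambiguous")
      }
    }
    egf_tab <- data.frame(start = egf$start, end = egf$end,
                          subtype = subtype, ambiguous = ambiguous,
                          stringsAsFactors = FALSE)
  }

  structure(
    list(
      protein_id = pid,
      family = family,
      protein_length = protein_length,
      ctld = if (nrow(ctld) == 1L) c(start = ctld$start[1],
                                     end = ctld$end[1]) else NULL,
      sushi = sushi,
      sushi_label = if (family == "Thrombomodulin") "hydrophobic stretch"
                    else "sushi-like",
      egfs = egf_tab,
      mucin = mucin,
      tm = if (nrow(tm) == 1L) c(start = tm$start[1], end = tm$end[1])
           else NULL,
      cytotail = cytotail
    ),
    class = "RegionSet"
  )
}

#' Flatten a RegionSet to a regions table
#'
#' @param x a `RegionSet`.
#' @param ... unused.
#' @return data.frame with columns `protein_id`, `region`, `start`,
#'   `end`, `subtype` (subtype is `NA` outside EGF rows); EGF rows are
#'   labelled `EGF_1`, `EGF_2`, ... in N-to-C order.
#' @method as.data.frame RegionSet
#' @export
as.data.frame.RegionSet <- function(x, ...) {
  rows <- list()
  add <- function(region, iv, subtype = NA_character_) {
    if (is.null(iv)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = x$protein_id, region = region,
      start = unname(iv[1]), end = unname(iv[2]),
      subtype = subtype, stringsAsFactors = FALSE)
  }
  add("CTLD", x$ctld)
  add(x$sushi_label, x$sushi)
  if (!is.null(x$egfs)) {
    for (i in seq_len(nrow(x$egfs))) {
      add(sprintf("EGF_%d", i), c(x$egfs$start[i], x$egfs$end[i]),
          x$egfs$subtype[i])
    }
  }
  add("mucin", x$mucin)
  add("TM", x$tm)
  add("cytotail", x$cytotail)
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(), region = character(),
                      start = integer(), end = integer(),
                      subtype = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet for %s (%s, %d aa)\n",
              x$protein_id, x$family, x$protein_length))
  print(as.data.frame(x))
  invisible(x)
}

#' Extract region sequences from a protein
#'
#' @param regions a `RegionSet`.
#' @param protein_sequence the protein string the regions refer to.
#' @return named character vector of region sequences (names as in
#'   [as.data.frame.RegionSet()]).
#' @export
region_sequences <- function(regions, protein_sequence) {
  tab <- as.data.frame(regions)
  setNames(substr(rep(protein_sequence, nrow(tab)), tab$start, tab$end),
           tab$region)
}

#' Check conservation of sushi-domain key residues
#'
#' The sushi-like module (~60 residues) depends on conserved
#' tryptophan, glycine, proline and cysteine residues.  Each query
#' region is globally aligned to a designated reference
#' ([align_proteins_nw()]); the configured key reference columns are
#' mapped through the alignment and the aligned residue is compared
#' with the expected residue class.  A gap at a key column counts as
#' not conserved (loss happens through truncation as well as
#' substitution).  A sequence is called `lacks_sushi` when more than
#' `tolerance` key columns are not conserved.
#'
#' @param region_sequences named character vector of extracted
#'   sushi-region sequences (one per protein).
#' @param reference_id name of the reference sequence.
#' @param key_columns data.frame with columns `position` (1-based
#'   residue index in the reference) and `class` (string of allowed
#'   residues, e.g. `"C"`); defaults to the first occurrence of each
#'   of C, W, G, P in the reference.
#' @param tolerance number of non-conserved key columns tolerated
#'   before calling `lacks_sushi` (default 0).
#' @param ... alignment options passed to [align_proteins_nw()].
#' @return object of class `sushi_check`: per-sequence conservation
#'   tables and an overall `has_sushi`/`lacks_sushi` call per sequence.
#' @export
check_sushi_residues <- function(region_sequences, reference_id,
                                 key_columns = NULL, tolerance = 0, ...) {
  stopifnot(is.character(region_sequences),
            !is.null(names(region_sequences)))
  if (!reference_id %in% names(region_sequences)) {
    stop("reference sequence not found: ", reference_id)
  }
  ref <- region_sequences[[reference_id]]
  if (is.null(key_columns)) {
    key_columns <- default_sushi_key_columns(ref)
  }
  stopifnot(all(c("position", "class") %in% names(key_columns)))
  ref_chars <- strsplit(ref, "")[[1]]
  for (i in seq_len(nrow(key_columns))) {
    pos <- key_columns$position[i]
    if (is.na(pos) || pos < 1L || pos > length(ref_chars)) {
      stop(sprintf("key column %d: reference has no position %s",
                   i, format(pos)))
    }
    if (!grepl(ref_chars[pos], key_columns$class[i], fixed = TRUE)) {
      stop(sprintf(
        "key column %d: reference residue '%s' at position %d not in class [%s]",
        i, ref_chars[pos], pos, key_columns$class[i]))
    }
  }
  per_sequence <- list()
  calls <- character()
  for (id in names(region_sequences)) {
    qry <- region_sequences[[id]]
    if (id == reference_id) {
      observed <- ref_chars[key_columns$position]
    } else {
      aln <- align_proteins_nw(ref, qry, ...)
      acols_ref <- strsplit(aln$a, "")[[1]]
      acols_qry <- strsplit(aln$b, "")[[1]]
      ref_pos_at_col <- cumsum(acols_ref != "-")
      observed <- vapply(key_columns$position, function(pos) {
        col <- match(pos, ref_pos_at_col)
        acols_qry[col]
      }, character(1))
    }
    conserved <- mapply(function(obs, cls) {
      obs != "-" && grepl(obs, cls, fixed = TRUE)
    }, observed, key_columns$class)
    per_sequence[[id]] <- data.frame(
      column = seq_len(nrow(key_columns)),
      position = key_columns$position,
      expected = key_columns$class,
      observed = observed,
      conserved = unname(conserved),
      stringsAsFactors = FALSE
    )
    calls[id] <- if (sum(!conserved) > tolerance) "lacks_sushi"
                 else "has_sushi"
  }
  structure(
    list(reference_id = reference_id, key_columns = key_columns,
         tolerance = tolerance, per_sequence = per_sequence,
         calls = calls),
    class = "sushi_check"
  )
}

#' Default sushi key columns from a reference sequence
#'
#' Takes the first occurrence of each of the four hallmark residues
#' (C, W, G, P) in the reference as key columns.
#'
#' @param reference_sequence amino-acid string.
#' @return data.frame with `position` and `class`.
#' @export
default_sushi_key_columns <- function(reference_sequence) {
  chars <- strsplit(reference_sequence, "")[[1]]
  classes <- c("C", "W", "G", "P")
  pos <- vapply(classes, function(cl) match(cl, chars), integer(1))
  if (anyNA(pos)) {
    stop("reference lacks hallmark residue(s): ",
         paste(classes[is.na(pos)], collapse = ", "))
  }
  out <- data.frame(position = unname(pos), class = classes,
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' @export
print.sushi_check <- function(x, ...) {
  cat(sprintf("Sushi key-residue check (reference %s, tolerance %d)\n",
              x$reference_id, x$tolerance))
  for (id in names(x$calls)) {
    n_bad <- sum(!x$per_sequence[[id]]$conserved)
    cat(sprintf("  %s: %s (%d/%d key columns lost)\n", id, x$calls[id],
                n_bad, nrow(x$key_columns)))
  }
  invisible(x)
}
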