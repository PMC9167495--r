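# Conserved synteny blocks around CTLDcp anchors and classification of
# gene-absence mechanisms (chromosome disruption vs locus-preserved
# loss).  "Syntenic gene" is operationalized at the family-label
# level; family assignment is input, strand is ignored.

#' Read a BED-like gene position table
#'
#' Tab-separated with a header and columns `chromosome`, `start`,
#' `end`, `gene_id`, `family` (optional `species`).
#'
#' @param path file path.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "gene_id", "family")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"species" %in% names(tab)) tab$species <- NA_character_
  bad <- which(tab$start > tab$end | !nzchar(tab$family))
  if (length(bad) > 0L) {
    stop("invalid gene records at rows: ", paste(bad, collapse = ", "))
  }
  tab
}

#' Build the synteny block around an anchor gene
#'
#' Collects the genes on the anchor's chromosome that overlap a window
#' of `window_bp` each side of the anchor (about 20 Mbp by default; on
#' short chromosomes this often covers the whole chromosome).
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param anchor_family family label of the anchor; exactly one gene
#'   of this family may lie on the designated chromosome.
#' @param window_bp window half-width in bp (default 2e7).
#' @param chromosome optional chromosome to restrict the anchor search
#'   (required when the family occurs on several chromosomes).
#' @return object of class `SyntenyBlock` (anchor record, window and
#'   the member gene records sorted by start).
#' @export
build_block <- function(genes, anchor_family, window_bp = 2e7,
                        chromosome = NULL) {
  stopifnot(window_bp > 0)
  cand <- genes[genes$family == anchor_family, , drop = FALSE]
  if (!is.null(chromosome)) {
    cand <- cand[cand$chromosome == chromosome, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    stop("anchor family not found in the gene table: ", anchor_family,
         call. = FALSE)
  }
  if (nrow(cand) > 1L) {
    stop("ambiguous anchor for family ", anchor_family, ": ",
         paste(sprintf("%s@%s:%d", cand$gene_id, cand$chromosome,
                       cand$start), collapse = ", "))
  }
  anchor <- cand[1L, ]
  lo <- anchor$start - window_bp
  hi <- anchor$end + window_bp
  members <- genes[genes$chromosome == anchor$chromosome &
                     genes$end >= lo & genes$start <= hi, , drop = FALSE]
  members <- members[order(members$start), , drop = FALSE]
  rownames(members) <- NULL
  structure(
    list(anchor = anchor, window_bp = window_bp,
         chromosome = anchor$chromosome, members = members),
    class = "SyntenyBlock"
  )
}

#' @export
print.SyntenyBlock <- function(x, ...) {
  cat(sprintf(
    "SyntenyBlock: %s (%s) on %s +/- %.1f Mbp; %d genes, %d families\n",
    x$anchor$family, x$anchor$gene_id, x$chromosome, x$window_bp / 1e6,
    nrow(x$members), length(unique(x$members$family))))
  invisible(x)
}

.synteny_report <- function(shared, min_families, absence_call,
                            counts = NULL, detail = NULL) {
  structure(
    list(shared_families = sort(shared), count = length(shared),
         min_families = min_families,
         meets_threshold = length(shared) >= min_families,
         absence_call = absence_call, counts = counts, detail = detail),
    class = "SyntenyReport"
  )
}

#' @export
print.SyntenyReport <- function(x, ...) {
  cat(sprintf("SyntenyReport: %d shared families (threshold %d: %s); call: %s\n",
              x$count, x$min_families,
              ifelse(x$meets_threshold, "met", "not met"),
              x$absence_call))
  if (!is.null(x$counts)) {
    cat("  ", paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = " "), "\n")
  }
  invisible(x)
}

#' Shared gene families between two synteny blocks
#'
#' @param a,b `SyntenyBlock` objects.
#' @param min_families minimum shared families for a locus to count as
#'   syntenic (default 15).
#' @return a `SyntenyReport` with `absence_call = "present"`.
#' @export
shared_families <- function(a, b, min_families = 15L) {
  stopifnot(inherits(a, "SyntenyBlock"), inherits(b, "SyntenyBlock"))
  shared <- intersect(unique(a$members$family), unique(b$members$family))
  .synteny_report(shared, min_families, absence_call = "present")
}

#' Pairwise shared-family count matrix
#'
#' @param blocks named list of `SyntenyBlock` objects.
#' @param min_families threshold passed to [shared_families()].
#' @return symmetric integer matrix of shared-family counts.
#' @export
shared_family_matrix <- function(blocks, min_families = 15L) {
  n <- length(blocks)
  out <- matrix(0L, n, n, dimnames = list(names(blocks), names(blocks)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- if (i == j) {
        length(unique(blocks[[i]]$members$family))
      } else {
        shared_families(blocks[[i]], blocks[[j]], min_families)$count
      }
    }
  }
  out
}

#' Classify the mechanism behind a gene absence
#'
#' Given the reference neighbourhood of a target gene and the genome
#' of a species lacking it, each reference neighbour family is
#' classified in the query genome as retained-in-block (present on the
#' best candidate chromosome within one window of the candidate
#' locus), relocated (present elsewhere) or missing.  The absence is
#' called `locus_preserved_loss` when the retained fraction reaches
#' `retained_fraction_threshold` (the locus survived; the gene itself
#' was deleted or pseudogenized), `chromosome_disruption` when the
#' relocated+missing fraction exceeds `1 - retained_fraction_threshold`
#' (the bearing chromosome was dismantled), and `indeterminate`
#' otherwise.  The best candidate locus is the chromosome carrying the
#' most neighbour families (ties broken lexicographically).  If the
#' target family itself occurs in the query block the call is
#' `present`.
#'
#' @param target_family family label of the absent gene.
#' @param reference_block `SyntenyBlock` around the target in the
#'   reference genome.
#' @param query_genome gene table of the query species.
#' @param retained_fraction_threshold default 0.5.
#' @param min_families minimum assessable neighbour families; below it
#'   the call is `indeterminate` (with a warning).
#' @param window_bp window half-width for the retained-in-block test;
#'   defaults to the reference block's window.
#' @return a `SyntenyReport` with `counts` (retained / relocated /
#'   missing) and a per-family `detail` table.
#' @export
classify_absence <- function(target_family, reference_block, query_genome,
                             retained_fraction_threshold = 0.5,
                             min_families = 15L,
                             window_bp = reference_block$window_bp) {
  stopifnot(inherits(reference_block, "SyntenyBlock"))
  neighbors <- setdiff(unique(reference_block$members$family),
                       target_family)
  n <- length(neighbors)
  if (n < min_families) {
    warning(sprintf(
      "only %d assessable neighbour families (minimum %d); indeterminate",
      n, min_families))
    return(.synteny_report(character(), min_families, "indeterminate"))
  }
  qry <- query_genome[query_genome$family %in% c(neighbors, target_family),
                      , drop = FALSE]
  # best candidate locus: chromosome with the most neighbour families
  qn <- qry[qry$family %in% neighbors, , drop = FALSE]
  status <- setNames(rep("missing", n), neighbors)
  shared <- character()
  best_chr <- NA_character_
  if (nrow(qn) > 0L) {
    per_chr <- vapply(split(qn$family, qn$chromosome),
                      function(f) length(unique(f)), integer(1))
    best_chr <- sort(names(per_chr)[per_chr == max(per_chr)])[1L]
    on_best <- qn[qn$chromosome == best_chr, , drop = FALSE]
    center <- median((on_best$start + on_best$end) / 2)
    in_block <- on_best$end >= center - window_bp &
      on_best$start <= center + window_bp
    retained_fams <- unique(on_best$family[in_block])
    status[retained_fams] <- "retained"
    elsewhere <- setdiff(unique(qn$family), retained_fams)
    status[elsewhere] <- "relocated"
    shared <- retained_fams
    # is the target itself present in the candidate block?
    qt <- qry[qry$family == target_family &
                qry$chromosome == best_chr, , drop = FALSE]
    if (nrow(qt) > 0L &&
        any(qt$end >= center - window_bp & qt$start <= center + window_bp)) {
      counts <- c(retained = sum(status == "retained"),
                  relocated = sum(status == "relocated"),
                  missing = sum(status == "missing"))
      return(.synteny_report(shared, min_families, "present", counts,
                             detail = data.frame(family = neighbors,
                                                 status = unname(status))))
    }
  }
  counts <- c(retained = sum(status == "retained"),
              relocated = sum(status == "relocated"),
              missing = sum(status == "missing"))
  retained_frac <- counts[["retained"]] / n
  call <- if (retained_frac >= retained_fraction_threshold) {
    "locus_preserved_loss"
  } else if ((counts[["relocated"]] + counts[["missing"]]) / n >
             1 - retained_fraction_threshold) {
    "chromosome_disruption"
  } else {
    "indeterminate"
  }
  .synteny_report(shared, min_families, call, counts,
                  detail = data.frame(family = neighbors,
                                      status = unname(status)))
}
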