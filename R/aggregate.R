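# Cohort-level per-domain Ka/Ks: align each region across all
# unordered species pairs, thread codons, estimate, and summarise per
# family x region (median and quartiles, matching box-plot summaries).

#' Per-domain Ka/Ks across all species pairs of a cohort
#'
#' For every family and region label, all unordered species pairs are
#' processed: the region's protein sequences are globally aligned
#' ([align_proteins_nw()]), the CDS are threaded through the alignment
#' ([backthread_codons()]) and Ka/Ks is estimated with the requested
#' method.  Species lacking a region are skipped for that region with
#' a logged warning.  Pairs with undefined ratios (e.g. `dS = 0`) are
#' kept in the long table but excluded from the summary medians.
#'
#' @param records list of per-species records, each a list with
#'   `species`, `family`, `protein`, `cds` and `regions` (a
#'   `RegionSet`), e.g. from [simulate_cohort()].
#' @param method `"ng86"` or `"yn00"`.
#' @param families optional subset of families to process.
#' @param regions optional subset of region labels (as in
#'   [as.data.frame.RegionSet()], e.g. `"CTLD"`, `"mucin"`, `"EGF_1"`).
#' @param ... extra arguments passed to the estimator (e.g. `kappa`
#'   for [yn00()]).
#' @return object of class `domain_kaks`: `table` (one row per
#'   family/region/pair) and `summary` (per family x region median and
#'   quartiles of the defined ratios, with `n` the number of pairs
#'   with a defined ratio).
#' @export
aggregate_domain_kaks <- function(records,
                                  method = c("ng86", "yn00"),
                                  families = NULL, regions = NULL, ...) {
  method <- match.arg(method)
  estimator <- switch(method, ng86 = ng86, yn00 = yn00)
  fams <- unique(vapply(records, function(r) r$family, character(1)))
  if (!is.null(families)) fams <- intersect(fams, families)
  rows <- list()
  for (fam in fams) {
    recs <- Filter(function(r) r$family == fam, records)
    if (length(recs) < 2L) {
      .log_warn("family %s has fewer than 2 species; skipped", fam)
      next
    }
    species <- vapply(recs, function(r) r$species, character(1))
    reg_tabs <- lapply(recs, function(r) as.data.frame(r$regions))
    labels <- unique(unlist(lapply(reg_tabs, function(t) t$region)))
    if (!is.null(regions)) labels <- intersect(labels, regions)
    for (lab in labels) {
      have <- vapply(reg_tabs, function(t) lab %in% t$region, logical(1))
      if (any(!have)) {
        .log_warn("region %s absent in species %s (family %s); skipped",
                  lab, paste(species[!have], collapse = ","), fam)
      }
      idx <- which(have)
      if (length(idx) < 2L) next
      for (a in idx) {
        for (b in idx) {
          if (b <= a) next
          iv_a <- reg_tabs[[a]][reg_tabs[[a]]$region == lab, ][1L, ]
          iv_b <- reg_tabs[[b]][reg_tabs[[b]]$region == lab, ][1L, ]
          prot_a <- substr(recs[[a]]$protein, iv_a$start, iv_a$end)
          prot_b <- substr(recs[[b]]$protein, iv_b$start, iv_b$end)
          nt_a <- map_protein_interval_to_cds(iv_a$start, iv_a$end,
                                              nchar(recs[[a]]$cds))
          nt_b <- map_protein_interval_to_cds(iv_b$start, iv_b$end,
                                              nchar(recs[[b]]$cds))
          cds_a <- substr(recs[[a]]$cds, nt_a[1], nt_a[2])
          cds_b <- substr(recs[[b]]$cds, nt_b[1], nt_b[2])
          aln <- align_proteins_nw(prot_a, prot_b)
          caln <- backthread_codons(aln$a, aln$b, cds_a, cds_b,
                                    ids = species[c(a, b)])
          est <- estimator(caln, ...)
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, region = lab,
            species_a = species[a], species_b = species[b],
            method = est$method, S = est$S, N = est$N,
            Sd = est$Sd, Nd = est$Nd, dN = est$dN, dS = est$dS,
            ratio = est$ratio, kappa = est$kappa,
            columns_retained = est$columns_retained,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(family = character(), region = character(),
               species_a = character(), species_b = character(),
               method = character(), S = numeric(), N = numeric(),
               Sd = numeric(), Nd = numeric(), dN = numeric(),
               dS = numeric(), ratio = numeric(), kappa = numeric(),
               columns_retained = integer())
  summ <- do.call(rbind, lapply(split(tab, tab[c("family", "region")],
                                      drop = TRUE), function(g) {
    ok <- g$ratio[!is.na(g$ratio)]
    data.frame(family = g$family[1], region = g$region[1],
               n_pairs = nrow(g), n = length(ok),
               median = if (length(ok)) median(ok) else NA_real_,
               q1 = if (length(ok)) unname(quantile(ok, 0.25)) else NA_real_,
               q3 = if (length(ok)) unname(quantile(ok, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) {
    summ <- data.frame(family = character(), region = character(),
                       n_pairs = integer(), n = integer(),
                       median = numeric(), q1 = numeric(), q3 = numeric())
  }
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, method = method),
            class = "domain_kaks")
}

#' @export
print.domain_kaks <- function(x, ...) {
  cat(sprintf("domain_kaks (%s): %d pairwise estimates\n",
              x$method, nrow(x$table)))
  print(x$summary)
  invisible(x)
}
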