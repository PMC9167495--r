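# End-to-end orchestration, run configuration, and the group
# statistics used for protein-length comparisons (one-way ANOVA with
# Tukey's multiple-comparison test).

#' One-way ANOVA over named groups
#'
#' Classical between/within mean-square F with (k-1, N-k) degrees of
#' freedom; the p value comes from the F distribution
#' ([stats::pf()]).  With zero within-group variance and unequal
#' means, F is reported as infinite with p = 0; with all values equal
#' the statistic is 0 and p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return list with `F`, `p`, `df` (`c(between, within)`), `means`
#'   and `n` per group.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("each group needs at least 2 values")
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- c(between = k - 1L, within = N - k)
  msb <- ssb / df[1]
  msw <- ssw / df[2]
  if (msw == 0) {
    if (msb == 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- msb / msw
    p <- pf(f, df[1], df[2], lower.tail = FALSE)
  }
  list(F = unname(f), p = unname(p), df = df, means = means, n = n,
       msw = unname(msw))
}

#' Tukey's honestly-significant-difference test
#'
#' Pairwise studentized-range statistics
#' `q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer form for unequal group sizes) with adjusted p
#' values from the studentized range distribution
#' ([stats::ptukey()]).
#'
#' @param groups as in [anova_oneway()].
#' @return data.frame with one row per unordered pair: `group_i`,
#'   `group_j`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  a <- anova_oneway(groups)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      diff <- a$means[j] - a$means[i]
      se <- sqrt(a$msw / 2 * (1 / a$n[i] + 1 / a$n[j]))
      if (se == 0) {
        q <- if (diff == 0) 0 else Inf
        p <- if (diff == 0) 1 else 0
      } else {
        q <- abs(diff) / se
        p <- ptukey(q, nmeans = k, df = a$df[["within"]],
                    lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_i = labs[i], group_j = labs[j],
        diff = unname(diff), q = unname(q), p_adj = unname(p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a run configuration (YAML)
#'
#' The configuration carries a versioned schema key, input paths, a
#' `protein_id -> family/species` map file and the analysis
#' thresholds; every threshold is surfaced here, never hard-coded in
#' the pipeline.
#'
#' @param path YAML file with keys `schema_version`, `inputs`
#'   (`protein_fasta`, `cds_fasta`, `domain_table`, `family_map`),
#'   optional `thresholds` (`score`, `window_bp`, `min_families`,
#'   `retained_fraction`), `method` (`ng86`/`yn00`), `seed`,
#'   `out_dir`.
#' @return config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    stop("unsupported or missing config schema_version (expected 1)")
  }
  defaults <- list(score = 0.5, window_bp = 2e7, min_families = 15L,
                   retained_fraction = 0.5)
  cfg$thresholds <- utils::modifyList(defaults,
                                      as.list(cfg$thresholds %||% list()))
  if (any(unlist(cfg$thresholds) <= 0)) {
    stop("all thresholds must be positive")
  }
  cfg$method <- cfg$method %||% "yn00"
  cfg$seed <- cfg$seed %||% 1L
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_fasta_named <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Run the domain-evolution pipeline end to end
#'
#' Orchestrates the stages: load protein/CDS FASTA, the anchor domain
#' table and the family map; segment every protein
#' ([segment_protein()], filling EGF subtypes); estimate per-domain
#' Ka/Ks over all species pairs per family
#' ([aggregate_domain_kaks()]); check sushi key residues per family
#' ([check_sushi_residues()]).  Every skipped record is logged with a
#' reason and collected in the skip table; outputs are byte-stable
#' given identical inputs, configuration and seed.
#'
#' @param config a list (or path to a YAML file read with
#'   [read_run_config()]) with `inputs` (`protein_fasta`, `cds_fasta`,
#'   `domain_table`, `family_map`), `method`, `seed` and optional
#'   `out_dir` (when set, result TSVs are written there).
#' @return invisible list with `regions` (long regions table),
#'   `egf_subtypes`, `kaks` (a `domain_kaks`), `sushi` (per-family
#'   `sushi_check` objects), `skipped` (skip log) and `config`.
#' @export
run_domain_evolution <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  set.seed(config$seed %||% 1L)
  method <- config$method %||% "yn00"
  .log_info("stage: load inputs")
  proteins <- .read_fasta_named(config$inputs$protein_fasta, "AA")
  cds <- .read_fasta_named(config$inputs$cds_fasta, "DNA")
  fam_map <- read.delim(config$inputs$family_map,
                        stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "family", "species") %in% names(fam_map)))
  domains <- load_domain_table(config$inputs$domain_table,
                               protein_lengths = nchar(proteins))

  skipped <- data.frame(protein_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(pid, reason) {
    .log_warn("skipping %s: %s", pid, reason)
    skipped <<- rbind(skipped, data.frame(protein_id = pid,
                                          reason = reason))
  }

  .log_info("stage: segmentation")
  records <- list()
  region_rows <- list()
  for (pid in names(proteins)) {
    if (!pid %in% fam_map$protein_id) { skip(pid, "no family mapping"); next }
    if (!pid %in% domains$protein_id) { skip(pid, "no domain anchors"); next }
    if (!pid %in% names(cds)) { skip(pid, "no CDS record"); next }
    row <- fam_map[fam_map$protein_id == pid, ][1L, ]
    fam <- if (row$family %in% c("CD93", "Clec14A", "CD248",
                                 "Thrombomodulin")) row$family else "other"
    regs <- tryCatch(
      segment_protein(domains[domains$protein_id == pid, , drop = FALSE],
                      protein_length = nchar(proteins[[pid]]),
                      family = fam,
                      protein_sequence = proteins[[pid]]),
      error = function(e) {
        stop(sprintf("[segmentation] %s: %s", pid, conditionMessage(e)),
             call. = FALSE)
      })
    region_rows[[pid]] <- as.data.frame(regs)
    records[[pid]] <- list(species = row$species, family = row$family,
                           protein = proteins[[pid]], cds = cds[[pid]],
                           regions = regs)
  }
  regions_tab <- do.call(rbind, region_rows)
  rownames(regions_tab) <- NULL
  egf_tab <- regions_tab[grepl("^EGF_", regions_tab$region), , drop = FALSE]

  .log_info("stage: Ka/Ks (%s)", method)
  kaks <- aggregate_domain_kaks(unname(records), method = method)

  .log_info("stage: sushi check")
  sushi_reports <- list()
  for (fam in unique(vapply(records, function(r) r$family, character(1)))) {
    recs <- Filter(function(r) r$family == fam, records)
    seqs <- c()
    for (r in recs) {
      tab <- as.data.frame(r$regions)
      iv <- tab[tab$region %in% c("sushi-like", "hydrophobic stretch"),
                , drop = FALSE]
      if (nrow(iv) == 1L) {
        seqs[r$species] <- substr(r$protein, iv$start, iv$end)
      }
    }
    if (length(seqs) >= 2L) {
      # use the configured reference, else the first species (sorted)
      # whose region still carries all four hallmark residues
      cands <- config$sushi_reference %||% sort(names(seqs))
      for (ref in intersect(cands, names(seqs))) {
        rep_try <- tryCatch(check_sushi_residues(seqs, ref),
                            error = function(e) NULL)
        if (!is.null(rep_try)) { sushi_reports[[fam]] <- rep_try; break }
      }
      if (is.null(sushi_reports[[fam]])) {
        .log_warn("no usable sushi reference for family %s", fam)
      }
    }
  }

  out <- list(regions = regions_tab, egf_subtypes = egf_tab,
              kaks = kaks, sushi = sushi_reports, skipped = skipped,
              config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(
      x, file.path(config$out_dir, f), sep = "\t",
      quote = FALSE, row.names = FALSE)
    wt(regions_tab, "regions.tsv")
    wt(egf_tab, "egf_subtypes.tsv")
    wt(kaks$table, "kaks_pairs.tsv")
    wt(kaks$summary, "kaks_summary.tsv")
    wt(skipped, "skipped.tsv")
    .log_info("wrote outputs to %s", config$out_dir)
  }
  invisible(out)
}
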