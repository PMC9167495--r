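# Seed-deterministic simulators: domain-structured proteins/CDS with
# known truth, codon evolution with per-region omega, and gene-order
# histories with known loss mechanisms.

# neutral filler alphabet for linkers/pads: no C (so no spurious
# disulfide signatures), no D/E/Q/N (no spurious calcium-binding
# consensus), no G/P aromatics (no spurious class hits)
.FILLER <- c("A", "S", "T", "L", "V", "I", "K", "R", "H", "M")
.TM_RESIDUES <- c("L", "V", "I", "F", "M", "A")

# signature-bearing EGF cores, built element-by-element so that
# classify_egf() recovers the planned subtype exactly
.EGF_CORES <- list(
  EGF1  = "CACAAAAAGAAC",            # PS00022 only
  EGF2  = "CACAAGFAAAAC",            # PS01186 only
  cbEGF = paste0("CACAAGFAAAAC",     # PS01186 ...
                 "DADDCAAACAAACAADAAAAFACACAAAAAAAACA"),  # ... + PS01187
  EGF_like = "",                     # no signature
  Tme5EGF  = ""                      # subtype comes from the cl07616 anchor
)

.rand_filler <- function(n) {
  paste(sample(.FILLER, n, replace = TRUE), collapse = "")
}

#' Architecture template for a CTLDcp family
#'
#' Encodes the segment plan used by [simulate_architecture()]:
#' N-terminal leader, CTLD, sushi-like region (hydrophobic stretch in
#' Thrombomodulin), the family's EGF repeats, mucin-like region,
#' transmembrane segment and cytoplasmic tail.  Default EGF counts
#' follow the canonical family architectures (CD93 5, Clec14A 1,
#' CD248 3, Thrombomodulin 6, the fifth Thrombomodulin EGF being the
#' `cl07616` Tme5 type).  Per-segment omega defaults encode strong
#' purifying selection on the folded extracellular modules
#' (omega 0.1) and positive selection on the mucin-like region
#' (omega 2.0); kappa defaults to 2 and the pairwise divergence `t`
#' to 0.3 expected substitutions per codon site.
#'
#' @param family one of `"CD93"`, `"Clec14A"`, `"CD248"`,
#'   `"Thrombomodulin"`.
#' @param egf_plan optional character vector of planned subtypes
#'   (`EGF1`, `EGF2`, `cbEGF`, `EGF_like`, `Tme5EGF`) overriding the
#'   family default.
#' @param omega named numeric of per-region omegas (names among
#'   `ctld`, `sushi`, `egf`, `mucin`, `tm`, `cytotail`).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param t pairwise divergence in expected substitutions per codon
#'   site.
#' @return a list of class `architecture_template`.
#' @export
architecture_template <- function(family = c("CD93", "Clec14A", "CD248",
                                             "Thrombomodulin"),
                                  egf_plan = NULL,
                                  omega = NULL, kappa = 2, t = 0.3) {
  family <- match.arg(family)
  default_plan <- switch(family,
    CD93 = c("cbEGF", "EGF2", "EGF2", "cbEGF", "EGF2"),
    Clec14A = "EGF2",
    CD248 = c("cbEGF", "EGF2", "EGF2"),
    Thrombomodulin = c("EGF_like", "EGF2", "cbEGF", "EGF2",
                       "Tme5EGF", "EGF2")
  )
  if (is.null(egf_plan)) egf_plan <- default_plan
  stopifnot(all(egf_plan %in% names(.EGF_CORES)), kappa > 0, t >= 0)
  omega_default <- c(ctld = 0.1, sushi = 0.1, egf = 0.1,
                     mucin = 2.0, tm = 0.1, cytotail = 0.5)
  if (!is.null(omega)) omega_default[names(omega)] <- omega
  structure(
    list(family = family, egf_plan = egf_plan,
         lengths = list(leader = c(18L, 24L), ctld = c(120L, 140L),
                        sushi = c(50L, 60L), mucin = c(80L, 100L),
                        tm = c(21L, 25L), cytotail = c(40L, 50L)),
         omega = omega_default, kappa = kappa, t = t),
    class = "architecture_template"
  )
}

.draw_len <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

# one EGF segment: signature core centred between neutral pads
.egf_segment <- function(subtype) {
  core <- .EGF_CORES[[subtype]]
  total <- if (nchar(core) > 12L) 60L else 40L
  if (nchar(core) == 0L) return(.rand_filler(total))
  pad <- total - nchar(core)
  left <- pad %/% 2L
  paste0(.rand_filler(left), core, .rand_filler(pad - left))
}

# a sushi-like segment carrying the hallmark C/W/G/P residues early,
# with a neutral tail so signatures never bleed into the first EGF
.sushi_segment <- function(len) {
  chars <- strsplit(.rand_filler(len), "")[[1]]
  chars[3] <- "C"; chars[10] <- "W"; chars[20] <- "G"
  chars[30] <- "P"; chars[38] <- "C"
  paste(chars, collapse = "")
}

.mucin_segment <- function(len) {
  pool <- sample(c("S", "T", "P"), len, replace = TRUE)
  other <- runif(len) > 0.7  # ~70% O-glycosylatable S/T/P
  pool[other] <- sample(c("A", "G", "V"), sum(other), replace = TRUE)
  paste(pool, collapse = "")
}

# reverse-translate with uniformly drawn synonymous codons
.reverse_translate <- function(protein) {
  tab <- .codon_tables()
  by_aa <- split(tab$sense, tab$aa[tab$sense])
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste(codons, collapse = "")
}

#' Simulate a domain-structured protein and CDS with known truth
#'
#' Builds a protein following the template's segment plan, embedding
#' the signature of each planned EGF subtype so that
#' [segment_protein()] + [classify_egf()] recover the plan exactly;
#' the mucin-like segment is enriched (about 70% of residues) in the
#' O-glycosylatable residues S/T/P.  The CDS is a uniform synonymous
#' reverse translation of the protein.  EGF anchors are emitted
#' contiguously, Tme5-type EGFs under the anchor name `cl07616`.
#'
#' @param template an `architecture_template`.
#' @param seed optional integer seed (same seed, identical records).
#' @param protein_id identifier used in the output records.
#' @return list with `protein_id`, `protein`, `cds`, `annotations`
#'   (a domain anchor data.frame) and `truth` (region intervals as a
#'   data.frame, the EGF subtype plan, per-region omega, seed).
#' @export
simulate_architecture <- function(template, seed = NULL,
                                  protein_id = template$family) {
  stopifnot(inherits(template, "architecture_template"))
  if (!is.null(seed)) set.seed(seed)
  L <- template$lengths
  leader <- .rand_filler(.draw_len(L$leader))
  ctld_len <- .draw_len(L$ctld)
  ctld <- paste(sample(.AA20, ctld_len, replace = TRUE), collapse = "")
  sushi <- .sushi_segment(.draw_len(L$sushi))
  egf_seqs <- vapply(template$egf_plan, .egf_segment, character(1))
  mucin <- .mucin_segment(.draw_len(L$mucin))
  tm <- paste(sample(.TM_RESIDUES, .draw_len(L$tm), replace = TRUE),
              collapse = "")
  tail_len <- .draw_len(L$cytotail)
  cyto <- strsplit(.rand_filler(tail_len), "")[[1]]
  cyto[seq(5, tail_len, by = 12)] <- "Y"  # phosphorylatable tyrosines
  cyto <- paste(cyto, collapse = "")

  segs <- c(leader = leader, ctld = ctld, sushi = sushi,
            setNames(egf_seqs, sprintf("EGF_%d", seq_along(egf_seqs))),
            mucin = mucin, tm = tm, cytotail = cyto)
  ends <- cumsum(nchar(segs))
  starts <- ends - nchar(segs) + 1L
  protein <- paste(segs, collapse = "")

  egf_idx <- grep("^EGF_", names(segs))
  ann <- data.frame(
    protein_id = protein_id,
    name = c("CLECT",
             ifelse(template$egf_plan == "Tme5EGF", "cl07616", "EGF"),
             "TM"),
    start = c(starts[["ctld"]], starts[egf_idx], starts[["tm"]]),
    end = c(ends[["ctld"]], ends[egf_idx], ends[["tm"]]),
    source = "simulated",
    stringsAsFactors = FALSE
  )

  region <- c("leader", "CTLD",
              if (template$family == "Thrombomodulin") "hydrophobic stretch"
              else "sushi-like",
              names(segs)[egf_idx], "mucin", "TM", "cytotail")
  truth_regions <- data.frame(
    region = region,
    start = unname(starts), end = unname(ends),
    omega = unname(template$omega[
      c("ctld", "ctld", "sushi", rep("egf", length(egf_idx)),
        "mucin", "tm", "cytotail")]),
    stringsAsFactors = FALSE
  )
  list(
    protein_id = protein_id,
    protein = protein,
    cds = .reverse_translate(protein),
    annotations = ann,
    truth = list(regions = truth_regions,
                 egf_plan = template$egf_plan,
                 omega = template$omega,
                 seed = seed)
  )
}

# per-codon substitution rates for one omega class, cached per
# (kappa, omega): for each sense codon a list(to = target codons,
# rate = kappa^ts * omega^nonsyn, total)
.codon_rates <- function(kappa, omega) {
  key <- sprintf("k%.10g_w%.10g", kappa, omega)
  env <- .ctldcpevo_cache
  if (is.null(env$rates)) env$rates <- new.env(parent = emptyenv())
  hit <- env$rates[[key]]
  if (!is.null(hit)) return(hit)
  tab <- .codon_tables()
  out <- lapply(tab$sense, function(cd) {
    nb <- tab$neighbors[[cd]]
    nb <- nb[!nb$to_stop, , drop = FALSE]  # changes creating stops rejected
    rate <- ifelse(nb$is_ts, kappa, 1) * ifelse(nb$syn, 1, omega)
    keep <- rate > 0
    list(to = nb$codon2[keep], rate = rate[keep],
         total = sum(rate[keep]))
  })
  names(out) <- tab$sense
  env$rates[[key]] <- out
  out
}

#' Simulate codon evolution of a pair from a common ancestor
#'
#' Continuous-time Markov jump process (Gillespie-style, exact):
#' single-nucleotide codon changes at rate proportional to
#' `kappa^[transition] * omega^[nonsynonymous]`, changes creating stop
#' codons rejected.  Both lineages evolve independently for `t/2`
#' from the ancestral CDS (a star tree of two).  Time is scaled so
#' that `t` is the expected number of substitutions per codon site
#' along the whole pair path, computed from the ancestor's codon
#' composition.
#'
#' @param cds in-frame ancestral CDS without internal stops (terminal
#'   stop stripped automatically).
#' @param omega nonsynonymous/synonymous rate ratio: a single value,
#'   or the default for codons not covered by `regions`.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param t total pair divergence (>= 0), expected substitutions per
#'   codon site.
#' @param regions optional data.frame with columns `start`, `end`
#'   (codon indices, 1-based closed) and `omega` for per-region rates.
#' @param seed optional integer seed.
#' @return list with `cds_a`, `cds_b` (the evolved pair) and
#'   `n_substitutions` per lineage.
#' @export
simulate_codon_evolution <- function(cds, omega = 1, kappa = 2, t = 0.3,
                                     regions = NULL, seed = NULL) {
  stopifnot(omega >= 0, kappa > 0, t >= 0)
  if (!is.null(seed)) set.seed(seed)
  cds <- .strip_terminal_stop(cds)
  codons <- .split_codons(cds)
  tab <- .codon_tables()
  if (!all(codons %in% tab$sense)) {
    stop("ancestral CDS contains stop or ambiguous codons")
  }
  n <- length(codons)
  omega_per_codon <- rep(omega, n)
  if (!is.null(regions)) {
    stopifnot(all(c("start", "end", "omega") %in% names(regions)))
    for (i in seq_len(nrow(regions))) {
      stopifnot(regions$omega[i] >= 0)
      omega_per_codon[regions$start[i]:regions$end[i]] <- regions$omega[i]
    }
  }
  rate_cache <- lapply(unique(omega_per_codon), .codon_rates,
                       kappa = kappa)
  names(rate_cache) <- as.character(unique(omega_per_codon))

  # scale: mean exit rate over the ancestor = 1 expected change per
  # codon per unit time
  exit0 <- vapply(seq_len(n), function(i) {
    rate_cache[[as.character(omega_per_codon[i])]][[codons[i]]]$total
  }, numeric(1))
  scale <- mean(exit0)
  if (scale <= 0) t <- 0

  evolve <- function(start_codons, duration) {
    cur <- start_codons
    nsub <- 0L
    if (duration <= 0) return(list(codons = cur, n = nsub))
    for (i in seq_len(n)) {
      rates_i <- rate_cache[[as.character(omega_per_codon[i])]]
      left <- duration
      repeat {
        r <- rates_i[[cur[i]]]
        if (r$total <= 0) break
        wait <- rexp(1, rate = r$total * (1 / scale))
        if (wait > left) break
        left <- left - wait
        cur[i] <- sample(r$to, 1L, prob = r$rate)
        nsub <- nsub + 1L
      }
    }
    list(codons = cur, n = nsub)
  }
  a <- evolve(codons, t / 2)
  b <- evolve(codons, t / 2)
  list(cds_a = paste(a$codons, collapse = ""),
       cds_b = paste(b$codons, collapse = ""),
       n_substitutions = c(a = a$n, b = b$n))
}

#' Simulate a cohort of species for one family
#'
#' Simulates one ancestral architecture, then evolves the CDS
#' independently for each species (each a `t/2` branch from the
#' ancestor, so every unordered pair is separated by about `t`) with
#' the template's per-region omegas.  Records are shaped for
#' [aggregate_domain_kaks()].
#'
#' @param template an `architecture_template`.
#' @param n_species number of species (>= 2).
#' @param seed optional integer seed.
#' @return list of per-species records, each with `species`, `family`,
#'   `protein`, `cds`, `regions` (a `RegionSet`), plus the shared
#'   `truth` in the `"truth"` attribute.
#' @export
simulate_cohort <- function(template, n_species = 3L, seed = NULL) {
  stopifnot(n_species >= 2L)
  if (!is.null(seed)) set.seed(seed)
  anc <- simulate_architecture(template)
  codon_regions <- data.frame(
    start = anc$truth$regions$start,
    end = anc$truth$regions$end,
    omega = anc$truth$regions$omega
  )
  records <- lapply(seq_len(n_species), function(k) {
    # one t/2 branch per species from the common ancestor
    ev <- simulate_codon_evolution(anc$cds, omega = 1,
                                   kappa = template$kappa,
                                   t = template$t, regions = codon_regions)
    cds_k <- ev$cds_a
    prot_k <- translate_cds(cds_k)
    regs <- segment_protein(anc$annotations, nchar(prot_k),
                            family = template$family,
                            protein_sequence = prot_k)
    list(species = sprintf("sp%02d", k), family = template$family,
         protein = prot_k, cds = cds_k, regions = regs)
  })
  attr(records, "truth") <- anc$truth
  records
}

#' Simulate a synteny history with a known gene-loss mechanism
#'
#' Builds a reference chromosome carrying a target gene surrounded by
#' `n_families` neighbour families, then derives a second genome in
#' which the target is absent: under `locus_preserved_loss` the
#' neighbourhood is left intact (gene deletion/pseudogenization);
#' under `chromosome_disruption` at least `intensity` of the
#' neighbours are deleted or relocated to other chromosomes.
#'
#' @param n_families number of neighbour families (>= 15 by default
#'   convention).
#' @param mechanism `"chromosome_disruption"` or
#'   `"locus_preserved_loss"`.
#' @param intensity fraction of neighbours affected under disruption,
#'   in (0, 1].
#' @param target_family family label of the target gene.
#' @param seed optional integer seed.
#' @return list with `reference` and `derived` gene tables
#'   (`chromosome`, `start`, `end`, `gene_id`, `family`, `species`)
#'   and `truth` (mechanism, event log, seed).
#' @export
simulate_synteny_history <- function(n_families = 20L,
                                     mechanism = c("chromosome_disruption",
                                                   "locus_preserved_loss"),
                                     intensity = 0.8,
                                     target_family = "CTLDcp",
                                     seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (intensity <= 0 || intensity > 1) {
    stop("intensity must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_families >= 2L)
  families <- sprintf("fam%02d", seq_len(n_families))
  # neighbours spread within ~18 Mbp each side of the target
  offsets <- sort(sample(c(-1, 1) * 1e5, n_families, replace = TRUE) *
                    sample(10:180, n_families, replace = TRUE))
  target_start <- 5e7
  starts <- target_start + offsets
  reference <- data.frame(
    chromosome = "chr1",
    start = c(starts, target_start),
    end = c(starts, target_start) + 2000L,
    gene_id = c(paste0(families, "_ref"), paste0(target_family, "_ref")),
    family = c(families, target_family),
    species = "reference",
    stringsAsFactors = FALSE
  )
  reference <- reference[order(reference$start), , drop = FALSE]
  rownames(reference) <- NULL

  derived <- reference[reference$family != target_family, , drop = FALSE]
  derived$species <- "derived"
  derived$gene_id <- sub("_ref$", "_der", derived$gene_id)
  events <- data.frame(family = target_family, event = "target_lost",
                       to_chromosome = NA_character_,
                       to_start = NA_real_, stringsAsFactors = FALSE)
  if (mechanism == "chromosome_disruption") {
    n_aff <- ceiling(intensity * n_families)
    affected <- sample(families, n_aff)
    for (fam in affected) {
      i <- which(derived$family == fam)
      if (runif(1) < 0.5) {
        derived <- derived[-i, , drop = FALSE]
        events <- rbind(events, data.frame(
          family = fam, event = "deleted", to_chromosome = NA_character_,
          to_start = NA_real_))
      } else {
        new_chr <- sample(paste0("chr", 2:5), 1L)
        new_start <- round(runif(1, 1e6, 9.5e7))
        derived$chromosome[i] <- new_chr
        derived$start[i] <- new_start
        derived$end[i] <- new_start + 2000L
        events <- rbind(events, data.frame(
          family = fam, event = "relocated", to_chromosome = new_chr,
          to_start = new_start))
      }
    }
  }
  rownames(derived) <- NULL
  list(reference = reference, derived = derived,
       truth = list(mechanism = mechanism, intensity = intensity,
                    target_family = target_family, events = events,
                    seed = seed))
}
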