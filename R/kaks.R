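# Codon alignments and pairwise Ka/Ks estimation (NG86 / YN00-style
# counting).  Standard genetic code only; coordinates 1-based closed.

.NT <- c("T", "C", "A", "G")
.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
  (a %in% c("C", "T") & b %in% c("C", "T"))
}

# genetic-code tables, cached on first use
.codon_tables <- function() {
  tab <- .ctldcpevo_cache$codon_tables
  if (!is.null(tab)) return(tab)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  sense <- codons[aa != "*"]
  split_nt <- do.call(rbind, strsplit(codons, ""))
  rownames(split_nt) <- codons
  # all single-nucleotide neighbours of every codon
  neighbors <- list()
  for (cd in codons) {
    nts <- split_nt[cd, ]
    rows <- list()
    for (pos in 1:3) {
      for (alt in setdiff(.NT, nts[pos])) {
        to <- nts
        to[pos] <- alt
        to_codon <- paste(to, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, from_nt = nts[pos], to_nt = alt, codon2 = to_codon,
          syn = gc_map[[cd]] == gc_map[[to_codon]],
          to_stop = gc_map[[to_codon]] == "*",
          is_ts = .is_transition(nts[pos], alt),
          stringsAsFactors = FALSE)
      }
    }
    neighbors[[cd]] <- do.call(rbind, rows)
  }
  # NG86 site count per codon: each position contributes 1 site split
  # by the synonymous fraction among its non-stop changes
  s_sites <- setNames(numeric(length(codons)), codons)
  for (cd in sense) {
    nb <- neighbors[[cd]]
    s <- 0
    for (pos in 1:3) {
      sub <- nb[nb$pos == pos & !nb$to_stop, , drop = FALSE]
      if (nrow(sub) > 0L) s <- s + sum(sub$syn) / nrow(sub)
    }
    s_sites[cd] <- s
  }
  # degeneracy fold class per codon x position: number of synonymous
  # alternatives (0 = nondegenerate, 3 = fourfold)
  fold <- matrix(NA_integer_, nrow = length(codons), ncol = 3,
                 dimnames = list(codons, NULL))
  for (cd in sense) {
    nb <- neighbors[[cd]]
    for (pos in 1:3) {
      fold[cd, pos] <- sum(nb$syn[nb$pos == pos])
    }
  }
  tab <- list(codons = codons, aa = setNames(aa, codons), sense = sense,
              split_nt = split_nt, neighbors = neighbors,
              s_sites = s_sites, fold = fold, gc_map = gc_map)
  .ctldcpevo_cache$codon_tables <- tab
  tab
}

.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# enumerate all shortest substitution pathways between two codons;
# each path is a data.frame of steps (one row per single-nt change)
.codon_paths <- function(c1, c2) {
  tab <- .codon_tables()
  n1 <- tab$split_nt[c1, ]
  n2 <- tab$split_nt[c2, ]
  diff_pos <- which(n1 != n2)
  d <- length(diff_pos)
  if (d == 0L) return(list())
  lapply(.PERMS[[d]], function(ord) {
    cur <- n1
    steps <- vector("list", d)
    for (k in seq_len(d)) {
      pos <- diff_pos[ord[k]]
      nxt <- cur
      nxt[pos] <- n2[pos]
      from_codon <- paste(cur, collapse = "")
      to_codon <- paste(nxt, collapse = "")
      steps[[k]] <- data.frame(
        pos = pos, from_nt = cur[pos], to_nt = n2[pos],
        from_codon = from_codon, to_codon = to_codon,
        syn = tab$gc_map[[from_codon]] == tab$gc_map[[to_codon]],
        through_stop = tab$gc_map[[to_codon]] == "*",
        is_ts = .is_transition(cur[pos], n2[pos]),
        stringsAsFactors = FALSE)
      cur <- nxt
    }
    do.call(rbind, steps)
  })
}

# compact, memoized pathway structure for one unordered codon pair
# ("CODON1 CODON2" key): stop-blocked pathways pre-filtered (all kept
# if every pathway is blocked), per-path index matrix into the F3x4
# frequency matrix plus transition/synonymous flags
.pair_paths_compact <- function(key) {
  env <- .ctldcpevo_cache
  if (is.null(env$pair_paths)) env$pair_paths <- new.env(parent = emptyenv())
  hit <- env$pair_paths[[key]]
  if (!is.null(hit)) return(hit)
  cs <- strsplit(key, " ")[[1]]
  paths <- .codon_paths(cs[1], cs[2])
  ok <- vapply(paths, function(p) !any(p$through_stop[-nrow(p)]),
               logical(1))
  use <- if (any(ok)) paths[ok] else paths
  compact <- lapply(use, function(p) {
    list(idx = cbind(p$pos, p$to_nt), is_ts = p$is_ts, syn = p$syn)
  })
  out <- list(paths = compact,
              syn_counts = vapply(use, function(p) sum(p$syn), numeric(1)),
              tot = nrow(use[[1]]))
  env$pair_paths[[key]] <- out
  out
}

# NG86 pathway-averaged difference counts for all sense codon pairs,
# cached as two 61x61 matrices.  Pathways passing through a stop codon
# are excluded; in the rare case that every pathway is blocked, all
# pathways are used (the pair still carries d differences).
.ng86_diff_tables <- function() {
  cached <- .ctldcpevo_cache$ng86_diff
  if (!is.null(cached)) return(cached)
  tab <- .codon_tables()
  sense <- tab$sense
  n <- length(sense)
  Sd <- matrix(0, n, n, dimnames = list(sense, sense))
  Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      paths <- .codon_paths(sense[i], sense[j])
      ok <- vapply(paths, function(p) !any(p$through_stop[-nrow(p)]),
                   logical(1))
      use <- if (any(ok)) paths[ok] else paths
      syn <- vapply(use, function(p) sum(p$syn), numeric(1))
      tot <- nrow(use[[1]])
      Sd[i, j] <- Sd[j, i] <- mean(syn)
      Nd[i, j] <- Nd[j, i] <- tot - mean(syn)
    }
  }
  out <- list(Sd = Sd, Nd = Nd)
  .ctldcpevo_cache$ng86_diff <- out
  out
}

.translate_codon <- function(codon) {
  tab <- .codon_tables()
  if (!all(strsplit(codon, "")[[1]] %in% .NT)) return("X")
  unname(tab$gc_map[[codon]])
}

#' Translate an in-frame CDS (standard code)
#'
#' @param cds nucleotide string with length divisible by 3; codons
#'   containing ambiguous nucleotides translate to `X`.
#' @return amino-acid string (stop codons as `*`).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(vapply(codons, .translate_codon, character(1)), collapse = "")
}

.split_codons <- function(cds) {
  if (nchar(cds) == 0L) return(character(0))
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

.strip_terminal_stop <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  if (nchar(cds) >= 3) {
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (all(strsplit(last, "")[[1]] %in% .NT) &&
        .translate_codon(last) == "*") {
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
  }
  cds
}

#' Build a codon alignment from two equal-length in-frame CDS
#'
#' Terminal stop codons are stripped; codon columns containing an
#' ambiguous nucleotide or an internal stop codon in either sequence
#' are dropped and counted.  Gap characters are not allowed here (use
#' [backthread_codons()] to thread CDS through a gapped protein
#' alignment).
#'
#' @param cds_a,cds_b nucleotide strings.
#' @param ids optional length-2 character of sequence identifiers.
#' @return object of class `codon_alignment` with retained codon
#'   vectors, the retained column indices and drop counts.
#' @export
codon_alignment <- function(cds_a, cds_b, ids = c("a", "b")) {
  cds_a <- .strip_terminal_stop(cds_a)
  cds_b <- .strip_terminal_stop(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("CDS lengths differ after terminal-stop stripping; ",
         "align the proteins and use backthread_codons()")
  }
  ca <- .split_codons(cds_a)
  cb <- .split_codons(cds_b)
  .finish_codon_alignment(ca, cb, ids, n_gap_dropped = 0L)
}

.finish_codon_alignment <- function(ca, cb, ids, n_gap_dropped) {
  tab <- .codon_tables()
  ambiguous <- !(ca %in% tab$codons) | !(cb %in% tab$codons)
  is_stop <- (!ambiguous) &
    (tab$aa[ca] == "*" | tab$aa[cb] == "*")
  keep <- !ambiguous & !is_stop
  if (any(is_stop)) {
    .log_warn("dropped %d codon column(s) containing internal stop codons",
              sum(is_stop))
  }
  structure(
    list(ids = ids,
         codons_a = ca[keep], codons_b = cb[keep],
         retained_columns = which(keep),
         n_columns = length(ca),
         n_dropped = c(gap = n_gap_dropped,
                       ambiguous = sum(ambiguous),
                       stop = sum(is_stop))),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf(
    "codon_alignment (%s vs %s): %d columns retained of %d (+%d gap)\n",
    x$ids[1], x$ids[2], length(x$codons_a), x$n_columns,
    x$n_dropped[["gap"]]))
  invisible(x)
}

#' Map a protein interval to CDS coordinates
#'
#' For a CDS in frame 0 starting at the initiator codon, residue
#' interval `(start, end)` corresponds to nucleotides
#' `(3*(start-1)+1, 3*end)`.
#'
#' @param start,end 1-based closed residue coordinates.
#' @param cds_length optional CDS length for range checking.
#' @return integer vector `c(nt_start, nt_end)`.
#' @examples
#' map_protein_interval_to_cds(10, 20)  # c(28, 60)
#' @export
map_protein_interval_to_cds <- function(start, end, cds_length = NULL) {
  stopifnot(start >= 1, end >= start)
  nt <- c(nt_start = 3L * (as.integer(start) - 1L) + 1L,
          nt_end = 3L * as.integer(end))
  if (!is.null(cds_length) && nt[2] > cds_length) {
    stop(sprintf("residue interval (%d,%d) maps beyond the CDS (%d nt)",
                 start, end, cds_length))
  }
  nt
}

#' Thread CDS through a gapped protein alignment
#'
#' Each aligned residue column becomes a codon column; columns with a
#' gap in either sequence are dropped (and counted), then ambiguous
#' and stop-containing columns are dropped as in [codon_alignment()].
#' The ungapped protein sequences must translate exactly to their CDS
#' (standard code, terminal stop stripped); `X` residues pair with
#' ambiguous codons.
#'
#' @param aligned_a,aligned_b aligned amino-acid strings (`-` = gap).
#' @param cds_a,cds_b in-frame CDS of the two ungapped proteins.
#' @param ids optional identifiers.
#' @return a `codon_alignment`.
#' @export
backthread_codons <- function(aligned_a, aligned_b, cds_a, cds_b,
                              ids = c("a", "b")) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences have different lengths")
  }
  cds_a <- .strip_terminal_stop(cds_a)
  cds_b <- .strip_terminal_stop(cds_b)
  check_one <- function(aligned, cds, id) {
    prot <- gsub("-", "", aligned, fixed = TRUE)
    if (nchar(cds) != 3L * nchar(prot)) {
      stop(sprintf("%s: CDS length %d is not 3 x %d residues",
                   id, nchar(cds), nchar(prot)))
    }
    trans <- translate_cds(cds)
    pc <- strsplit(prot, "")[[1]]
    tc <- strsplit(trans, "")[[1]]
    mismatch <- which(pc != tc)
    if (length(mismatch) > 0L) {
      i <- mismatch[1]
      stop(sprintf(
        "%s: protein residue %d ('%s') does not match CDS translation ('%s')",
        id, i, pc[i], tc[i]))
    }
  }
  check_one(aligned_a, cds_a, ids[1])
  check_one(aligned_b, cds_b, ids[2])
  ca_all <- .split_codons(cds_a)
  cb_all <- .split_codons(cds_b)
  cols_a <- strsplit(aligned_a, "")[[1]]
  cols_b <- strsplit(aligned_b, "")[[1]]
  ia <- cumsum(cols_a != "-")
  ib <- cumsum(cols_b != "-")
  keep <- cols_a != "-" & cols_b != "-"
  ca <- ca_all[ia[keep]]
  cb <- cb_all[ib[keep]]
  .finish_codon_alignment(ca, cb, ids, n_gap_dropped = sum(!keep))
}

# ---- estimators -----------------------------------------------------

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p == 0) return(0)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# method-of-moments inversion of the expected total difference
# proportion under a two-parameter (kappa) substitution model; reduces
# exactly to the Jukes-Cantor correction at kappa = 1
.k80_fixed_kappa_correct <- function(p, kappa) {
  if (is.na(p)) return(NA_real_)
  if (p == 0) return(0)
  if (p >= 0.75) return(NA_real_)
  if (abs(kappa - 1) < 1e-12) return(.jc_correct(p))
  f <- function(d) {
    0.75 - 0.25 * exp(-4 * d / (kappa + 2)) -
      0.5 * exp(-2 * (kappa + 1) * d / (kappa + 2)) - p
  }
  upper <- 1
  while (f(upper) < 0 && upper < 1e4) upper <- upper * 2
  uniroot(f, lower = 0, upper = upper, tol = 1e-12)$root
}

.kaks_result <- function(S, N, Sd, Nd, dS, dN, kappa, method,
                         columns, converged = TRUE,
                         kappa_estimated = FALSE) {
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  ratio <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_
  structure(
    list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         dS = dS, dN = dN, ratio = ratio, kappa = kappa,
         method = method, columns_retained = columns,
         converged = converged, kappa_estimated = kappa_estimated),
    class = "kaks_result"
  )
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "%s: S=%.3f N=%.3f Sd=%.3f Nd=%.3f dS=%s dN=%s Ka/Ks=%s kappa=%.3f (%d codons%s)\n",
    x$method, x$S, x$N, x$Sd, x$Nd,
    ifelse(is.na(x$dS), "NA", sprintf("%.4f", x$dS)),
    ifelse(is.na(x$dN), "NA", sprintf("%.4f", x$dN)),
    ifelse(is.na(x$ratio), "undefined", sprintf("%.4f", x$ratio)),
    x$kappa, x$columns_retained,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

.ng86_core <- function(aln, method_label = "NG86") {
  tab <- .codon_tables()
  diff_tab <- .ng86_diff_tables()
  ca <- aln$codons_a
  cb <- aln$codons_b
  L <- length(ca)
  if (L == 0L) stop("codon alignment has no retained columns")
  S <- (sum(tab$s_sites[ca]) + sum(tab$s_sites[cb])) / 2
  N <- 3 * L - S
  idx <- cbind(ca, cb)
  Sd <- sum(diff_tab$Sd[idx])
  Nd <- sum(diff_tab$Nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  .kaks_result(S, N, Sd, Nd,
               dS = .jc_correct(pS), dN = .jc_correct(pN),
               kappa = 1, method = method_label, columns = L)
}

#' Nei-Gojobori (1986) Ka/Ks estimation
#'
#' Classical counting method: sites counted by per-position degeneracy
#' with mutations to stop codons excluded from the denominator; for
#' codon pairs differing at more than one position all shortest
#' substitution pathways are averaged (pathways through stop codons
#' excluded); proportions corrected with the Jukes-Cantor formula.
#' Site counts are averaged over the two sequences, so
#' `S + N = 3 * columns` exactly.  The ratio is undefined (`NA`) when
#' `dS` is zero or a proportion reaches the correction's 3/4
#' saturation limit.
#'
#' @param aln a `codon_alignment`.
#' @return a `kaks_result` with fields `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`, `ratio`, `kappa` (fixed at 1), `method`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3(5):418-426.
#' @export
ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  .ng86_core(aln)
}

# kappa from fourfold-degenerate and nondegenerate site pairs with the
# standard two-parameter (K80) correction; estimates from the two
# classes are combined weighted by their site counts
.estimate_kappa <- function(ca, cb) {
  tab <- .codon_tables()
  nta <- ntb <- character(0)
  fa <- fb <- integer(0)
  for (pos in 1:3) {
    nta <- c(nta, substr(ca, pos, pos))
    ntb <- c(ntb, substr(cb, pos, pos))
    fa <- c(fa, tab$fold[ca, pos])
    fb <- c(fb, tab$fold[cb, pos])
  }
  sel4 <- fa == 3L & fb == 3L
  sel0 <- fa == 0L & fb == 0L
  est_one <- function(sel) {
    n <- sum(sel)
    if (n == 0L) return(NULL)
    a1 <- nta[sel]; b1 <- ntb[sel]
    differ <- a1 != b1
    P <- mean(differ & .is_transition(a1, b1))
    Q <- mean(differ & !.is_transition(a1, b1))
    if (P + Q == 0) return(NULL)
    a <- 1 - 2 * P - Q
    b <- 1 - 2 * Q
    if (a <= 0 || b <= 0) return(NULL)
    alpha_t <- -0.5 * log(a) + 0.25 * log(b)
    beta_t <- -0.25 * log(b)
    if (beta_t <= 1e-9) return(list(kappa = 100, n = n))
    list(kappa = max(alpha_t / beta_t, 0.01), n = n)
  }
  e4 <- est_one(sel4)
  e0 <- est_one(sel0)
  ests <- Filter(Negate(is.null), list(e4, e0))
  if (length(ests) == 0L) return(list(kappa = 1, informative = FALSE))
  w <- vapply(ests, function(e) e$n, numeric(1))
  k <- vapply(ests, function(e) e$kappa, numeric(1))
  list(kappa = min(sum(w * k) / sum(w), 100), informative = TRUE)
}

# position-specific nucleotide frequencies (F3x4), pooled over both
# sequences' retained codons
.f3x4_freqs <- function(ca, cb) {
  f <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(as.character(1:3), .NT))
  for (pos in 1:3) {
    nts <- c(substr(ca, pos, pos), substr(cb, pos, pos))
    counts <- table(factor(nts, levels = .NT))
    f[pos, ] <- (as.numeric(counts) + 1e-9) / sum(counts + 1e-9)
  }
  f
}

#' Yang-Nielsen (2000) style approximate Ka/Ks estimation
#'
#' Approximate counting method accounting for transition/transversion
#' bias and codon usage: codon frequencies enter through the F3x4
#' model (position-specific nucleotide frequencies); kappa is
#' estimated from fourfold-degenerate and nondegenerate sites with the
#' standard two-parameter correction (or fixed via `kappa`); site and
#' difference counts are weighted by the mutation model, with
#' multiple-hit pathways additionally weighted by the current omega
#' estimate and re-weighted iteratively until the difference counts
#' change by less than `tol` (at most `max_iter` rounds;
#' non-convergence is flagged and the last iterate returned).
#' Distances are corrected by inverting the expected total-difference
#' curve of the two-parameter model at the estimated kappa.
#'
#' With `kappa = 1` and `codon_freqs = "uniform"` the weighting is
#' fully symmetric and the estimator reduces exactly to [ng86()].
#'
#' @param aln a `codon_alignment`.
#' @param kappa transition/transversion rate ratio; `NULL` (default)
#'   to estimate from the data.
#' @param codon_freqs `"f3x4"` (default) or `"uniform"`.
#' @param max_iter,tol iteration controls for the omega re-weighting.
#' @return a `kaks_result` (`kappa_estimated` records whether kappa
#'   was estimated; `converged` flags the iteration).
#' @references Yang Z, Nielsen R (2000) Mol Biol Evol 17(1):32-43.
#' @export
yn00 <- function(aln, kappa = NULL, codon_freqs = c("f3x4", "uniform"),
                 max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(aln, "codon_alignment"))
  codon_freqs <- match.arg(codon_freqs)
  ca <- aln$codons_a
  cb <- aln$codons_b
  L <- length(ca)
  if (L == 0L) stop("codon alignment has no retained columns")

  kappa_estimated <- is.null(kappa)
  if (kappa_estimated) kappa <- .estimate_kappa(ca, cb)$kappa

  if (!kappa_estimated && abs(kappa - 1) < 1e-12 &&
      codon_freqs == "uniform") {
    # fully symmetric mutation model: the weighted scheme collapses to
    # the NG86 special case (equal pathway weighting, JC correction)
    res <- .ng86_core(aln, method_label = "YN00")
    res$kappa_estimated <- FALSE
    return(res)
  }

  tab <- .codon_tables()
  freqs <- if (codon_freqs == "f3x4") .f3x4_freqs(ca, cb)
           else matrix(0.25, 3, 4,
                       dimnames = list(as.character(1:3), .NT))

  # weighted site counts: per position, the synonymous fraction of the
  # mutation-rate mass over non-stop changes
  site_count <- function(codon) {
    nb <- tab$neighbors[[codon]]
    s <- 0
    for (pos in 1:3) {
      sub <- nb[nb$pos == pos & !nb$to_stop, , drop = FALSE]
      if (nrow(sub) == 0L) next
      w <- freqs[pos, sub$to_nt] * ifelse(sub$is_ts, kappa, 1)
      s <- s + sum(w[sub$syn]) / sum(w)
    }
    s
  }
  uniq <- unique(c(ca, cb))
  s_per <- setNames(vapply(uniq, site_count, numeric(1)), uniq)
  S <- (sum(s_per[ca]) + sum(s_per[cb])) / 2
  N <- 3 * L - S

  # pathway-weighted difference counts for the codon pairs present
  pair_key <- paste(pmin(ca, cb), pmax(ca, cb))
  uniq_pairs <- unique(pair_key[ca != cb])
  pair_paths <- lapply(uniq_pairs, .pair_paths_compact)
  names(pair_paths) <- uniq_pairs
  pair_n <- table(factor(pair_key[ca != cb], levels = uniq_pairs))

  count_diffs <- function(omega) {
    Sd <- 0; Nd <- 0
    for (key in uniq_pairs) {
      pp <- pair_paths[[key]]
      w <- vapply(pp$paths, function(p) {
        prod(freqs[p$idx] * ifelse(p$is_ts, kappa, 1) *
               ifelse(p$syn, 1, omega))
      }, numeric(1))
      w <- w / sum(w)
      n_here <- as.numeric(pair_n[[key]])
      syn_mean <- sum(w * pp$syn_counts)
      Sd <- Sd + n_here * syn_mean
      Nd <- Nd + n_here * (pp$tot - syn_mean)
    }
    c(Sd = Sd, Nd = Nd)
  }

  omega <- 1
  prev <- c(Sd = Inf, Nd = Inf)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- count_diffs(omega)
    if (max(abs(cur - prev)) < tol) { converged <- TRUE; break }
    prev <- cur
    pS <- if (S > 0) cur[["Sd"]] / S else NA_real_
    pN <- if (N > 0) cur[["Nd"]] / N else NA_real_
    dS <- .k80_fixed_kappa_correct(pS, kappa)
    dN <- .k80_fixed_kappa_correct(pN, kappa)
    omega <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else 1
  }
  if (!converged) {
    .log_warn("yn00 pathway weighting did not converge in %d iterations",
              max_iter)
  }
  Sd <- cur[["Sd"]]; Nd <- cur[["Nd"]]
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  .kaks_result(S, N, Sd, Nd,
               dS = .k80_fixed_kappa_correct(pS, kappa),
               dN = .k80_fixed_kappa_correct(pN, kappa),
               kappa = kappa, method = "YN00", columns = L,
               converged = converged, kappa_estimated = kappa_estimated)
}
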