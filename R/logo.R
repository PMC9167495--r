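# Phospho-site filtering, residue windows, and consensus-logo matrices
# (probability and information-content renderings).

.PAD <- "-"

#' Filter phospho-site predictions
#'
#' Keeps sites on the target residue with a score strictly above the
#' threshold; duplicate (protein, position) rows collapse to the
#' maximal score.
#'
#' @param table data.frame with columns `protein_id`, `position`,
#'   `residue`, `score` (scores in \[0, 1\]).
#' @param threshold reliability cutoff; only `score > threshold` is
#'   kept (default 0.5).
#' @param residue_filter target residue (default `"Y"`,
#'   phospho-tyrosine).
#' @return filtered data.frame, one row per (protein, position).
#' @export
select_phospho_sites <- function(table, threshold = 0.5,
                                 residue_filter = "Y") {
  need <- c("protein_id", "position", "residue", "score")
  stopifnot(all(need %in% names(table)))
  if (any(table$score < 0 | table$score > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]")
  }
  keep <- table[table$residue == residue_filter &
                  !is.na(table$score) & table$score > threshold,
                , drop = FALSE]
  if (nrow(keep) == 0L) {
    rownames(keep) <- NULL
    return(keep)
  }
  keep <- keep[order(keep$protein_id, keep$position, -keep$score),
               , drop = FALSE]
  dup <- duplicated(keep[, c("protein_id", "position")])
  out <- keep[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract fixed-width residue windows around phospho-sites
#'
#' Window = residues `position - halfwidth` to `position + halfwidth`,
#' padded with `-` at protein ends so all windows have equal width
#' `2 * halfwidth + 1`; pad symbols are excluded from logo counts.
#'
#' @param sequences named character vector of protein strings.
#' @param sites data.frame as from [select_phospho_sites()]; each site
#'   is validated against its protein (position in range, residue
#'   matching).
#' @param halfwidth residues each side of the site (default 5).
#' @return character matrix (one row per site, one column per window
#'   position), with a `sites` attribute.
#' @export
extract_windows <- function(sequences, sites, halfwidth = 5L) {
  stopifnot(halfwidth >= 0L)
  w <- 2L * halfwidth + 1L
  if (nrow(sites) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = w))
  }
  rows <- matrix(.PAD, nrow = nrow(sites), ncol = w)
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    pos <- sites$position[i]
    seqstr <- sequences[[pid]]
    if (is.null(seqstr)) stop("no sequence for protein ", pid)
    L <- nchar(seqstr)
    if (pos < 1L || pos > L) {
      stop(sprintf("site %s:%d outside protein (length %d)", pid, pos, L))
    }
    obs <- substr(seqstr, pos, pos)
    if (obs != sites$residue[i]) {
      stop(sprintf("site %s:%d expected residue %s but sequence has %s",
                   pid, pos, sites$residue[i], obs))
    }
    for (k in seq_len(w)) {
      p <- pos - halfwidth - 1L + k
      if (p >= 1L && p <= L) rows[i, k] <- substr(seqstr, p, p)
    }
  }
  colnames(rows) <- as.character(seq_len(w) - halfwidth - 1L)
  attr(rows, "sites") <- sites
  rows
}

#' Consensus-logo matrix of aligned residue windows
#'
#' Per-position residue frequencies and information content:
#' `f(a, i) = count / total` over non-pad observations,
#' `H_i = -sum f log2 f`, `R_i = log2(20) - H_i - e_n` where the
#' small-sample correction `e_n = (s - 1) / (2 n ln 2)` (s = 20
#' residue states, n = observations at the position) is applied when
#' `small_sample_correction` is `TRUE`; `R_i` is clipped at 0.
#' The probability rendering letter heights are the frequencies; the
#' entropy rendering heights are `f(a, i) * R_i` (information-scaled
#' stack, as in standard sequence logos).
#'
#' @param windows character matrix from [extract_windows()].
#' @param rendering `"probability"` or `"entropy"`.
#' @param small_sample_correction apply `e_n`? Defaults to `TRUE` for
#'   the entropy rendering and `FALSE` for the probability rendering.
#' @return object of class `LogoMatrix`: `freq` (20 x width),
#'   `bits` (per position, `NA` where a position has no non-pad
#'   observations), `heights` (rendering-dependent), `n`, `n_obs`
#'   per position, `e_n` at full `n`, `rendering`.
#' @export
logo_matrix <- function(windows,
                        rendering = c("probability", "entropy"),
                        small_sample_correction = NULL) {
  rendering <- match.arg(rendering)
  if (is.null(small_sample_correction)) {
    small_sample_correction <- rendering == "entropy"
  }
  if (nrow(windows) == 0L) stop("no windows supplied")
  w <- ncol(windows)
  if (is.null(colnames(windows))) {
    colnames(windows) <- as.character(seq_len(w))
  }
  freq <- matrix(0, nrow = length(.AA20), ncol = w,
                 dimnames = list(.AA20, colnames(windows)))
  bits <- rep(NA_real_, w)
  n_obs <- integer(w)
  s <- length(.AA20)
  for (k in seq_len(w)) {
    col <- windows[, k]
    col <- col[col != .PAD]
    bad <- setdiff(unique(col), .AA20)
    if (length(bad) > 0L) {
      stop("non-standard residue(s) in windows: ",
           paste(bad, collapse = ", "))
    }
    n_obs[k] <- length(col)
    if (length(col) == 0L) next
    counts <- table(factor(col, levels = .AA20))
    f <- as.numeric(counts) / length(col)
    freq[, k] <- f
    nz <- f[f > 0]
    H <- -sum(nz * log2(nz))
    e_n <- if (small_sample_correction) {
      (s - 1) / (2 * length(col) * log(2))
    } else 0
    bits[k] <- max(log2(s) - H - e_n, 0)
  }
  heights <- if (rendering == "probability") freq
             else sweep(freq, 2, ifelse(is.na(bits), 0, bits), `*`)
  structure(
    list(freq = freq, bits = bits, heights = heights,
         n = nrow(windows), n_obs = n_obs,
         e_n = (s - 1) / (2 * nrow(windows) * log(2)),
         small_sample_correction = small_sample_correction,
         rendering = rendering),
    class = "LogoMatrix"
  )
}

#' @export
print.LogoMatrix <- function(x, ...) {
  cat(sprintf("LogoMatrix: %d positions, n = %d windows, %s rendering%s\n",
              ncol(x$freq), x$n, x$rendering,
              if (x$small_sample_correction) " (small-sample corrected)"
              else ""))
  cat("bits:", paste(sprintf("%.2f", x$bits), collapse = " "), "\n")
  invisible(x)
}

#' Write a logo matrix as a position x residue TSV
#'
#' @param x a `LogoMatrix`.
#' @param path output file.
#' @return the written data.frame, invisibly.
#' @export
write_logo_tsv <- function(x, path) {
  stopifnot(inherits(x, "LogoMatrix"))
  out <- data.frame(position = colnames(x$freq), t(x$freq),
                    bits = x$bits, n_obs = x$n_obs,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Plot a sequence logo (text rendering)
#'
#' Simple base-graphics rendering: stacked letters scaled by the
#' rendering heights.
#'
#' @param x a `LogoMatrix`.
#' @param ... passed to [graphics::plot()].
#' @method plot LogoMatrix
#' @export
plot.LogoMatrix <- function(x, ...) {
  w <- ncol(x$heights)
  ymax <- if (x$rendering == "entropy") log2(20) else 1
  graphics::plot(NA, xlim = c(0.5, w + 0.5), ylim = c(0, ymax),
                 xlab = "position", xaxt = "n",
                 ylab = if (x$rendering == "entropy") "bits"
                        else "probability", ...)
  graphics::axis(1, at = seq_len(w), labels = colnames(x$heights))
  for (k in seq_len(w)) {
    h <- x$heights[, k]
    ord <- order(h)
    y0 <- 0
    for (i in ord) {
      if (h[i] <= 0) next
      graphics::text(k, y0 + h[i] / 2, rownames(x$heights)[i],
                     cex = max(0.3, min(2.5, h[i] / ymax * 6)))
      y0 <- y0 + h[i]
    }
  }
  invisible(x)
}
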