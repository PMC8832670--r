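# Position scoring, key-position selection, difference-table encoding and
# compositional features.

# 2 x 20 residue contingency table at one window offset
offset_table <- function(frag_mat, labels, offset) {
  col <- frag_mat[, as.character(offset)]
  pos <- table(factor(col[labels == 1L], levels = AA20))
  neg <- table(factor(col[labels == 0L], levels = AA20))
  contingency_table(as.integer(pos), as.integer(neg), AA20)
}

#' Select key window offsets by compressed-table chi-square
#'
#' For every offset in `-flank ... +flank` (excluding 0, which is always
#' K) the 2 x 20 residue-by-class table is built, compressed in unordered
#' mode, and scored with [chi2_stat()]. Offsets whose score strictly
#' exceeds the mean over all offsets are the key positions; the window
#' spans from the smallest to the largest key offset (it always contains
#' the central K).
#'
#' @param fragments Labelled `chidt_fragments` (labels 0/1, both present).
#' @param alpha Local-test significance level for compression.
#' @return Object of class `chidt_keypos`: `chi2` (named vector per
#'   offset), `chi2_ave`, `key_offsets`, `window` (c(start, end)),
#'   `compressed` (per-offset group assignments).
#' @export
select_key_positions <- function(fragments, alpha = 0.05) {
  labels <- fragments$label
  if (length(unique(stats::na.omit(labels))) < 2L)
    stop("both classes must be present to select key positions")
  mat <- fragment_matrix(fragments)
  flank <- (ncol(mat) - 1L) %/% 2L
  offs <- setdiff((-flank):flank, 0L)
  comp <- vector("list", length(offs)); names(comp) <- as.character(offs)
  chi2 <- numeric(length(offs)); names(chi2) <- as.character(offs)
  for (k in seq_along(offs)) {
    tab <- offset_table(mat, labels, offs[k])
    cmp <- compress_table(tab, alpha = alpha, mode = "unordered")
    comp[[k]] <- vapply(cmp$groups, paste, character(1), collapse = "")
    chi2[k] <- chi2_stat(cmp$table)
  }
  ave <- mean(chi2)
  key <- offs[chi2 > ave]
  if (!length(key)) stop("no offset exceeds the mean chi-square; degenerate input")
  structure(list(chi2 = chi2, chi2_ave = ave, key_offsets = key,
                 window = c(min(key), max(key)), compressed = comp,
                 flank = flank),
            class = "chidt_keypos")
}

#' @export
print.chidt_keypos <- function(x, ...) {
  cat("Key-position model:", length(x$key_offsets), "key offsets of",
      length(x$chi2), "scanned\n")
  cat("  chi2_ave:", format(x$chi2_ave), "\n")
  cat("  key offsets:", paste(x$key_offsets, collapse = ", "), "\n")
  cat("  window:", x$window[1], "...", x$window[2], "\n")
  invisible(x)
}

#' Plot per-offset chi-square values of a key-position model
#'
#' @param x A `chidt_keypos` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.chidt_keypos <- function(x, ...) {
  offs <- as.integer(names(x$chi2))
  graphics::plot(offs, x$chi2, type = "h", xlab = "offset from central K",
                 ylab = "chi-square (compressed table)", ...)
  graphics::abline(h = x$chi2_ave, col = "red", lty = 2)
  graphics::points(x$key_offsets, x$chi2[as.character(x$key_offsets)],
                   pch = 19, col = "red")
  invisible(x)
}

# Eq.-1 statistic after incrementing one cell of a 2 x 20 table; all
# marginals are re-derived from the edited cells.
chi2_incremented <- function(tab, row, col) {
  tab[row, col] <- tab[row, col] + 1
  chi2_stat(tab)
}

#' Build the chi-square statistical difference table
#'
#' For each key offset `i` and residue `j`, the score is
#' `delta_chi2[i, j] = chi2(+1 to positive cell j) - chi2(+1 to negative
#' cell j)`: the change in the position's chi-square when one hypothetical
#' new sample carrying residue j is counted as positive versus negative.
#' Scores are computed from the raw (uncompressed) 2 x 20 tables.
#'
#' @param fragments Labelled `chidt_fragments`.
#' @param key_offsets Integer vector of key offsets (non-empty).
#' @return Object of class `chidt_dtable`: `scores` (20 x K matrix,
#'   rows = residues, columns = offsets), `base_tables` (the raw 2 x 20
#'   tables per key offset).
#' @export
build_difference_table <- function(fragments, key_offsets) {
  if (!length(key_offsets)) stop("key_offsets must be non-empty")
  labels <- fragments$label
  mat <- fragment_matrix(fragments)
  base <- lapply(key_offsets, function(o) offset_table(mat, labels, o))
  names(base) <- as.character(key_offsets)
  scores <- vapply(base, function(tab) {
    if (sum(tab[1L, ]) == 0 || sum(tab[2L, ]) == 0)
      stop("zero class marginal at a key position")
    vapply(seq_len(20L), function(j)
      chi2_incremented(tab, 1L, j) - chi2_incremented(tab, 2L, j),
      numeric(1))
  }, numeric(20L))
  rownames(scores) <- AA20
  structure(list(scores = scores, base_tables = base),
            class = "chidt_dtable")
}

#' Positional features of fragments via difference-table lookup
#'
#' The feature at key offset `i` of a fragment is the difference-table
#' score of the residue the fragment carries at that offset — a pure
#' deterministic lookup.
#'
#' @param fragments `chidt_fragments`.
#' @param dtable A `chidt_dtable` from [build_difference_table()].
#' @return Numeric matrix, one row per fragment, columns `P_<offset>`.
#' @export
encode_positional <- function(fragments, dtable) {
  mat <- fragment_matrix(fragments)
  offs <- colnames(dtable$scores)
  out <- vapply(offs, function(o) dtable$scores[mat[, o], o], numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- paste0("P_", offs)
  out
}

# residues of each fragment restricted to the model window
window_strings <- function(fragments, window) {
  mat <- fragment_matrix(fragments)
  cols <- as.character(window[1]:window[2])
  apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
}

#' Amino-acid composition of window sequences
#'
#' Occurrence frequency of each of the 20 standard residues, normalized by
#' window length, so each row sums to 1.
#'
#' @param windows Character vector of residue strings.
#' @return Numeric matrix with columns `f_A ... f_Y` (alphabetical code
#'   order).
#' @export
encode_aac <- function(windows) {
  if (any(nchar(windows) < 1L)) stop("windows must be non-empty")
  out <- t(vapply(strsplit(windows, "", fixed = TRUE), function(ch)
    as.numeric(table(factor(ch, levels = AA20))) / length(ch),
    numeric(20L)))
  colnames(out) <- paste0("f_", AA20)
  out
}

# the 210 unordered residue pairs, in row-major upper-triangle order
pcaac_pairs <- function() {
  idx <- which(upper.tri(matrix(0, 20, 20), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste0(AA20[idx[, 1]], AA20[idx[, 2]])
}

#' Undirected pair-coupled amino-acid composition
#'
#' Frequency of each unordered pair of adjacent residues (210 pairs for 20
#' residues, `f_AR == f_RA`), normalized by the number of adjacent pairs
#' (window length - 1); each row sums to 1.
#'
#' @param windows Character vector of residue strings (length >= 2 each).
#' @return Numeric matrix with 210 columns named `f_<pair>`.
#' @export
encode_pcaac <- function(windows) {
  if (any(nchar(windows) < 2L)) stop("windows must have length >= 2")
  pairs <- pcaac_pairs()
  key <- matrix("", 20L, 20L, dimnames = list(AA20, AA20))
  for (p in pairs) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    key[a, b] <- p; key[b, a] <- p
  }
  out <- t(vapply(strsplit(windows, "", fixed = TRUE), function(ch) {
    n <- length(ch)
    lab <- key[cbind(ch[-n], ch[-1L])]
    as.numeric(table(factor(lab, levels = pairs))) / (n - 1L)
  }, numeric(length(pairs))))
  colnames(out) <- paste0("f_", pairs)
  out
}

#' Full feature matrix: positional + AAC + undirected-PCAAC
#'
#' With the canonical 9 key positions this yields 9 + 20 + 210 = 239
#' features; in general `length(key_offsets) + 230`.
#'
#' @param fragments `chidt_fragments`.
#' @param keypos A `chidt_keypos` model (for the window).
#' @param dtable A `chidt_dtable` (for positional lookups).
#' @return Numeric matrix, one row per fragment, named columns.
#' @export
encode_features <- function(fragments, keypos, dtable) {
  win <- window_strings(fragments, keypos$window)
  cbind(encode_positional(fragments, dtable),
        encode_aac(win),
        encode_pcaac(win))
}

#' Write a feature matrix as a tab-separated table
#'
#' @param features Numeric matrix with named columns.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
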