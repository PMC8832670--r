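# 2 x m class-by-status contingency tables and their greedy compression.
#
# Tables are plain numeric matrices with two rows ("pos", "neg") and one
# column per status value; counts may be non-integer (the balanced decision
# table carries theta-weighted negatives).

#' Construct a 2 x m class-by-status contingency table
#'
#' @param pos_counts,neg_counts Non-negative counts per status value, one
#'   for the positive and one for the negative class.
#' @param status_labels Optional status identifiers (residue symbols or bin
#'   names); defaults to `V1 ... Vm`.
#' @return Numeric matrix with rows `pos`, `neg`.
#' @export
contingency_table <- function(pos_counts, neg_counts, status_labels = NULL) {
  if (length(pos_counts) != length(neg_counts))
    stop("pos_counts and neg_counts must have equal length")
  if (any(pos_counts < 0) || any(neg_counts < 0)) stop("counts must be non-negative")
  if (is.null(status_labels))
    status_labels <- paste0("V", seq_along(pos_counts))
  tab <- rbind(pos = as.numeric(pos_counts), neg = as.numeric(neg_counts))
  colnames(tab) <- as.character(status_labels)
  tab
}

#' Chi-square statistic of a 2 x m contingency table
#'
#' Computes `N^2 / (f+ * f-) * [sum_j (f+_j)^2 / f_j  -  (f+)^2 / N]`,
#' where `f+_j` is the positive count in column j, `f_j` the column total,
#' `f+`/`f-` the class totals and `N` the grand total. Columns with a zero
#' total contribute nothing. Algebraically this equals the Pearson
#' statistic of the table; this closed form is what every downstream stage
#' (position scoring, difference-table encoding, the decision rule) uses.
#'
#' @param table 2 x m numeric matrix (rows = classes).
#' @return Non-negative scalar.
#' @export
chi2_stat <- function(table) {
  if (!is.matrix(table) || nrow(table) != 2L) stop("table must be a 2 x m matrix")
  fp <- sum(table[1L, ]); fn <- sum(table[2L, ])
  if (fp <= 0 || fn <= 0)
    stop("chi-square statistic undefined for a zero class marginal")
  n <- fp + fn
  ct <- colSums(table)
  keep <- ct > 0
  n^2 / (fp * fn) * (sum(table[1L, keep]^2 / ct[keep]) - fp^2 / n)
}

# chi2_stat that treats a zero class marginal as "no association" instead
# of erroring; used while ranking candidate merges (pure leaves in the
# classifier collapse to a single column this way).
chi2_safe <- function(table) {
  if (sum(table[1L, ]) <= 0 || sum(table[2L, ]) <= 0) return(0)
  chi2_stat(table)
}

#' Local chi-square test of a 2 x 2 count table
#'
#' Pearson chi-square with 1 degree of freedom and no continuity
#' correction. A table with a zero row or column marginal carries no
#' evidence of association and returns p = 1.
#'
#' @param table 2 x 2 non-negative numeric matrix.
#' @return p-value in `[0, 1]`.
#' @export
local_chi2_test <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L)) stop("table must be 2 x 2")
  if (any(table < 0)) stop("counts must be non-negative")
  n <- sum(table)
  if (n <= 0) stop("total count must be positive")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) return(1)
  stat <- n * (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])^2 /
    prod(rs, cs)
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Compress a contingency table by greedy column merging
#'
#' Repeatedly merges the pair of columns whose merged table has the
#' largest chi-square statistic ([chi2_stat()]); the merge is kept only if
#' a local 2 x 2 chi-square test on the two merged columns is
#' non-significant (`p >= alpha`), otherwise the merge is backtracked and
#' compression stops. In `"unordered"` mode any pair may merge (residue
#' statuses); in `"adjacent"` mode only neighbouring columns may merge
#' (ordered numeric statuses), so every group is a contiguous run.
#' Zero-total columns always merge first (their local test is p = 1 by
#' convention). Ties in the merged chi-square go to the first pair in
#' status order.
#'
#' @param table 2 x m numeric matrix (m >= 2) with column names.
#' @param alpha Significance level of the local test gate (default 0.05).
#' @param mode `"unordered"` or `"adjacent"`.
#' @param min_groups Smallest number of columns compression may reach
#'   (default 2; the classifier's per-leaf recompression uses 1, in which
#'   case full collapse means the feature carries no signal there).
#' @return List of class `chidt_compressed`: `table` (the 2 x r merged
#'   matrix), `groups` (list of original-label character vectors),
#'   `merge_log` (data frame of accepted merges with local p-values).
#' @export
compress_table <- function(table, alpha = 0.05,
                           mode = c("unordered", "adjacent"),
                           min_groups = 2L) {
  mode <- match.arg(mode)
  if (!is.matrix(table) || nrow(table) != 2L) stop("table must be a 2 x m matrix")
  m <- ncol(table)
  if (is.null(colnames(table))) colnames(table) <- paste0("V", seq_len(m))
  groups <- lapply(colnames(table), identity)
  cur <- table
  log_pair <- character(); log_p <- numeric()

  repeat {
    r <- ncol(cur)
    if (r <= max(min_groups, 1L)) break
    pairs <- if (mode == "adjacent")
      cbind(seq_len(r - 1L), seq_len(r)[-1L])
    else {
      idx <- utils::combn(r, 2L)
      cbind(idx[1L, ], idx[2L, ])
    }
    best <- NULL; best_chi <- -Inf
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      merged <- merge_columns(cur, i, j)
      chi <- chi2_safe(merged)
      if (chi > best_chi + 1e-9) {         # strict improvement; first pair wins ties
        best_chi <- chi; best <- c(i, j)
      }
    }
    i <- best[1L]; j <- best[2L]
    local <- cbind(cur[, i], cur[, j])
    p <- if (sum(cur[, i]) == 0 || sum(cur[, j]) == 0) 1 else local_chi2_test(local)
    if (p < alpha) break                   # backtrack: keep `cur`, terminate
    log_pair <- c(log_pair,
                  paste(colnames(cur)[i], colnames(cur)[j], sep = "|"))
    log_p <- c(log_p, p)
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups[[j]] <- NULL
    cur <- merge_columns(cur, i, j)
  }
  colnames(cur) <- vapply(groups, paste, character(1), collapse = "")
  structure(list(table = cur, groups = groups,
                 merge_log = data.frame(pair = log_pair, p_value = log_p,
                                        stringsAsFactors = FALSE)),
            class = "chidt_compressed")
}

# merge columns i and j (i < j) of a 2 x r matrix, keeping column order
merge_columns <- function(tab, i, j) {
  tab[, i] <- tab[, i] + tab[, j]
  tab[, -j, drop = FALSE]
}

#' @export
print.chidt_compressed <- function(x, ...) {
  cat("Compressed 2 x", ncol(x$table), "contingency table\n")
  cat("groups:", paste(colnames(x$table), collapse = "  "), "\n")
  cat("accepted merges:", nrow(x$merge_log), "\n")
  invisible(x)
}
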