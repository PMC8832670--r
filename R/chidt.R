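# The chi-square decision-table classifier: adjacent-merge discretization
# of each retained feature, gain-ratio-ordered introduction producing
# variable-length conjunction rules, theta-weighted balancing of the rule
# table, and an incremental-chi-square decision.

#' Shannon entropy of a binary label multiset
#'
#' `-sum_k p_k log2 p_k` with `0 * log 0 = 0`.
#'
#' @param labels Vector of class labels (any two values), or a length-2
#'   vector of class counts if `counts = TRUE`.
#' @param counts Interpret `labels` as counts.
#' @return Entropy in bits.
#' @export
entropy <- function(labels, counts = FALSE) {
  cnt <- if (counts) as.numeric(labels) else as.numeric(table(labels))
  if (!length(cnt) || sum(cnt) <= 0) stop("empty sample set")
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain and gain ratio of a discretized feature
#'
#' Gain is the drop in label entropy from partitioning `D` by the
#' feature's bins; the intrinsic value IV is the entropy of the bin sizes;
#' the ratio is `gain / IV`. A feature whose samples all fall in one bin
#' has `IV = 0` and is flagged (`ratio = NA`) rather than an error: it is
#' simply not a candidate for introduction.
#'
#' @param labels Binary labels (0/1) of the sample set D.
#' @param bins Bin assignment of each sample (integer or factor).
#' @return List with `gain` (bits), `iv`, `ratio` (`NA` when `iv == 0`).
#' @export
gain_and_ratio <- function(labels, bins) {
  if (length(labels) != length(bins)) stop("labels and bins lengths differ")
  n <- length(labels)
  h <- entropy(labels)
  tab <- table(bins, labels)
  sizes <- rowSums(tab)
  hj <- apply(tab, 1L, function(cnt) if (sum(cnt) == 0) 0 else entropy(cnt, counts = TRUE))
  gain <- h - sum(sizes / n * hj)
  pj <- sizes[sizes > 0] / n
  iv <- -sum(pj * log2(pj))
  list(gain = gain, iv = iv,
       ratio = if (iv > 0) gain / iv else NA_real_)
}

# Adjacent-merge discretization of one numeric feature on the training set.
# Distinct values form the initial 2 x m status table; compression groups
# contiguous runs. Returns NULL when the feature has < 2 distinct values.
discretize_feature <- function(x, y, alpha = 0.05) {
  vals <- sort(unique(x))
  m <- length(vals)
  if (m < 2L) return(NULL)
  idx <- match(x, vals)
  pos <- tabulate(idx[y == 1L], nbins = m)
  neg <- tabulate(idx[y == 0L], nbins = m)
  tab <- contingency_table(pos, neg, seq_len(m))
  cmp <- compress_table(tab, alpha = alpha, mode = "adjacent", min_groups = 2L)
  bin_of_val <- integer(m)
  for (g in seq_along(cmp$groups))
    bin_of_val[as.integer(cmp$groups[[g]])] <- g
  r <- length(cmp$groups)
  # routing boundaries: midpoints between the last value of one bin and
  # the first value of the next; boundary bins extend to +/- Inf
  ends <- vapply(seq_len(r - 1L), function(g) max(vals[bin_of_val == g]), numeric(1))
  starts <- vapply(seq_len(r - 1L) + 1L, function(g) min(vals[bin_of_val == g]), numeric(1))
  list(values = vals, bin_of_val = bin_of_val, r = r,
       boundaries = (ends + starts) / 2)
}

# map raw feature values to global bins (1..r), extending boundary bins
route_bins <- function(x, disc) {
  findInterval(x, disc$boundaries) + 1L
}

#' Fit the chi-square decision-table classifier
#'
#' Each feature is discretized by adjacent-mode compression of its
#' distinct-value contingency table. The first introduced feature is the
#' one with the highest gain ratio among features whose information gain
#' is at or above the candidate average; afterwards, each remaining
#' feature's bins are recompressed inside every current rule cell (leaf),
#' a feature remaining splittable in at least one leaf stays a candidate,
#' and the next introduction again maximizes gain ratio among
#' above-average-gain candidates. A feature splits only the leaves where
#' it retains at least two bins, so rules have variable length. Finally
#' negative rule counts are weighted by `theta = n_pos / n_neg`
#' ([balance_table()]) and per-rule decisions are precomputed with the
#' incremental chi-square criterion.
#'
#' @param features Numeric matrix (columns = retained features, named).
#' @param y Binary labels (0/1), both classes present.
#' @param alpha Local-test significance level for all compressions.
#' @return Object of class `chidt_fit`: discretizations, introduction
#'   order, rule table (with raw and weighted counts), `theta`, and the
#'   per-rule decision of the incremental-chi-square and of the
#'   unweighted majority rule.
#' @export
chidt_fit <- function(features, y, alpha = 0.05) {
  if (!is.matrix(features) || ncol(features) < 1L)
    stop("features must be a matrix with >= 1 column")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  n <- nrow(features)
  p <- ncol(features)
  fnames <- colnames(features)
  if (is.null(fnames)) fnames <- paste0("X", seq_len(p))

  disc <- lapply(seq_len(p), function(j) discretize_feature(features[, j], y, alpha))
  names(disc) <- fnames
  gbin <- vapply(seq_len(p), function(j) {
    if (is.null(disc[[j]])) rep(1L, n) else
      disc[[j]]$bin_of_val[match(features[, j], disc[[j]]$values)]
  }, integer(n))
  if (n == 1L) gbin <- matrix(gbin, nrow = 1L)

  leaves <- list(list(idx = seq_len(n), conds = list()))
  introduced <- integer()
  remaining <- which(!vapply(disc, is.null, logical(1)))

  repeat {
    cand <- list()
    for (j in remaining) {
      r <- disc[[j]]$r
      total_gain <- 0; total_iv <- 0; splittable <- FALSE
      leaf_groups <- vector("list", length(leaves))
      for (li in seq_along(leaves)) {
        idx <- leaves[[li]]$idx
        if (!length(idx)) { leaf_groups[[li]] <- rep(1L, r); next }
        b <- gbin[idx, j]
        pos <- tabulate(b[y[idx] == 1L], nbins = r)
        neg <- tabulate(b[y[idx] == 0L], nbins = r)
        tab <- contingency_table(pos, neg, seq_len(r))
        cmp <- compress_leaf(tab, alpha)
        grp <- integer(r)
        for (g in seq_along(cmp)) grp[cmp[[g]]] <- g
        leaf_groups[[li]] <- grp
        if (max(grp) >= 2L) {
          splittable <- TRUE
          gr <- gain_and_ratio(y[idx], grp[b])
          w <- length(idx) / n
          total_gain <- total_gain + w * gr$gain
          total_iv <- total_iv + w * gr$iv
        }
      }
      if (splittable && total_iv > 0)
        cand[[as.character(j)]] <- list(j = j, gain = total_gain,
                                        ratio = total_gain / total_iv,
                                        groups = leaf_groups)
    }
    if (!length(cand)) break
    gains <- vapply(cand, `[[`, numeric(1), "gain")
    pool <- cand[gains >= mean(gains)]     # >= : never empty when gains tie
    ratios <- vapply(pool, `[[`, numeric(1), "ratio")
    pick <- pool[[which.max(ratios)]]      # ties: lowest feature index
    j <- pick$j

    new_leaves <- list()
    for (li in seq_along(leaves)) {
      grp <- pick$groups[[li]]
      leaf <- leaves[[li]]
      if (max(grp) < 2L) { new_leaves <- c(new_leaves, list(leaf)); next }
      b <- gbin[leaf$idx, j]
      for (g in seq_len(max(grp))) {
        bins_g <- which(grp == g)
        child <- leaf
        child$idx <- leaf$idx[grp[b] == g]
        child$conds[[fnames[j]]] <- c(min(bins_g), max(bins_g))
        new_leaves <- c(new_leaves, list(child))
      }
    }
    leaves <- new_leaves
    introduced <- c(introduced, j)
    remaining <- setdiff(remaining, j)
  }

  rules <- build_rule_table(leaves, y, fnames, disc)
  rules <- balance_table(rules)
  fit <- structure(list(discretizations = disc,
                        introduced = fnames[introduced],
                        rules = rules,
                        alpha = alpha,
                        feature_names = fnames),
                   class = "chidt_fit")
  fit$decisions <- rule_decisions(rules)
  fit
}

# per-leaf recompression: adjacent merges down to (possibly) one column;
# returns list of integer vectors of global-bin indices per group
compress_leaf <- function(tab, alpha) {
  cmp <- compress_table(tab, alpha = alpha, mode = "adjacent", min_groups = 1L)
  lapply(cmp$groups, as.integer)
}

build_rule_table <- function(leaves, y, fnames, disc) {
  n_rules <- length(leaves)
  conds <- lapply(leaves, `[[`, "conds")
  pos_count <- vapply(leaves, function(l) sum(y[l$idx] == 1L), numeric(1))
  neg_count <- vapply(leaves, function(l) sum(y[l$idx] == 0L), numeric(1))
  structure(list(conditions = conds,
                 pos_count = pos_count,
                 neg_count = neg_count,
                 n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                 feature_names = fnames,
                 discretizations = disc),
            class = "chidt_rules")
}

#' Weight the negative rule counts to balance the decision table
#'
#' Multiplies each rule's negative count by `theta`, the ratio of total
#' positive to total negative training samples, so that the weighted
#' negative row sums to the positive total. Positive counts are untouched.
#'
#' @param rules A `chidt_rules` table from [chidt_fit()].
#' @param theta Weight; defaults to `n_pos / n_neg` of the training data.
#' @return The rule table with a `weighted_neg` component and `theta`.
#' @export
balance_table <- function(rules, theta = NULL) {
  if (is.null(theta)) {
    if (rules$n_pos <= 0 || rules$n_neg <= 0)
      stop("both class totals must be positive")
    theta <- rules$n_pos / rules$n_neg
  }
  rules$theta <- theta
  rules$weighted_neg <- rules$neg_count * theta
  rules
}

# Precompute, for every rule, the incremental-chi-square decision and the
# unweighted majority decision.
rule_decisions <- function(rules) {
  B <- rbind(rules$pos_count, rules$weighted_neg)
  R <- ncol(B)
  chidt <- logical(R)
  for (c in seq_len(R)) {
    Bp <- B; Bp[1L, c] <- Bp[1L, c] + 1
    Bm <- B; Bm[2L, c] <- Bm[2L, c] + 1
    chidt[c] <- chi2_stat(Bp) > chi2_stat(Bm)   # tie -> negative
  }
  list(chidt = chidt,
       majority = rules$pos_count > rules$neg_count)
}

# Route feature rows to rule indices. Returns integer vector; 0 when no
# rule matches (cannot happen for features routed through the stored
# discretizations, but kept as a guarded path).
route_rules <- function(fit, features) {
  n <- nrow(features)
  rules <- fit$rules
  gb <- lapply(fit$feature_names, function(f) {
    d <- fit$discretizations[[f]]
    if (is.null(d)) rep(1L, n) else route_bins(features[, f], d)
  })
  names(gb) <- fit$feature_names
  out <- integer(n)
  match_mat <- matrix(TRUE, n, length(rules$conditions))
  for (ri in seq_along(rules$conditions)) {
    for (f in names(rules$conditions[[ri]])) {
      rng <- rules$conditions[[ri]][[f]]
      match_mat[, ri] <- match_mat[, ri] &
        gb[[f]] >= rng[1] & gb[[f]] <= rng[2]
    }
  }
  for (i in seq_len(n)) {
    hit <- which(match_mat[i, ])
    out[i] <- if (length(hit)) hit[1L] else 0L
  }
  if (any(out == 0L))
    message(sum(out == 0L), " sample(s) matched no rule; predicted negative")
  out
}

#' Predict class labels with a fitted decision table
#'
#' A sample is routed to its unique rule; the full balanced table is then
#' evaluated twice with the chi-square statistic — once with the rule's
#' positive count incremented by one, once with its weighted negative
#' count incremented — and the sample is called positive exactly when the
#' positive increment yields the larger statistic (ties are negative).
#' `method = "majority"` instead applies an unweighted majority vote on
#' the raw rule counts (the naive baseline that collapses under class
#' imbalance).
#'
#' @param object A `chidt_fit`.
#' @param features Numeric matrix with the fitted feature columns.
#' @param method `"chidt"` (default) or `"majority"`.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.chidt_fit <- function(object, features, method = c("chidt", "majority"),
                              ...) {
  method <- match.arg(method)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL, object$feature_names))
  ri <- route_rules(object, features)
  dec <- object$decisions[[method]]
  as.integer(ifelse(ri == 0L, FALSE, dec[pmax(ri, 1L)]))
}

#' Predict a single sample (vector of retained-feature values)
#'
#' @param features Named numeric vector of feature values.
#' @param fit A `chidt_fit`.
#' @return `"positive"` or `"negative"`.
#' @export
predict_sample <- function(features, fit) {
  lab <- predict(fit, matrix(features, nrow = 1L,
                             dimnames = list(NULL, fit$feature_names)))
  if (lab == 1L) "positive" else "negative"
}

#' Human-readable rule conditions of a fitted decision table
#'
#' Each rule is rendered as a conjunction of conditions; a condition whose
#' bin holds a single training value prints as an equality, otherwise as a
#' closed interval over the training values it covers.
#'
#' @param fit A `chidt_fit`.
#' @param digits Significant digits for printed values.
#' @return Character vector, one string per rule.
#' @export
format_rules <- function(fit, digits = 4L) {
  vapply(seq_along(fit$rules$conditions), function(ri) {
    conds <- fit$rules$conditions[[ri]]
    if (!length(conds)) return("(always)")
    parts <- vapply(names(conds), function(f) {
      d <- fit$discretizations[[f]]
      rng <- conds[[f]]
      vals <- d$values[d$bin_of_val >= rng[1] & d$bin_of_val <= rng[2]]
      if (length(vals) == 1L)
        sprintf("(%s = %s)", f, signif(vals, digits))
      else
        sprintf("(%s <= %s <= %s)", signif(min(vals), digits), f,
                signif(max(vals), digits))
    }, character(1))
    paste(parts, collapse = " ^ ")
  }, character(1))
}

#' @export
print.chidt_fit <- function(x, ...) {
  cat("Chi-square decision table:",
      length(x$introduced), "introduced feature(s),",
      length(x$rules$pos_count), "rule(s)\n")
  cat("  introduction order:", paste(x$introduced, collapse = ", "), "\n")
  cat("  theta:", format(x$rules$theta), "\n")
  invisible(x)
}
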