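# Independent oracle implementations and small fixture builders.
# These deliberately avoid the package's own code paths: the textbook
# Pearson formula, naive double loops, and brute-force enumeration.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# textbook Pearson chi-square, sum (O - E)^2 / E; zero-total columns drop out
pearson_chi2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0)) return(0)
  E <- outer(rs, cs) / n
  keep <- E > 0
  sum((tab[keep] - E[keep])^2 / E[keep])
}

# exhaustive-at-each-step merge search under the same accept/stop rule
oracle_compress_groups <- function(tab, alpha, mode, min_groups = 2L) {
  groups <- as.list(seq_len(ncol(tab)))
  cur <- tab
  repeat {
    r <- ncol(cur)
    if (r <= min_groups) break
    prs <- if (mode == "adjacent") cbind(seq_len(r - 1L), seq_len(r)[-1L])
           else t(utils::combn(r, 2L))
    best <- NULL; bestchi <- -Inf
    for (k in seq_len(nrow(prs))) {
      i <- prs[k, 1L]; j <- prs[k, 2L]
      m <- cur; m[, i] <- m[, i] + m[, j]; m <- m[, -j, drop = FALSE]
      chi <- pearson_chi2(m)
      if (chi > bestchi + 1e-9) { bestchi <- chi; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    two <- cbind(cur[, i], cur[, j])
    p <- if (sum(two[, 1]) == 0 || sum(two[, 2]) == 0 ||
             any(rowSums(two) == 0)) 1 else
      suppressWarnings(stats::chisq.test(two, correct = FALSE)$p.value)
    if (is.na(p)) p <- 1
    if (p < alpha) break
    groups[[i]] <- c(groups[[i]], groups[[j]]); groups[[j]] <- NULL
    m <- cur; m[, i] <- m[, i] + m[, j]; cur <- m[, -j, drop = FALSE]
  }
  groups
}

# naive redundancy-shared total score, direct double loop over Eq-style sums
oracle_share_score <- function(rel, red, members) {
  total <- 0
  for (i in members) {
    denom <- 0
    for (j in members) denom <- denom + red[i, j]
    total <- total + rel[i] / denom
  }
  total
}

# naive entropy / information gain / intrinsic value
oracle_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}
oracle_gain_iv <- function(labels, bins) {
  n <- length(labels)
  g <- oracle_entropy(labels)
  iv <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    g <- g - sum(sel) / n * oracle_entropy(labels[sel])
    iv <- iv - sum(sel) / n * log2(sum(sel) / n)
  }
  list(gain = g, iv = iv)
}

# build a chidt_fragments data frame from raw window strings
frags_from_strings <- function(strings, labels) {
  flank <- (nchar(strings[1]) - 1L) %/% 2L
  out <- data.frame(protein_id = sprintf("T%04d", seq_along(strings)),
                    position = rep(flank + 1L, length(strings)),
                    fragment = strings, label = as.integer(labels),
                    stringsAsFactors = FALSE)
  attr(out, "flank") <- flank
  class(out) <- c("chidt_fragments", class(out))
  out
}

# random fragments with uniform residues, K at centre
random_fragments <- function(n, flank = 25L, seed = 1L, labels = NULL) {
  set.seed(seed)
  width <- 2L * flank + 1L
  strs <- vapply(seq_len(n), function(i) {
    ch <- sample(AA, width, replace = TRUE)
    ch[flank + 1L] <- "K"
    paste(ch, collapse = "")
  }, character(1))
  if (is.null(labels)) labels <- rep_len(0:1, n)
  frags_from_strings(strs, labels)
}

# independent rule routing: check every sample against every rule's
# conditions using the stored discretizations
oracle_route <- function(fit, features) {
  n <- nrow(features)
  hits <- matrix(FALSE, n, length(fit$rules$conditions))
  for (ri in seq_along(fit$rules$conditions)) {
    ok <- rep(TRUE, n)
    conds <- fit$rules$conditions[[ri]]
    for (f in names(conds)) {
      d <- fit$discretizations[[f]]
      bins <- d$bin_of_val[match(features[, f], d$values)]
      ok <- ok & bins >= conds[[f]][1] & bins <= conds[[f]][2]
    }
    hits[, ri] <- ok
  }
  hits
}

# independent incremental-chi-square decision for rule column `c`
oracle_decision <- function(pos, wneg, c) {
  Bp <- rbind(pos, wneg); Bp[1, c] <- Bp[1, c] + 1
  Bm <- rbind(pos, wneg); Bm[2, c] <- Bm[2, c] + 1
  pearson_chi2(Bp) > pearson_chi2(Bm)
}
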