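# helper: independent recomputation of a difference-table score from the
# stored raw position table (increment, re-derive marginals, Pearson form)
oracle_delta <- function(base, residue) {
  j <- match(residue, colnames(base))
  tp <- base; tp[1L, j] <- tp[1L, j] + 1
  tn <- base; tn[2L, j] <- tn[2L, j] + 1
  pearson_chi2(tp) - pearson_chi2(tn)
}

test_that("a planted offset is selected as a key position", {
  frags <- generate_fragments(generator_spec(n_pos = 150L, n_neg = 1500L,
                                             planted_offsets = -2L,
                                             effect_size = 0.5, seed = 21L))
  kp <- select_key_positions(frags)
  expect_true(-2L %in% kp$key_offsets)
  expect_equal(unname(which.max(kp$chi2)), which(names(kp$chi2) == "-2"))
  # key set is exactly the offsets above the mean
  expect_setequal(kp$key_offsets,
                  as.integer(names(kp$chi2)[kp$chi2 > kp$chi2_ave]))
  # window spans min..max key offset
  expect_equal(kp$window, c(min(kp$key_offsets), max(kp$key_offsets)))
})

test_that("key-position selection requires both classes", {
  frags <- random_fragments(20, labels = rep(1L, 20))
  expect_error(select_key_positions(frags), "both classes")
})

test_that("difference-table scores carry the sign of class preference", {
  # residue W appears only in positives at offset -1, Y only in negatives
  set.seed(5)
  base <- random_fragments(40, flank = 3L, seed = 5,
                           labels = rep(c(1L, 0L), each = 20))
  mat <- do.call(rbind, strsplit(base$fragment, ""))
  mat[base$label == 1L, 3L] <- "W"
  mat[base$label == 0L, 3L] <- "Y"
  frags <- frags_from_strings(apply(mat, 1L, paste, collapse = ""), base$label)
  dt <- build_difference_table(frags, key_offsets = -1L)
  expect_gt(dt$scores["W", "-1"], 0)
  expect_lt(dt$scores["Y", "-1"], 0)
  # every cell agrees with the independent incremental Pearson oracle
  for (res in c("A", "K", "W", "Y")) {
    expect_equal(dt$scores[res, "-1"],
                 oracle_delta(dt$base_tables[["-1"]], res),
                 tolerance = 1e-10)
  }
})

test_that("swapping the class rows negates every difference score", {
  frags <- random_fragments(60, flank = 4L, seed = 9,
                            labels = rep_len(c(1L, 0L), 60))
  flipped <- frags
  flipped$label <- 1L - frags$label
  dt1 <- build_difference_table(frags, key_offsets = c(-2L, 1L))
  dt2 <- build_difference_table(flipped, key_offsets = c(-2L, 1L))
  expect_equal(dt1$scores, -dt2$scores, tolerance = 1e-10)
})

test_that("positional encoding is a deterministic lookup", {
  frags <- random_fragments(30, flank = 4L, seed = 13,
                            labels = rep_len(c(1L, 0L), 30))
  dt <- build_difference_table(frags, key_offsets = c(-1L, 2L))
  enc <- encode_positional(frags, dt)
  mat <- do.call(rbind, strsplit(frags$fragment, ""))
  # fragments sharing a residue at an offset share the feature value
  res_m1 <- mat[, 4L]                        # offset -1 at flank 4
  for (r in unique(res_m1)) {
    expect_equal(length(unique(enc[res_m1 == r, "P_-1"])), 1L)
    expect_equal(unique(enc[res_m1 == r, "P_-1"]), unname(dt$scores[r, "-1"]))
  }
  # a fragment with K everywhere picks out the K row
  kfrag <- frags_from_strings(paste(rep("K", 9), collapse = ""), 1L)
  expect_equal(unname(encode_positional(kfrag, dt)[1L, ]),
               unname(dt$scores["K", c("-1", "2")]))
})

test_that("compositional features are proportions that sum to one", {
  expect_equal(unname(encode_aac(strrep("K", 16))[1L, "f_K"]), 1)
  w <- paste0(strrep("K", 4), strrep("A", 12))
  expect_equal(unname(encode_aac(w)[1L, "f_K"]), 0.25)
  expect_equal(unname(encode_pcaac(strrep("AR", 8))[1L, "f_AR"]), 1)
  expect_equal(unname(encode_pcaac(strrep("A", 16))[1L, "f_AA"]), 1)
  set.seed(31)
  wins <- vapply(1:10, function(i)
    paste(sample(AA, 16, replace = TRUE), collapse = ""), character(1))
  expect_equal(unname(rowSums(encode_aac(wins))), rep(1, 10))
  expect_equal(unname(rowSums(encode_pcaac(wins))), rep(1, 10))
})

test_that("pair frequencies match an independent sliding-window tally", {
  set.seed(41)
  for (i in 1:5) {
    w <- paste(sample(AA, 16, replace = TRUE), collapse = "")
    enc <- encode_pcaac(w)[1L, ]
    ch <- strsplit(w, "")[[1]]
    tally <- setNames(numeric(length(enc)), names(enc))
    for (k in 1:15) {
      a <- ch[k]; b <- ch[k + 1]
      nm <- paste0("f_", a, b)
      if (!nm %in% names(tally)) nm <- paste0("f_", b, a)
      tally[nm] <- tally[nm] + 1 / 15
    }
    expect_equal(enc, tally, tolerance = 1e-12)
  }
})

test_that("nine key positions yield the canonical 239 features", {
  frags <- generate_fragments(generator_spec(n_pos = 60L, n_neg = 120L,
                                             seed = 51L))
  keypos <- structure(list(key_offsets = c(-8L, -4L, -3L, -2L, -1L, 1L, 2L, 5L, 7L),
                           window = c(-8L, 7L), flank = 25L),
                      class = "chidt_keypos")
  dt <- build_difference_table(frags, keypos$key_offsets)
  X <- encode_features(frags, keypos, dt)
  expect_equal(ncol(X), 9L + 20L + 210L)
  expect_equal(colnames(X)[1:2], c("P_-8", "P_-4"))
})

test_that("a single-residue insertion barely moves the composition", {
  w <- paste(sample(AA, 16, replace = TRUE), collapse = "")
  mutated <- paste0(substr(w, 1, 3), "E", substr(w, 4, 15))  # still 16-mer
  d <- abs(encode_aac(w) - encode_aac(mutated))
  expect_lte(max(d), 2 / 16 + 1e-12)
})
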