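test_that("entropy and gain match closed forms and a naive oracle", {
  expect_equal(entropy(rep(c(0, 1), each = 10)), 1)
  expect_equal(entropy(rep(1, 7)), 0)
  expect_equal(entropy(c(5, 15), counts = TRUE),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))

  y <- rep(c(0, 1), each = 20)
  bins <- rep(c(1, 2), each = 20)            # perfect 2-bin separation
  gr <- gain_and_ratio(y, bins)
  expect_equal(gr$gain, 1); expect_equal(gr$iv, 1); expect_equal(gr$ratio, 1)

  gr0 <- gain_and_ratio(y, rep(c(1, 2), 20)) # bins orthogonal to class
  expect_equal(gr0$gain, 0)

  set.seed(81)
  for (i in 1:8) {
    y <- rbinom(50, 1, 0.4)
    bins <- sample(1:4, 50, replace = TRUE)
    got <- gain_and_ratio(y, bins)
    want <- oracle_gain_iv(y, bins)
    expect_equal(got$gain, want$gain, tolerance = 1e-12)
    expect_equal(got$iv, want$iv, tolerance = 1e-12)
  }
  # single-bin feature is flagged, not an error
  expect_true(is.na(gain_and_ratio(y, rep(1, 50))$ratio))
})

test_that("a perfectly separating binary feature yields two pure rules", {
  y <- rep(c(1L, 0L), each = 25)
  X <- cbind(f = c(rep(0, 25), rep(5, 25)))
  fit <- chidt_fit(X, y)
  expect_equal(length(fit$rules$pos_count), 2L)
  expect_setequal(fit$rules$pos_count, c(25, 0))
  expect_setequal(fit$rules$neg_count, c(0, 25))
  expect_equal(predict(fit, cbind(f = c(0, 5))), c(1L, 0L))
})

test_that("a leaf-local feature produces variable-length rules", {
  # f2 is constant where f1 = 0 and decisive where f1 = 1 (or, if f2 is
  # introduced first, its positive branch is pure): one branch never
  # splits again, so rules end up with unequal numbers of conditions
  f1 <- c(rep(0, 300), rep(1, 300))
  f2 <- c(rep(0, 300), rep(1, 250), rep(0, 50))
  y <- c(rep(1L, 100), rep(0L, 200), rep(1L, 250), rep(0L, 50))
  fit <- chidt_fit(cbind(f1 = f1, f2 = f2), y)
  nconds <- vapply(fit$rules$conditions, length, integer(1))
  expect_true(length(unique(nconds)) > 1L)   # some 1-condition, some 2
  # counts verified by brute-force sample routing
  n <- length(y)
  hits <- oracle_route(fit, cbind(f1 = f1, f2 = f2))
  expect_true(all(rowSums(hits) == 1L))
  routed <- apply(hits, 1L, which)
  expect_equal(as.numeric(table(factor(routed[y == 1],
                                       levels = seq_along(fit$rules$pos_count)))),
               fit$rules$pos_count)
  expect_equal(as.numeric(table(factor(routed[y == 0],
                                       levels = seq_along(fit$rules$neg_count)))),
               fit$rules$neg_count)
})

test_that("rule tables partition the training set and conserve counts", {
  frags <- generate_fragments(generator_spec(n_pos = 80L, n_neg = 800L,
                                             seed = 83L))
  kp <- select_key_positions(frags)
  dt <- build_difference_table(frags, kp$key_offsets)
  X <- encode_positional(frags, dt)
  fit <- chidt_fit(X, frags$label)
  hits <- oracle_route(fit, X)
  expect_true(all(rowSums(hits) == 1L))      # exactly one rule per sample
  expect_equal(sum(fit$rules$pos_count), 80)
  expect_equal(sum(fit$rules$neg_count), 800)
  # theta weighting balances the negative row
  expect_equal(sum(fit$rules$weighted_neg), sum(fit$rules$pos_count),
               tolerance = 1e-6)
})

test_that("theta weighting reproduces hand-computed balanced counts", {
  rules <- structure(list(conditions = list(list(), list()),
                          pos_count = c(23, 32), neg_count = c(2907, 83),
                          n_pos = 4748, n_neg = 50551),
                     class = "chidt_rules")
  bal <- balance_table(rules)
  expect_equal(round(bal$weighted_neg[1], 2), 273.04)
  expect_equal(round(bal$weighted_neg[2], 2), 7.80)
  # theta = 1 leaves the counts untouched
  expect_equal(balance_table(rules, theta = 1)$weighted_neg, rules$neg_count)
})

test_that("the incremental decision matches an independent evaluation", {
  # a pure-positive rule is decided positive
  pos <- c(10, 2); wneg <- c(0, 9)
  expect_true(oracle_decision(pos, wneg, 1L))
  set.seed(84)
  for (i in 1:20) {
    R <- sample(2:6, 1)
    pos <- rpois(R, 5); wneg <- rpois(R, 5) + runif(R)
    if (sum(pos) == 0 || sum(wneg) == 0) next
    rules <- structure(list(conditions = rep(list(list()), R),
                            pos_count = pos, neg_count = wneg,
                            n_pos = sum(pos), n_neg = sum(wneg)),
                       class = "chidt_rules")
    bal <- balance_table(rules, theta = 1)
    dec <- chidt:::rule_decisions(bal)$chidt
    for (c in seq_len(R)) {
      expect_equal(dec[c], oracle_decision(pos, wneg, c),
                   info = sprintf("seed-case %d col %d", i, c))
    }
  }
})

test_that("exact symmetry between the classes forces the negative tie rule", {
  rules <- structure(list(conditions = list(list(), list()),
                          pos_count = c(5, 7), neg_count = c(5, 7),
                          n_pos = 12, n_neg = 12),
                     class = "chidt_rules")
  bal <- balance_table(rules, theta = 1)     # weighted_neg == pos_count
  dec <- chidt:::rule_decisions(bal)$chidt
  expect_false(any(dec))                     # chi2+ == chi2-: negative
})

test_that("flipping labels and inverting theta flips tie-free decisions", {
  set.seed(85)
  pos <- c(12, 3, 8); neg <- c(40, 30, 9)
  rules <- structure(list(conditions = rep(list(list()), 3),
                          pos_count = pos, neg_count = neg,
                          n_pos = sum(pos), n_neg = sum(neg)),
                     class = "chidt_rules")
  dec <- chidt:::rule_decisions(balance_table(rules))$chidt
  flipped <- structure(list(conditions = rep(list(list()), 3),
                            pos_count = neg, neg_count = pos,
                            n_pos = sum(neg), n_neg = sum(pos)),
                       class = "chidt_rules")
  dec_f <- chidt:::rule_decisions(balance_table(flipped))$chidt
  expect_equal(dec, !dec_f)
})

test_that("prediction-time values outside the training range are routed", {
  y <- rep(c(1L, 0L), each = 30)
  X <- cbind(f = c(rnorm(30, 0), rnorm(30, 4)))
  fit <- chidt_fit(X, y)
  p <- predict(fit, cbind(f = c(-100, 100)))  # far outside training values
  expect_length(p, 2L)
  expect_true(all(p %in% 0:1))
  expect_equal(predict_sample(c(f = -100), fit), "positive")
})

test_that("a single-class training set is rejected", {
  expect_error(chidt_fit(cbind(f = rnorm(10)), rep(1L, 10)), "both classes")
})
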