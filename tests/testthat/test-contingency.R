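test_that("the closed-form statistic matches the textbook Pearson formula", {
  expect_equal(chi2_stat(contingency_table(c(10, 10), c(10, 10))), 0)
  # perfect association in a 2x2 gives chi2 = N
  expect_equal(chi2_stat(contingency_table(c(10, 0), c(0, 10))), 20)
  for (s in 1:20) {
    set.seed(s)
    tab <- contingency_table(rpois(5, 8) + 1L, rpois(5, 8) + 1L)
    expect_equal(chi2_stat(tab), pearson_chi2(tab), tolerance = 1e-12)
  }
  # zero-total columns contribute nothing
  tab0 <- contingency_table(c(3, 0, 7), c(5, 0, 2))
  expect_equal(chi2_stat(tab0),
               chi2_stat(contingency_table(c(3, 7), c(5, 2))))
  expect_error(chi2_stat(contingency_table(c(0, 0), c(1, 2))), "marginal")
})

test_that("the local 2x2 test behaves at its boundaries and matches an oracle", {
  expect_equal(local_chi2_test(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_lt(local_chi2_test(matrix(c(10, 0, 0, 10), 2)), 1e-4)
  tab <- matrix(c(8, 3, 2, 7), 2)            # pos=(8,2), neg=(3,7)
  expect_equal(local_chi2_test(tab),
               suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
               tolerance = 1e-12)
  # a zero marginal carries no evidence
  expect_equal(local_chi2_test(matrix(c(0, 5, 0, 7), 2)), 1)
  expect_error(local_chi2_test(matrix(c(-1, 5, 3, 7), 2)), "non-negative")
})

test_that("greedy compression merges look-alike columns and stops at evidence", {
  tab <- contingency_table(c(10, 10, 1, 20), c(10, 10, 20, 1), c("a", "b", "c", "d"))
  cmp <- compress_table(tab, alpha = 0.05, mode = "unordered")
  expect_equal(length(cmp$groups), 3L)
  expect_true(any(vapply(cmp$groups, function(g) setequal(g, c("a", "b")),
                         logical(1))))
  # proportional columns collapse to the floor of two groups
  prop <- contingency_table(c(10, 20, 40), c(5, 10, 20))
  expect_equal(length(compress_table(prop)$groups), 2L)
})

test_that("greedy compression equals exhaustive per-step search on small tables", {
  for (s in 1:30) {
    set.seed(100 + s)
    m <- sample(3:5, 1)
    tab <- contingency_table(rpois(m, 6), rpois(m, 6))
    for (mode in c("unordered", "adjacent")) {
      got <- compress_table(tab, alpha = 0.05, mode = mode)
      want <- oracle_compress_groups(tab, 0.05, mode)
      got_idx <- lapply(got$groups, function(g) match(g, colnames(tab)))
      expect_equal(got_idx, want, info = sprintf("seed %d mode %s", s, mode))
    }
  }
})

test_that("compression invariants hold on random tables", {
  for (s in 1:12) {
    set.seed(200 + s)
    tab <- contingency_table(rpois(8, 5), rpois(8, 5))
    for (mode in c("unordered", "adjacent")) {
      cmp <- compress_table(tab, alpha = 0.05, mode = mode)
      # count conservation group-wise
      for (g in seq_along(cmp$groups)) {
        cols <- match(cmp$groups[[g]], colnames(tab))
        expect_equal(unname(cmp$table[, g]), unname(rowSums(tab[, cols, drop = FALSE])))
      }
      # groups partition the labels
      expect_setequal(unlist(cmp$groups), colnames(tab))
      # every accepted merge passed the local gate
      if (nrow(cmp$merge_log)) expect_true(all(cmp$merge_log$p_value >= 0.05))
      # 2 <= r <= m
      expect_gte(length(cmp$groups), 2L)
      expect_lte(length(cmp$groups), 8L)
      if (mode == "adjacent") {
        # contiguous runs of the original order
        for (g in cmp$groups) {
          idx <- sort(match(g, colnames(tab)))
          expect_equal(idx, seq(min(idx), max(idx)))
        }
      }
    }
  }
})

test_that("zero-total columns never block compression", {
  tab <- contingency_table(c(10, 0, 1), c(2, 0, 12), c("a", "b", "c"))
  cmp <- compress_table(tab, alpha = 0.05, mode = "adjacent")
  expect_equal(length(cmp$groups), 2L)        # the empty column was absorbed
  expect_true(all(colSums(cmp$table) > 0))
})

test_that("a stricter gate (larger alpha) can only shorten the merge log", {
  set.seed(77)
  tab <- contingency_table(rpois(10, 6) + 1L, rpois(10, 6) + 1L)
  loose <- compress_table(tab, alpha = 0.001, mode = "adjacent")
  strict <- compress_table(tab, alpha = 0.5, mode = "adjacent")
  expect_lte(nrow(strict$merge_log), nrow(loose$merge_log))
})
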