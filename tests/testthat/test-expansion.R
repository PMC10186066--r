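test_that("ploidy adjustment rescales to diploid-equivalent counts", {
  profiles <- data.frame(name = c("A", "B"), ploidy = c(2L, 4L))
  row <- c(A = 4, B = 2)
  expect_identical(adjusted_counts(row, profiles, normalize = TRUE),
                   c(A = 4, B = 1))
  expect_identical(adjusted_counts(row, profiles, normalize = FALSE), row)
  # ploidy 2 everywhere: normalization is the identity
  dip <- data.frame(name = c("A", "B"), ploidy = 2L)
  expect_identical(adjusted_counts(row, dip, normalize = TRUE), row)
  expect_error(adjusted_counts(c(A = 1), data.frame(name = "A", ploidy = 0L),
                               normalize = TRUE), "ploidy")
})

test_that("pairwise predicate: factor, difference and the count>=1 guard", {
  expect_true(pairwise_expanded(4, 2, factor = 2, difference = 0))
  expect_false(pairwise_expanded(3, 2, factor = 2, difference = 0))
  expect_true(pairwise_expanded(2, 0, factor = 2, difference = 2))
  expect_false(pairwise_expanded(0, 0, factor = 2, difference = 0))
  # equality at the factor boundary counts as expanded
  expect_true(pairwise_expanded(4, 2, factor = 2, difference = 2))
})

test_that("call_expansion integrates qualifying species and nmin", {
  hyp <- hypothesis(1, "h", c("A", "B"), c("C", "D"),
                    nmin_expanded_in = 2, min_expansion_factor = 2,
                    min_expansion_difference = 0)
  call <- call_expansion(c(A = 4, B = 5, C = 2, D = 1), hyp)
  expect_identical(call$qualifying, c(A = TRUE, B = TRUE))
  expect_true(call$expanded)
  # B fails against C (3 < 2*2): nmin 2 not reached
  call2 <- call_expansion(c(A = 4, B = 3, C = 2, D = 1), hyp)
  expect_identical(call2$qualifying, c(A = TRUE, B = FALSE))
  expect_false(call2$expanded)
  h1 <- hypothesis(1, "h", "A", "B")
  expect_false(call_expansion(c(A = 0, B = 0), h1)$expanded)
  expect_error(call_expansion(c(A = 1), h1), "missing")
})

test_that("call_all is table-shaped, ordered and counts hypotheses", {
  set.seed(1)
  counts <- random_counts(3, 4)
  tab <- og_table_from_counts(counts)
  h1 <- hypothesis(1, "h1", "sp1", c("sp2", "sp3"))
  h2 <- hypothesis(2, "h2", "sp4", "sp1")
  calls <- call_all(tab, list(h1, h2))
  expect_named(calls, c("hypothesis_1", "hypothesis_2"))
  expect_identical(nrow(calls$hypothesis_1) + nrow(calls$hypothesis_2), 6L)
  expect_identical(calls$hypothesis_1$og_id, names(tab$rows))
  expect_length(call_all(tab, list()), 0L)
})

test_that("call_all matches the brute-force oracle on random tables", {
  set.seed(42)
  for (rep in 1:50) {
    n_sp <- sample(2:6, 1L)
    counts <- random_counts(sample(5:20, 1L), n_sp)
    tab <- og_table_from_counts(counts)
    hyp <- random_hypothesis(colnames(counts))
    got <- call_all(tab, hyp)[[1L]]
    for (i in seq_len(nrow(counts))) {
      want <- oracle_call(counts[i, ], hyp)
      expect_identical(got$expanded[[i]], want$expanded)
      for (a in hyp$expanded_in) {
        expect_identical(got[[paste0("qualifying_", a)]][[i]],
                         unname(want$qualifying[[a]]))
      }
    }
  }
})

test_that("expanded set shrinks as cutoffs tighten (monotonicity)", {
  set.seed(7)
  for (rep in 1:20) {
    counts <- random_counts(30, 4)
    tab <- og_table_from_counts(counts)
    base <- random_hypothesis(colnames(counts))
    n_exp <- function(h) sum(call_all(tab, h)[[1L]]$expanded)
    tighter_f <- base; tighter_f$min_expansion_factor <- base$min_expansion_factor + 1
    tighter_d <- base; tighter_d$min_expansion_difference <- base$min_expansion_difference + 2L
    expect_lte(n_exp(tighter_f), n_exp(base))
    expect_lte(n_exp(tighter_d), n_exp(base))
    if (base$nmin_expanded_in < length(base$expanded_in)) {
      tighter_n <- base
      tighter_n$nmin_expanded_in <- base$nmin_expanded_in + 1L
      expect_lte(n_exp(tighter_n), n_exp(base))
    }
  }
})

test_that("equal ploidies leave calls unchanged under normalization", {
  set.seed(9)
  counts <- random_counts(25, 3)
  tab <- og_table_from_counts(counts)
  profiles <- data.frame(name = colnames(counts), ploidy = 4L)
  h <- random_hypothesis(colnames(counts))
  h_norm <- h; h_norm$ploidy_normalize <- TRUE
  expect_identical(call_all(tab, h)[[1L]]$expanded,
                   call_all(tab, h_norm, profiles)[[1L]]$expanded)
})
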