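# exact tail values computed independently with integer rational
# arithmetic (Python fractions); frozen here as constants
frozen_urns <- list(
  c(20, 7, 6, 4, 0.07765737874097008),     # = 3010/38760
  c(10, 5, 5, 5, 1 / 252),
  c(60, 2, 8, 2, 0.015819209039548022),
  c(47, 9, 15, 2, 0.86363085414771235),
  c(57, 38, 6, 4, 0.68672208294849801),
  c(58, 52, 18, 18, 0.094832515131799452),
  c(48, 16, 9, 9, 6.821271663440555e-06),
  c(57, 48, 17, 17, 0.030394044410216918),
  c(53, 26, 38, 22, 0.039545385834511088),
  c(48, 14, 5, 5, 0.0011691849110905541),
  c(59, 25, 5, 4, 0.096522721180508253),
  c(60, 57, 40, 39, 0.25540619520748098),
  c(58, 46, 13, 2, 0.99999999998542266),
  c(50, 50, 50, 50, 1),
  c(57, 1, 56, 1, 0.98245614035087714)
)

test_that("hypergeometric tail matches frozen exact-rational values", {
  for (u in frozen_urns) {
    expect_equal(hypergeom_sf(u[1], u[2], u[3], u[4]), u[5],
                 tolerance = 1e-12)
  }
})

test_that("degenerate urns behave: k=0 gives 1, full overlap gives 1", {
  expect_identical(hypergeom_sf(10, 5, 5, 0), 1)
  expect_identical(hypergeom_sf(7, 7, 7, 7), 1)
  # impossible-to-be-lower k (k <= max(0, n+K-N)) is certain
  expect_identical(hypergeom_sf(10, 8, 7, 5), 1)
})

test_that("urn invariants are enforced", {
  expect_error(hypergeom_sf(10, 11, 5, 2), "K <= N")
  expect_error(hypergeom_sf(10, 5, 11, 2), "n <= N")
  expect_error(hypergeom_sf(10, 5, 5, 6), "min")
  expect_error(hypergeom_sf(10.5, 5, 5, 2), "integer")
  expect_error(fisher_one_sided(10, 5, 5, 6), "invariant")
})

test_that("the log-space branch agrees with the reference CDF at scale", {
  cases <- list(c(20000, 500, 800, 40), c(50000, 100, 100, 5),
                c(12000, 6000, 6000, 3100))
  for (u in cases) {
    expect_equal(hypergeom_sf(u[1], u[2], u[3], u[4]),
                 stats::phyper(u[4] - 1, u[2], u[1] - u[2], u[3],
                               lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("one-sided Fisher is the same tail as the hypergeometric", {
  set.seed(31)
  for (rep in 1:200) {
    N <- sample(2:80, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0, n + K - N)
    k <- sample(lo:min(K, n), 1)
    a <- hypergeom_sf(N, K, n, k)
    b <- fisher_one_sided(N, K, n, k)
    expect_lt(abs(a - b) / max(b, .Machine$double.xmin), 1e-12)
  }
  # and agrees with fisher.test on a spot check
  expect_equal(fisher_one_sided(20, 7, 6, 4),
               stats::fisher.test(matrix(c(4, 3, 2, 11), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("direct tail equals 1 - P[X <= k-1] (symmetry)", {
  set.seed(37)
  for (rep in 1:100) {
    N <- sample(5:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(1, n + K - N):min(K, n), 1)
    direct <- hypergeom_sf(N, K, n, k)
    complement <- 1 - stats::phyper(k - 1, K, N - K, n)
    # absolute 1e-12: the complement route cancels catastrophically for
    # tiny tails, so relative agreement there is not meaningful
    expect_lt(abs(direct - complement), 1e-12)
  }
})

test_that("predicate atoms parse and evaluate on summary rows", {
  rows <- data.frame(og_id = c("o1", "o2", "o3"),
                     count_A = c(5L, 2L, 0L), count_B = c(1L, 2L, 3L),
                     expanded = c(TRUE, FALSE, FALSE),
                     deg_A = c(2L, 0L, 0L), deg_B = c(0L, 1L, 0L),
                     conserved = c(TRUE, TRUE, FALSE))
  eval_p <- function(s) which(parse_predicate(s)(rows))
  expect_identical(eval_p("expanded"), 1L)
  expect_identical(eval_p("conserved & any_deg>=1"), c(1L, 2L))
  expect_identical(eval_p("deg[A]>=1"), 1L)
  expect_identical(eval_p("count[A]>4"), 1L)
  expect_identical(eval_p("count[B]==3"), 3L)
  expect_identical(eval_p("all"), 1:3)
  # duplicated atoms are idempotent
  expect_identical(eval_p("expanded & expanded"), eval_p("expanded"))
  expect_error(parse_predicate("bogus[A]>=1"), "cannot parse")
  expect_error(parse_predicate(""), "empty predicate")
  expect_error(eval_p("deg[Zz]>=1"), "unknown species")
})

test_that("overrepresentation builds the urn by set algebra", {
  set.seed(41)
  n <- 60
  rows <- data.frame(
    og_id = paste0("o", 1:n),
    count_A = sample(0:6, n, TRUE), count_B = sample(0:6, n, TRUE),
    expanded = sample(c(TRUE, FALSE), n, TRUE, prob = c(.3, .7)),
    deg_A = sample(0:3, n, TRUE), deg_B = sample(0:3, n, TRUE),
    conserved = sample(c(TRUE, FALSE), n, TRUE, prob = c(.6, .4)))
  res <- overrepresentation(rows, sample = "expanded & deg[A]>=1",
                            success = "any_deg>=1",
                            background = "conserved")
  # brute-force set cardinalities
  bg <- rows$conserved
  sc <- bg & (rows$deg_A >= 1 | rows$deg_B >= 1)
  sm <- bg & rows$expanded & rows$deg_A >= 1
  expect_identical(unname(res$urn),
                   c(sum(bg), sum(sc), sum(sm), sum(sc & sm)))
  expect_equal(res$p, hypergeom_sf(sum(bg), sum(sc), sum(sm), sum(sc & sm)))
  expect_equal(res$fold, (sum(sc & sm) / sum(sm)) / (sum(sc) / sum(bg)))
  # success == background: k = n, K = N, p = 1
  res2 <- overrepresentation(rows, sample = "expanded",
                             success = "conserved",
                             background = "conserved")
  expect_identical(res2$urn[["K"]], res2$urn[["N"]])
  expect_identical(res2$urn[["k"]], res2$urn[["n"]])
  expect_identical(res2$p, 1)
  expect_error(overrepresentation(rows, "expanded", "expanded",
                                  "count[A]>99"), "empty background")
  # empty sample: p = 1, fold missing
  res3 <- overrepresentation(rows, "count[A]>99", "expanded", "all")
  expect_identical(res3$p, 1)
  expect_true(is.na(res3$fold))
})
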