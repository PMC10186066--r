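#' Upper-tail hypergeometric probability
#'
#' For an urn with `N` objects of which `K` are successes, and a sample of
#' size `n` containing `k` observed successes, returns
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)` — the classic
#' over-representation p-value.
#'
#' For `N <= 1000` the tail is summed from exact binomial coefficients in
#' double precision with Kahan-compensated accumulation; above that the
#' terms are evaluated in log space via `lchoose` and combined with a
#' log-sum-exp, so the result is reproducible and stable at both scales.
#'
#' @param N Background size.
#' @param K Successes in background (`K <= N`).
#' @param n Sample size (`n <= N`).
#' @param k Observed successes in sample (`0 <= k <= min(K, n)`).
#' @return p-value in (0, 1]; vectorized over its arguments.
#' @export
hypergeom_sf <- function(N, K, n, k) {
  args <- cbind(N = N, K = K, n = n, k = k)  # recycles
  vapply(seq_len(nrow(args)), function(i) {
    hypergeom_sf_scalar(args[i, 1L], args[i, 2L], args[i, 3L], args[i, 4L])
  }, numeric(1))
}

hypergeom_sf_scalar <- function(N, K, n, k) {
  if (any(c(N, K, n, k) != round(c(N, K, n, k))) || N < 0) {
    stop("urn values must be non-negative integers")
  }
  if (K > N || n > N) stop("urn invariant violated: need K <= N and n <= N")
  if (k < 0 || k > min(K, n)) {
    stop("urn invariant violated: need 0 <= k <= min(K, n)")
  }
  lo <- max(0, n + K - N)  # smallest achievable success count
  if (k <= lo) return(1)
  i <- k:min(K, n)
  if (N <= 1000) {
    terms <- choose(K, i) * choose(N - K, n - i)
    # Kahan-compensated summation keeps the tail exact at small N
    s <- 0
    c_ <- 0
    for (t in terms) {
      y <- t - c_
      tmp <- s + y
      c_ <- (tmp - s) - y
      s <- tmp
    }
    p <- s / choose(N, n)
  } else {
    lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(lt)
    p <- exp(m) * sum(exp(lt - m))
  }
  min(max(p, 0), 1)
}

#' One-sided Fisher exact test on the urn's 2x2 table
#'
#' The one-sided (greater) Fisher exact test of the contingency table
#' implied by the urn is the same tail probability as [hypergeom_sf()]; this
#' route computes it through R's hypergeometric CDF and serves as an
#' independent formulation for cross-checking.
#'
#' @inheritParams hypergeom_sf
#' @return p-value in (0, 1]; vectorized.
#' @export
fisher_one_sided <- function(N, K, n, k) {
  bad <- K > N | n > N | k < 0 | k > pmin(K, n)
  if (any(bad)) stop("urn invariant violated")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Fisher exact test on the urn
#'
#' @inheritParams hypergeom_sf
#' @return Two-sided p-value (via [stats::fisher.test()]).
#' @export
fisher_two_sided <- function(N, K, n, k) {
  mapply(function(N, K, n, k) {
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2L)
    if (any(tab < 0)) stop("urn invariant violated")
    stats::fisher.test(tab)$p.value
  }, N, K, n, k)
}

#' Parse a compact OG-set predicate
#'
#' A predicate is a conjunction of atoms joined by `&`.  Atoms:
#' \describe{
#'   \item{`expanded`}{the OG's expansion call is TRUE}
#'   \item{`conserved`}{>= 1 gene from every hypothesis species}
#'   \item{`deg[Species] >= m`}{significant-DEG count in a species
#'     (operators `>=`, `>`, `<=`, `<`, `==`/`=`)}
#'   \item{`count[Species] > c`}{gene count in a species (same operators)}
#'   \item{`any_deg >= m`}{some species has a DEG count satisfying the
#'     comparison}
#'   \item{`all` / `true`}{every OG}
#' }
#' Example: `"expanded & deg[Hordeum_vulgare]>=1"`.
#'
#' @param text Predicate string.
#' @return A function mapping an OG summary `data.frame` (see
#'   [summarize_ogs()]) to a logical vector.
#' @export
parse_predicate <- function(text) {
  atoms <- trimws(strsplit(text, "&", fixed = TRUE)[[1L]])
  atoms <- atoms[nzchar(atoms)]
  if (!length(atoms)) stop("empty predicate: '", text, "'")
  fns <- lapply(atoms, parse_atom)
  function(rows) {
    out <- rep(TRUE, nrow(rows))
    for (f in fns) out <- out & f(rows)
    out
  }
}

parse_atom <- function(atom) {
  cmp_fn <- function(op) switch(op,
    ">=" = `>=`, ">" = `>`, "<=" = `<=`, "<" = `<`,
    "==" = `==`, "=" = `==`,
    stop("unknown comparison operator: ", op))
  if (atom %in% c("expanded", "conserved")) {
    col <- atom
    return(function(rows) {
      if (!col %in% names(rows)) stop("summary table has no '", col, "' column")
      as.logical(rows[[col]])
    })
  }
  if (atom %in% c("all", "true", "TRUE")) {
    return(function(rows) rep(TRUE, nrow(rows)))
  }
  m <- regmatches(atom,
    regexec("^(deg|count)\\[([^]]+)\\]\\s*(>=|<=|==|=|>|<)\\s*(-?[0-9.]+)$",
            atom))[[1L]]
  if (length(m)) {
    col <- paste0(m[[2L]], "_", m[[3L]])
    op <- cmp_fn(m[[4L]])
    val <- as.numeric(m[[5L]])
    return(function(rows) {
      if (!col %in% names(rows)) {
        stop("summary table has no '", col, "' column (unknown species?)")
      }
      op(rows[[col]], val)
    })
  }
  m <- regmatches(atom,
    regexec("^any_deg\\s*(>=|<=|==|=|>|<)\\s*(-?[0-9.]+)$", atom))[[1L]]
  if (length(m)) {
    op <- cmp_fn(m[[2L]])
    val <- as.numeric(m[[3L]])
    return(function(rows) {
      cols <- grep("^deg_", names(rows), value = TRUE)
      if (!length(cols)) stop("summary table has no deg_ columns")
      hit <- rep(FALSE, nrow(rows))
      for (cl in cols) hit <- hit | op(rows[[cl]], val)
      hit
    })
  }
  stop("cannot parse predicate atom: '", atom, "'")
}

as_predicate <- function(x) {
  if (is.function(x)) x else parse_predicate(x)
}

#' Over-representation of one OG set within another
#'
#' Builds the hypergeometric urn from three predicates evaluated over an OG
#' summary table: the background defines the urn (`N`), the success
#' predicate marks successes within it (`K`), and the sample predicate —
#' always intersected with the background — draws the sample (`n`) with its
#' observed successes (`k`).  The four ring counts for an urn-model plot are
#' returned along with the one-sided p-value and the fold enrichment
#' `(k/n) / (K/N)`.
#'
#' @param rows OG summary `data.frame` (see [summarize_ogs()]).
#' @param sample,success,background Predicate strings or functions (see
#'   [parse_predicate()]).
#' @param two_sided Also report the two-sided Fisher p.
#' @return List with urn (N, K, n, k), p, fold (NA when n or K is 0),
#'   p_two_sided (optional), rings (named counts for plotting).
#' @export
overrepresentation <- function(rows, sample, success, background = "all",
                               two_sided = FALSE) {
  bg <- as_predicate(background)(rows)
  if (!any(bg)) stop("empty background set")
  sc <- as_predicate(success)(rows) & bg
  sm <- as_predicate(sample)(rows) & bg
  N <- sum(bg)
  K <- sum(sc)
  n <- sum(sm)
  k <- sum(sc & sm)
  p <- if (n == 0L) 1 else hypergeom_sf(N, K, n, k)
  fold <- if (n == 0L || K == 0L) NA_real_ else (k / n) / (K / N)
  out <- list(urn = c(N = N, K = K, n = n, k = k), p = p, fold = fold,
              rings = c(complete_background = N, success_in_background = K,
                        sample_size = n, success_in_sample = k))
  if (two_sided) out$p_two_sided <- fisher_two_sided(N, K, n, k)
  out
}
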