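#' Euclidean distance matrix
#'
#' Pairwise Euclidean distances among observations (rows). The distance layer
#' feeding the permutational ANOVA; all pipeline responses are scalar or
#' real-valued, for which Euclidean distance is the appropriate metric
#' (signed values rule out ecological dissimilarities like Bray-Curtis).
#'
#' @param x numeric vector (univariate) or matrix/data.frame (observations in
#'   rows). All values must be finite.
#' @return a `dist` object with attribute `metric = "euclidean"`.
#' @export
euclidean_dist <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) stop("non-finite values in input")
  if (nrow(x) < 2L) stop("need at least 2 observations")
  d <- stats::dist(x, method = "euclidean")
  attr(d, "metric") <- "euclidean"
  d
}

as_d2 <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance input must be square or a dist object")
  if (any(abs(diag(m)) > 0)) stop("distance matrix must have a zero diagonal")
  if (any(m < 0)) stop("distances must be non-negative")
  if (any(abs(m - t(m)) > 1e-8 * (1 + max(m)))) stop("distance matrix must be symmetric")
  m^2
}

# number of distinct arrangements of a label multiset
n_arrangements <- function(counts) {
  exp(lfactorial(sum(counts)) - sum(lfactorial(counts)))
}

# all distinct arrangements of integer codes 1..a with the given counts,
# returned as an n x N matrix (columns are arrangements)
multiset_arrangements <- function(counts) {
  n <- sum(counts)
  rec <- function(counts, n) {
    if (n == 0L) return(matrix(integer(0), nrow = 0, ncol = 1))
    blocks <- lapply(which(counts > 0L), function(g) {
      cnt <- counts
      cnt[g] <- cnt[g] - 1L
      sub <- rec(cnt, n - 1L)
      rbind(matrix(g, 1L, ncol(sub)), sub)
    })
    do.call(cbind, blocks)
  }
  rec(as.integer(counts), as.integer(n))
}

# B distinct random arrangements (columns, integer codes), rejection-sampling
# duplicates; excludes nothing - the observed order may occur by chance
sample_unique_arrangements <- function(codes, B) {
  n <- length(codes)
  draw <- function(m) {
    vapply(seq_len(m), function(i) codes[sample.int(n)], integer(n))
  }
  arr <- draw(B)
  keys <- apply(arr, 2L, paste, collapse = ",")
  for (iter in 1:100) {
    dup <- duplicated(keys)
    if (!any(dup)) break
    repl <- draw(sum(dup))
    arr[, dup] <- repl
    keys[dup] <- apply(repl, 2L, paste, collapse = ",")
  }
  arr
}

# pseudo-F for every column of an arrangement matrix, vectorized.
# D2: squared distances; arr: n x M integer codes; counts: group sizes
pseudo_f_cols <- function(D2, arr, counts) {
  n <- nrow(D2)
  a <- length(counts)
  ss_total <- sum(D2) / (2 * n)
  ss_w <- numeric(ncol(arr))
  for (g in seq_len(a)) {
    Z <- (arr == g) + 0
    ss_w <- ss_w + colSums(Z * (D2 %*% Z)) / (2 * counts[g])
  }
  ss_b <- ss_total - ss_w
  list(F = (ss_b / (a - 1)) / (ss_w / (n - a)),
       ss_total = ss_total, ss_between = ss_b, ss_within = ss_w)
}

#' Permutational analysis of variance on a distance matrix
#'
#' Distance-based (pseudo-F) ANOVA tested by permutation of group labels.
#' Sums of squares are partitioned on the matrix of squared dissimilarities
#' (equivalently on the Gower-centered inner-product matrix
#' \eqn{G = -\tfrac12 C \Delta^2 C}); for a single factor,
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n} and
#' \eqn{F = (SS_B/(a-1)) / (SS_W/(n-a))}. With univariate Euclidean input the
#' pseudo-F is numerically identical to the classical one-way ANOVA F.
#'
#' The permutation p-value uses the "+1" convention,
#' \eqn{p = (\#\{F^\pi \ge F\} + 1)/(B + 1)}, and honors unique permutations:
#' when the number of distinct label arrangements is below `10 * permutations`
#' the null is enumerated exhaustively (p is then an exact fraction of the
#' full arrangement space), otherwise `permutations` distinct arrangements
#' are drawn by rejection sampling.
#'
#' Multi-factor designs: pass a data.frame whose columns are factors; terms
#' are added sequentially (Type-I sums of squares via the McArdle-Anderson
#' projection-trace formulation) and tested by free permutation of rows - an
#' approximation to reduced-model residual permutation.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param groups a factor (single-factor test) or a data.frame of factors
#'   (sequential multi-factor test).
#' @param permutations requested number of permutations B (default 999).
#' @param seed optional integer seed for the permutation RNG.
#' @return object of class `permanova`: a results table `tab` (term, df, SS,
#'   R2, pseudo-F, p), plus `n_perm`, `method` ("exhaustive" or
#'   "unique-sampled"), and `degenerate`.
#' @examples
#' d <- euclidean_dist(c(1, 2, 3, 4, 5, 6))
#' permanova(d, factor(rep(c("a", "b"), each = 3)))
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL) {
  stopifnot(permutations >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(groups)) {
    return(permanova_terms(d, groups, permutations))
  }
  groups <- droplevels(as.factor(groups))
  D2 <- as_d2(d)
  n <- nrow(D2)
  if (length(groups) != n) stop("groups length must match distance matrix")
  counts <- as.integer(table(groups))
  a <- length(counts)
  if (a < 2L) stop("need at least 2 groups")
  codes <- as.integer(groups)

  obs <- pseudo_f_cols(D2, matrix(codes, ncol = 1), counts)
  ss_total <- obs$ss_total
  degenerate <- ss_total <= .Machine$double.eps * n
  tol <- 1e-12 * max(1, abs(obs$F))

  if (degenerate) {
    f_obs <- 0
    p <- 1
    n_perm <- 0L
    method <- "degenerate"
  } else {
    f_obs <- obs$F
    n_arr <- n_arrangements(counts)
    if (n_arr < 10 * permutations) {
      arr <- multiset_arrangements(counts)
      # map enumerated code patterns onto the observed ordering of units:
      # arrangements are over sorted codes; relabel to the observed multiset
      perm_f <- pseudo_f_cols(D2, arr, counts)$F
      p <- sum(perm_f >= f_obs - tol) / ncol(arr)
      n_perm <- ncol(arr)
      method <- "exhaustive"
    } else {
      arr <- sample_unique_arrangements(codes, permutations)
      perm_f <- pseudo_f_cols(D2, arr, counts)$F
      p <- (sum(perm_f >= f_obs - tol) + 1) / (permutations + 1)
      n_perm <- permutations
      method <- "unique-sampled"
    }
  }

  ss_b <- if (degenerate) 0 else obs$ss_between
  ss_w <- ss_total - ss_b
  tab <- data.frame(
    term = c("groups", "Residual", "Total"),
    df = c(a - 1L, n - a, n - 1L),
    SS = c(ss_b, ss_w, ss_total),
    R2 = c(if (ss_total > 0) ss_b / ss_total else 0,
           if (ss_total > 0) ss_w / ss_total else 0, 1),
    pseudo_F = c(f_obs, NA, NA),
    p_perm = c(p, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(
    list(tab = tab, n = n, n_perm = n_perm, method = method,
         degenerate = degenerate, pseudo_F = f_obs, R2 = tab$R2[1],
         p_perm = p),
    class = "permanova"
  )
}

# sequential (Type-I) multi-factor distance-based ANOVA via projection traces
permanova_terms <- function(d, groups, permutations) {
  D2 <- as_d2(d)
  n <- nrow(D2)
  stopifnot(nrow(groups) == n)
  A <- -0.5 * D2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)

  terms <- names(groups)
  X <- matrix(1, n, 1)
  H_prev <- tcrossprod(rep(1 / sqrt(n), n))
  Ps <- list(); dfs <- integer(0)
  for (tm in terms) {
    X <- cbind(X, stats::model.matrix(~f, data.frame(f = factor(groups[[tm]])))[, -1, drop = FALSE])
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    H <- tcrossprod(Q)
    Ps[[tm]] <- H - H_prev
    dfs[tm] <- as.integer(qrX$rank - round(sum(diag(H_prev))))
    H_prev <- H
  }
  R <- diag(n) - H_prev
  df_res <- n - as.integer(round(sum(diag(H_prev))))
  if (df_res <= 0) stop("no residual degrees of freedom")

  ss_term <- vapply(Ps, function(P) sum(P * G), numeric(1))
  ss_res <- sum(R * G)
  ss_total <- sum(diag(G))
  f_obs <- (ss_term / dfs) / (ss_res / df_res)

  perm_count <- matrix(0, length(terms), 1)
  keys <- character(permutations)
  counts_f <- numeric(length(terms))
  seen <- new.env(hash = TRUE)
  b <- 0L; guard <- 0L
  while (b < permutations && guard < 100 * permutations) {
    guard <- guard + 1L
    p <- sample.int(n)
    key <- paste(p, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    b <- b + 1L
    Gp <- G[p, p]
    ss_res_p <- sum(R * Gp)
    fp <- (vapply(Ps, function(P) sum(P * Gp), numeric(1)) / dfs) /
      (ss_res_p / df_res)
    counts_f <- counts_f + (fp >= f_obs - 1e-12 * pmax(1, abs(f_obs)))
  }
  p_perm <- (counts_f + 1) / (b + 1)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(ss_term, ss_res, ss_total),
    R2 = c(ss_term, ss_res, ss_total) / ss_total,
    pseudo_F = c(f_obs, NA, NA),
    p_perm = c(p_perm, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(
    list(tab = tab, n = n, n_perm = b, method = "unique-sampled",
         degenerate = FALSE, pseudo_F = f_obs[1], R2 = tab$R2[1],
         p_perm = p_perm[1]),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutational ANOVA on a distance matrix\n")
  cat(sprintf("Permutations: %d (%s)\n", x$n_perm, x$method))
  if (x$degenerate) cat("Note: degenerate input (zero total sum of squares)\n")
  tab <- x$tab
  tab$SS <- signif(tab$SS, 6)
  tab$R2 <- round(tab$R2, 5)
  tab$pseudo_F <- signif(tab$pseudo_F, 6)
  print(tab, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Pairwise permutational ANOVA with Bonferroni correction
#'
#' One single-factor [permanova()] per unordered pair of group levels on the
#' corresponding sub-matrix of distances; p-values are Bonferroni-adjusted
#' over the number of pairs (`p_adj = min(1, p * m)`).
#'
#' @inheritParams permanova
#' @return data.frame of class `pairwise_permanova`: one row per pair with
#'   `pseudo_F`, `R2`, `p_perm`, `p_adj`, `n_perm`, `method`.
#' @export
pairwise_permanova <- function(d, groups, permutations = 999, seed = NULL) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  D <- as.matrix(d)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    keep <- groups %in% pairs[, k]
    fit <- permanova(D[keep, keep, drop = FALSE], droplevels(groups[keep]),
                     permutations = permutations)
    data.frame(
      group1 = pairs[1, k], group2 = pairs[2, k],
      pseudo_F = fit$pseudo_F, R2 = fit$R2, p_perm = fit$p_perm,
      n_perm = fit$n_perm, method = fit$method, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$p_adj <- pmin(1, res$p_perm * m)
  class(res) <- c("pairwise_permanova", "data.frame")
  res
}

#' Kruskal-Wallis rank-sum test with tie correction and exact small-sample p
#'
#' The H statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - (N+1)/2)^2}
#' divided by the tie-correction factor \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)}.
#' The p-value uses the chi-squared approximation with `groups - 1` degrees
#' of freedom; for pooled N of at most `exact_limit` the exact permutation
#' null (every distinct assignment of the observed values to the group
#' sizes) is also enumerated and reported as `p_exact`. The chi-squared
#' approximation is known to be unreliable at such sizes, which is why both
#' are returned.
#'
#' @param x numeric vector of observations, or a list of numeric group
#'   vectors (then `g` is ignored).
#' @param g group factor, parallel to `x`.
#' @param exact_limit largest pooled N for which the exact null is enumerated.
#' @return object of class `kw_test`: `H`, `df`, `p_chi2`, `p_exact` (NA when
#'   not enumerated), `tie_correction`, `n`, `degenerate`.
#' @export
kruskal_wallis <- function(x, g = NULL, exact_limit = 10) {
  if (is.list(x) && !is.data.frame(x)) {
    g <- factor(rep(seq_along(x), lengths(x)))
    x <- unlist(x, use.names = FALSE)
  }
  stopifnot(is.numeric(x))
  g <- droplevels(as.factor(g))
  if (length(g) != length(x)) stop("x and g must have the same length")
  counts <- as.integer(table(g))
  if (any(counts == 0L)) stop("empty group")
  a <- length(counts)
  if (a < 2L) stop("need at least 2 groups")
  N <- length(x)
  if (N < 3L) stop("need at least 3 observations")

  r <- rank(x)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h_of <- function(codes_mat) {
    # codes_mat: N x M arrangements of group codes
    h <- numeric(ncol(codes_mat))
    for (gg in seq_len(a)) {
      rbar <- colSums((codes_mat == gg) * r) / counts[gg]
      h <- h + counts[gg] * (rbar - (N + 1) / 2)^2
    }
    12 / (N * (N + 1)) * h
  }
  degenerate <- tie_corr <= 0
  H <- if (degenerate) 0 else h_of(matrix(as.integer(g), ncol = 1)) / tie_corr

  p_exact <- NA_real_
  if (!degenerate && N <= exact_limit) {
    arr <- multiset_arrangements(counts)
    h_all <- h_of(arr) / tie_corr
    p_exact <- sum(h_all >= H - 1e-12 * max(1, H)) / ncol(arr)
  }
  structure(
    list(H = as.numeric(H), df = a - 1L,
         p_chi2 = if (degenerate) 1 else stats::pchisq(H, a - 1L, lower.tail = FALSE),
         p_exact = p_exact, tie_correction = tie_corr, n = N,
         group_sizes = counts, degenerate = degenerate),
    class = "kw_test"
  )
}

#' @export
print.kw_test <- function(x, ...) {
  cat("Kruskal-Wallis rank-sum test (tie-corrected)\n")
  cat(sprintf("  H = %.4f, df = %d, p (chi-squared) = %.4g\n",
              x$H, x$df, x$p_chi2))
  if (!is.na(x$p_exact)) {
    cat(sprintf("  exact permutation p (N = %d) = %.4g\n", x$n, x$p_exact))
  }
  if (x$degenerate) cat("  note: all values tied; statistic degenerate\n")
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite (possibly
#' fractional) degrees of freedom and a two-sided p from the t distribution.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return object of class `welch_t`: `t`, `df`, `p`, group means, and a
#'   `degenerate` flag (both samples constant and equal).
#' @export
welch_t <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  se2 <- va + vb
  degenerate <- se2 == 0
  if (degenerate) {
    tt <- if (mean(a) == mean(b)) NaN else sign(mean(a) - mean(b)) * Inf
    df <- NA_real_
    p <- if (is.nan(tt)) NA_real_ else 0
  } else {
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  structure(
    list(t = tt, df = df, p = p, mean_a = mean(a), mean_b = mean(b),
         degenerate = degenerate),
    class = "welch_t"
  )
}

#' @export
print.welch_t <- function(x, ...) {
  cat("Welch two-sample t-test\n")
  cat(sprintf("  t = %.4f, df = %.3f, two-sided p = %.4g\n", x$t, x$df, x$p))
  if (x$degenerate) cat("  note: zero variance in both samples\n")
  invisible(x)
}
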