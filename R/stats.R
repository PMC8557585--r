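# Statistics layer: group summaries, exact Wilcoxon rank-sum, exact /
# permutation Spearman correlation, rank-based partial correlation.
# Exact small-sample behaviour matters here: the motivating cohorts have
# n = 16 with groups of 13 and 3.

stat_result <- function(statistic, p_value, method, n_used,
                        missing_excluded, estimate = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value,
                 estimate = estimate, method = method,
                 n_used = as.integer(n_used),
                 missing_excluded = as.integer(missing_excluded)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic=%s estimate=%s p=%s (n=%d, excluded=%d)\n",
              x$method, format(x$statistic, digits = 5),
              format(x$estimate, digits = 5),
              format(x$p_value, digits = 4), x$n_used, x$missing_excluded))
  invisible(x)
}

#' Per-group summary statistics
#'
#' Mean, sample SD (n-1 denominator), median, min and max of a numeric
#' outcome per group label.  Groups with a single observation report
#' `NA` for the SD; empty groups yield a flagged all-`NA` row.
#'
#' @param values numeric vector (may contain `NA`, which are dropped).
#' @param labels factor/character vector of group labels, same length.
#' @return data.frame with one row per group level:
#'   `label, n, mean, sd, median, min, max`.
#' @export
group_summary <- function(values, labels) {
  labels <- as.factor(labels)
  out <- lapply(levels(labels), function(lv) {
    v <- values[labels == lv & !is.na(values)]
    if (!length(v)) {
      return(data.frame(label = lv, n = 0L, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, min = NA_real_, max = NA_real_))
    }
    data.frame(label = lv, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = stats::median(v), min = min(v), max = max(v))
  })
  do.call(rbind, out)
}

# rank-sum statistic over all C(N, n1) group assignments of the pooled
# mid-ranks; feasible up to N ~ 20 (C(20,10) = 184756)
wilcoxon_enumerate <- function(r, n1) {
  idx <- utils::combn(length(r), n1)
  colSums(matrix(r[idx], nrow = n1))
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test using mid-ranks for
#' ties.  In `exact` mode (the default for `n1 + n2 <= 20`) the p-value
#' is computed by full enumeration of all `choose(n1 + n2, n1)` group
#' assignments of the pooled ranks, so the permutation distribution
#' respects ties exactly.  Above that, a normal approximation with
#' tie-corrected variance and continuity correction is used.  The
#' two-sided p-value is `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return a `stat_result` with the rank-sum statistic of `x`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  miss <- sum(is.na(x)) + sum(is.na(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) vq_stop("both samples must be non-empty",
                                "vq_input_error")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (mode == "auto") mode <- if (n <= 20) "exact" else "normal"
  if (mode == "exact") {
    perm <- wilcoxon_enumerate(r, n1)
    eps <- 1e-9
    p_lo <- mean(perm <= w + eps)
    p_hi <- mean(perm >= w - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(stat_result(w, p, "wilcoxon_exact", n, miss))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  stat_result(w, p, "wilcoxon_normal", n, miss)
}

# all permutations of 1..n as an n! x n matrix (used for exact Spearman,
# n <= 8)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[p], nrow(p)))
  }))
}

spearman_r <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman rank correlation with exact or permutation p-value
#'
#' `r` is the Pearson correlation of the mid-ranks.  The two-sided
#' p-value is the permutation probability of `|r|` at least as large as
#' observed: full `n!` enumeration for `n <= 8`, seeded Monte-Carlo
#' permutation (100,000 draws, internal seed 20210) for `8 < n <= 20`,
#' and the t approximation (`t = r * sqrt((n-2)/(1-r^2))`, `n - 2` df)
#' above that or on request.  Pairs with a missing member are dropped.
#'
#' @param x,y paired numeric vectors.
#' @param mode `"auto"`, `"exact"`, `"mc"` or `"t_approx"`.
#' @param mc_draws Monte-Carlo permutation count for `"mc"` mode.
#' @return a `stat_result`; `estimate` is `r`.  Zero rank variance in
#'   either variable yields a flagged result with `NA` estimate.
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$estimate  # 0.6
#' @export
spearman_cor <- function(x, y, mode = c("auto", "exact", "mc", "t_approx"),
                         mc_draws = 1e5) {
  mode <- match.arg(mode)
  ok <- !is.na(x) & !is.na(y)
  miss <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    return(stat_result(NA_real_, NA_real_, "spearman_undefined", n, miss))
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(stat_result(NA_real_, NA_real_, "spearman_undefined", n, miss))
  }
  r <- stats::cor(rx, ry)
  if (mode == "auto") {
    mode <- if (n <= 8) "exact" else if (n <= 20) "mc" else "t_approx"
  }
  eps <- 1e-12
  if (mode == "exact") {
    perms <- permutations_of(n)
    xs <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    ys <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    r_perm <- as.vector(matrix(ys[perms], nrow(perms)) %*% xs)
    p <- mean(abs(r_perm) >= abs(r) - eps)
    return(stat_result(r, p, "spearman_exact", n, miss, estimate = r))
  }
  if (mode == "mc") {
    xs <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    ys <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    hits <- with_seed(20210, {
      idx <- vapply(seq_len(mc_draws), function(b) sample.int(n), integer(n))
      r_perm <- colSums(matrix(ys[idx], n) * xs)
      sum(abs(r_perm) >= abs(r) - eps)
    })
    p <- (1 + hits) / (1 + mc_draws)
    return(stat_result(r, p, "spearman_mc", n, miss, estimate = r))
  }
  tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  p <- min(1, 2 * stats::pt(-abs(tt), n - 2))
  stat_result(tt, p, "spearman_t", n, miss, estimate = r)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables (mid-ranks), then computes the partial
#' Pearson correlation of the ranks of `x` and `y` given the covariate
#' ranks through the inverse of the joint correlation matrix.  The
#' p-value uses the t approximation with `n - 2 - k` degrees of freedom
#' (`k` covariates).
#'
#' @param x,y paired numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @return a `stat_result`; `estimate` is the partial rank correlation.
#'   A singular rank correlation matrix (e.g. a covariate identical to
#'   `y`) yields a flagged result with `NA` estimate.
#' @export
partial_spearman <- function(x, y, covariates) {
  z <- as.matrix(covariates)
  k <- ncol(z)
  ok <- !is.na(x) & !is.na(y) & stats::complete.cases(z)
  miss <- sum(!ok)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  if (n < 4 + k) {
    return(stat_result(NA_real_, NA_real_, "partial_spearman_undefined",
                       n, miss))
  }
  rmat <- cbind(rank(x), rank(y), apply(z, 2, rank))
  if (any(apply(rmat, 2, stats::sd) == 0)) {
    return(stat_result(NA_real_, NA_real_, "partial_spearman_undefined",
                       n, miss))
  }
  cm <- stats::cor(rmat)
  df <- n - 2 - k
  # x and y rank-identical (up to sign): residuals given any
  # non-collinear covariates coincide, so the partial correlation is +/-1
  if (abs(cm[1, 2]) >= 1 - 1e-12) {
    zcor <- cm[1, -(1:2)]
    if (all(abs(zcor) < 1 - 1e-12)) {
      return(stat_result(sign(cm[1, 2]) * Inf, 0, "partial_spearman",
                         n, miss, estimate = sign(cm[1, 2])))
    }
  }
  pinv <- tryCatch(solve(cm), error = function(e) NULL)
  if (is.null(pinv)) {
    return(stat_result(NA_real_, NA_real_, "partial_spearman_undefined",
                       n, miss))
  }
  denom <- pinv[1, 1] * pinv[2, 2]
  if (denom <= 0 || !is.finite(denom)) {
    return(stat_result(NA_real_, NA_real_, "partial_spearman_undefined",
                       n, miss))
  }
  r <- -pinv[1, 2] / sqrt(denom)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
    tt <- sign(r) * Inf
  } else {
    tt <- r * sqrt(df / (1 - r^2))
    p <- min(1, 2 * stats::pt(-abs(tt), df))
  }
  stat_result(tt, p, "partial_spearman", n, miss, estimate = r)
}

#' Cross-modality Spearman correlation table
#'
#' One Spearman correlation per (SMI parameter, CD34 parameter) pair
#' with pairwise deletion of missing values -- the cross-modality
#' correlation matrix layout.  Raw (unadjusted) p-values are reported;
#' no multiple-testing correction is applied.
#'
#' @param data data.frame holding all named columns.
#' @param smi_params character vector of SMI parameter column names
#'   (default: the ten profile fields).
#' @param cd34_params character vector of CD34 column names.
#' @param mode p-value mode passed to [spearman_cor()].
#' @return list with matrices `r`, `p` and `n`
#'   (rows = SMI parameters, columns = CD34 parameters); cells with
#'   fewer than 3 complete pairs or zero rank variance are `NA`.
#' @export
correlation_table <- function(data,
                              smi_params = profile_fields,
                              cd34_params = c("cd34_100_fold",
                                              "cd34_25_fold", "cd34_all"),
                              mode = "auto") {
  if (!nrow(data)) vq_stop("empty cohort", "vq_input_error")
  rmat <- matrix(NA_real_, length(smi_params), length(cd34_params),
                 dimnames = list(smi_params, cd34_params))
  pmat <- rmat
  nmat <- matrix(0L, length(smi_params), length(cd34_params),
                 dimnames = dimnames(rmat))
  for (i in seq_along(smi_params)) {
    for (j in seq_along(cd34_params)) {
      res <- spearman_cor(data[[smi_params[i]]], data[[cd34_params[j]]],
                          mode = mode)
      rmat[i, j] <- res$estimate
      pmat[i, j] <- res$p_value
      nmat[i, j] <- res$n_used
    }
  }
  list(r = rmat, p = pmat, n = nmat)
}
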