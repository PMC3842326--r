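#' Wilson score confidence interval for a binomial proportion
#'
#' The score-based interval has good coverage at the small per-species
#' sample sizes typical of barcode evaluation, where every species is one
#' independent binomial trial.
#'
#' @param k number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level.
#' @return A list of class `wilson_ci`: `k`, `n`, `level`, `estimate`
#'   (`k/n`), `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(list(k = k, n = n, level = level, estimate = p,
                 lower = max(0, centre - half),
                 upper = min(1, centre + half)),
            class = "wilson_ci")
}

#' Scheffé simultaneous pairwise contrasts
#'
#' All pairwise group contrasts protected by Scheffé's simultaneous
#' criterion: a contrast is significant at level `alpha` when its squared
#' standardised difference exceeds `(g - 1) F(1 - alpha; g - 1, df2)`.
#' Gaussian mode takes raw numeric samples per group and uses the pooled
#' within-group variance (`df2 = N - g`). Binomial mode takes `(k, n)`
#' pairs per group — e.g. species discriminated out of species tested —
#' and uses normal-approximation variances `p(1-p)/n` (`df2 = Inf`).
#'
#' @param groups named list: numeric vectors (gaussian) or length-2
#'   vectors `c(k, n)` (binomial).
#' @param distribution `"gaussian"` or `"binomial"`.
#' @param alpha significance level.
#' @return data.frame, one row per pair: `group1`, `group2`, `estimate`
#'   (difference of means/proportions), `statistic` (the F-scaled
#'   contrast), `p_value`, `significant`.
#' @export
scheffe_test <- function(groups, distribution = c("gaussian", "binomial"),
                         alpha = 0.05) {
  distribution <- match.arg(distribution)
  g <- length(groups)
  if (g < 2) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(g))

  if (distribution == "gaussian") {
    sizes <- lengths(groups)
    if (any(sizes < 1)) stop("empty group")
    means <- vapply(groups, mean, numeric(1))
    N <- sum(sizes)
    df2 <- N - g
    sse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
    if (df2 <= 0 || sse == 0) {
      stop("degenerate gaussian input: pooled within-group variance is zero")
    }
    mse <- sse / df2
    var_of <- function(i) mse / sizes[i]
  } else {
    ks <- vapply(groups, `[`, numeric(1), 1)
    ns <- vapply(groups, `[`, numeric(1), 2)
    if (any(ns < 1)) stop("empty group")
    means <- ks / ns
    df2 <- Inf
    var_of <- function(i) means[i] * (1 - means[i]) / ns[i]
  }

  pairs <- utils::combn(g, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    v <- var_of(i) + var_of(j)
    est <- means[i] - means[j]
    f_stat <- if (v > 0) est^2 / v / (g - 1) else if (est == 0) 0 else Inf
    p <- stats::pf(f_stat, g - 1, df2, lower.tail = FALSE)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               estimate = est, statistic = f_stat, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation with a two-sided asymptotic test
#'
#' Ranks use average ranks for ties; the p-value uses the t transform
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list of class `cor_test_result`: `method`, `estimate` (rho),
#'   `statistic` (t), `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant vector: rank correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  t_p <- cor_t_test(rho, length(x))
  structure(list(method = "spearman", estimate = rho,
                 statistic = t_p[["t"]], p_value = t_p[["p"]],
                 n = length(x)),
            class = "cor_test_result")
}

#' Point-biserial correlation with a two-sided test
#'
#' Pearson correlation between a dichotomous (0/1 or logical) vector and a
#' numeric vector — e.g. presence of a barcode gap against individuals
#' sampled per species — with the usual t transform for the p-value.
#'
#' @param binary logical or 0/1 vector containing both classes.
#' @param numeric_ numeric vector, non-constant, same length.
#' @return A list of class `cor_test_result` (see [spearman_test()]).
#' @export
point_biserial <- function(binary, numeric_) {
  b <- as.numeric(binary)
  if (length(b) != length(numeric_)) stop("vectors differ in length")
  if (!all(b %in% c(0, 1))) stop("binary vector must be 0/1 or logical")
  if (length(unique(b)) < 2) stop("binary vector has a single class")
  if (length(unique(numeric_)) < 2) {
    stop("numeric vector is constant: correlation undefined")
  }
  r <- stats::cor(b, numeric_)
  t_p <- cor_t_test(r, length(b))
  structure(list(method = "point_biserial", estimate = r,
                 statistic = t_p[["t"]], p_value = t_p[["p"]],
                 n = length(b)),
            class = "cor_test_result")
}

#' @noRd
cor_t_test <- function(r, n) {
  if (abs(r) >= 1) return(c(t = sign(r) * Inf, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(t = t, p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
}

#' McNemar's test on discordant counts
#'
#' For paired binary outcomes (e.g. barcode gap versus discrimination
#' success per species) only the discordant cells `b` and `c` are
#' informative. Exact mode is the two-sided binomial test of `b` out of
#' `b + c` at probability 0.5 (doubled smaller tail, capped at 1; `p = 1`
#' when `b + c = 0`). Chi-squared mode is `(b - c)^2 / (b + c)` on 1 df,
#' without continuity correction.
#'
#' @param b,c discordant cell counts.
#' @param mode `"exact"` or `"chi2"`.
#' @return A list of class `mcnemar_result`: `b`, `c`, `mode`, `statistic`
#'   (`NA` for exact mode), `p_value`.
#' @export
mcnemar_test <- function(b, c, mode = c("exact", "chi2")) {
  mode <- match.arg(mode)
  if (b < 0 || c < 0) stop("counts must be non-negative")
  if (mode == "exact") {
    p <- if (b + c == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), b + c,
                                                         0.5))
    res <- list(b = b, c = c, mode = mode, statistic = NA_real_,
                p_value = p)
  } else {
    if (b + c == 0) stop("b + c = 0: chi-squared form undefined")
    stat <- (b - c)^2 / (b + c)
    res <- list(b = b, c = c, mode = mode, statistic = stat,
                p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
  }
  structure(res, class = "mcnemar_result")
}
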