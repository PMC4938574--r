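## Group-comparison statistics: one-way ANOVA, Tukey HSD post-hoc and
## two-sample t-tests, computed from sums of squares rather than delegated to
## model-fitting machinery. The studentized-range CDF backing the Tukey
## adjustment is evaluated here by 2-D Gauss-Legendre quadrature; base R's
## ptukey serves as an independent cross-check in the test suite only.

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  if (length(groups) < 2) stop_capmorph("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop_capmorph("every group needs at least 2 values")
  groups
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with (k - 1, N - k) degrees of freedom; the
#' p-value is the upper tail of the F distribution.
#'
#' @param groups named list of numeric vectors (one value per experimental
#'   unit, i.e. per animal), or a data.frame with columns `group`, `value`.
#' @return list of class `capmorph_test` with `statistic`, `df`, `p_value`
#'   and the decomposition (`ss_between`, `ss_within`).
#' @export
one_way_anova <- function(groups) {
  g <- as_group_list(groups)
  k <- length(g)
  n <- vapply(g, length, integer(1))
  N <- sum(n)
  means <- vapply(g, mean, numeric(1))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0 && ssb == 0)
    stop_capmorph("all observations identical: F undefined")
  df1 <- k - 1; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  p <- if (ssw == 0) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(method = "one-way ANOVA", statistic = f, df = c(df1, df2),
                 p_value = p, ss_between = ssb, ss_within = ssw,
                 group_means = means, group_n = n),
            class = "capmorph_test")
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise comparisons after a one-way ANOVA, adjusted with the
#' studentized-range distribution with parameters (k, N - k). Unequal group
#' sizes use the Tukey-Kramer standard error. All pairs are returned;
#' by convention figures display only the significant ones.
#'
#' @inheritParams one_way_anova
#' @param conf_level unused placeholder for interface stability.
#' @return list of class `capmorph_test`; `pairwise` is a data.frame with
#'   columns `group_a`, `group_b`, `mean_diff`, `q`, `adjusted_p`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  g <- as_group_list(groups)
  av <- one_way_anova(g)
  k <- length(g)
  n <- vapply(g, length, integer(1))
  N <- sum(n)
  mse <- av$ss_within / (N - k)
  means <- vapply(g, mean, numeric(1))
  prs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    i1 <- prs[1, j]; i2 <- prs[2, j]
    diff <- means[i2] - means[i1]
    se <- sqrt(mse / 2 * (1 / n[i1] + 1 / n[i2]))
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- if (is.infinite(q)) 0 else 1 - pstudrange(q, k, N - k)
    data.frame(group_a = names(g)[i1], group_b = names(g)[i2],
               mean_diff = diff, q = q, adjusted_p = min(max(p, 0), 1),
               stringsAsFactors = FALSE)
  })
  structure(list(method = "Tukey HSD", statistic = av$statistic, df = av$df,
                 p_value = av$p_value, pairwise = do.call(rbind, rows)),
            class = "capmorph_test")
}

#' Two-sample t-test
#'
#' Two-sided; pooled-variance by default, Welch optional. Two identical
#' constant samples give p = 1 by convention.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param welch use the Welch-Satterthwaite unequal-variance form.
#' @return list of class `capmorph_test`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2)
    stop_capmorph("each sample needs at least 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(structure(list(method = "t-test", statistic = 0,
                            df = na + nb - 2, p_value = 1),
                       class = "capmorph_test"))
    return(structure(list(method = "t-test", statistic = Inf * sign(mean(a) - mean(b)),
                          df = na + nb - 2, p_value = 0),
                     class = "capmorph_test"))
  }
  if (welch) {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  structure(list(method = if (welch) "Welch t-test" else "pooled t-test",
                 statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df)),
            class = "capmorph_test")
}

#' @export
print.capmorph_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n"); print(x$pairwise)
  }
  invisible(x)
}

## ---- studentized range distribution ----------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch.
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    bsub <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- bsub
    J[cbind(i + 1, i)] <- bsub
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    ord <- order(x)
    res <- list(x = x[ord], w = w[ord])
    cache[[key]] <<- res
    res
  }
})

gl_on <- function(a, b, n) {
  gl <- gauss_legendre(n)
  list(x = (b - a) / 2 * gl$x + (a + b) / 2, w = (b - a) / 2 * gl$w)
}

# P(range of k iid N(0,1) <= r): k * Integral phi(z) [Phi(z) - Phi(z-r)]^(k-1) dz
prange_normal <- function(r, k, n_nodes = 240L) {
  if (r <= 0) return(0)
  # z is the sample maximum; the phi(z) weight confines all mass to |z| < 8.5
  g <- gl_on(-8.5, 8.5, n_nodes)
  sum(g$w * k * stats::dnorm(g$x) *
        pmax(stats::pnorm(g$x) - stats::pnorm(g$x - r), 0)^(k - 1))
}

#' Studentized range CDF
#'
#' `P(Q <= q)` for the range of `k` independent standard normals divided by an
#' independent chi estimate of scale on `df` degrees of freedom, evaluated by
#' Gauss-Legendre quadrature over both the scale and range integrals
#' (absolute accuracy about 1e-6 for the k and df in routine use;
#' `df = Inf` reduces to the plain normal-range CDF).
#'
#' @param q quantile (scalar or vector).
#' @param k number of groups (>= 2).
#' @param df error degrees of freedom.
#' @return CDF values in `[0, 1]`.
#' @export
pstudrange <- function(q, k, df) {
  vapply(q, function(qi) {
    if (qi <= 0) return(0)
    if (!is.finite(df)) return(min(max(prange_normal(qi, k), 0), 1))
    # s = chi_df / sqrt(df); density g(s) ~ s^(df-1) exp(-df s^2 / 2)
    lcons <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
    smax <- 1 + 16 / sqrt(df)
    g <- gl_on(1e-8, smax, 240L)
    dens <- exp(lcons + (df - 1) * log(g$x) - df * g$x^2 / 2)
    inner <- vapply(g$x, function(s) prange_normal(qi * s, k), numeric(1))
    min(max(sum(g$w * dens * inner), 0), 1)
  }, numeric(1))
}

#' Studentized range quantile
#'
#' Inverse of [pstudrange()] by bisection to 1e-8 in `q`.
#'
#' @param p probability in (0, 1).
#' @param k number of groups.
#' @param df error degrees of freedom.
#' @return quantile `q` with `pstudrange(q, k, df) = p`.
#' @export
qstudrange <- function(p, k, df) {
  stopifnot(p > 0, p < 1)
  lo <- 0; hi <- 2
  while (pstudrange(hi, k, df) < p) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (pstudrange(mid, k, df) < p) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  (lo + hi) / 2
}

#' Permutation p-value for the one-way ANOVA F statistic
#'
#' Independent resampling oracle: relabels observations uniformly at random
#' and returns the fraction of permuted F statistics at least as large as the
#' observed one (with the +1 correction). Used to validate the parametric
#' ANOVA on small fixtures.
#'
#' @inheritParams one_way_anova
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `p_value`, `se` (binomial standard error) and the
#'   observed `statistic`.
#' @export
anova_permutation_p <- function(groups, n_perm = 2000L, seed = NULL) {
  g <- as_group_list(groups)
  obs <- one_way_anova(g)$statistic
  values <- unlist(g, use.names = FALSE)
  sizes <- vapply(g, length, integer(1))
  idx <- rep(seq_along(g), sizes)
  with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      perm <- split(values[sample.int(length(values))], idx)
      f <- one_way_anova(perm)$statistic
      if (f >= obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
    list(p_value = p, se = sqrt(p * (1 - p) / n_perm), statistic = obs)
  })
}
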