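#' Group summaries: mean and SEM across biological samples
#'
#' Technical replicates are first averaged within each sample, then the mean
#' and standard error of the mean (`SEM = sd / sqrt(n_samples)`) are computed
#' across samples, per group and covariate value. The unit of analysis is the
#' biological sample (animal), never the replicate, which prevents
#' pseudo-replication.
#'
#' @param data data frame with columns `group`, `sample`, `replicate`,
#'   a covariate column and a value column.
#' @param covariate name of the covariate column (e.g. `"t_min"` or
#'   `"r_over_R_mid"`).
#' @param value name of the value column.
#' @return Data frame: `group`, covariate, `mean`, `sem` (`NA` and flagged
#'   when only one sample), `n_samples`.
#' @export
summarize_group <- function(data, covariate, value) {
  stopifnot(all(c("group", "sample", "replicate", covariate, value) %in% names(data)))
  d <- data[is.finite(data[[value]]), , drop = FALSE]
  # replicate -> sample means
  sm <- stats::aggregate(d[[value]],
                         by = list(group = d$group, sample = d$sample,
                                   cov = d[[covariate]]),
                         FUN = mean)
  agg <- stats::aggregate(sm$x, by = list(group = sm$group, cov = sm$cov),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group = agg$group, cov = agg$cov,
                    mean = agg$x[, "mean"],
                    sem = agg$x[, "sd"] / sqrt(agg$x[, "n"]),
                    n_samples = as.integer(agg$x[, "n"]))
  names(out)[names(out) == "cov"] <- covariate
  out$sem_defined <- out$n_samples > 1L
  out$sem[!out$sem_defined] <- NA_real_
  out[order(out$group, out[[covariate]]), , drop = FALSE]
}

#' Exact two-tailed Mann-Whitney U test
#'
#' `U` is computed from midranks (average ranks for ties). For combined sample
#' sizes `n_x + n_y <= 24` the two-tailed p-value is exact, by full
#' enumeration of all `choose(n_x + n_y, n_x)` assignments of the pooled
#' values to the groups:
#' `p = Pr(|U - n_x n_y / 2| >= |U_obs - n_x n_y / 2|)`
#' (the reflection rule around the null mean, not doubling of one tail).
#' Larger samples fall back to the tie-corrected normal approximation and are
#' flagged `exact = FALSE`.
#'
#' @param x,y numeric vectors (unpaired groups).
#' @return List of class `muco_test`: `method`, `statistic` (U of `x`),
#'   `p_value`, `n`, `exact`.
#' @export
mann_whitney_exact <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty")
  n <- nx + ny
  r <- rank(c(x, y))                        # midranks
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= 24L) {
    rs <- utils::combn(n, nx, FUN = function(idx) sum(r[idx]))
    dev <- abs(rs - nx * (nx + 1) / 2 - mu)
    p <- mean(dev >= abs(u_obs - mu) - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(method = "mann_whitney", statistic = unname(u_obs),
                 p_value = p, n = c(nx = nx, ny = ny), exact = exact),
            class = "muco_test")
}

#' @export
print.muco_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (%s; n = %s)\n",
              x$method, x$statistic, x$p_value,
              if (isTRUE(x$exact)) "exact" else "asymptotic/approximate",
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom (via [stats::kruskal.test()]). When every pooled
#' value is identical the statistic is degenerate; `H = 0`, `p = 1` is
#' returned with a `degenerate` flag.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return A `muco_test` with fields `statistic` (H), `p_value`, `df`, `n`,
#'   `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(vals)) == 1L) {
    return(structure(list(method = "kruskal_wallis", statistic = 0,
                          p_value = 1, df = length(groups) - 1L,
                          n = lengths(groups), exact = FALSE,
                          degenerate = TRUE),
                     class = "muco_test"))
  }
  kt <- stats::kruskal.test(vals, g)
  structure(list(method = "kruskal_wallis",
                 statistic = unname(kt$statistic), p_value = kt$p.value,
                 df = unname(kt$parameter), n = lengths(groups),
                 exact = FALSE, degenerate = FALSE),
            class = "muco_test")
}

#' Two-sided Grubbs test for a single outlier
#'
#' `G = max |x_i - mean(x)| / sd(x)`; the p-value follows the standard
#' t-distribution relation for the two-sided single-outlier test,
#' `p = 2 n Pr(T_{n-2} > t)` with
#' `t^2 = (n - 2) g^2 / (1 - g^2)`, `g = G sqrt(n) / (n - 1)` (clipped to
#' `[0, 1]`).
#'
#' @param x numeric vector, `n >= 3`, non-constant.
#' @return A `muco_test` with `statistic` (G), `p_value`, `n`, and `outlier`
#'   (the most extreme value).
#' @export
grubbs_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("Grubbs test needs at least 3 values")
  s <- stats::sd(x)
  if (s == 0) stop("no variability: all values identical")
  dev <- abs(x - mean(x))
  g_stat <- max(dev) / s
  g <- g_stat * sqrt(n) / (n - 1)
  if (g >= 1) {
    p <- 0
  } else {
    t_val <- sqrt((n - 2) * g^2 / (1 - g^2))
    p <- min(1, 2 * n * stats::pt(t_val, df = n - 2, lower.tail = FALSE))
  }
  structure(list(method = "grubbs", statistic = g_stat, p_value = p,
                 n = n, exact = FALSE, outlier = x[which.max(dev)]),
            class = "muco_test")
}

#' Permutation test for a difference between two group curves
#'
#' Replicates are averaged within sample at each covariate value; the test
#' statistic is the maximum absolute two-sample t statistic across the shared
#' covariate grid, and the null distribution is generated by permuting
#' sample-level group labels (replicates travel with their sample). With
#' `n_perm` random permutations, `p = (1 + #(perm >= obs)) / (1 + n_perm)`;
#' when fewer distinct label assignments exist than `n_perm`, all of them are
#' enumerated instead and the test is flagged exhaustive.
#'
#' @param data data frame with `group` (exactly two levels), `sample`,
#'   `replicate`, a covariate column and a value column.
#' @param covariate,value column names, as in [summarize_group()].
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation draw.
#' @return A `muco_test` with `statistic` (max |t|), `p_value`, `n`
#'   (samples per group), `exact` (TRUE when exhaustive), `n_perm`.
#' @export
curve_permutation_test <- function(data, covariate, value, n_perm = 999L,
                                   seed = 1L) {
  stopifnot(all(c("group", "sample", covariate, value) %in% names(data)))
  groups <- unique(data$group)
  if (length(groups) != 2L) stop("curve permutation test needs exactly two groups")
  sm <- stats::aggregate(data[[value]],
                         by = list(group = data$group, sample = data$sample,
                                   cov = data[[covariate]]),
                         FUN = mean)
  wide <- stats::reshape(sm, idvar = c("group", "sample"), timevar = "cov",
                         direction = "wide")
  m <- as.matrix(wide[, -(1:2), drop = FALSE])
  lab <- wide$group == groups[1]
  n1 <- sum(lab); n2 <- sum(!lab)
  max_t <- function(sel) {
    a <- m[sel, , drop = FALSE]; b <- m[!sel, , drop = FALSE]
    va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
    sp <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    tt <- (colMeans(a) - colMeans(b)) / se
    tt[!is.finite(tt)] <- 0
    max(abs(tt))
  }
  obs <- max_t(lab)
  n_tot <- n1 + n2
  n_assign <- choose(n_tot, n1)
  if (n_assign <= n_perm) {
    idx <- utils::combn(n_tot, n1)
    perm <- apply(idx, 2, function(ii) {
      sel <- rep(FALSE, n_tot); sel[ii] <- TRUE; max_t(sel)
    })
    p <- mean(perm >= obs - 1e-12)
    exact <- TRUE; n_used <- n_assign
  } else {
    perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(k) {
      max_t(sample(n_tot) <= n1)
    }, numeric(1)))
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    exact <- FALSE; n_used <- n_perm
  }
  structure(list(method = "curve_permutation", statistic = obs, p_value = p,
                 n = c(n1 = n1, n2 = n2), exact = exact, n_perm = n_used),
            class = "muco_test")
}

# Evaluate `expr` under a private Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
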