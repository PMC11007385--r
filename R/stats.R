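# Nonparametric feature-screening statistics, implemented from their
# standard formulas (rank sums, tie corrections, asymptotic references) so
# each can be verified against enumeration and base-R oracles.

#' Kolmogorov--Smirnov normality check
#'
#' One-sample KS statistic of `x` against a normal distribution with the
#' sample mean and standard deviation; p-value from the asymptotic
#' Kolmogorov distribution. Used as the gate that routes screening to
#' nonparametric tests.
#'
#' @param x Numeric sample, `n >= 5`, non-degenerate.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_normality <- function(x) {
  n <- length(x)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate (zero-variance) sample", call. = FALSE)
  z <- sort(stats::pnorm(x, mean = mean(x), sd = s))
  i <- seq_len(n)
  D <- max(i / n - z, z - (i - 1) / n)
  lambda <- sqrt(n) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p_value = min(max(p, 0), 1))
}

# pooled midranks and the tie term sum(t^3 - t)
rank_with_ties <- function(all) {
  r <- rank(all)
  t <- table(all)
  list(r = r, tie3 = sum(t^3 - t))
}

#' Kruskal--Wallis rank test
#'
#' Tie-corrected H statistic over three or more samples, referred to a
#' chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param groups List of numeric samples (>= 2 groups, each `n >= 2`).
#' @return List with `statistic` (H), `df` and `p_value`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  n_i <- lengths(groups)
  if (any(n_i < 2)) stop("each group needs n >= 2", call. = FALSE)
  N <- sum(n_i)
  rt <- rank_with_ties(unlist(groups))
  gi <- rep(seq_along(groups), n_i)
  Rbar <- tapply(rt$r, gi, mean)
  H <- 12 / (N * (N + 1)) * sum(n_i * Rbar^2) - 3 * (N + 1)
  corr <- 1 - rt$tie3 / (N^3 - N)
  if (corr > 0) H <- H / corr
  df <- length(groups) - 1
  list(statistic = H, df = df,
       p_value = pchisq(H, df, lower.tail = FALSE))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled midranks with tie correction,
#' following a significant Kruskal--Wallis test; p-values are two-sided and
#' adjusted for multiplicity (Bonferroni by default).
#'
#' @inheritParams kruskal_wallis
#' @param adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  n_i <- lengths(groups)
  if (any(n_i < 2)) stop("each group needs n >= 2", call. = FALSE)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  N <- sum(n_i)
  rt <- rank_with_ties(unlist(groups))
  gi <- rep(seq_along(groups), n_i)
  Rbar <- tapply(rt$r, gi, mean)
  varterm <- N * (N + 1) / 12 - rt$tie3 / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(varterm * (1 / n_i[i1] + 1 / n_i[i2]))
    d <- Rbar[i1] - Rbar[i2]
    z[j] <- if (se > 0) d / se else 0   # fully tied data: no rank contrast
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             z = z, p_value = p,
             p_adjusted = pmin(p.adjust(p, method = adjust), 1),
             stringsAsFactors = FALSE)
}

# Exact null distribution of the Mann-Whitney U statistic (tie-free case):
# counts[u + 1] = number of rank arrangements with U = u, by the standard
# dynamic program f(m, n, u) = f(m - 1, n, u - n) + f(m, n - 1, u).
mwu_counts_dp <- function(nx, ny) {
  U <- nx * ny
  # f[[n + 1]] holds counts over u for current m and given n
  prev <- lapply(0:ny, function(n) c(1, numeric(U)))  # m = 0
  for (m in seq_len(nx)) {
    cur <- vector("list", ny + 1)
    cur[[1]] <- c(1, numeric(U))  # n = 0
    for (n in seq_len(ny)) {
      a <- c(numeric(n), prev[[n + 1]][seq_len(U + 1 - n)])  # shift by n
      cur[[n + 1]] <- a + cur[[n]]
    }
    prev <- cur
  }
  prev[[ny + 1]]
}

#' Mann--Whitney U test
#'
#' U statistic for `x` (number of (x, y) pairs with x > y, counting ties as
#' half). The p-value is exact (full enumeration of the null distribution)
#' when `length(x) * length(y) <= 400` and the pooled sample is tie-free;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used. Two-sided.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (U for `x`), `p_value` and `method`.
#' @examples
#' mann_whitney_u(1:3, 4:6)  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx * ny <= 400) {
    counts <- mwu_counts_dp(nx, ny)
    total <- sum(counts)
    cdf <- cumsum(counts) / total
    u <- round(U)
    p_le <- cdf[u + 1]
    p_ge <- 1 - if (u >= 1) cdf[u] else 0
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- nx + ny
    t <- table(c(x, y))
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    mu <- nx * ny / 2
    d <- U - mu
    cc <- sign(d) * 0.5
    z <- if (sigma2 > 0) (d - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = unname(U), p_value = p, method = method)
}

#' Screen frontal features for parkinsonian group contrasts
#'
#' For each frontal feature column and each vigilance state, compares sham
#' vs lesion epochs with the Mann--Whitney U test. Returns the comparisons
#' ranked by p-value, with the conventional marker set -- normalized frontal
#' alpha, high-beta and low-gamma power plus unnormalized frontal high-gamma
#' power -- attached as `attr(, "markers")`.
#'
#' @param table A normalized `somno_features` table containing both groups
#'   and state labels (see [normalize_features()]).
#' @param aggregate `"epoch"` (default) compares epochs; `"rat"` compares
#'   per-rat per-state medians (guards against pseudo-replication, at the
#'   cost of n = number of animals).
#' @return Data frame of class `somno_screening`: `feature`, `state`,
#'   `statistic`, `p_value`, sorted by `p_value`.
#' @export
screen_pd_features <- function(table, aggregate = c("epoch", "rat")) {
  stopifnot(inherits(table, "somno_features"))
  aggregate <- match.arg(aggregate)
  if (!all(c("sham", "lesion") %in% table$group)) {
    stop("table must contain both sham and lesion epochs", call. = FALSE)
  }
  if (any(is.na(table$state))) {
    stop("table must carry state labels", call. = FALSE)
  }
  feats <- grep("^(pow|cmc)_frontal_|^raw_pow_frontal_", names(table),
                value = TRUE)
  rows <- list()
  for (st in vigilance_states()) {
    sub <- table[table$state == st, , drop = FALSE]
    if (!all(c("sham", "lesion") %in% sub$group)) next  # state absent in a group
    for (f in feats) {
      xs <- sub[[f]][sub$group == "sham"]
      xl <- sub[[f]][sub$group == "lesion"]
      if (aggregate == "rat") {
        xs <- tapply(xs, sub$rat_id[sub$group == "sham"], median)
        xl <- tapply(xl, sub$rat_id[sub$group == "lesion"], median)
      }
      mw <- mann_whitney_u(xs, xl)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, state = st, statistic = mw$statistic,
        p_value = mw$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "markers") <- pd_marker_features()
  class(out) <- c("somno_screening", "data.frame")
  out
}

#' The four parkinsonian marker features
#'
#' Normalized frontal alpha, high-beta and low-gamma band power plus the
#' unnormalized frontal high-gamma power.
#' @return Character vector of feature column names.
#' @export
pd_marker_features <- function() {
  c("pow_frontal_alpha", "pow_frontal_hbeta", "pow_frontal_lgamma",
    "raw_pow_frontal_hgamma")
}
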