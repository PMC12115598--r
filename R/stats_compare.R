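# Statistical comparison of the per-iteration F1 distributions between
# the body and world reference frames: assumption checks, a location
# test chosen by those checks, and the rank-biserial effect size.
#
# The Mann-Whitney U statistic, its p-value and the rank-biserial
# correlation carry the headline comparison, so they are implemented
# here; Shapiro-Wilk, Levene and the t-test are assumption checks and
# delegate to stats/car.

#' Descriptive statistics of a score sample
#'
#' @param x nonempty numeric vector.
#' @return named vector `(mean, median, sd)`; sd uses divisor n-1
#'   (the usual reporting convention; a singleton has sd 0).
#' @export
describe_samples <- function(x) {
  if (!length(x)) stop("empty sample")
  c(mean = mean(x), median = median(x),
    sd = if (length(x) > 1) sd(x) else 0)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is the number of pairs `(x in g1, y in g2)` with `x > y`, counting
#' ties as 1/2 (equivalently computed from midranks). The convention is
#' "U of group 1": small U means group 1 tends to lie below group 2.
#' The p-value comes from exact permutation enumeration when the smaller
#' group has at most 8 members and the enumeration is tractable
#' (`choose(n1+n2, n1) <= 2e5`), otherwise from the normal approximation
#' with tie correction and continuity correction.
#'
#' @param g1,g2 nonempty numeric vectors.
#' @return list `(U, p, n1, n2, method)`.
#' @export
mann_whitney_u <- function(g1, g2) {
  if (!length(g1) || !length(g2)) stop("both groups must be nonempty")
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  exact_ok <- min(n1, n2) <= 8 && choose(n1 + n2, n1) <= 2e5
  if (exact_ok) {
    combos <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact permutation"
  } else {
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {                    # all values tied
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(U = U, p = p, n1 = n1, n2 = n2, method = method)
}

#' Rank-biserial correlation from a Mann-Whitney U
#'
#' `r = 1 - 2U/(n1*n2)`, in `[-1, 1]`. With U the statistic of group 1,
#' positive values mean group 2 tends to be larger.
#'
#' @param U Mann-Whitney U of group 1.
#' @param n1,n2 group sizes.
#' @return the correlation.
#' @export
rank_biserial <- function(U, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (U < 0 || U > n1 * n2) stop("U must lie in [0, n1*n2]")
  1 - 2 * U / (n1 * n2)
}

#' Hodges-Lehmann estimate and CI of a location difference
#'
#' Median of the `n1*n2` pairwise differences `g2[j] - g1[i]`, with a
#' distribution-free CI whose order statistics come from the normal
#' approximation to the Mann-Whitney null.
#'
#' @param g1,g2 numeric vectors.
#' @param conf confidence level.
#' @return list `(estimate, lower, upper)`.
#' @export
hodges_lehmann <- function(g1, g2, conf = 0.95) {
  d <- sort(as.vector(outer(g2, g1, "-")))
  n1 <- length(g1); n2 <- length(g2); m <- n1 * n2
  z <- qnorm(1 - (1 - conf) / 2)
  k <- floor(m / 2 - z * sqrt(n1 * n2 * (n1 + n2 + 1) / 12))
  k <- max(k, 0)
  list(estimate = median(d),
       lower = d[k + 1],
       upper = d[m - k])
}

#' Compare body-frame vs world-frame score distributions
#'
#' Runs Shapiro-Wilk normality on each group and the median-centered
#' (Brown-Forsythe) Levene test across groups. If both groups pass
#' normality at `alpha`, a two-sample t-test is used (pooled variance if
#' Levene passes, Welch otherwise); otherwise the Mann-Whitney U test.
#' The rank-biserial effect size, descriptive statistics, and a CI of
#' the difference (group 2 minus group 1) are attached either way. A
#' zero-variance group cannot be Shapiro-tested and falls through to the
#' nonparametric branch with a warning.
#'
#' @param f1_body score sample of the body-frame model (group 1).
#' @param f1_world score sample of the world-frame model (group 2).
#' @param alpha significance level of the assumption checks.
#' @return object of class `frame_comparison`.
#' @export
compare_frames <- function(f1_body, f1_world, alpha = 0.05) {
  stopifnot(length(f1_body) >= 3, length(f1_world) >= 3)
  sw <- lapply(list(body = f1_body, world = f1_world), function(g) {
    tryCatch(shapiro.test(g)$p.value,
             error = function(e) {
               warning("Shapiro-Wilk undefined (degenerate group); ",
                       "treating as non-normal")
               0
             })
  })
  lev_df <- data.frame(value = c(f1_body, f1_world),
                       group = factor(rep(c("body", "world"),
                                          c(length(f1_body), length(f1_world)))))
  lev_p <- tryCatch(
    car::leveneTest(value ~ group, data = lev_df, center = median)[1, "Pr(>F)"],
    error = function(e) NA_real_)
  normal <- sw$body > alpha && sw$world > alpha
  mw <- mann_whitney_u(f1_body, f1_world)
  rb <- rank_biserial(mw$U, mw$n1, mw$n2)
  if (normal) {
    pooled <- !is.na(lev_p) && lev_p > alpha
    tt <- t.test(f1_world, f1_body, var.equal = pooled)
    test <- list(name = if (pooled) "Student t" else "Welch t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 ci = as.numeric(tt$conf.int))
  } else {
    hl <- hodges_lehmann(f1_body, f1_world)
    test <- list(name = "Mann-Whitney U", statistic = mw$U, p = mw$p,
                 ci = c(hl$lower, hl$upper))
  }
  structure(list(
    body = describe_samples(f1_body),
    world = describe_samples(f1_world),
    shapiro_p = c(body = sw$body, world = sw$world),
    levene_p = lev_p,
    test = test$name, statistic = test$statistic, p = test$p,
    rank_biserial = rb,
    mean_diff = mean(f1_world) - mean(f1_body),
    ci = test$ci, alpha = alpha,
    decision_path = sprintf(
      "shapiro body p=%.3g, world p=%.3g; levene p=%.3g -> %s",
      sw$body, sw$world, lev_p, test$name)
  ), class = "frame_comparison")
}

#' @export
print.frame_comparison <- function(x, ...) {
  cat("<frame_comparison>\n")
  cat(sprintf("  body : mean %.3f median %.3f sd %.3f\n",
              x$body["mean"], x$body["median"], x$body["sd"]))
  cat(sprintf("  world: mean %.3f median %.3f sd %.3f\n",
              x$world["mean"], x$world["median"], x$world["sd"]))
  cat("  ", x$decision_path, "\n", sep = "")
  cat(sprintf("  %s: statistic %.4g, p = %.3g, rank-biserial %.3f\n",
              x$test, x$statistic, x$p, x$rank_biserial))
  cat(sprintf("  mean diff (world - body) %.4g, %d%% CI [%.4g, %.4g]\n",
              x$mean_diff, round(100 * (1 - x$alpha)), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Export a frame comparison as JSON
#'
#' @param cmp a `frame_comparison`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_comparison_json <- function(cmp, path) {
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
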