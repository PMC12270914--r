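# Age-trend statistics: Spearman correlations with the t-distribution
# p-value approximation, Wilcoxon rank-sum sex-difference tests, and the
# continuous two-phase ("broken stick") regression used to estimate the age
# at which each domain starts to decline.

#' Spearman correlation with t-approximated p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' two-sided p-value uses `t = rho * sqrt((n-2) / (1-rho^2))` on n-2 degrees
#' of freedom, the approximation used for nonlinear age trends.
#'
#' @param x,y numeric vectors of equal length (n >= 4, finite).
#' @return list with `rho`, `p` and `n`.
#' @export
spearman_with_p <- function(x, y) {
  check_aligned(length(x), length(y), "x", "y")
  if (length(x) < 4L) {
    stop_ic("need n >= 4 for the t approximation",
            class = "icclock_contract_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_ic("non-finite values in input", class = "icclock_input_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ic("correlation undefined for a constant vector",
            class = "icclock_degenerate_domain")
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Wilcoxon rank-sum test for a sex difference
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. When both groups have at
#' most `exact_max` members the null distribution of the group-1 rank sum is
#' enumerated exhaustively over all assignments (ties included) and the
#' p-value is the probability of a rank sum at least as far from its mean as
#' observed. Larger samples use the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param score numeric scores.
#' @param group two-level factor/character grouping (e.g. sex).
#' @param exact_max switch to exact enumeration when both groups are at most
#'   this size.
#' @return list with `W` (Mann-Whitney U for the first group level), `p`,
#'   and the `method` used.
#' @export
sex_difference_test <- function(score, group, exact_max = 10L) {
  check_aligned(length(score), length(group), "score", "group")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop_ic("exactly two nonempty groups required",
            class = "icclock_contract_error")
  }
  group <- droplevels(group)
  r <- rank(score)
  g1 <- group == levels(group)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  s_obs <- sum(r[g1])
  u_obs <- s_obs - n1 * (n1 + 1) / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    mu <- mean(sums)
    p <- mean(abs(sums - mu) >= abs(s_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(W = u_obs, p = p, method = method)
}

#' Continuous two-phase (hinge) regression of a score on age
#'
#' Fits `score ~ b0 + b1 * age + b2 * max(0, age - c)` by least squares for
#' each candidate breakpoint `c` on a grid over the interior of the observed
#' age range, and returns the breakpoint minimizing the residual sum of
#' squares. The fit is continuous at the breakpoint by construction;
#' `slope1 = b1` (pre-breakpoint) and `slope2 = b1 + b2` (post-breakpoint).
#' Ties in RSS are broken toward the smallest candidate breakpoint.
#'
#' @param age,score numeric vectors (n >= 6).
#' @param grid_step breakpoint grid spacing in years.
#' @param interior_quantile fraction of the age distribution excluded at
#'   each end of the grid (guards against boundary degeneracy).
#' @return a `two_phase_fit` list: breakpoint, intercept, slope1, slope2,
#'   rss, and the searched grid.
#' @export
two_phase_fit <- function(age, score, grid_step = 1,
                          interior_quantile = 0.05) {
  check_aligned(length(age), length(score), "age", "score")
  if (length(age) < 6L) {
    stop_ic("need n >= 6 for a two-phase fit",
            class = "icclock_contract_error")
  }
  lo <- stats::quantile(age, interior_quantile, names = FALSE)
  hi <- stats::quantile(age, 1 - interior_quantile, names = FALSE)
  if (hi - lo <= 2 * grid_step) {
    stop_ic("age span too small for the requested grid step",
            class = "icclock_contract_error")
  }
  grid <- seq(lo, hi, by = grid_step)
  best <- NULL
  for (cand in grid) {
    X <- cbind(1, age, pmax(0, age - cand))
    fit <- tryCatch(stats::lm.fit(X, score), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) next
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- fit$coefficients
      best <- list(breakpoint = cand, intercept = cf[[1]],
                   slope1 = cf[[2]], slope2 = cf[[2]] + cf[[3]], rss = rss)
    }
  }
  if (is.null(best)) {
    stop_ic("all candidate two-phase fits were singular",
            class = "icclock_degenerate_design")
  }
  best$grid <- grid
  class(best) <- "two_phase_fit"
  best
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat(sprintf(
    "Two-phase fit: breakpoint %.2f years, slopes %.4g -> %.4g (RSS %.4g)\n",
    x$breakpoint, x$slope1, x$slope2, x$rss))
  invisible(x)
}

#' Age-trend summary for an IC score table
#'
#' Per domain (and overall IC): Spearman correlation with age, Wilcoxon
#' sex-difference p, and the two-phase age-of-decline fit.
#'
#' @param scores an [ic_score()] table.
#' @param cohort the cohort table supplying `age` and `sex` (joined on
#'   `participant_id`).
#' @param grid_step breakpoint grid spacing in years.
#' @return data.frame with one row per domain.
#' @export
age_trend_table <- function(scores, cohort, grid_step = 1) {
  m <- match(scores$participant_id, cohort$participant_id)
  if (anyNA(m)) {
    stop_ic("score table contains participants absent from cohort",
            class = "icclock_alignment_error")
  }
  age <- cohort$age[m]
  sex <- cohort$sex[m]
  domains <- c("cognition", "locomotion", "psychological", "sensory",
               "vitality", "overall_ic")
  rows <- lapply(domains, function(d) {
    sc <- scores[[d]]
    sp <- spearman_with_p(age, sc)
    wx <- sex_difference_test(sc, sex)
    tp <- two_phase_fit(age, sc, grid_step = grid_step)
    data.frame(domain = d, rho_age = sp$rho, p_age = sp$p,
               p_sex = wx$p, breakpoint = tp$breakpoint,
               slope_post = tp$slope2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
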