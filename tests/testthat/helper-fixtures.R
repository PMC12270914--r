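# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny complete cohort with hand-controllable domain values.
toy_cohort <- function(n = 20, seed = 1) {
  withr_seed(seed)
  data.frame(
    participant_id = sprintf("T%03d", seq_len(n)),
    age = seq(25, 95, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    cognition = pmin(pmax(rnorm(n, 27, 2), 0), 30),
    locomotion = pmin(pmax(rnorm(n, 10, 1.5), 0), 12),
    psychological = pmin(pmax(rnorm(n, 5, 3), 0), 27),
    sensory_vision = pmin(pmax(rnorm(n, 2.5, 0.4), 0), 3),
    sensory_hearing = pmin(pmax(rnorm(n, 1.7, 0.3), 0), 2),
    vitality = pmax(rnorm(n, 35, 8), 1),
    stringsAsFactors = FALSE
  )
}

withr_seed <- function(seed) set.seed(seed)

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Dense-grid changepoint oracle: exhaustive least-squares over a 0.1-year
# grid using stats::lm, independent of two_phase_fit's internals.
oracle_two_phase <- function(age, score, step = 0.1, interior = 0.05) {
  lo <- quantile(age, interior, names = FALSE)
  hi <- quantile(age, 1 - interior, names = FALSE)
  grid <- seq(lo, hi, by = step)
  rss <- vapply(grid, function(cand) {
    h <- pmax(0, age - cand)
    sum(resid(lm(score ~ age + h))^2)
  }, numeric(1))
  grid[which.min(rss)]
}

# Direct-summation GSEA running-sum oracle (explicit loop).
oracle_gsea_es <- function(scores_desc, member) {
  nh_sum <- sum(scores_desc[member])
  nm <- sum(!member)
  run <- 0
  best <- -Inf
  for (i in seq_along(scores_desc)) {
    run <- run + if (member[i]) scores_desc[i] / nh_sum else -1 / nm
    best <- max(best, run)
  }
  best
}

# 1-D Cox partial-likelihood oracle (no ties), maximized numerically.
oracle_cox_coef <- function(time, event, x) {
  negll <- function(b) {
    ord <- order(time)
    t_s <- time[ord]; e_s <- event[ord]; x_s <- x[ord]
    ll <- 0
    for (i in which(e_s == 1)) {
      risk <- t_s >= t_s[i]
      ll <- ll + b * x_s[i] - log(sum(exp(b * x_s[risk])))
    }
    -ll
  }
  optimize(negll, c(-10, 10), tol = 1e-10)$minimum
}

# Power-iteration PC1 oracle on the standardized matrix.
oracle_pc1 <- function(m, iters = 2000) {
  z <- scale(as.matrix(m))
  C <- crossprod(z) / (nrow(z) - 1)
  v <- rep(1, ncol(C))
  for (i in seq_len(iters)) {
    v <- C %*% v
    v <- v / sqrt(sum(v^2))
  }
  drop(z %*% v)
}
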