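# Clock training, selection, prediction, acceleration, quintiles.

test_that("bin filter partitions [0,1] into 20 bins and drops sparse bins", {
  withr_seed(20)
  ic <- runif(400)
  bf <- bin_filter(ic)
  expect_equal(nrow(bf$report), 20)
  expect_equal(bf$report$bin_lower, seq(0, 0.95, by = 0.05))

  # a single populous bin is fully retained
  bf2 <- bin_filter(rep(0.7, 12))
  expect_true(all(bf2$keep))

  # crafted cohort: 9 samples in [0.50, 0.55), >= 10 everywhere else populated
  ic3 <- c(runif(9, 0.50, 0.549), runif(200, 0.6, 1), runif(50, 0, 0.049))
  bf3 <- bin_filter(ic3)
  expect_false(any(bf3$keep[1:9]))
  in_sparse <- ic3 >= 0.50 & ic3 < 0.55
  expect_equal(sum(!bf3$keep), sum(in_sparse))
  # direct counting oracle for the report
  expect_equal(bf3$report$count,
               as.integer(table(cut(ic3, seq(0, 1, 0.05), right = FALSE,
                                    include.lowest = TRUE))))

  # ic = 1 belongs to the final (closed) bin
  bf4 <- bin_filter(c(rep(1, 10), rep(0.975, 2)))
  expect_true(all(bf4$keep))

  expect_error(bin_filter(c(-0.1, 0.5)), class = "icclock_input_error")
  expect_error(bin_filter(runif(9)), class = "icclock_empty_retention")
})

test_that("full shrinkage collapses the model to the mean", {
  withr_seed(21)
  betas <- matrix(runif(40 * 30), nrow = 40,
                  dimnames = list(sprintf("cg%02d", 1:40),
                                  sprintf("s%02d", 1:30)))
  y <- runif(30)
  x <- t(betas)
  fit <- glmnet::glmnet(x, y, alpha = 1)
  cf <- as.matrix(coef(fit, s = max(fit$lambda) * 10))
  expect_true(all(cf[-1, 1] == 0))
  expect_equal(cf[1, 1], mean(y), tolerance = 1e-8)
})

test_that("penalized refit matches a direct objective minimizer (unstandardized oracle)", {
  withr_seed(22)
  n <- 60; p <- 4
  x <- matrix(rnorm(n * p), nrow = n)
  y <- drop(x %*% c(1, -0.5, 0, 0.25)) + rnorm(n, 0, 0.1)
  # unit population variance so the documented penalized objective and the
  # solver's internal outcome scaling coincide exactly
  y <- y / sqrt(mean((y - mean(y))^2))
  betas <- t(x); rownames(betas) <- paste0("cg", 1:p); colnames(betas) <- paste0("s", 1:n)
  cv <- cv_elastic_net(betas, y, alphas = 0.1, folds = 5, seed = 1,
                       standardize = FALSE, thresh = 1e-14)
  model <- select_model(cv, betas, y, standardize = FALSE, thresh = 1e-14)
  lam <- model$lambda; alp <- 0.1
  obj <- function(b) {
    r <- y - b[1] - drop(x %*% b[-1])
    sum(r^2) / (2 * n) + lam * (alp * sum(abs(b[-1])) +
                                  (1 - alp) / 2 * sum(b[-1]^2))
  }
  b_hat <- c(model$intercept, unname(model$weights[paste0("cg", 1:p)]))
  b_hat[is.na(b_hat)] <- 0
  direct <- optim(rep(0, p + 1), obj, method = "BFGS",
                  control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(abs(obj(b_hat) - direct$value), 1e-7)
  # KKT stationarity of the returned solution (subgradient oracle)
  r <- y - b_hat[1] - drop(x %*% b_hat[-1])
  g <- -drop(crossprod(x, r)) / n + lam * (1 - alp) * b_hat[-1]
  for (j in seq_len(p)) {
    if (b_hat[j + 1] != 0) {
      expect_lt(abs(g[j] + lam * alp * sign(b_hat[j + 1])), 1e-6)
    } else {
      expect_lte(abs(g[j]), lam * alp + 1e-6)
    }
  }
  # objective at solution beats the zero vector and the OLS solution
  expect_lte(obj(b_hat), obj(rep(0, p + 1)))
  ols <- coef(lm(y ~ x))
  expect_lte(obj(b_hat), obj(unname(ols)))
})

test_that("nonzero count is monotone along the lambda path (alpha = 1)", {
  withr_seed(23)
  betas <- matrix(runif(50 * 80), nrow = 50,
                  dimnames = list(sprintf("cg%02d", 1:50), NULL))
  y <- drop(t(betas[1:3, ]) %*% c(1, -1, 0.5)) + rnorm(80, 0, 0.05)
  cv <- cv_elastic_net(betas, y, alphas = 1, folds = 5, seed = 2)
  nz <- cv[[1]]$nzero
  lam <- cv[[1]]$lambda   # decreasing
  # monotone modulo path-algorithm tolerance: features may transiently
  # leave the active set, but never more than a couple at a time and the
  # overall trend is strictly increasing as lambda decreases
  expect_true(all(diff(nz[order(-lam)]) >= -2))
  expect_gt(cor(seq_along(lam), nz[order(-lam)], method = "spearman"), 0.9)
})

test_that("model selection ranks by correlation, error and sparsity with ties to larger alpha", {
  fake <- function(alpha, corr, mae, ncpg) {
    structure(list(alpha = alpha, cv_corr = corr, cv_mae = mae,
                   n_cpgs = ncpg, lambda_min = 0.01,
                   lambda = 0.01, cvm = mae, nzero = ncpg,
                   oof = numeric(0), cv_mae = mae, cv_corr = corr),
              class = "cv_result")
  }
  withr_seed(24)
  betas <- matrix(runif(10 * 40), nrow = 10,
                  dimnames = list(sprintf("cg%02d", 1:10), NULL))
  y <- runif(40)

  # strict dominance
  cvs <- list(fake(0.2, 0.5, 0.10, 30), fake(0.9, 0.8, 0.05, 10))
  m <- select_model(cvs, betas, y)
  expect_equal(m$alpha, 0.9)
  sel <- attr(m, "selection")
  # hand-computed ranks: alpha 0.9 is rank 1 on all three metrics
  expect_equal(sel$rank_sum, c(6, 3))

  # rank-sum tie: each wins one metric outright, third metric tied
  cvs2 <- list(fake(0.3, 0.9, 0.08, 20), fake(0.8, 0.7, 0.04, 20))
  m2 <- select_model(cvs2, betas, y)
  expect_equal(attr(m2, "selection")$rank_sum, c(4.5, 4.5))
  expect_equal(m2$alpha, 0.8)

  expect_error(select_model(list(), betas, y),
               class = "icclock_contract_error")
})

test_that("predict_clock computes the linear score and enforces the CpG policy", {
  toy <- matrix(c(0.2, 0.4, 0.6,
                  0.8, 0.5, 0.1), nrow = 2, byrow = TRUE,
                dimnames = list(c("cgA", "cgB"), c("s1", "s2", "s3")))
  model <- clock_model(0.8, c(cgA = 0.5, cgB = -0.25))
  # hand arithmetic: 0.8 + 0.5*beta_A - 0.25*beta_B
  expect_equal(unname(predict_clock(model, toy)),
               c(0.8 + 0.1 - 0.2, 0.8 + 0.2 - 0.125, 0.8 + 0.3 - 0.025),
               tolerance = 1e-12)

  # all-zero weights score the intercept
  m0 <- clock_model(0.37, c(cgA = 0, cgB = 0))
  expect_equal(unname(predict_clock(m0, toy)), rep(0.37, 3))

  # missing CpGs: error by default, mean imputation when allowed
  m2 <- clock_model(0.1, c(cgA = 1, cgZ = 2),
                    training_means = c(cgA = 0.5, cgZ = 0.25))
  expect_error(predict_clock(m2, toy), class = "icclock_missing_cpgs")
  sc <- predict_clock(m2, toy, impute = "mean", max_missing = 0.5)
  expect_equal(unname(sc), 0.1 + 1 * toy["cgA", ] + 2 * 0.25,
               ignore_attr = TRUE)

  # linearity per sample
  withr_seed(25)
  b1 <- matrix(runif(6), nrow = 2, dimnames = dimnames(toy))
  b2 <- matrix(runif(6), nrow = 2, dimnames = dimnames(toy))
  a <- 0.3
  expect_equal(predict_clock(model, a * b1 + (1 - a) * b2),
               a * predict_clock(model, b1) +
                 (1 - a) * predict_clock(model, b2),
               tolerance = 1e-12)
})

test_that("out-of-fold predictions are invariant to sample ordering given the folds", {
  withr_seed(26)
  betas <- matrix(runif(30 * 60), nrow = 30,
                  dimnames = list(sprintf("cg%02d", 1:30),
                                  sprintf("s%02d", 1:60)))
  y <- drop(t(betas[1:2, ]) %*% c(2, -2)) + rnorm(60, 0, 0.1)
  foldid <- rep_len(1:5, 60)
  cv <- cv_elastic_net(betas, y, alphas = 0.5, foldid = foldid)
  perm <- sample(60)
  cv_p <- cv_elastic_net(betas[, perm], y[perm], alphas = 0.5,
                         foldid = foldid[perm])
  expect_equal(cv_p[[1]]$oof[order(perm)], cv[[1]]$oof, tolerance = 1e-8)
  expect_equal(cv_p[[1]]$cv_mae, cv[[1]]$cv_mae, tolerance = 1e-10)
})

test_that("age acceleration is the OLS residual with the expected identities", {
  age <- c(50, 60, 70)
  score <- c(1.0, 0.8, 0.9)
  # hand OLS: slope -0.005, intercept 1.2 -> residuals (0.05, -0.1, 0.05)
  expect_equal(age_acceleration(score, age), c(0.05, -0.1, 0.05),
               tolerance = 1e-12)

  withr_seed(27)
  a <- runif(100, 20, 90)
  s <- 2 - 0.01 * a
  expect_equal(age_acceleration(s, a), rep(0, 100), tolerance = 1e-10)
  s2 <- s + rnorm(100)
  expect_equal(sum(age_acceleration(s2, a)), 0, tolerance = 1e-10)
  expect_error(age_acceleration(s2, rep(50, 100)),
               class = "icclock_degenerate_design")
})

test_that("quintile groups pick the extreme 20% deterministically", {
  v <- c(10, 2, 7, 1, 9, 4, 8, 3, 6, 5)
  g <- quintile_groups(v)
  expect_equal(sum(g == "lowest20"), 2)
  expect_equal(sum(g == "highest20"), 2)
  expect_equal(which(g == "lowest20"), c(2, 4))
  expect_equal(which(g == "highest20"), c(1, 5))

  # all equal: rank ties broken by first occurrence, still 2 per extreme
  ge <- quintile_groups(rep(1, 10))
  expect_equal(as.character(ge[1:2]), c("lowest20", "lowest20"))
  expect_equal(as.character(ge[9:10]), c("highest20", "highest20"))

  # sort-based oracle on the extreme-group means
  withr_seed(28)
  z <- rnorm(1000)
  gz <- quintile_groups(z)
  zs <- sort(z)
  expect_equal(mean(z[gz == "lowest20"]), mean(zs[1:200]), tolerance = 1e-12)
  expect_equal(mean(z[gz == "highest20"]), mean(zs[801:1000]),
               tolerance = 1e-12)
})
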