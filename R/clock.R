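# The DNAm IC clock: bin-based sample filtering, tenfold cross-validated
# elastic net over an alpha grid with mean absolute error as the metric,
# three-criterion model selection (highest out-of-fold correlation, lowest
# CV MAE, fewest CpGs), linear prediction applicable to any coefficient-file
# clock, age-acceleration residuals and quintile grouping.

#' Filter samples by IC-score bin occupancy
#'
#' Splits \[0,1\] into `1/bin_width` bins (`[k*w, (k+1)*w)`, last bin closed
#' at 1) and drops samples lying in bins with fewer than `min_count`
#' members, so sparsely observed regions of the score do not destabilize
#' training.
#'
#' @param ic scores in \[0,1\].
#' @param bin_width bin width (default 0.05, i.e. 20 bins).
#' @param min_count minimum bin occupancy to retain.
#' @return list with `keep` (logical mask), `report` (per-bin counts and
#'   retention) and `excluded_fraction`.
#' @export
bin_filter <- function(ic, bin_width = 0.05, min_count = 10L) {
  if (any(!is.finite(ic)) || any(ic < 0 | ic > 1)) {
    stop_ic("IC scores must lie in [0,1]", class = "icclock_input_error")
  }
  n_bins <- round(1 / bin_width)
  bin <- pmin(floor(ic / bin_width), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  retained_bin <- counts >= min_count
  keep <- retained_bin[bin]
  if (!any(keep)) {
    stop_ic("bin filter retained no samples", class = "icclock_empty_retention")
  }
  report <- data.frame(
    bin_lower = (seq_len(n_bins) - 1L) * bin_width,
    bin_upper = seq_len(n_bins) * bin_width,
    count = counts,
    retained = retained_bin
  )
  list(keep = keep, report = report,
       excluded_fraction = mean(!keep))
}

# Deterministic fold assignment stratified by outcome decile: within each
# decile, samples are shuffled and folds dealt out cyclically.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    dec <- as.integer(cut(rank(y, ties.method = "first"),
                          breaks = folds_breaks(length(y)), labels = FALSE,
                          include.lowest = TRUE))
    foldid <- integer(length(y))
    for (d in unique(dec)) {
      idx <- sample(which(dec == d))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
    foldid
  })
}

folds_breaks <- function(n) {
  seq(0.5, n + 0.5, length.out = min(10L, n) + 1L)
}

#' Tenfold cross-validated elastic net over an alpha grid
#'
#' For each mixing parameter alpha, fits the elastic-net path
#' (glmnet parameterization: `(1/2n)*RSS + lambda*(alpha*||b||_1 +
#' (1-alpha)/2*||b||_2^2)`, predictors standardized internally,
#' coefficients returned on the original scale), selects the lambda
#' minimizing the mean out-of-fold absolute error, and records the
#' out-of-fold predictions at that lambda.
#'
#' @param betas CpG x sample beta matrix.
#' @param ic outcome scores aligned to the samples.
#' @param alphas alpha grid (default 0.1 to 1 by 0.1).
#' @param folds number of CV folds.
#' @param seed integer seed controlling the fold assignment (stratified by
#'   outcome decile).
#' @param nlambda length of the lambda path per alpha.
#' @param foldid optional explicit fold assignment (overrides the seeded
#'   stratified assignment).
#' @param thresh coordinate-descent convergence threshold.
#' @param standardize standardize predictors inside the penalized fit
#'   (coefficients are always returned on the original scale).
#' @return list of per-alpha `cv_result` entries (alpha, lambda path with
#'   CV MAE and nonzero counts, selected lambda, out-of-fold predictions,
#'   cv_mae, cv_corr, n_cpgs) with the fold ids attached.
#' @export
cv_elastic_net <- function(betas, ic, alphas = seq(0.1, 1, by = 0.1),
                           folds = 10L, seed = 1L, nlambda = 100L,
                           foldid = NULL, standardize = TRUE,
                           thresh = 1e-10) {
  x <- t(betas)
  check_aligned(nrow(x), length(ic), "samples", "ic scores")
  if (any(!is.finite(x))) {
    stop_ic("non-finite beta values", class = "icclock_input_error")
  }
  if (nrow(x) < folds) {
    stop_ic("fewer samples than folds", class = "icclock_fold_error")
  }
  if (is.null(foldid)) foldid <- stratified_folds(ic, folds, seed)
  results <- lapply(alphas, function(a) {
    cvfit <- glmnet::cv.glmnet(x, ic, alpha = a, foldid = foldid,
                               type.measure = "mae", keep = TRUE,
                               nlambda = nlambda, standardize = standardize,
                               thresh = thresh)
    i_min <- which.min(cvfit$cvm)
    oof <- cvfit$fit.preval[, i_min]
    structure(list(
      alpha = a,
      lambda = cvfit$lambda,
      cvm = cvfit$cvm,
      nzero = as.integer(cvfit$nzero),
      lambda_min = cvfit$lambda[i_min],
      oof = as.numeric(oof),
      cv_mae = cvfit$cvm[i_min],
      cv_corr = stats::cor(ic, oof),
      n_cpgs = as.integer(cvfit$nzero[i_min])
    ), class = "cv_result")
  })
  attr(results, "foldid") <- foldid
  attr(results, "ic") <- ic
  results
}

#' Select the best clock across alphas and refit it
#'
#' Ranks the alpha candidates by (i) descending correlation between the
#' observed scores and the out-of-fold predictions, (ii) ascending CV MAE
#' and (iii) ascending number of selected CpGs; the winner minimizes the
#' rank sum, with ties broken toward the larger alpha (the sparser regime).
#' The winner is refit on all retained samples at its selected lambda.
#'
#' @param cv_results output of [cv_elastic_net()].
#' @param betas,ic the training data used for the refit.
#' @param standardize must match the value used in [cv_elastic_net()].
#' @param thresh coordinate-descent convergence threshold for the refit.
#' @return a `clock_model`: intercept, named sparse `weights`, alpha,
#'   lambda, cv_mae, cv_corr, n_cpgs, and per-CpG training mean betas (for
#'   optional mean imputation at prediction time). The selection table is
#'   attached as `attr(, "selection")`.
#' @export
select_model <- function(cv_results, betas, ic, standardize = TRUE,
                         thresh = 1e-10) {
  if (!length(cv_results)) {
    stop_ic("no CV results supplied", class = "icclock_contract_error")
  }
  tab <- data.frame(
    alpha = vapply(cv_results, `[[`, numeric(1), "alpha"),
    cv_corr = vapply(cv_results, `[[`, numeric(1), "cv_corr"),
    cv_mae = vapply(cv_results, `[[`, numeric(1), "cv_mae"),
    n_cpgs = vapply(cv_results, `[[`, numeric(1), "n_cpgs")
  )
  tab$rank_corr <- rank(-tab$cv_corr, ties.method = "average")
  tab$rank_mae <- rank(tab$cv_mae, ties.method = "average")
  tab$rank_ncpg <- rank(tab$n_cpgs, ties.method = "average")
  tab$rank_sum <- tab$rank_corr + tab$rank_mae + tab$rank_ncpg
  winners <- which(tab$rank_sum == min(tab$rank_sum))
  best <- winners[which.max(tab$alpha[winners])]
  sel <- cv_results[[best]]

  x <- t(betas)
  fit <- glmnet::glmnet(x, ic, alpha = sel$alpha, standardize = standardize,
                        thresh = thresh)
  cf <- as.matrix(stats::coef(fit, s = sel$lambda_min, exact = FALSE))
  w <- cf[-1, 1]
  nz <- w != 0
  model <- structure(list(
    intercept = cf[1, 1],
    weights = w[nz],
    alpha = sel$alpha,
    lambda = sel$lambda_min,
    cv_mae = sel$cv_mae,
    cv_corr = sel$cv_corr,
    n_cpgs = sum(nz),
    training_means = colMeans(x)[nz]
  ), class = "clock_model")
  attr(model, "selection") <- tab
  model
}

#' Construct a linear clock from intercept and weights
#'
#' Wraps any published linear epigenetic clock (intercept plus per-CpG
#' weights) so it can be applied with [predict_clock()].
#'
#' @param intercept numeric intercept.
#' @param weights named numeric vector (names = CpG ids).
#' @param training_means optional named per-CpG mean betas used for
#'   `impute = "mean"`.
#' @return a `clock_model`.
#' @export
clock_model <- function(intercept, weights, training_means = NULL) {
  if (is.null(names(weights)) || anyDuplicated(names(weights))) {
    stop_ic("weights must have unique CpG names",
            class = "icclock_contract_error")
  }
  structure(list(intercept = intercept, weights = weights,
                 alpha = NA_real_, lambda = NA_real_,
                 cv_mae = NA_real_, cv_corr = NA_real_,
                 n_cpgs = sum(weights != 0),
                 training_means = training_means),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Linear DNAm clock: %d CpGs, intercept %.4g", x$n_cpgs,
              x$intercept))
  if (!is.na(x$alpha)) {
    cat(sprintf(" (alpha %.1f, lambda %.4g, CV MAE %.4g, CV corr %.3f)",
                x$alpha, x$lambda, x$cv_mae, x$cv_corr))
  }
  cat("\n")
  invisible(x)
}

#' Apply a linear clock to a beta matrix
#'
#' `intercept + sum(weight * beta)` per sample. Model CpGs absent from the
#' matrix are an error by default; with `impute = "mean"` the stored
#' training mean beta is substituted (at most `max_missing` fraction).
#'
#' @param model a `clock_model`.
#' @param betas CpG x sample matrix with CpG rownames.
#' @param impute `"error"` or `"mean"`.
#' @param max_missing maximum fraction of model CpGs that may be imputed.
#' @return named numeric per-sample score.
#' @export
predict_clock <- function(model, betas, impute = c("error", "mean"),
                          max_missing = 0.1) {
  impute <- match.arg(impute)
  cpgs <- names(model$weights)
  present <- cpgs %in% rownames(betas)
  if (!all(present)) {
    miss <- cpgs[!present]
    if (impute == "error") {
      stop_ic("model CpGs missing from beta matrix: ",
              paste(utils::head(miss, 5), collapse = ", "),
              if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5),
              class = "icclock_missing_cpgs")
    }
    if (is.null(model$training_means) ||
        mean(!present) > max_missing) {
      stop_ic(length(miss), " model CpGs missing exceeds the allowed ",
              "fraction or no training means stored",
              class = "icclock_missing_cpgs")
    }
  }
  x <- matrix(NA_real_, nrow = length(cpgs), ncol = ncol(betas),
              dimnames = list(cpgs, colnames(betas)))
  x[present, ] <- betas[cpgs[present], , drop = FALSE]
  if (any(!present)) {
    x[!present, ] <- model$training_means[cpgs[!present]]
  }
  score <- drop(model$intercept + crossprod(x, model$weights))
  names(score) <- colnames(betas)
  score
}

#' Age acceleration: residuals of a clock score on chronological age
#'
#' OLS residuals of `score ~ age` (optionally `~ age + sex` for the
#' mortality analyses); mean zero by construction. Positive residuals mean
#' the score is higher than expected for that age.
#'
#' @param score per-sample clock output.
#' @param age chronological ages.
#' @param sex optional sex factor for additional adjustment.
#' @return numeric residuals.
#' @export
age_acceleration <- function(score, age, sex = NULL) {
  check_aligned(length(score), length(age), "score", "age")
  if (length(score) < 3L) {
    stop_ic("need n >= 3", class = "icclock_contract_error")
  }
  if (stats::sd(age) == 0) {
    stop_ic("constant age: acceleration undefined",
            class = "icclock_degenerate_design")
  }
  X <- if (is.null(sex)) cbind(1, age) else {
    cbind(1, age, as.numeric(as.factor(sex)) - 1)
  }
  as.numeric(stats::lm.fit(X, score)$residuals)
}

#' Quintile extreme groups of an acceleration vector
#'
#' Labels the lowest and highest 20% (`floor(n/5)` members each, rank-based
#' with ties broken by first occurrence so the assignment is deterministic)
#' and everything else as `mid`.
#'
#' @param acceleration numeric vector (n >= 5).
#' @return factor with levels lowest20, mid, highest20.
#' @export
quintile_groups <- function(acceleration) {
  n <- length(acceleration)
  if (n < 5L) stop_ic("need n >= 5", class = "icclock_contract_error")
  k <- floor(n / 5)
  r <- rank(acceleration, ties.method = "first")
  lab <- rep("mid", n)
  lab[r <= k] <- "lowest20"
  lab[r > n - k] <- "highest20"
  factor(lab, levels = c("lowest20", "mid", "highest20"))
}
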