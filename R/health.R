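# Health and lifestyle associations: a PCA-based overall-health score,
# logistic regression of individual health variables against extreme DNAm IC
# groups, and a Spearman + BH screen for diet/lifestyle features.

#' Overall-health score as the first principal component
#'
#' Variables with more than `max_missing` missing fraction are dropped,
#' remaining samples are restricted to complete cases, constant columns are
#' removed with a warning, columns are standardized, and PC1 scores are
#' returned. The sign is fixed so the score correlates positively with the
#' `anchor` variable (default: the first retained column), making "higher =
#' healthier" reproducible.
#'
#' @param health sample x variable numeric data.frame/matrix (rownames =
#'   sample ids).
#' @param anchor column name anchoring the sign convention.
#' @param max_missing per-variable missingness cap before samples are
#'   dropped.
#' @return named numeric PC1 scores for the retained samples, with
#'   `attr(, "loadings")` and `attr(, "var_explained")`.
#' @export
overall_health_pc1 <- function(health, anchor = NULL, max_missing = 0.2) {
  health <- as.data.frame(health)
  if (ncol(health) < 2L || nrow(health) < 3L) {
    stop_ic("need >= 2 variables and >= 3 samples",
            class = "icclock_contract_error")
  }
  frac_na <- vapply(health, function(x) mean(is.na(x)), numeric(1))
  health <- health[, frac_na <= max_missing, drop = FALSE]
  keep <- stats::complete.cases(health)
  health <- health[keep, , drop = FALSE]
  sds <- vapply(health, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping constant columns: ",
            paste(names(health)[sds == 0], collapse = ", "))
    health <- health[, sds > 0, drop = FALSE]
  }
  if (ncol(health) < 2L) {
    stop_ic("fewer than two informative variables remain",
            class = "icclock_degenerate_domain")
  }
  pc <- stats::prcomp(as.matrix(health), center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  anchor <- anchor %||% colnames(health)[1]
  if (!anchor %in% colnames(health)) {
    stop_ic("anchor variable '", anchor, "' not among retained columns",
            class = "icclock_contract_error")
  }
  if (stats::cor(score, health[[anchor]]) < 0) {
    score <- -score
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  names(score) <- rownames(health)
  attr(score, "loadings") <- pc$rotation[, 1]
  attr(score, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  score
}

#' Logistic association of a variable with high-vs-low DNAm IC group
#'
#' Maximum-likelihood logistic regression (IRLS via `glm`) of membership in
#' the high group on the variable plus optional covariates, with a
#' two-sided Wald test for the variable. Complete separation and
#' non-convergence are detected and reported as non-estimable.
#'
#' @param group factor/character with levels containing "high" and "low"
#'   (e.g. from [quintile_groups()] extremes).
#' @param variable numeric exposure.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list with `or` (odds ratio per unit), `coef`, `se`, `p`, `n`.
#' @export
logistic_assoc <- function(group, variable, covariates = NULL) {
  check_aligned(length(group), length(variable), "group", "variable")
  if (any(!is.finite(variable))) {
    stop_ic("variable contains non-finite values",
            class = "icclock_input_error")
  }
  if (stats::sd(variable) == 0) {
    stop_ic("constant variable: non-estimable",
            class = "icclock_nonestimable")
  }
  y <- as.integer(grepl("high", as.character(group)))
  if (length(unique(y)) != 2L) {
    stop_ic("both groups must be present", class = "icclock_contract_error")
  }
  df <- data.frame(y = y, variable = variable)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  if (!fit$converged) {
    stop_ic("logistic fit did not converge", class = "icclock_nonestimable")
  }
  co <- summary(fit)$coefficients
  if (abs(co["variable", "Estimate"]) > 15 ||
      co["variable", "Std. Error"] > 1e3) {
    stop_ic("complete or quasi-complete separation: non-estimable",
            class = "icclock_nonestimable")
  }
  list(or = exp(co["variable", "Estimate"]),
       coef = co["variable", "Estimate"],
       se = co["variable", "Std. Error"],
       p = co["variable", "Pr(>|z|)"],
       n = length(y))
}

#' Spearman screen of lifestyle/diet features against DNAm IC
#'
#' Per feature: Spearman rho and t-approximated p against the DNAm IC, with
#' BH adjustment across the non-constant features. Constant features are
#' flagged and excluded from the multiplicity count.
#'
#' @param dnam_ic per-sample DNAm IC.
#' @param features sample x feature data.frame.
#' @param fdr significance threshold on q.
#' @return an `association_table` data.frame: feature, effect (rho), p, q,
#'   significant; constant features carry NA statistics.
#' @export
lifestyle_screen <- function(dnam_ic, features, fdr = 0.05) {
  features <- as.data.frame(features)
  check_aligned(length(dnam_ic), nrow(features), "dnam_ic", "feature rows")
  stats_list <- lapply(features, function(f) {
    if (stats::sd(f) == 0) return(c(NA_real_, NA_real_))
    sp <- spearman_with_p(dnam_ic, f)
    c(sp$rho, sp$p)
  })
  rho <- vapply(stats_list, `[`, numeric(1), 1)
  p <- vapply(stats_list, `[`, numeric(1), 2)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(!ok)) {
    warning("constant features excluded from FDR adjustment: ",
            paste(names(features)[!ok], collapse = ", "))
  }
  q[ok] <- bh_fdr(p[ok])
  out <- data.frame(feature = names(features), effect = rho, p = p, q = q,
                    significant = !is.na(q) & q < fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}
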