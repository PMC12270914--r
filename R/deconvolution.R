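# Reference-based cell-type deconvolution (Houseman-style constrained
# projection): per sample, the vector of beta values at the reference CpGs
# is projected onto the convex hull of the cell-type reference profiles by
# solving min ||x - R p||^2 subject to p >= 0, sum(p) = 1.
#
# The quadratic program is solved exactly by enumerating the nonzero-support
# subsets of the (small) cell-type set: each equality-constrained subproblem
# is a linear KKT solve, and the feasible solution with minimal residual sum
# of squares is returned. For the handful of leukocyte subsets used in
# practice this is exact and fast.

#' Estimate cell-type proportions by constrained projection
#'
#' @param betas CpG x sample beta matrix (CpG rownames).
#' @param reference CpG x cell-type matrix of reference mean betas.
#' @return sample x cell-type matrix of proportions on the probability
#'   simplex (each row >= 0, sums to 1).
#' @export
estimate_proportions <- function(betas, reference) {
  shared <- intersect(rownames(reference), rownames(betas))
  k <- ncol(reference)
  if (k > 12L) {
    stop_ic("support enumeration supports at most 12 cell types",
            class = "icclock_input_error")
  }
  if (length(shared) < k) {
    stop_ic("need at least ", k, " shared CpGs between sample and reference",
            class = "icclock_input_error")
  }
  R <- as.matrix(reference[shared, , drop = FALSE])
  if (qr(R)$rank < k) {
    stop_ic("reference columns are linearly dependent on the shared CpGs",
            class = "icclock_identifiability_error")
  }
  X <- as.matrix(betas[shared, , drop = FALSE])

  # Precompute, per nonempty support subset S, the inverse of the KKT matrix
  # [2 R_S'R_S, 1; 1', 0] so each sample costs one matrix-vector product.
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) != 0))
  G <- crossprod(R)
  kkt_inv <- lapply(subsets, function(S) {
    s <- length(S)
    M <- rbind(cbind(2 * G[S, S, drop = FALSE], rep(1, s)),
               c(rep(1, s), 0))
    tryCatch(solve(M), error = function(e) NULL)
  })
  Rt2 <- 2 * t(R)

  out <- matrix(0, nrow = ncol(X), ncol = k,
                dimnames = list(colnames(X), colnames(reference)))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    q <- Rt2 %*% x
    best_rss <- Inf
    best_p <- NULL
    for (i in seq_along(subsets)) {
      Minv <- kkt_inv[[i]]
      if (is.null(Minv)) next
      S <- subsets[[i]]
      sol <- Minv %*% c(q[S], 1)
      p <- sol[seq_along(S)]
      if (any(p < -1e-10)) next
      p <- pmax(p, 0)
      p <- p / sum(p)
      rss <- sum((x - R[, S, drop = FALSE] %*% p)^2)
      if (rss < best_rss - 1e-12) {
        best_rss <- rss
        best_p <- numeric(k)
        best_p[S] <- p
      }
    }
    out[j, ] <- best_p
  }
  out
}

#' Cell-count correlations with age and with DNAm IC
#'
#' Per cell type: Spearman correlation of the raw proportion with age, and
#' the age-adjusted correlation between the proportion and the DNAm IC
#' (both residualized on age before correlating), mirroring how cell-count
#' changes are attributed to IC rather than to chronological age.
#'
#' @param proportions sample x cell-type matrix.
#' @param age chronological ages.
#' @param dnam_ic per-sample DNAm IC scores.
#' @return data.frame: cell_type, rho_age, p_age, rho_ic_adj, p_ic_adj.
#' @export
cellcount_ic_correlations <- function(proportions, age, dnam_ic) {
  check_aligned(nrow(proportions), length(age), "proportion rows", "age")
  check_aligned(nrow(proportions), length(dnam_ic),
                "proportion rows", "dnam_ic")
  ic_resid <- age_acceleration(dnam_ic, age)
  rows <- lapply(colnames(proportions), function(ct) {
    p <- proportions[, ct]
    if (stats::sd(p) == 0) {
      stop_ic("constant proportion column for cell type ", ct,
              class = "icclock_degenerate_domain")
    }
    sa <- spearman_with_p(p, age)
    p_resid <- age_acceleration(p, age)
    si <- spearman_with_p(p_resid, ic_resid)
    data.frame(cell_type = ct, rho_age = sa$rho, p_age = sa$p,
               rho_ic_adj = si$rho, p_ic_adj = si$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
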