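# Transcriptome association with age-adjusted DNAm IC and enrichment:
# per-gene ordinary least squares with t-based two-sided p-values and
# Benjamini-Hochberg control, the CpG-gene permutation linkage test,
# hypergeometric over-representation, and one-signed preranked GSEA.

#' Per-gene linear-model association with a predictor
#'
#' OLS of each gene's expression on the predictor plus optional covariates;
#' the reported effect is the predictor slope, with a t statistic on the
#' residual degrees of freedom and a two-sided p-value. BH-adjusted q-values
#' are appended and the significant set is `q < fdr`.
#'
#' @param expr gene x sample expression matrix (assumed already normalized,
#'   log scale).
#' @param predictor per-sample predictor (e.g. age-adjusted DNAm IC).
#' @param covariates optional data.frame/matrix of per-sample covariates.
#' @param fdr significance threshold on q.
#' @return an `association_table` data.frame: feature, effect, t, p, q,
#'   significant.
#' @export
linear_de <- function(expr, predictor, covariates = NULL, fdr = 0.05) {
  n <- ncol(expr)
  check_aligned(n, length(predictor), "expression samples", "predictor")
  X <- cbind(intercept = 1, predictor = predictor)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    check_aligned(n, nrow(covariates), "expression samples", "covariate rows")
    X <- cbind(X, covariates)
  }
  p_par <- ncol(X)
  if (n <= p_par + 1L) {
    stop_ic("too few samples for the design", class = "icclock_design_error")
  }
  XtX <- crossprod(X)
  XtX_inv <- tryCatch(solve(XtX), error = function(e) {
    stop_ic("singular design matrix", class = "icclock_design_error")
  })
  Y <- t(expr)                       # n x G
  B <- XtX_inv %*% crossprod(X, Y)   # p x G
  resid <- Y - X %*% B
  df <- n - p_par
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtX_inv["predictor", "predictor"])
  eff <- B["predictor", ]
  tstat <- ifelse(se > 0, eff / se, sign(eff) * Inf)
  pval <- 2 * stats::pt(-abs(tstat), df = df)
  qval <- bh_fdr(pval)
  out <- data.frame(feature = rownames(expr), effect = eff, t = tstat,
                    p = pval, q = qval, significant = qval < fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in input
#' order.
#'
#' @param pvals p-values in \[0,1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_ic("p-values must lie in [0,1]", class = "icclock_input_error")
  }
  m <- length(pvals)
  o <- order(pvals)
  q_sorted <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Spearman correlation matrix between the rows of two matrices sharing
# columns (samples): Pearson correlation of the row-wise mid-ranks.
spearman_matrix <- function(a, b) {
  ra <- t(apply(a, 1, rank))
  rb <- t(apply(b, 1, rank))
  stats::cor(t(ra), t(rb))
}

#' Permutation linkage between clock CpGs and DE-gene expression
#'
#' Statistic: the mean over clock CpGs of the maximum over DE genes of the
#' absolute Spearman correlation between the CpG's betas and the gene's
#' expression ("each CpG's best-correlated gene"). The null distribution is
#' built by permuting the sample labels of the expression matrix, which
#' preserves both correlation structures while breaking the linkage;
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param clock_betas CpG x sample matrix restricted to the clock CpGs.
#' @param de_expr gene x sample matrix restricted to the significant genes.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `observed`, `null_mean` (the chance level), `p` and
#'   `n_perm`.
#' @export
cpg_gene_linkage <- function(clock_betas, de_expr, n_perm = 10000L,
                             seed = 1L) {
  n <- ncol(clock_betas)
  check_aligned(n, ncol(de_expr), "clock beta samples", "expression samples")
  if (n_perm < 1L) {
    stop_ic("n_perm must be at least 1", class = "icclock_contract_error")
  }
  ra <- t(apply(clock_betas, 1, rank))  # cpg x n
  rb <- t(apply(de_expr, 1, rank))      # gene x n
  ta <- t(ra); tb <- t(rb)              # n x cpg, n x gene
  stat_from <- function(tb_perm) {
    C <- abs(stats::cor(ta, tb_perm))
    mean(apply(C, 1, max))
  }
  observed <- stat_from(tb)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_from(tb[sample(n), , drop = FALSE]),
           numeric(1))
  })
  list(observed = observed, null_mean = mean(null),
       p = (1 + sum(null >= observed)) / (1 + n_perm), n_perm = n_perm)
}

#' Per-gene counts of significantly correlated clock CpGs
#'
#' Spearman correlation (t-approximated p) for every CpG x gene pair, BH
#' adjustment over the whole grid, and for each gene the number of clock
#' CpGs whose correlation is significant at `fdr`.
#'
#' @param clock_betas CpG x sample matrix.
#' @param de_expr gene x sample matrix.
#' @param fdr BH threshold over the CpG x gene grid.
#' @return data.frame: gene, n_correlated_cpgs, fraction of clock CpGs.
#' @export
per_gene_cpg_counts <- function(clock_betas, de_expr, fdr = 0.05) {
  n <- ncol(clock_betas)
  check_aligned(n, ncol(de_expr), "clock beta samples", "expression samples")
  C <- spearman_matrix(clock_betas, de_expr)
  r <- pmin(pmax(C, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  q <- matrix(bh_fdr(as.numeric(p)), nrow = nrow(p))
  data.frame(gene = rownames(de_expr),
             n_correlated_cpgs = colSums(q < fdr),
             fraction = colSums(q < fdr) / nrow(clock_betas),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided hypergeometric tail probability of observing at least the seen
#' overlap between the significant genes and each set (both intersected
#' with the universe), with BH adjustment across sets. Sets disjoint from
#' the universe are skipped with a warning.
#'
#' @param sig_genes significant gene ids (subset of `universe`).
#' @param universe all tested gene ids.
#' @param gene_sets named list of gene-id vectors.
#' @return data.frame: set, overlap, set_size, p, q.
#' @export
overrepresentation <- function(sig_genes, universe, gene_sets) {
  if (!length(universe)) {
    stop_ic("empty universe", class = "icclock_contract_error")
  }
  if (!all(sig_genes %in% universe)) {
    stop_ic("sig_genes must be a subset of the universe",
            class = "icclock_contract_error")
  }
  N <- length(unique(universe))
  n_sig <- length(unique(sig_genes))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    if (!length(set)) {
      warning("gene set '", nm, "' is disjoint from the universe; skipped")
      return(NULL)
    }
    K <- length(set)
    k <- length(intersect(set, sig_genes))
    p <- stats::phyper(k - 1, K, N - K, n_sig, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q <- bh_fdr(out$p)
  out
}

# Running-sum enrichment score for a ranked score vector (descending) and a
# membership indicator; weight exponent 1, one-signed (positive extreme).
gsea_es <- function(scores_desc, member) {
  sum_hit <- sum(scores_desc[member])
  n_miss <- sum(!member)
  if (sum_hit <= 0 || n_miss == 0L) return(NA_real_)
  step <- ifelse(member, scores_desc / sum_hit, -1 / n_miss)
  max(cumsum(step))
}

#' One-signed preranked gene set enrichment
#'
#' Genes are ranked by `-log10(p)` descending; the running sum increases by
#' the gene's score (normalized by the in-set score total) at set members
#' and decreases by a constant at non-members (weight exponent 1). The
#' enrichment score is the maximum of the running sum (one-signed), and the
#' p-value comes from gene-label permutations with the +1 convention.
#'
#' @param assoc an [linear_de()] association table (columns feature, p).
#' @param gene_set character vector of member gene ids.
#' @param n_perm number of gene-label permutations (>= 1).
#' @param seed integer seed.
#' @return list with `es`, `p`, `n_perm`, `set_size`.
#' @export
ranked_gsea <- function(assoc, gene_set, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) {
    stop_ic("n_perm must be at least 1", class = "icclock_contract_error")
  }
  genes <- assoc$feature
  member_ids <- intersect(gene_set, genes)
  if (!length(member_ids)) {
    stop_ic("no gene-set member is scoreable", class = "icclock_contract_error")
  }
  if (length(member_ids) >= length(genes)) {
    stop_ic("gene set covers the whole universe: ES degenerate",
            class = "icclock_contract_error")
  }
  scores <- -log10(pmax(assoc$p, .Machine$double.xmin))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  member <- genes[o] %in% member_ids
  es <- gsea_es(s, member)
  nh <- sum(member)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      m <- logical(length(s))
      m[sample(length(s), nh)] <- TRUE
      gsea_es(s, m)
    }, numeric(1))
  })
  list(es = es, p = (1 + sum(null >= es)) / (1 + n_perm),
       n_perm = n_perm, set_size = nh)
}
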