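# Synthetic cohort generator.
#
# Emulates a lifespan cohort (ages ~20-102) carrying the statistical
# structure the downstream analyses assume: five clinical domain scores that
# are flat until a domain-specific breakpoint age and decline linearly after
# it, CpG beta values linearly coupled (on the logit scale) to intrinsic
# capacity, cell-mixture-driven CpGs, gene expression coupled to age-adjusted
# IC, and proportional-hazards survival. Ground truth (causal CpGs, IC genes,
# breakpoints, true log-HR, true cell proportions) is always returned
# alongside the data so recovery tests are possible.

#' Default clinical-domain trajectory parameters
#'
#' One row per instrument: baseline score in young adulthood, breakpoint age
#' at which decline starts, post-breakpoint slope (score units per year; the
#' PHQ-9 slope is positive because higher PHQ-9 is worse), additive offset
#' for male participants, and Gaussian noise standard deviation. Instrument
#' bounds follow the standard clinical ranges (MMSE 0-30, SPPB 0-12, PHQ-9
#' 0-27, simple eye chart 0-3, whisper test 0-2, grip strength unbounded).
#'
#' @return a data.frame with one row per domain instrument.
#' @export
default_domain_trajectories <- function() {
  data.frame(
    domain       = c("cognition", "locomotion", "psychological",
                     "sensory_vision", "sensory_hearing", "vitality"),
    baseline     = c(29, 11.5, 3, 2.9, 1.9, 38),
    breakpoint_age = c(78, 62, 60, 55, 55, 55),
    post_slope   = c(-0.30, -0.20, 0.08, -0.035, -0.025, -0.35),
    sex_offset   = c(0, 0, -1.2, -0.15, -0.10, 10),
    noise_sd     = c(1.2, 1.0, 2.5, 0.35, 0.30, 5),
    min          = c(0, 0, 0, 0, 0, 0),
    max          = c(30, 12, 27, 3, 2, Inf),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' @param n_participants cohort size.
#' @param age_range increasing pair of ages in years.
#' @param seed master integer seed; every stage derives a deterministic
#'   sub-stream from it, so the same config is bit-reproducible.
#' @param trajectories data.frame as [default_domain_trajectories()]; any
#'   subset of cells may be overridden.
#' @param missing_rate per-domain probability that a raw score is missing.
#' @param n_cpgs,n_causal_cpgs,n_celltype_cpgs methylome layout.
#' @param causal_effect_sd sd of the logit-scale slope linking a causal CpG's
#'   mean beta to IC.
#' @param beta_noise_sd Gaussian measurement noise added to every beta.
#' @param n_genes,n_ic_genes expression layout.
#' @param expression_effect_sd sd of the per-gene slope on the IC predictor
#'   (log-expression units per predictor unit).
#' @param expression_noise_sd residual sd of expression.
#' @param baseline_rate baseline hazard (events/year).
#' @param log_hr_per_sd log hazard ratio per s.d. of the risk predictor.
#' @param censor_rate independent exponential censoring rate (events/year).
#' @param horizon administrative censoring horizon (years).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 1000L,
                       age_range = c(20, 102),
                       seed = 1L,
                       trajectories = default_domain_trajectories(),
                       missing_rate = 0.007,
                       n_cpgs = 2000L,
                       n_causal_cpgs = 50L,
                       causal_effect_sd = 4,
                       beta_noise_sd = 0.03,
                       n_celltype_cpgs = 200L,
                       n_genes = 1000L,
                       n_ic_genes = 50L,
                       expression_effect_sd = 1,
                       expression_noise_sd = 1,
                       baseline_rate = 0.02,
                       log_hr_per_sd = log(1.38),
                       censor_rate = 0.015,
                       horizon = 25) {
  cfg <- list(
    n_participants = as.integer(n_participants), age_range = age_range,
    seed = as.integer(seed), trajectories = trajectories,
    missing_rate = missing_rate,
    n_cpgs = as.integer(n_cpgs), n_causal_cpgs = as.integer(n_causal_cpgs),
    causal_effect_sd = causal_effect_sd, beta_noise_sd = beta_noise_sd,
    n_celltype_cpgs = as.integer(n_celltype_cpgs),
    n_genes = as.integer(n_genes), n_ic_genes = as.integer(n_ic_genes),
    expression_effect_sd = expression_effect_sd,
    expression_noise_sd = expression_noise_sd,
    baseline_rate = baseline_rate, log_hr_per_sd = log_hr_per_sd,
    censor_rate = censor_rate, horizon = horizon
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0) {
    stop_ic("age_range must be an increasing pair of ages",
            class = "icclock_config_error")
  }
  if (cfg$n_participants < 1L) {
    stop_ic("n_participants must be positive", class = "icclock_config_error")
  }
  if (cfg$n_causal_cpgs + cfg$n_celltype_cpgs > cfg$n_cpgs) {
    stop_ic("n_causal_cpgs + n_celltype_cpgs must not exceed n_cpgs",
            class = "icclock_config_error")
  }
  if (cfg$n_ic_genes > cfg$n_genes) {
    stop_ic("n_ic_genes must not exceed n_genes",
            class = "icclock_config_error")
  }
  sds <- c(cfg$causal_effect_sd, cfg$beta_noise_sd, cfg$expression_effect_sd,
           cfg$expression_noise_sd, cfg$missing_rate, cfg$censor_rate,
           unlist(cfg$trajectories$noise_sd))
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop_ic("all sd/rate parameters must be finite and >= 0",
            class = "icclock_config_error")
  }
  if (!is.finite(cfg$baseline_rate) || cfg$baseline_rate <= 0) {
    stop_ic("baseline_rate must be positive", class = "icclock_config_error")
  }
  invisible(cfg)
}

#' Simulate a clinical cohort
#'
#' Ages are uniform over `age_range`, sex is Bernoulli(0.5), and each domain
#' raw score follows a flat-then-linear-decline trajectory in age with an
#' additive sex offset and Gaussian noise, clipped afterwards to the
#' instrument bounds. Missing raw scores are planted completely at random at
#' `missing_rate` per domain so that the complete-case rule has work to do.
#'
#' @param config a [sim_config()].
#' @return a data.frame (participant_id, age, sex, one column per domain raw
#'   score) with the generating trajectory table attached as
#'   `attr(, "truth")`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  tr <- config$trajectories
  with_seed(substream_seed(config$seed, "cohort"), {
    n <- config$n_participants
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "male", "female")
    out <- data.frame(
      participant_id = sprintf("P%05d", seq_len(n)),
      age = age, sex = sex, stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(tr))) {
      mu <- tr$baseline[i] +
        tr$sex_offset[i] * (sex == "male") +
        tr$post_slope[i] * pmax(0, age - tr$breakpoint_age[i])
      raw <- mu + stats::rnorm(n, 0, tr$noise_sd[i])
      raw <- pmin(pmax(raw, tr$min[i]), tr$max[i])
      if (config$missing_rate > 0) {
        raw[stats::runif(n) < config$missing_rate] <- NA_real_
      }
      out[[tr$domain[i]]] <- raw
    }
    attr(out, "truth") <- tr
    out
  })
}

#' Synthetic leukocyte reference matrix
#'
#' A stand-in for a published blood cell-type methylation reference: each CpG
#' is a marker for one cell type, with the marker type's mean beta offset from
#' the shared baseline. Columns are linearly independent by construction.
#'
#' @param n_cpgs number of reference CpGs.
#' @param cell_types ordered cell-type names.
#' @param seed integer seed.
#' @return a CpG x cell-type matrix of mean beta values in \[0,1\].
#' @export
synthetic_reference <- function(n_cpgs = 200L,
                                cell_types = c("CD8T", "CD4T", "NK", "B",
                                               "Mono", "Gran"),
                                seed = 2024L) {
  with_seed(seed, {
    k <- length(cell_types)
    base <- stats::runif(n_cpgs, 0.25, 0.75)
    ref <- matrix(rep(base, k), nrow = n_cpgs, ncol = k)
    marker <- rep_len(seq_len(k), n_cpgs)
    offs <- sample(c(-1, 1), n_cpgs, replace = TRUE) *
      stats::runif(n_cpgs, 0.25, 0.4)
    ref[cbind(seq_len(n_cpgs), marker)] <- base + offs
    ref <- pmin(pmax(ref, 0.01), 0.99)
    dimnames(ref) <- list(sprintf("ref%04d", seq_len(n_cpgs)), cell_types)
    ref
  })
}

# Age-trending cell proportions: granulocytes rise with age while naive
# lymphocyte compartments shrink, via a softmax over drifting log-weights.
simulate_cell_proportions <- function(age, cell_types, noise_sd = 0.25) {
  base <- c(CD8T = log(0.10), CD4T = log(0.16), NK = log(0.07),
            B = log(0.08), Mono = log(0.09), Gran = log(0.50))
  drift <- c(CD8T = -0.010, CD4T = -0.008, NK = 0.004,
             B = -0.004, Mono = 0.002, Gran = 0.008)
  base <- base[cell_types]; drift <- drift[cell_types]
  base[is.na(base)] <- log(0.1); drift[is.na(drift)] <- 0
  z <- matrix(base, nrow = length(age), ncol = length(cell_types),
              byrow = TRUE) +
    outer(age - 60, drift) +
    matrix(stats::rnorm(length(age) * length(cell_types), 0, noise_sd),
           nrow = length(age))
  p <- exp(z)
  p <- p / rowSums(p)
  colnames(p) <- cell_types
  p
}

#' Simulate a methylome coupled to intrinsic capacity
#'
#' Three CpG strata: causal CpGs whose mean beta is
#' `plogis(b0 + b1 * (ic - mean(ic)))` with `b1` drawn at
#' `causal_effect_sd`; cell-type CpGs that are convex mixtures of a
#' reference matrix with age-trending mixing proportions; and pure-noise
#' CpGs. Gaussian measurement noise is added everywhere and values are
#' clipped to \[0,1\].
#'
#' @param cohort cohort table (rows aligned to `ic`).
#' @param ic per-sample IC score.
#' @param config a [sim_config()].
#' @param reference optional CpG x cell-type reference matrix; defaults to
#'   [synthetic_reference()] with `n_celltype_cpgs` rows.
#' @return list with `betas` (CpG x sample matrix), `truth` (per-CpG stratum
#'   and planted coefficients), `reference` and `cell_props`.
#' @export
simulate_methylome <- function(cohort, ic, config, reference = NULL) {
  validate_sim_config(config)
  check_aligned(nrow(cohort), length(ic), "cohort rows", "ic scores")
  n <- nrow(cohort)
  if (is.null(reference)) {
    reference <- synthetic_reference(config$n_celltype_cpgs,
                                     seed = substream_seed(config$seed, "reference"))
  }
  with_seed(substream_seed(config$seed, "methylome"), {
    n_causal <- config$n_causal_cpgs
    n_cell <- config$n_celltype_cpgs
    if (nrow(reference) < n_cell) {
      stop_ic("reference has fewer CpGs than n_celltype_cpgs",
              class = "icclock_config_error")
    }
    n_noise <- config$n_cpgs - n_causal - n_cell
    # cell-type rows inherit the reference CpG ids so deconvolution can
    # match them; the other strata carry opaque cg identifiers
    cpg_ids <- c(sprintf("cg%06d", seq_len(n_causal)),
                 rownames(reference)[seq_len(n_cell)],
                 sprintf("cg%06d", n_causal + n_cell + seq_len(n_noise)))

    b0 <- stats::rnorm(n_causal, 0, 1.0)
    b1 <- stats::rnorm(n_causal, 0, config$causal_effect_sd)
    ic_c <- ic - mean(ic)
    causal <- stats::plogis(outer(b0, rep(1, n)) + outer(b1, ic_c))

    cell_props <- simulate_cell_proportions(cohort$age, colnames(reference))
    celltype <- reference[seq_len(n_cell), , drop = FALSE] %*% t(cell_props)

    noise_mu <- stats::runif(n_noise, 0.05, 0.95)
    noise <- matrix(rep(noise_mu, n), nrow = n_noise, ncol = n)

    betas <- rbind(causal, celltype, noise)
    if (config$beta_noise_sd > 0) {
      betas <- betas + matrix(stats::rnorm(length(betas), 0, config$beta_noise_sd),
                              nrow = nrow(betas))
    }
    betas <- pmin(pmax(betas, 0), 1)
    dimnames(betas) <- list(cpg_ids, cohort$participant_id)

    truth <- data.frame(
      cpg = cpg_ids,
      stratum = rep(c("causal", "celltype", "noise"),
                    c(n_causal, n_cell, n_noise)),
      b0 = c(b0, rep(NA_real_, n_cell + n_noise)),
      b1 = c(b1, rep(NA_real_, n_cell + n_noise)),
      stringsAsFactors = FALSE
    )
    rownames(cell_props) <- cohort$participant_id
    list(betas = betas, truth = truth, reference = reference,
         cell_props = cell_props)
  })
}

#' Simulate gene expression coupled to age-adjusted IC
#'
#' The first `n_ic_genes` genes are linear in the supplied predictor (slopes
#' drawn from `N(0, expression_effect_sd)`) plus Gaussian noise; the rest are
#' pure noise around a gene-specific baseline.
#'
#' @param cohort cohort table (rows aligned to `ic_acceleration`).
#' @param ic_acceleration per-sample age-adjusted IC predictor.
#' @param config a [sim_config()].
#' @return list with `expr` (gene x sample matrix) and `truth` (per-gene
#'   planted slope and IC-gene flag).
#' @export
simulate_expression <- function(cohort, ic_acceleration, config) {
  validate_sim_config(config)
  check_aligned(nrow(cohort), length(ic_acceleration),
                "cohort rows", "ic_acceleration")
  n <- nrow(cohort)
  with_seed(substream_seed(config$seed, "expression"), {
    g <- config$n_genes
    gene_ids <- sprintf("gene%05d", seq_len(g))
    slope <- c(stats::rnorm(config$n_ic_genes, 0, config$expression_effect_sd),
               rep(0, g - config$n_ic_genes))
    baseline <- stats::rnorm(g, 7, 2)
    expr <- outer(baseline, rep(1, n)) + outer(slope, ic_acceleration)
    if (config$expression_noise_sd > 0) {
      expr <- expr + matrix(stats::rnorm(length(expr), 0,
                                         config$expression_noise_sd),
                            nrow = g)
    }
    dimnames(expr) <- list(gene_ids, cohort$participant_id)
    truth <- data.frame(gene = gene_ids, slope = slope,
                        is_ic_gene = seq_len(g) <= config$n_ic_genes,
                        stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(log_hr_per_sd * predictor)`; censoring is the
#' minimum of an independent exponential (rate `censor_rate`) and the
#' administrative horizon.
#'
#' @param cohort cohort table.
#' @param predictor standardized (mean 0, sd 1) risk score; higher = higher
#'   hazard.
#' @param config a [sim_config()].
#' @return data.frame with `participant_id`, `survival_time` (> 0) and
#'   `event` (0/1).
#' @export
simulate_survival <- function(cohort, predictor, config) {
  validate_sim_config(config)
  check_aligned(nrow(cohort), length(predictor), "cohort rows", "predictor")
  with_seed(substream_seed(config$seed, "survival"), {
    n <- nrow(cohort)
    rate <- config$baseline_rate * exp(config$log_hr_per_sd * predictor)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (config$censor_rate > 0) {
      stats::rexp(n, config$censor_rate)
    } else rep(Inf, n)
    t_cens <- pmin(t_cens, config$horizon)
    data.frame(
      participant_id = cohort$participant_id,
      survival_time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE
    )
  })
}

# Health and lifestyle covariates for the association screens: a block of
# health variables linearly coupled to IC (gait speed and lung function
# positively, CRP/IL-6-style inflammation negatively) and a block of
# lifestyle features of which a configurable number are null.
simulate_health_variables <- function(cohort, ic, seed,
                                      n_lifestyle = 8L, n_linked = 3L) {
  check_aligned(nrow(cohort), length(ic), "cohort rows", "ic")
  with_seed(substream_seed(seed, "health"), {
    n <- nrow(cohort)
    z <- as.numeric(scale(ic))
    health <- data.frame(
      gait_speed    =  0.8 * z + stats::rnorm(n, 1.2, 0.6),
      lung_fev1     =  0.7 * z + stats::rnorm(n, 3.0, 0.7),
      bone_density  =  0.5 * z + stats::rnorm(n, 1.0, 0.8),
      crp           = -0.6 * z + stats::rnorm(n, 2.0, 0.9),
      il6           = -0.5 * z + stats::rnorm(n, 1.5, 0.9),
      tau           = -0.4 * z + stats::rnorm(n, 1.0, 1.0)
    )
    lifestyle <- matrix(stats::rnorm(n * n_lifestyle), nrow = n)
    colnames(lifestyle) <- sprintf("lifestyle%02d", seq_len(n_lifestyle))
    for (j in seq_len(min(n_linked, n_lifestyle))) {
      lifestyle[, j] <- lifestyle[, j] + 0.4 * z
    }
    rownames(health) <- cohort$participant_id
    rownames(lifestyle) <- cohort$participant_id
    list(health = health, lifestyle = as.data.frame(lifestyle))
  })
}
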