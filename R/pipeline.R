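# End-to-end pipeline: simulate (optional) -> IC score -> age trends ->
# clock training -> prediction -> acceleration -> deconvolution ->
# association -> survival -> health. Each stage writes a CSV artifact and
# the run ends with a JSON manifest (seed, parameters, per-file checksums)
# that is byte-reproducible from config + seed.

#' Default pipeline configuration
#'
#' Small enough to run end-to-end in well under a minute while leaving every
#' stage statistically non-trivial.
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("icclock_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    sim = sim_config(n_participants = 400L, n_cpgs = 600L,
                     n_causal_cpgs = 20L, n_celltype_cpgs = 100L,
                     n_genes = 400L, n_ic_genes = 30L,
                     expression_effect_sd = 15, seed = seed),
    alpha_grid = seq(0.1, 1, by = 0.1),
    folds = 10L,
    bin_width = 0.05,
    min_bin_count = 10L,
    n_perm = 1000L,
    fdr = 0.05,
    tau = 20,
    survival = TRUE
  )
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic cohort, writes per-stage CSVs, a
#' human-readable `summary.txt` and a machine-readable `manifest.json`
#' containing the seed, parameters, package version and md5 checksum of
#' every artifact. Identical config and seed produce byte-identical
#' artifacts and manifest.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[icclock] ", ...)
  files <- character()
  skipped <- character()

  log_stage("simulate")
  cohort <- simulate_cohort(config$sim)
  files["cohort"] <- write_stage_csv(cohort, config$outdir, "cohort")

  log_stage("score")
  scores <- ic_score(cohort)
  files["ic_scores"] <- write_stage_csv(as.data.frame(scores), config$outdir,
                                        "ic_scores")

  log_stage("trends")
  trends <- age_trend_table(scores, cohort)
  files["age_trends"] <- write_stage_csv(trends, config$outdir, "age_trends")

  cc <- cohort[match(scores$participant_id, cohort$participant_id), ]
  meth <- simulate_methylome(cc, scores$overall_ic, config$sim)
  files["betas"] <- {
    p <- file.path(config$outdir, "betas.csv")
    write_beta_matrix(meth$betas, p); p
  }
  files["cpg_truth"] <- write_stage_csv(meth$truth, config$outdir, "cpg_truth")

  log_stage("train")
  bf <- bin_filter(scores$overall_ic, config$bin_width, config$min_bin_count)
  cv <- cv_elastic_net(meth$betas[, bf$keep, drop = FALSE],
                       scores$overall_ic[bf$keep],
                       alphas = config$alpha_grid, folds = config$folds,
                       seed = substream_seed(config$seed, "cv"))
  model <- select_model(cv, meth$betas[, bf$keep, drop = FALSE],
                        scores$overall_ic[bf$keep])
  files["clock_model"] <- {
    p <- file.path(config$outdir, "clock_model.csv")
    write_clock_model(model, p); p
  }

  log_stage("predict + accelerate")
  dnam_ic <- predict_clock(model, meth$betas)
  accel <- age_acceleration(dnam_ic, cc$age)
  pred <- data.frame(participant_id = cc$participant_id,
                     dnam_ic = unname(dnam_ic), acceleration = accel)
  files["predictions"] <- write_stage_csv(pred, config$outdir, "predictions")

  log_stage("deconvolve")
  props <- estimate_proportions(meth$betas, meth$reference)
  cellcor <- cellcount_ic_correlations(props, cc$age, dnam_ic)
  files["cell_proportions"] <- write_stage_csv(
    data.frame(participant_id = rownames(props), props,
               check.names = FALSE),
    config$outdir, "cell_proportions")
  files["cell_correlations"] <- write_stage_csv(cellcor, config$outdir,
                                                "cell_correlations")

  log_stage("associate")
  exprs <- simulate_expression(cc, accel, config$sim)
  de <- linear_de(exprs$expr, accel, fdr = config$fdr)
  files["de_table"] <- write_stage_csv(de, config$outdir, "de_table")
  sig <- de$feature[de$significant]
  linkage <- NULL
  if (length(sig) >= 1L) {
    clock_cpgs <- intersect(names(model$weights), rownames(meth$betas))
    linkage <- cpg_gene_linkage(meth$betas[clock_cpgs, , drop = FALSE],
                                exprs$expr[sig, , drop = FALSE],
                                n_perm = config$n_perm,
                                seed = substream_seed(config$seed, "linkage"))
    files["linkage"] <- write_stage_csv(
      data.frame(observed = linkage$observed, null_mean = linkage$null_mean,
                 p = linkage$p, n_perm = linkage$n_perm),
      config$outdir, "linkage")
  }

  surv_res <- NULL
  if (isTRUE(config$survival)) {
    log_stage("survive")
    risk <- -as.numeric(scale(scores$overall_ic))
    surv <- simulate_survival(cc, risk, config$sim)
    cox <- cox_fit(surv$survival_time, surv$event, -accel,
                   covariates = data.frame(age = cc$age, sex = cc$sex))
    grp <- quintile_groups(accel)
    ext <- grp != "mid"
    km <- kaplan_meier(surv$survival_time[ext], surv$event[ext],
                       droplevels(grp[ext]))
    lr <- logrank_test(surv$survival_time[ext], surv$event[ext],
                       droplevels(grp[ext]))
    tau <- min(config$tau, max(km$highest20$time), max(km$lowest20$time))
    rmst <- rmst_difference(km$highest20, km$lowest20, tau)
    surv_res <- list(cox = cox, logrank = lr, rmst = rmst, tau = tau)
    files["survival"] <- write_stage_csv(
      cbind(surv, group = as.character(grp)), config$outdir, "survival")
    files["mortality"] <- write_stage_csv(
      data.frame(hr = cox$hr, ci_low = cox$ci[1], ci_high = cox$ci[2],
                 p_wald = cox$p, p_logrank = lr$p, rmst_diff_years = rmst,
                 tau = tau),
      config$outdir, "mortality")
  } else {
    skipped <- c(skipped, "survival")
  }

  log_stage("health")
  hv <- simulate_health_variables(cc, scores$overall_ic, config$seed)
  pc1 <- overall_health_pc1(hv$health, anchor = "gait_speed")
  grp <- quintile_groups(accel)
  ext <- grp != "mid"
  health_assoc <- do.call(rbind, lapply(names(hv$health), function(v) {
    res <- tryCatch(
      logistic_assoc(ifelse(grp[ext] == "highest20", "high", "low"),
                     hv$health[[v]][ext]),
      icclock_nonestimable = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(variable = v, or = res$or, p = res$p,
               stringsAsFactors = FALSE)
  }))
  lifestyle <- lifestyle_screen(dnam_ic, hv$lifestyle, fdr = config$fdr)
  files["health_pc1"] <- write_stage_csv(
    data.frame(participant_id = names(pc1), overall_health = unname(pc1)),
    config$outdir, "health_pc1")
  files["health_assoc"] <- write_stage_csv(health_assoc, config$outdir,
                                           "health_assoc")
  files["lifestyle"] <- write_stage_csv(lifestyle, config$outdir, "lifestyle")

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("icclock")),
    parameters = list(
      n_participants = config$sim$n_participants,
      n_cpgs = config$sim$n_cpgs, alpha_grid = config$alpha_grid,
      folds = config$folds, bin_width = config$bin_width,
      min_bin_count = config$min_bin_count, n_perm = config$n_perm,
      fdr = config$fdr, tau = config$tau
    ),
    skipped_stages = as.list(skipped),
    checksums = as.list(tools::md5sum(unname(files)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  summary_lines <- c(
    sprintf("icclock pipeline run (seed %d)", config$seed),
    sprintf("participants scored: %d (removed %d incomplete)",
            nrow(scores), attr(scores, "n_removed")),
    sprintf("clock: alpha %.1f, %d CpGs, CV MAE %.4f, CV corr %.3f",
            model$alpha, model$n_cpgs, model$cv_mae, model$cv_corr),
    sprintf("DE genes at FDR<%.2f: %d", config$fdr, length(sig)),
    if (!is.null(linkage)) {
      sprintf("CpG-gene linkage: observed %.3f vs chance %.3f (p %.4g)",
              linkage$observed, linkage$null_mean, linkage$p)
    },
    if (!is.null(surv_res)) {
      sprintf("mortality: HR %.3f per s.d. (p %.3g), RMST diff %.2f years",
              surv_res$cox$hr, surv_res$cox$p, surv_res$rmst)
    }
  )
  writeLines(summary_lines, file.path(config$outdir, "summary.txt"))

  invisible(list(cohort = cohort, scores = scores, trends = trends,
                 model = model, dnam_ic = dnam_ic, acceleration = accel,
                 proportions = props, de = de, linkage = linkage,
                 survival = surv_res, health_pc1 = pc1,
                 lifestyle = lifestyle, manifest = manifest,
                 files = files, outdir = config$outdir))
}
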