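# Synthetic cohort generator: determinism, bounds, planted structure.

test_that("same config and seed give bit-identical outputs", {
  cfg <- sim_config(n_participants = 200L, seed = 1L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  sc <- ic_score(a)
  cc <- a[match(sc$participant_id, a$participant_id), ]
  m1 <- simulate_methylome(cc, sc$overall_ic, cfg)
  m2 <- simulate_methylome(cc, sc$overall_ic, cfg)
  expect_identical(m1$betas, m2$betas)

  s1 <- simulate_survival(cc, scale(sc$overall_ic)[, 1], cfg)
  s2 <- simulate_survival(cc, scale(sc$overall_ic)[, 1], cfg)
  expect_identical(s1, s2)
})

test_that("noise-free trajectories sit strictly below baseline past the breakpoint", {
  tr <- default_domain_trajectories()
  tr$noise_sd[] <- 0
  cfg <- sim_config(n_participants = 300L, seed = 2L, trajectories = tr,
                    missing_rate = 0)
  ch <- simulate_cohort(cfg)
  for (i in seq_len(nrow(tr))) {
    d <- tr$domain[i]
    past <- ch$age > tr$breakpoint_age[i] + 1e-9
    expected_base <- tr$baseline[i] + tr$sex_offset[i] * (ch$sex == "male")
    if (tr$post_slope[i] < 0) {
      expect_true(all(ch[[d]][past] < expected_base[past] |
                        ch[[d]][past] == tr$min[i]))
    } else if (tr$post_slope[i] > 0) {
      expect_true(all(ch[[d]][past] > expected_base[past] |
                        ch[[d]][past] == tr$max[i]))
    }
    flat <- ch$age <= tr$breakpoint_age[i]
    expect_equal(ch[[d]][flat], expected_base[flat])
  }
})

test_that("raw scores stay within instrument bounds and betas within [0,1]", {
  cfg <- sim_config(n_participants = 150L, seed = 3L, beta_noise_sd = 0.1)
  ch <- simulate_cohort(cfg)
  tr <- attr(ch, "truth")
  for (i in seq_len(nrow(tr))) {
    v <- ch[[tr$domain[i]]]
    expect_true(all(is.na(v) | (v >= tr$min[i] & v <= tr$max[i])))
  }
  sc <- ic_score(ch)
  cc <- ch[match(sc$participant_id, ch$participant_id), ]
  m <- simulate_methylome(cc, sc$overall_ic, cfg)
  expect_gte(min(m$betas), 0)
  expect_lte(max(m$betas), 1)
  expect_false(anyDuplicated(rownames(m$betas)) > 0)
})

test_that("a strong noise-free causal CpG is strictly monotone in IC", {
  cfg <- sim_config(n_participants = 80L, seed = 4L, n_cpgs = 60L,
                    n_causal_cpgs = 5L, n_celltype_cpgs = 20L,
                    causal_effect_sd = 10, beta_noise_sd = 0)
  ch <- simulate_cohort(cfg)
  sc <- ic_score(ch)
  cc <- ch[match(sc$participant_id, ch$participant_id), ]
  m <- simulate_methylome(cc, sc$overall_ic, cfg)
  causal <- m$truth[m$truth$stratum == "causal", ]
  # beta = plogis(b0 + b1*(ic - mean)) with no noise: |spearman| = 1
  for (j in which(abs(causal$b1) > 1)) {
    rho <- cor(m$betas[causal$cpg[j], ], sc$overall_ic, method = "spearman")
    expect_equal(abs(rho), 1, tolerance = 1e-12)
  }
})

test_that("causal_effect_sd = 0 yields a null methylome", {
  cfg <- sim_config(n_participants = 1000L, seed = 5L, n_cpgs = 300L,
                    n_causal_cpgs = 100L, n_celltype_cpgs = 50L,
                    causal_effect_sd = 0)
  ch <- simulate_cohort(cfg)
  sc <- ic_score(ch)
  cc <- ch[match(sc$participant_id, ch$participant_id), ]
  m <- simulate_methylome(cc, sc$overall_ic, cfg)
  causal <- m$truth$cpg[m$truth$stratum == "causal"]
  rhos <- apply(m$betas[causal, ], 1, function(b) {
    if (sd(b) == 0) return(0)
    cor(b, sc$overall_ic, method = "spearman")
  })
  expect_gte(mean(abs(rhos) < 0.1), 0.95)
})

test_that("survival generator honours its limiting cases", {
  cfg <- sim_config(n_participants = 200L, seed = 6L, censor_rate = 1e6)
  ch <- simulate_cohort(cfg)
  pred <- scale(rnorm(nrow(ch)))[, 1]
  sv <- simulate_survival(ch, pred, cfg)
  expect_true(all(sv$event == 0L))
  expect_true(all(sv$survival_time > 0))

  cfg0 <- sim_config(n_participants = 2000L, seed = 7L, log_hr_per_sd = 0,
                     censor_rate = 0.01)
  ch0 <- simulate_cohort(cfg0)
  pred0 <- scale(rnorm(nrow(ch0)))[, 1]
  sv0 <- simulate_survival(ch0, pred0, cfg0)
  cx <- cox_fit(sv0$survival_time, sv0$event, pred0)
  expect_gte(cx$hr, 0.9)
  expect_lte(cx$hr, 1.1)
})

test_that("zero-noise planted expression is recovered exactly by the DE stage", {
  cfg <- sim_config(n_participants = 50L, seed = 8L, n_genes = 30L,
                    n_ic_genes = 5L, expression_effect_sd = 2,
                    expression_noise_sd = 0, missing_rate = 0)
  ch <- simulate_cohort(cfg)
  accel <- rnorm(nrow(ch))
  ex <- simulate_expression(ch, accel, cfg)
  de <- linear_de(ex$expr, accel)
  planted <- ex$truth[ex$truth$is_ic_gene, ]
  est <- de$effect[match(planted$gene, de$feature)]
  expect_equal(est, planted$slope, tolerance = 1e-8)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(age_range = c(80, 20)), class = "icclock_config_error")
  expect_error(sim_config(n_causal_cpgs = 3000, n_cpgs = 100),
               class = "icclock_config_error")
  expect_error(sim_config(causal_effect_sd = -1), class = "icclock_config_error")
  expect_error(sim_config(baseline_rate = 0), class = "icclock_config_error")
  cfg <- sim_config(n_participants = 10L)
  ch <- simulate_cohort(cfg)
  expect_error(simulate_methylome(ch, c(0.5, 0.6), cfg),
               class = "icclock_alignment_error")
})
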