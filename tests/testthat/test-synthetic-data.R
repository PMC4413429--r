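test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_sim_config(n_genes = 10, seed = 1)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  e1 <- simulate_expression(a1, cfg)
  e2 <- simulate_expression(a2, cfg)
  expect_identical(e1, e2)
  t1 <- simulate_chip_coverage(a1, e1$truth, cfg)
  t2 <- simulate_chip_coverage(a1, e1$truth, cfg)
  expect_identical(t1, t2)
  # and written artifacts are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(list(annotation = a1, expression = e1$matrix,
                        truth = e1$truth, tracks = t1, config = cfg,
                        seed = 1), d1)
  write_simulation(list(annotation = a2, expression = e2$matrix,
                        truth = e2$truth, tracks = t2, config = cfg,
                        seed = 1), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("TSS placement honours end clearance and spacing", {
  cfg <- small_sim_config(n_genes = 120, min_tss_spacing = 8000, seed = 4)
  ann <- simulate_annotation(cfg)
  g <- ann$genes
  expect_true(all(g$tss >= 3000))
  expect_true(all(g$tss <= cfg$chrom_length - 3001))
  for (ch in unique(g$chrom)) {
    tss <- sort(g$tss[g$chrom == ch])
    if (length(tss) > 1) expect_true(all(diff(tss) >= 8000))
  }
  expect_error(simulate_annotation(sim_config(n_genes = 100, n_chroms = 1,
                                              chrom_length = 5e4)),
               "chromosome too short")
})

test_that("n_genes = 0 yields a valid empty annotation", {
  ann <- simulate_annotation(small_sim_config(n_genes = 0))
  expect_s3_class(ann, "GenomeAnnotation")
  expect_identical(nrow(ann$genes), 0L)
})

test_that("delta = 0 with zero DE fractions plants no effects", {
  cfg <- small_sim_config(n_genes = 50, de_frac_down = 0, de_frac_up = 0,
                          delta = 0)
  ex <- simulate_expression(simulate_annotation(cfg), cfg)
  expect_true(all(ex$truth$class == "null"))
  expect_true(all(ex$truth$log2fc_true == 0))
  expect_true(all(ex$matrix$values > 0))
})

test_that("variance prior is recoverable from sampled true variances", {
  cfg <- sim_config(n_genes = 2000, n_chroms = 2, chrom_length = 1e7,
                    d0_true = 4, s0sq_true = 0.05, seed = 7)
  ex <- simulate_expression(simulate_annotation(cfg), cfg)
  v <- ex$truth$var_true
  # independent method-of-moments on log variances:
  # log v = log(s0^2 d0) - log chi2_{d0}
  half <- stats::uniroot(function(x) trigamma(x) - stats::var(log(v)),
                         lower = 1e-6, upper = 1e6, tol = 1e-12)$root
  d0_hat <- 2 * half
  s0sq_hat <- exp(mean(log(v)) + digamma(half) + log(2)) / d0_hat
  expect_lt(abs(d0_hat - 4) / 4, 0.15)
  expect_lt(abs(s0sq_hat - 0.05) / 0.05, 0.15)
})

test_that("null genes have mean sample log2FC near 0 (CLT bound)", {
  cfg <- sim_config(n_genes = 2000, n_chroms = 2, chrom_length = 1e7,
                    de_frac_down = 0, de_frac_up = 0, seed = 5)
  ex <- simulate_expression(simulate_annotation(cfg), cfg)
  x <- log2(ex$matrix$values)
  geno <- ex$matrix$samples$genotype
  lfc <- rowMeans(x[, geno == "KO"]) - rowMeans(x[, geno == "WT"])
  # per-gene lfc variance is sigma_g^2 * (2/3); bound the mean by 3 SE
  se <- sqrt(sum(ex$truth$var_true * (2 / 3)) / length(lfc)^2)
  expect_lt(abs(mean(lfc)), 3 * se)
})

test_that("zero amplitude makes the ChIP track match the input statistically", {
  cfg <- small_sim_config(n_genes = 20, peak_amplitude = 0, seed = 2)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(ann, cfg)
  tracks <- simulate_chip_coverage(ann, ex$truth, cfg)
  expected <- cfg$background_rate * cfg$depth * sum(ann$chrom_lengths)
  for (id in c("H3ac_WT", "input_WT"))
    expect_lt(abs(tracks[[id]]$total_signal - expected), 3 * sqrt(expected))
})

test_that("background-only Poisson totals match the analytic expectation", {
  cfg <- sim_config(n_genes = 0, n_chroms = 1, chrom_length = 1e6,
                    background_rate = 0.01, depth = 1, seed = 3)
  ann <- simulate_annotation(cfg)
  truth <- data.frame(gene_id = character(), class = character(),
                      log2fc_true = numeric(), var_true = numeric(),
                      amp_wt = numeric(), amp_ko = numeric())
  tracks <- simulate_chip_coverage(ann, truth, cfg)
  expect_lt(abs(tracks$H3ac_WT$total_signal - 1e4), 3 * sqrt(1e4))
})

test_that("TSS-proximal windowed mean matches the Gaussian-peak integral", {
  cfg <- small_sim_config(n_genes = 60, peak_amplitude = 2, peak_sd = 300,
                          de_frac_down = 0, de_frac_up = 0, seed = 8)
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(ann, cfg)
  tracks <- simulate_chip_coverage(ann, ex$truth, cfg)
  grid <- window_grid()
  central <- which(abs(grid$offsets) <= 50)  # windows covering the summit
  vals <- vapply(seq_len(nrow(ann$genes)), function(i)
    mean(windowed_density(tracks$H3ac_WT, ann$genes$chrom[i],
                          ann$genes$tss[i], ann$genes$strand[i],
                          grid)[central]), numeric(1))
  # analytic per-base mean over a 100-bp summit window
  b <- -50:49
  expected <- cfg$background_rate + 2 * mean(exp(-b^2 / (2 * 300^2)))
  se <- sqrt(expected / (100 * length(vals)))
  expect_lt(abs(mean(vals) - expected), 4 * se)
})

test_that("increasing delta increases mean |moderated t| of DE genes", {
  mean_abs_t <- function(delta, seed) {
    cfg <- small_sim_config(n_genes = 300, delta = delta, seed = seed,
                            de_frac_down = 0.1, de_frac_up = 0.1)
    ann <- simulate_annotation(cfg)
    ex <- simulate_expression(ann, cfg)
    de <- suppressWarnings(
      moderated_t_test(vst_transform(ex$matrix, "log2")))
    idx <- ex$truth$class != "null"
    mean(abs(de$table$t_mod[match(ex$truth$gene_id[idx],
                                  de$table$gene_id)]))
  }
  for (seed in 1:3)
    expect_lt(mean_abs_t(0.5, seed), mean_abs_t(1.5, seed))
})

test_that("attenuation rho = 1 leaves WT and KO exchangeable", {
  effects <- vapply(1:10, function(seed) {
    cfg <- small_sim_config(n_genes = 60, ko_down_attenuation = 1,
                            de_frac_down = 0.5, de_frac_up = 0,
                            seed = seed)
    ann <- simulate_annotation(cfg)
    ex <- simulate_expression(ann, cfg)
    tracks <- depth_normalize(simulate_chip_coverage(ann, ex$truth, cfg))
    down <- ex$truth$gene_id[ex$truth$class == "down"]
    compare_profiles(tracks$H3ac_WT, tracks$H3ac_KO, ann, down)$effect
  }, numeric(1))
  # signs should be balanced: with no planted chromatin effect the
  # WT-KO effect is symmetric around zero
  expect_gte(sum(effects > 0), 1)
  expect_lte(sum(effects > 0), 9)
  expect_lt(abs(mean(effects)), 3 * stats::sd(effects) / sqrt(10))
})

test_that("asymmetric peaks respect gene orientation", {
  cfg <- small_sim_config(n_genes = 0, peak_sd = 100,
                          peak_sd_downstream = 400)
  # expected rates via the dense oracle on a plus and a minus gene
  lam_p <- chipcomposite:::chip_lambda_chrom(10000, 5000, 1, "+", cfg)
  lam_m <- chipcomposite:::chip_lambda_chrom(10000, 5000, 1, "-", cfg)
  # plus gene: wide side downstream (right); minus gene mirrored
  expect_gt(lam_p[5000 + 1 + 300], lam_p[5000 + 1 - 300])
  expect_equal(lam_m[5000 + 1 - 300], lam_p[5000 + 1 + 300], tolerance = 1e-12)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(de_frac_down = 0.6, de_frac_up = 0.5), "< 1")
  expect_error(sim_config(ko_down_attenuation = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(background_rate = 0), "positive")
})
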