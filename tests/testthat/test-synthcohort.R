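test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(pi_los = 1.5), "pi_los")
  expect_error(sim_config(implantation_prob = -0.1), "implantation_prob")
  expect_error(sim_config(n_de_genes = 50, n_genes = 10), "n_de_genes")
  expect_error(sim_config(libsize_range = c(2, 1)), "libsize_range")
  expect_error(sim_config(measurement_cv = -1), "measurement_cv")
  expect_error(sim_config(growth_divergence_d55 = 2), "growth_divergence_d55")
})

test_that("generation is deterministic and substreams are independent", {
  cfg <- sim_config(seed = 5, n_genes = 80)
  a <- simulate_cohort(cfg, day = 105)
  b <- simulate_cohort(cfg, day = 105)
  expect_identical(a, b)
  meta <- sample_meta_from_cohort(a$fetuses)
  expect_identical(simulate_counts(cfg, meta)$counts, simulate_counts(cfg, meta)$counts)
  # enlarging the gene panel leaves the cohort stream untouched
  big <- sim_config(seed = 5, n_genes = 200)
  expect_identical(simulate_cohort(big, day = 105)$fetuses, a$fetuses)
  folds <- stats::setNames(rep(1, 4), sprintf("s%d", 1:4))
  expect_identical(simulate_qpcr(cfg, folds), simulate_qpcr(cfg, folds))
})

test_that("cohort marginals match the configured distributions", {
  cfg <- sim_config(seed = 31, n_ai_dams = 600, n_ivp_dams = 1200,
                    female_loss_d105 = 0, pi_los = 0)
  coh <- simulate_cohort(cfg, day = 105)
  expect_gt(nrow(coh$fetuses), 1000)
  # sex ratio at p_female = 0.5 with no loss
  pf <- mean(coh$fetuses$sex == "F")
  se <- sqrt(0.25 / nrow(coh$fetuses))
  expect_lt(abs(pf - 0.5), 3 * se)
  # log-weight mean/SD within 3 standard errors per sex
  for (s in c("M", "F")) {
    lw <- log(coh$fetuses$weight_g[coh$fetuses$sex == s])
    wp <- cfg$weight_params[cfg$weight_params$sex == s & cfg$weight_params$day == 105, ]
    n <- length(lw)
    expect_lt(abs(mean(lw) - wp$meanlog), 3 * wp$sdlog / sqrt(n))
    expect_lt(abs(stats::sd(lw) - wp$sdlog), 3 * wp$sdlog / sqrt(2 * n))
  }
  # AI dams carry singletons; IVP dams at most two fetuses
  per_dam <- table(coh$fetuses$dam_id)
  ai <- grepl("^AI", names(per_dam))
  expect_true(all(per_dam[ai] == 1))
  expect_true(all(per_dam[!ai] <= 2))
})

test_that("the percentile classifier false-flags about 3% of exchangeable IVP fetuses", {
  cfg <- sim_config(seed = 32, n_ai_dams = 500, n_ivp_dams = 1000,
                    female_loss_d105 = 0, pi_los = 0)
  coh <- simulate_cohort(cfg, day = 105)
  labs <- classify_los(coh$fetuses)
  frac <- los_prevalence(labs)
  n_ivp <- sum(coh$fetuses$group == "IVP")
  # threshold-estimation noise shifts the whole cohort coherently, so the
  # tolerance is wider than the binomial standard error alone
  expect_lt(abs(frac - 0.03), 0.025)
  expect_gt(n_ivp, 800)
})

test_that("IVP-specific female loss skews the D105 sex ratio only", {
  cfg <- sim_config(seed = 33, n_ai_dams = 400, n_ivp_dams = 800, female_loss_d105 = 0.6)
  coh105 <- simulate_cohort(cfg, day = 105)
  coh56 <- simulate_cohort(cfg, day = 56)
  f105 <- mean(coh105$fetuses$sex[coh105$fetuses$group == "IVP"] == "F")
  f56 <- mean(coh56$fetuses$sex[coh56$fetuses$group == "IVP"] == "F")
  fai <- mean(coh105$fetuses$sex[coh105$fetuses$group == "AI"] == "F")
  expect_lt(f105, 0.35)
  expect_gt(f56, 0.45)
  expect_gt(fai, 0.45)
})

test_that("with noise and effects zeroed every biometric is exactly allometric", {
  cfg <- sim_config(seed = 34, n_ai_dams = 20, n_ivp_dams = 20,
                    measurement_cv = 0, pi_los = 0)
  coh <- simulate_cohort(cfg, day = 56)
  w55 <- coh$truth$weight_d55[coh$exams$fetus_id]
  base <- loscreen:::.d55_base_shape
  for (m in names(base)) {
    expected <- base[[m]] * (w55 / coh$truth$ref_weight)^(1 / 3)
    expect_equal(coh$exams[[m]], unname(expected), tolerance = 1e-12)
  }
})

test_that("simulated counts carry the planted structure", {
  cfg <- sim_config(seed = 35, n_genes = 150, n_de_genes = 10, n_stable_genes = 10,
                    de_log2fc = 3)
  coh <- simulate_cohort(cfg, day = 105)
  meta <- sample_meta_from_cohort(coh$fetuses, n_dams = 23)
  sc <- simulate_counts(cfg, meta)
  expect_true(all(sc$counts >= 0))
  expect_identical(storage.mode(sc$counts), "integer")
  expect_equal(sum(sc$truth$de), 10)
  expect_equal(sum(sc$truth$stable), 10)
  # planted genes are visibly shifted in extreme samples
  de <- names(which(sc$truth$de))
  ex <- meta$sample_id[meta$extreme]
  rest <- meta$sample_id[!meta$extreme]
  norm <- normalize_counts(sc$counts, size_factors_mor(sc$counts))
  shift <- log2(rowMeans(norm[de, ex, drop = FALSE]) + 1) -
           log2(rowMeans(norm[de, rest, drop = FALSE]) + 1)
  expect_gt(median(shift), 1.5)
  expect_error(simulate_counts(cfg, meta[0, ]), "samples")
})

test_that("null count simulations yield uniform LRT p-values", {
  cfg <- sim_config(seed = 36, n_genes = 400, n_de_genes = 0, n_stable_genes = 0,
                    de_log2fc = 0, dam_effect_sd = 0)
  coh <- simulate_cohort(cfg, day = 105)
  meta <- sample_meta_from_cohort(coh$fetuses, n_dams = 23)
  sc <- simulate_counts(cfg, meta)
  tb <- nb_lrt(sc$counts, meta, ~extreme, ~1, backend = "B")
  ks <- suppressWarnings(stats::ks.test(tb$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("dam expression profiles make a dam's two samples nearest neighbours", {
  cfg <- sim_config(seed = 37, n_genes = 300, n_de_genes = 0, dam_effect_sd = 1)
  coh <- simulate_cohort(cfg, day = 105)
  meta <- sample_meta_from_cohort(coh$fetuses, n_dams = 23)
  sc <- simulate_counts(cfg, meta)
  norm <- normalize_counts(sc$counts, size_factors_mor(sc$counts), log2 = TRUE)
  D <- as.matrix(stats::dist(t(norm)))
  diag(D) <- Inf
  nn <- colnames(D)[apply(D, 1, which.min)]
  dam_of <- function(x) sub("^D[0-9]+_", "", x)
  mutual <- mapply(function(a, b) dam_of(a) == dam_of(b), rownames(D), nn)
  expect_gt(mean(mutual), 0.8)
})

test_that("qPCR simulation inverts exactly at zero noise and recovers under noise", {
  cfg <- sim_config(seed = 38)
  base <- sprintf("b%02d", 1:10)
  folds <- stats::setNames(c(rep(1, 10), 2), c(base, "t1"))
  tab <- simulate_qpcr(cfg, folds, noise_sd = 0)
  res <- ddct_fold(tab, "TTF1", baseline = base)
  expect_equal(res$fold[res$sample_id == "t1"], 2, tolerance = 1e-12)
  expect_true(all(abs(res$fold[res$baseline] - 1) < 1e-12))
  # Monte-Carlo recovery: mean estimated fold within 5% of truth at sd 0.1
  est <- vapply(1:100, function(i) {
    tabi <- simulate_qpcr(sim_config(seed = 1000 + i), folds, noise_sd = 0.1)
    resi <- ddct_fold(tabi, "TTF1", baseline = base)
    resi$fold[resi$sample_id == "t1"]
  }, numeric(1))
  expect_lt(abs(mean(est) / 2 - 1), 0.05)
  expect_error(simulate_qpcr(cfg, stats::setNames(c(1, -2), c("a", "b"))), "folds")
})

test_that("fixtures conserve the published subgroup counts and ranges", {
  f56 <- study_fixture(56)
  expect_equal(nrow(f56$fetuses), 57)
  expect_equal(sum(f56$fetuses$group == "IVP"), 43)
  expect_equal(f56$thresholds, c(M = 10.18, F = 10.16))
  rng <- function(fx, g, s) range(fx$fetuses$weight_g[fx$fetuses$group == g & fx$fetuses$sex == s])
  expect_equal(rng(f56, "AI", "M"), c(6.21, 10.27))
  expect_equal(rng(f56, "IVP", "F"), c(5.55, 10.31))

  f105 <- study_fixture(105)
  expect_equal(sum(f105$fetuses$group == "AI"), 12)
  expect_equal(sum(f105$fetuses$group == "IVP"), 46)
  expect_equal(f105$thresholds, c(M = 548.92, F = 463.14))
  expect_equal(rng(f105, "AI", "M"), c(442, 550))
  expect_equal(rng(f105, "IVP", "M"), c(366, 1080))
  expect_equal(rng(f105, "IVP", "F"), c(318, 986))
  tab <- table(f105$fetuses$sex[f105$fetuses$group == "IVP"])
  expect_equal(as.integer(tab[c("M", "F")]), c(33L, 13L))
  labs <- classify_los(f105$fetuses, thresholds = f105$thresholds)
  expect_equal(sum(labs$labels$label == "IVP-LOS"), 17)
  expect_error(study_fixture(77), "day")
})
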