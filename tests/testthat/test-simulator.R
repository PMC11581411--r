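# Genotype chain, scenario generation, Wishart LD perturbation, replication.

test_that("independent chain gives uncorrelated genotypes with target MAF", {
  g <- markov_genotypes(c(0.2, 0.35), 0, 10000, seed = 1)
  expect_true(all(g %in% 0:2))
  expect_lt(abs(cor(g)[1, 2]), 3 / sqrt(10000))
  expect_lt(max(abs(colMeans(g) / 2 - c(0.2, 0.35))), 3 * sqrt(0.35 * 0.65 / 20000))
})

test_that("successive genotype correlations match their targets", {
  # moment check over repeated draws
  devs <- sapply(1:20, function(s) {
    g <- markov_genotypes(c(0.3, 0.3), 0.7, 10000, seed = s)
    cor(g)[1, 2] - 0.7
  })
  expect_lt(abs(mean(devs)), 0.01)
  expect_lt(max(abs(devs)), 0.03)
})

test_that("non-adjacent correlations follow the Markov product", {
  g <- markov_genotypes(c(0.25, 0.3, 0.35), c(0.5, 0.6), 200000, seed = 3)
  expect_equal(cor(g)[1, 3], 0.5 * 0.6, tolerance = 0.02)
  R <- markov_ld_matrix(c(0.5, 0.6))
  expect_equal(R[1, 3], 0.3)
  expect_equal(diag(R), rep(1, 3), ignore_attr = TRUE)
})

test_that("PC1 of a standardized correlated pair explains (1 + r)/2 of variance", {
  r <- 0.6
  g <- markov_genotypes(c(0.3, 0.3), r, 20000, seed = 4)
  ev <- prcomp(g, scale. = TRUE)$sdev^2
  expect_equal(ev[1] / sum(ev), (1 + r) / 2, tolerance = 0.02)
})

test_that("infeasible MAF/LD corners are clipped with a warning (or error in strict mode)", {
  w <- testthat::capture_warnings(
    g <- markov_genotypes(c(0.05, 0.45), 0.9, 1000, seed = 5)
  )
  expect_true(all(grepl("Frechet", w)))
  expect_gte(length(w), 1)
  expect_true(all(g %in% 0:2))
  expect_error(
    markov_genotypes(c(0.05, 0.45), 0.9, 1000, seed = 5, strict = TRUE),
    "infeasible"
  )
})

test_that("generation is deterministic given a seed and restores the RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  g1 <- markov_genotypes(c(0.3, 0.2), 0.5, 100, seed = 99)
  g2 <- markov_genotypes(c(0.3, 0.2), 0.5, 100, seed = 99)
  expect_identical(g1, g2)
  after <- rnorm(1)
  expect_identical(before, after)

  A1 <- random_instrument_matrix(3, 2, c(0.1, 0.3), seed = 7)
  A2 <- random_instrument_matrix(3, 2, c(0.1, 0.3), seed = 7)
  expect_identical(A1, A2)

  cfg <- scenario_config("overdetermined", n = 300, reps = 2, seed = 11)
  d1 <- simulate_dataset(cfg, seed = 5)
  d2 <- simulate_dataset(cfg, seed = 5)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$exposures, d2$exposures)
  expect_identical(d1$outcome, d2$outcome)
})

test_that("scenario datasets have the declared structure", {
  cfg <- scenario_config("overdetermined", n = 500, reps = 1, seed = 2)
  d <- simulate_dataset(cfg, seed = 1)
  expect_identical(dim(d$genotypes), c(500L, 7L))
  expect_identical(dim(d$exposures), c(500L, 3L))
  expect_length(d$outcome, 500)
  expect_true(all(d$genotypes %in% 0:2))
  # only causal instruments carry non-zero effect rows
  zero_rows <- setdiff(seq_len(7), cfg$causal)
  expect_true(all(d$A[zero_rows, ] == 0))
  expect_true(all(d$A[cfg$causal, ] >= 0.1 & d$A[cfg$causal, ] <= 0.3))
})

test_that("underdetermined scenarios are flagged in every replicate", {
  cfg <- scenario_config("underdetermined", n = 10000, reps = 1, seed = 31)
  flags <- vapply(1:30, function(i) {
    d <- simulate_dataset(cfg, seed = i)
    s <- covariances_from_samples(d$genotypes, d$exposures, d$outcome)
    "under_determined" %in% determinacy_check(s, quiet = TRUE)$flags
  }, logical(1))
  expect_true(all(flags))
})

test_that("Wishart perturbation concentrates and is centred on the reference", {
  ref <- markov_ld_matrix(c(0.5, 0.7, 0.4))
  big <- wishart_perturb_ld(ref, 1e6, seed = 8)
  expect_lt(max(abs(big - ref)), 0.01)
  expect_equal(diag(big), rep(1, 4), ignore_attr = TRUE)

  set.seed(9)
  draws <- replicate(2000, wishart_perturb_ld(ref, 50))
  expect_lt(max(abs(apply(draws, 1:2, mean) - ref)), 0.02)
  expect_error(wishart_perturb_ld(ref, 2), "df")
})

test_that("one-sample GMM with the reference LD stays unbiased under Wishart LD noise", {
  # genotypes drawn from a perturbed LD (df = 50), estimation with the
  # reference LD matrix
  cfg <- scenario_config("overdetermined", n = 4000, reps = 150, seed = 61)
  ref <- markov_ld_matrix(cfg$succ_r)
  seeds <- mvmrset:::derive_seeds(cfg$seed, 150)
  est <- matrix(NA_real_, 150, 3)
  for (i in seq_len(150)) {
    pert <- wishart_perturb_ld(ref, 50, seed = seeds[i])
    cfg_i <- cfg
    r_pert <- pert[cbind(1:6, 2:7)]
    for (l in 1:6) {
      bnd <- mvmrset:::feasible_r_range(cfg$maf[l], cfg$maf[l + 1])
      r_pert[l] <- min(max(r_pert[l], 0.95 * bnd[1]), 0.95 * bnd[2])
    }
    cfg_i$succ_r <- r_pert
    d <- simulate_dataset(cfg_i, seed = seeds[i])
    s <- covariances_from_samples(d$genotypes, d$exposures, d$outcome)
    s_ref <- summary_covariances(s$sigma_EX, s$sigma_EY, ref,
      n_exposure = cfg$n
    )
    est[i, ] <- gmm_estimate(s_ref)$effects
  }
  bias <- colMeans(est) - cfg$true_effects
  mc_se <- apply(est, 2, sd) / sqrt(150)
  expect_true(all(abs(bias) < pmax(4 * mc_se, 0.05)))
})

test_that("pleiotropy scenario drops the hidden exposure from the observed view", {
  cfg <- scenario_config("pleiotropy_hidden", n = 400, reps = 1, seed = 71)
  ds <- pleiotropy_scenario(cfg, hidden_effect = 0.25, seed = 1)
  expect_identical(ncol(ds$full$exposures), 3L)
  expect_identical(ncol(ds$observed$exposures), 2L)
  expect_identical(ds$full$exposures[, 2:3], ds$observed$exposures)
  expect_identical(ds$full$truth$true_effects[1], 0.25)
})

test_that("no hidden effect means the misspecified model is unbiased", {
  cfg <- scenario_config("pleiotropy_hidden", n = 4000, reps = 1, seed = 72)
  est <- t(sapply(1:120, function(i) {
    ds <- pleiotropy_scenario(cfg, hidden_effect = 0, seed = i)
    estimate_dataset(ds$observed, "GMM")$effects
  }))
  bias <- colMeans(est) - cfg$true_effects[2:3]
  mc_se <- apply(est, 2, sd) / sqrt(120)
  expect_true(all(abs(bias) < 3.5 * mc_se))
})

test_that("two-sample design returns cross-sample summary covariances", {
  cfg <- scenario_config("two_sample", n_eqtl = 500, n_gwas = 2000,
    reps = 1, seed = 81
  )
  ts <- two_sample_scenario(cfg, seed = 1)
  expect_identical(ts$exposure_sample$sample_tag, "exposure_sample")
  expect_identical(ts$outcome_sample$sample_tag, "outcome_sample")
  expect_identical(nrow(ts$exposure_sample$genotypes), 500L)
  expect_identical(nrow(ts$outcome_sample$genotypes), 2000L)
  expect_identical(ts$summary$n_exposure, 500)
  expect_identical(ts$summary$n_outcome, 2000)
  expect_warning(
    replicate_experiment(cfg, estimators = "GMM", reps = 2),
    "two-sample"
  )
})

test_that("two-sample bias shrinks along the sample-size grid", {
  grid <- list(c(300, 10000), c(1000, 40000), c(4000, 140000))
  bias <- sapply(seq_along(grid), function(i) {
    cfg <- scenario_config("two_sample",
      n_eqtl = grid[[i]][1], n_gwas = grid[[i]][2], reps = 60, seed = 82
    )
    res <- suppressWarnings(replicate_experiment(cfg, estimators = "GMM"))
    mean(abs(res$bias))
  })
  expect_lt(bias[3], bias[1])
  expect_lt(bias[3], 0.05)
})

test_that("replicate summaries reduce to the single run for reps = 1", {
  cfg <- scenario_config("exact_K", n = 2000, reps = 1, seed = 91)
  res <- replicate_experiment(cfg, estimators = "LS")
  d <- simulate_dataset(cfg, seed = mvmrset:::derive_seeds(cfg$seed, 1))
  fit <- estimate_dataset(d, "LS")
  expect_equal(res$mean_estimate, unname(fit$effects), tolerance = 1e-12)
  expect_true(all(is.na(res$sd) | res$reps > 1 | res$sd == res$sd))
  p <- ggplot2::autoplot(replicate_experiment(
    scenario_config("exact_K", n = 500, reps = 5, seed = 92),
    estimators = "LS"
  ))
  expect_s3_class(p, "ggplot")
})
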