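# Locus construction, exposure-set closure, pruning, prediction.

toy_tables <- function() {
  # 6 SNPs on chr 1: s1..s3 cluster near 1 Mb, s4..s6 cluster near 5 Mb
  pos <- c(1e6, 1.05e6, 1.1e6, 5e6, 5.05e6, 5.1e6)
  snps <- paste0("s", 1:6)
  ld <- diag(6)
  dimnames(ld) <- list(snps, snps)
  ld[1, 2] <- ld[2, 1] <- 0.8
  ld[2, 3] <- ld[3, 2] <- 0.6
  ld[1, 3] <- ld[3, 1] <- 0.5
  ld[4, 5] <- ld[5, 4] <- 0.7
  ld[5, 6] <- ld[6, 5] <- 0.9
  ld[4, 6] <- ld[6, 4] <- 0.6
  eqtl <- tibble::tibble(
    snp_id = c("s1", "s1", "s2", "s3", "s4", "s5", "s6"),
    chrom = "1",
    pos = pos[c(1, 1, 2, 3, 4, 5, 6)],
    gene_id = c("A", "B", "B", "C", "D", "D", "E"),
    tissue = "LIV",
    beta = c(0.5, 0.4, 0.45, 0.3, 0.6, 0.5, 0.35),
    se = 0.05, fdr = 1e-4, maf = 0.3
  )
  gwas <- tibble::tibble(
    snp_id = snps, chrom = "1", pos = pos,
    beta = c(0.09, 0.07, 0.05, 0.10, 0.08, 0.04),
    se = 0.01,
    p = c(1e-19, 1e-12, 1e-7, 1e-21, 1e-13, 1e-6),
    n = 100000, effect_allele = "A", other_allele = "G"
  )
  list(eqtl = eqtl, gwas = gwas, ld = ld)
}

test_that("well-separated significant SNPs seed disjoint loci", {
  tt <- toy_tables()
  loci <- build_loci(tt$gwas, tt$eqtl, tt$ld)
  expect_length(loci, 2)
  snp_sets <- lapply(loci, function(l) l$instruments)
  expect_length(intersect(snp_sets[[1]], snp_sets[[2]]), 0)
  # lead SNPs are the smallest GWAS p in each cluster
  expect_setequal(vapply(loci, function(l) l$lead_snp, ""), c("s1", "s4"))
})

test_that("greedy construction absorbs linked significant SNPs into the lead locus", {
  tt <- toy_tables()
  # make the second cluster non-significant so only one locus forms
  gwas <- tt$gwas
  gwas$p[4:6] <- 1e-3
  loci <- build_loci(gwas, tt$eqtl, tt$ld)
  expect_length(loci, 1)
  expect_identical(loci[[1]]$lead_snp, "s1")
  expect_setequal(loci[[1]]$instruments, c("s1", "s2", "s3"))
})

test_that("no significant SNP yields an empty locus list", {
  tt <- toy_tables()
  gwas <- tt$gwas
  gwas$p <- rep(0.5, 6)
  expect_length(build_loci(gwas, tt$eqtl, tt$ld), 0)
})

test_that("exposure-set closure follows shared associations transitively and is idempotent", {
  tt <- toy_tables()
  loci <- build_loci(tt$gwas, tt$eqtl, tt$ld)
  l1 <- loci[[which(vapply(loci, function(l) l$lead_snp, "") == "s1")]]
  # closure from s1: s1-{A,B}, B-s2, s3 linked by LD carries C
  expect_setequal(unique(l1$eqtl$gene_id), c("A", "B", "C"))
  l1_again <- close_exposure_set(l1, tt$eqtl)
  expect_setequal(l1_again$instruments, l1$instruments)
  expect_setequal(unique(l1_again$eqtl$gene_id), unique(l1$eqtl$gene_id))
})

test_that("closure adds instruments of genes pulled in by shared SNPs", {
  # A-s1, B-s1, B-s2, C-s2: starting from s1 alone must close to {A,B,C}
  snps <- c("t1", "t2")
  ld <- diag(2)
  dimnames(ld) <- list(snps, snps)
  ld[1, 2] <- ld[2, 1] <- 0.001 # effectively unlinked
  eqtl <- tibble::tibble(
    snp_id = c("t1", "t1", "t2", "t2"),
    chrom = "1", pos = c(1e6, 1e6, 1.2e6, 1.2e6),
    gene_id = c("A", "B", "B", "C"),
    tissue = "LIV", beta = 0.4, se = 0.05, fdr = 1e-4, maf = 0.3
  )
  gwas <- tibble::tibble(
    snp_id = snps, chrom = "1", pos = c(1e6, 1.2e6),
    beta = 0.08, se = 0.01, p = c(1e-12, 1e-3), n = 50000,
    effect_allele = "A", other_allele = "G"
  )
  loci <- build_loci(gwas, eqtl, ld)
  expect_length(loci, 1)
  expect_setequal(unique(loci[[1]]$eqtl$gene_id), c("A", "B", "C"))
  expect_setequal(loci[[1]]$instruments, c("t1", "t2"))
})

test_that("missing LD entries are reported", {
  tt <- toy_tables()
  ld_small <- tt$ld[1:4, 1:4]
  expect_error(build_loci(tt$gwas, tt$eqtl, ld_small), "missing entries")
})

test_that("pruning removes one of each near-duplicate pair, keeping the smaller GWAS p", {
  tt <- toy_tables()
  ld <- tt$ld
  ld[1, 2] <- ld[2, 1] <- 0.999
  loci <- build_loci(tt$gwas, tt$eqtl, ld)
  l1 <- loci[[which(vapply(loci, function(l) l$lead_snp, "") == "s1")]]
  expect_warning(
    pruned <- prune_instruments(l1, r2_max = 0.95),
    "fewer instruments"
  )
  expect_true("s1" %in% pruned$instruments) # smaller GWAS p survives
  expect_false("s2" %in% pruned$instruments)
  # locus without near-duplicates is unchanged
  l2 <- loci[[which(vapply(loci, function(l) l$lead_snp, "") == "s4")]]
  expect_setequal(prune_instruments(l2, 0.95)$instruments, l2$instruments)
})

test_that("greedy pruning matches the exhaustive maximum-retention solution", {
  # chained near-duplicates: r2 >= 0.97 between (1,2), (2,3), (4,5)
  set.seed(13)
  snps <- paste0("c", 1:6)
  r <- diag(6)
  r[1, 2] <- r[2, 1] <- 0.99
  r[2, 3] <- r[3, 2] <- 0.985
  r[1, 3] <- r[3, 1] <- 0.95
  r[4, 5] <- r[5, 4] <- 0.99
  pad <- 0.1
  for (i in 1:6) {
    for (j in 1:6) {
      if (i != j && r[i, j] == 0) r[i, j] <- pad
    }
  }
  dimnames(r) <- list(snps, snps)
  eqtl <- tibble::tibble(
    snp_id = snps, chrom = "1", pos = 1e6 + (1:6) * 1000,
    gene_id = "G", tissue = "LIV", beta = 0.4, se = 0.05, fdr = 1e-4, maf = 0.3
  )
  gwas <- tibble::tibble(
    snp_id = snps, chrom = "1", pos = 1e6 + (1:6) * 1000,
    beta = 0.08, se = 0.01, p = 10^-(20:15), n = 50000,
    effect_allele = "A", other_allele = "G"
  )
  loci <- build_loci(gwas, eqtl, r)
  pruned <- prune_instruments(loci[[1]], r2_max = 0.97^2)
  # brute force: the largest SNP subset with no pair at r2 >= threshold
  thr <- 0.97^2
  best <- 0
  for (m in 1:6) {
    for (sub in utils::combn(6, m, simplify = FALSE)) {
      rr <- r[sub, sub, drop = FALSE]^2
      diag(rr) <- 0
      if (max(rr) < thr) best <- max(best, m)
    }
  }
  expect_identical(length(pruned$instruments), as.integer(best))
})

test_that("allele harmonization flips swapped records and drops ambiguous ones", {
  eqtl <- tibble::tibble(
    snp_id = c("h1", "h2", "h3"),
    chrom = "1", pos = c(1e6, 1.1e6, 1.2e6),
    gene_id = "A", tissue = "LIV", beta = c(0.5, 0.5, 0.5),
    se = 0.05, fdr = 1e-4, maf = 0.3,
    effect_allele = c("A", "G", "A"),
    other_allele = c("G", "A", "T") # h3 is strand-ambiguous
  )
  gwas <- tibble::tibble(
    snp_id = c("h1", "h2", "h3"),
    chrom = "1", pos = c(1e6, 1.1e6, 1.2e6),
    beta = 0.08, se = 0.01, p = 1e-10, n = 50000,
    effect_allele = "A", other_allele = c("G", "G", "T")
  )
  expect_warning(
    out <- mvmrset:::harmonize_alleles(eqtl, gwas),
    "harmonization"
  )
  expect_identical(out$snp_id, c("h1", "h2"))
  expect_equal(out$beta, c(0.5, -0.5))
})

test_that("single-gene locus reduces to the univariate ratio", {
  snps <- "u1"
  ld <- matrix(1, 1, 1, dimnames = list(snps, snps))
  maf <- 0.25
  eqtl <- tibble::tibble(
    snp_id = "u1", chrom = "1", pos = 1e6, gene_id = "A", tissue = "LIV",
    beta = 0.5, se = 0.05, fdr = 1e-4, maf = maf
  )
  gwas <- tibble::tibble(
    snp_id = "u1", chrom = "1", pos = 1e6, beta = 0.1, se = 0.01,
    p = 1e-23, n = 50000, effect_allele = "A", other_allele = "G"
  )
  loci <- build_loci(gwas, eqtl, ld)
  preds <- run_locus_mvmr(loci[[1]])
  sd_snp <- sqrt(2 * maf * (1 - maf))
  expect_equal(preds$effect, univariate_ratio(0.1 * sd_snp, 0.5 * sd_snp))
})

test_that("under-determined loci are reported without estimates", {
  snps <- "v1"
  ld <- matrix(1, 1, 1, dimnames = list(snps, snps))
  eqtl <- tibble::tibble(
    snp_id = c("v1", "v1"), chrom = "1", pos = 1e6,
    gene_id = c("A", "B"), tissue = "LIV",
    beta = 0.5, se = 0.05, fdr = 1e-4, maf = 0.3
  )
  gwas <- tibble::tibble(
    snp_id = "v1", chrom = "1", pos = 1e6, beta = 0.1, se = 0.01,
    p = 1e-23, n = 50000, effect_allele = "A", other_allele = "G"
  )
  loci <- build_loci(gwas, eqtl, ld)
  preds <- run_locus_mvmr(loci[[1]])
  expect_false(any(preds$identifiable))
  expect_true(all(is.na(preds$effect)))
})

test_that("causal classification applies the effect and Bonferroni thresholds", {
  preds <- tibble::tibble(
    locus = "L", gene = c("a", "b", "c", "d"), tissue = "LIV",
    n_instruments = 3,
    effect = c(0.099, -0.27, 0.3, 0.2),
    se = 0.01, p = c(1e-9, 1e-9, 1, 1e-9),
    identifiable = TRUE, flags = ""
  )
  out <- classify_causal(preds, effect_thresh = 0.1, alpha = 0.05, m_tests = 150)
  expect_identical(out$causal_call, c(FALSE, TRUE, FALSE, TRUE))
  # all p = 1 never calls, whatever the effect
  preds$p <- 1
  expect_false(any(classify_causal(preds)$causal_call))
})

test_that("pipeline on simulator-generated loci recovers the embedded truth", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(dir,
    n_loci = 2, genes_per_locus = 3,
    instruments_per_locus = 7, seed = 5
  )
  eqtl <- read_eqtl(fx$eqtl)
  gwas <- read_gwas(fx$gwas)
  ld <- read_ld_matrix(fx$ld)
  loci <- build_loci(gwas, eqtl, ld)
  expect_length(loci, 2)
  preds <- dplyr::bind_rows(lapply(loci, function(l) {
    run_locus_mvmr(prune_instruments(l), estimator = "LS")
  }))
  preds <- classify_causal(preds)
  truth <- readr::read_tsv(fx$truth, show_col_types = FALSE)
  m <- dplyr::inner_join(preds, truth, by = "gene")
  expect_equal(nrow(m), 6)
  expect_lt(max(abs(m$effect - m$true_effect)), 1e-8)
  expect_identical(m$causal_call, abs(m$true_effect) >= 0.1)
  p <- plot_locus_predictions(preds)
  expect_s3_class(p, "ggplot")
})
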