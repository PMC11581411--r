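#' Read eQTL, GWAS and LD summary tables
#'
#' All tabular IO uses tab-delimited UTF-8 files with a header row and `NA`
#' for missing values. A `column_map` (named character vector,
#' `c(internal = "file_column")`) adapts other dialects to the expected
#' column names.
#'
#' @param path Path to a TSV file.
#' @param column_map Optional named character vector renaming file columns to
#'   the internal schema.
#' @return A validated tibble ([read_eqtl()], [read_gwas()]) or a numeric
#'   matrix with SNP-id dimnames ([read_ld_matrix()]).
#' @name read_summary_tables
NULL

read_tsv_strict <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_guess()),
    na = "NA", progress = FALSE, show_col_types = FALSE
  )
}

apply_column_map <- function(df, column_map) {
  if (is.null(column_map)) {
    return(df)
  }
  for (internal in names(column_map)) {
    file_col <- column_map[[internal]]
    if (!file_col %in% names(df)) {
      stop("column_map refers to missing column: ", file_col, call. = FALSE)
    }
    names(df)[names(df) == file_col] <- internal
  }
  df
}

check_columns <- function(df, required, numeric_cols, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " table is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(what, " column `", col, "` is not numeric (first bad row: ",
        if (length(bad) > 0) bad[1] else "?", ")",
        call. = FALSE
      )
    }
    if (anyNA(v)) {
      stop(what, " column `", col, "` contains NA (first at row ",
        which(is.na(v))[1], ")",
        call. = FALSE
      )
    }
  }
  invisible(df)
}

#' @rdname read_summary_tables
#' @export
read_eqtl <- function(path, column_map = NULL) {
  df <- apply_column_map(read_tsv_strict(path), column_map)
  check_columns(df,
    required = c("snp_id", "chrom", "pos", "gene_id", "tissue", "beta", "se", "fdr", "maf"),
    numeric_cols = c("pos", "beta", "se", "fdr", "maf"),
    what = "eQTL"
  )
  if (any(df$pos <= 0)) stop("eQTL positions must be positive (1-based)", call. = FALSE)
  if (any(df$maf <= 0 | df$maf >= 0.5)) {
    stop("eQTL maf must lie in (0, 0.5)", call. = FALSE)
  }
  key <- paste(df$snp_id, df$gene_id, df$tissue)
  if (anyDuplicated(key)) {
    stop("duplicate (snp, gene, tissue) eQTL record(s): ",
      paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
      call. = FALSE
    )
  }
  df$chrom <- as.character(df$chrom)
  tibble::as_tibble(df)
}

#' @rdname read_summary_tables
#' @export
read_gwas <- function(path, column_map = NULL) {
  df <- apply_column_map(read_tsv_strict(path), column_map)
  check_columns(df,
    required = c("snp_id", "chrom", "pos", "beta", "se", "p", "n"),
    numeric_cols = c("pos", "beta", "se", "p", "n"),
    what = "GWAS"
  )
  if (any(df$p <= 0 | df$p > 1)) stop("GWAS p must lie in (0, 1]", call. = FALSE)
  if (any(df$n <= 0)) stop("GWAS n must be positive", call. = FALSE)
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate GWAS snp_id(s)", call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  tibble::as_tibble(df)
}

#' @rdname read_summary_tables
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv_strict(path)
  snps <- names(df)[-1]
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), snps)) {
    stop("LD matrix row ids do not match column header", call. = FALSE)
  }
  if (!is.numeric(m)) stop("LD matrix must be numeric", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) {
    stop("LD matrix is asymmetric beyond tolerance 1e-8", call. = FALSE)
  }
  m
}

#' Write tabular outputs
#'
#' Writers paired with the readers above; all emit tab-delimited UTF-8 with a
#' header row and `NA` for missing values.
#'
#' @param x Object to write (tibble or matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @name write_summary_tables
NULL

#' @rdname write_summary_tables
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  invisible(path)
}

#' @rdname write_summary_tables
#' @export
write_ld_matrix <- function(x, path) {
  df <- tibble::as_tibble(x, rownames = "snp_id")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Serialize summary covariances as TSV blocks
#'
#' Writes/reads a [summary_covariances()] object as three TSV files sharing
#' SNP and gene headers — `<prefix>_EX.tsv` (instrument x exposure
#' covariances), `<prefix>_EY.tsv` (instrument-outcome covariances and sample
#' sizes), `<prefix>_EE.tsv` (LD matrix).
#'
#' @param s A [summary_covariances()] object.
#' @param prefix File path prefix.
#' @return `write_summary_covariances()` returns the three paths invisibly;
#'   `read_summary_covariances()` returns the reconstructed object.
#' @export
write_summary_covariances <- function(s, prefix) {
  stopifnot(inherits(s, "summary_covariances"))
  p_ex <- paste0(prefix, "_EX.tsv")
  p_ey <- paste0(prefix, "_EY.tsv")
  p_ee <- paste0(prefix, "_EE.tsv")
  ex <- tibble::as_tibble(s$sigma_EX, rownames = "snp_id")
  readr::write_tsv(ex, p_ex, na = "NA")
  ey <- tibble::tibble(
    snp_id = s$instrument_ids, sigma_EY = s$sigma_EY,
    n_exposure = s$n_exposure, n_outcome = s$n_outcome
  )
  readr::write_tsv(ey, p_ey, na = "NA")
  write_ld_matrix(s$sigma_EE, p_ee)
  invisible(c(EX = p_ex, EY = p_ey, EE = p_ee))
}

#' @rdname write_summary_covariances
#' @export
read_summary_covariances <- function(prefix) {
  ex <- read_tsv_strict(paste0(prefix, "_EX.tsv"))
  ey <- read_tsv_strict(paste0(prefix, "_EY.tsv"))
  ee <- read_ld_matrix(paste0(prefix, "_EE.tsv"))
  snps <- ex[[1]]
  if (!identical(snps, ey$snp_id) || !identical(snps, rownames(ee))) {
    stop("SNP ids disagree between the EX, EY and EE blocks", call. = FALSE)
  }
  EX <- as.matrix(ex[, -1])
  rownames(EX) <- snps
  summary_covariances(
    sigma_EX = EX, sigma_EY = ey$sigma_EY, sigma_EE = ee,
    n_exposure = ey$n_exposure[1], n_outcome = ey$n_outcome[1]
  )
}

#' Generate a toy eQTL/GWAS/LD fixture with embedded ground truth
#'
#' Builds well-separated synthetic loci with Markov-chain LD, a chosen number
#' of exposure genes per locus (each locus has as many causal variants as
#' genes), and population summary statistics implied by the generating SEM
#' (per-allele betas recoverable to standardized covariances through the MAF
#' column). Running the locus pipeline on the files recovers the embedded true
#' effects exactly, because the written covariances are population quantities.
#'
#' @param dir Output directory (created if needed).
#' @param n_loci Number of loci.
#' @param genes_per_locus Number of exposure genes per locus.
#' @param instruments_per_locus Number of instrument SNPs per locus.
#' @param tissues Character vector of tissue labels (genes are associated in
#'   the first tissue).
#' @param n_eqtl,n_gwas Nominal sample sizes written into the tables.
#' @param true_effects Optional list (one vector per locus) of true gene
#'   effects; default draws magnitudes in 0.1-0.3 with random signs.
#' @param seed Seed for the fixture.
#' @return Invisibly, a list with the four file paths (`eqtl`, `gwas`, `ld`,
#'   `truth`) and the truth table.
#' @export
generate_fixture <- function(dir, n_loci = 1, genes_per_locus = 3,
                             instruments_per_locus = 7, tissues = "LIV",
                             n_eqtl = 600, n_gwas = 100000,
                             true_effects = NULL, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    eqtl <- list()
    gwas <- list()
    truth <- list()
    ld_blocks <- list()
    for (loc in seq_len(n_loci)) {
      L <- instruments_per_locus
      K <- genes_per_locus
      center <- 1e7 + (loc - 1) * 4e7
      snps <- sprintf("rs%d%03d", loc, seq_len(L))
      genes <- sprintf("GENE%d_%s", loc, LETTERS[seq_len(K)])
      maf <- stats::runif(L, 0.1, 0.4)
      succ_r <- if (L > 1) stats::runif(L - 1, 0.3, 0.8) else numeric(0)
      ld <- markov_ld_matrix(succ_r)
      dimnames(ld) <- list(snps, snps)
      A <- matrix(0, L, K)
      causal <- sort(sample.int(L, K))
      # eQTL effects with random signs; reject ill-conditioned causal blocks
      repeat {
        block <- matrix(
          stats::runif(K * K, 0.1, 0.3) * sample(c(-1, 1), K * K, replace = TRUE),
          K, K
        )
        if (abs(det(block)) > 0.05) break
      }
      A[causal, ] <- block
      cc <- if (is.null(true_effects)) {
        stats::runif(K, 0.1, 0.3) * sample(c(-1, 1), K, replace = TRUE)
      } else {
        true_effects[[loc]]
      }
      EX <- ld %*% A # population standardized instrument-exposure covariances
      EY <- as.numeric(EX %*% cc)
      sd_snp <- sqrt(2 * maf * (1 - maf))
      pos <- round(center + seq(-2e5, 2e5, length.out = L))
      for (k in seq_len(K)) {
        eqtl[[length(eqtl) + 1L]] <- tibble::tibble(
          snp_id = snps, chrom = "1", pos = pos,
          gene_id = genes[k], tissue = tissues[1],
          beta = EX[, k] / sd_snp,
          se = 1 / (sd_snp * sqrt(n_eqtl)),
          fdr = 1e-6, maf = maf,
          effect_allele = "A", other_allele = "G"
        )
      }
      gw_se <- 1 / (sd_snp * sqrt(n_gwas))
      gw_beta <- EY / sd_snp
      gwas[[length(gwas) + 1L]] <- tibble::tibble(
        snp_id = snps, chrom = "1", pos = pos,
        beta = gw_beta, se = gw_se,
        p = pmax(2 * stats::pnorm(-abs(gw_beta / gw_se)), 1e-300),
        n = n_gwas, effect_allele = "A", other_allele = "G"
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        locus = loc, lead_hint = snps[which.max(abs(EY))],
        gene = genes, tissue = tissues[1], true_effect = cc
      )
      ld_blocks[[length(ld_blocks) + 1L]] <- ld
    }
    eqtl <- dplyr::bind_rows(eqtl)
    gwas <- dplyr::bind_rows(gwas)
    truth <- dplyr::bind_rows(truth)
    all_snps <- unlist(lapply(ld_blocks, rownames))
    LD <- diag(length(all_snps)) * 0
    dimnames(LD) <- list(all_snps, all_snps)
    for (b in ld_blocks) LD[rownames(b), colnames(b)] <- b
    diag(LD) <- 1
    paths <- list(
      eqtl = file.path(dir, "eqtl.tsv"),
      gwas = file.path(dir, "gwas.tsv"),
      ld = file.path(dir, "ld.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_tsv_table(eqtl, paths$eqtl)
    write_tsv_table(gwas, paths$gwas)
    write_ld_matrix(LD, paths$ld)
    write_tsv_table(truth, paths$truth)
    invisible(c(paths, list(truth_table = truth)))
  })
}

#' Write a machine-readable diagnostics report
#'
#' @param diag An `mvmr_diagnostics` object (from [determinacy_check()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(diag, path) {
  stopifnot(inherits(diag, "mvmr_diagnostics"))
  jsonlite::write_json(
    list(
      det_EE = diag$det_EE,
      det_EX = diag$det_A_proxy,
      rank_EX = diag$rank_EX,
      conditional_F = as.list(diag$cond_F),
      flags = as.list(diag$flags)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
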