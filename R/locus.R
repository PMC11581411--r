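#' Build closed causal diagrams (loci) from GWAS and eQTL summary statistics
#'
#' Greedy locus construction: significant cis-eQTL SNPs are filtered to those
#' genome-wide significant in the GWAS (`p < gwas_p_thresh`) and sorted by
#' GWAS p-value. The most significant remaining SNP seeds a locus as its lead
#' SNP; all eQTL SNPs within `radius_bp` of the lead and with non-negligible
#' LD (`|r| > ld_floor`) join the locus and are removed from the list, and the
#' procedure repeats with the next lead SNP. Each locus is then closed over
#' exposures ([close_exposure_set()]): genes sharing any instrument and
#' instruments associated with any included gene are added until a fixed
#' point. Loci are disjoint in SNPs.
#'
#' @param gwas Tibble of GWAS records: `snp_id`, `chrom`, `pos`, `beta`
#'   (log-odds), `se`, `p`, `n`, `effect_allele`, `other_allele`.
#' @param eqtl Tibble of eQTL records: `snp_id`, `chrom`, `pos`, `gene_id`,
#'   `tissue`, `beta`, `se`, `fdr`, `maf` (optionally `effect_allele`,
#'   `other_allele`).
#' @param ld Square LD correlation matrix with SNP ids as dimnames.
#' @param gwas_p_thresh Genome-wide significance threshold (default 5e-8).
#' @param radius_bp Locus radius around the lead SNP in base pairs; windows
#'   are closed intervals `[lead - radius, lead + radius]` on 1-based
#'   coordinates (default 500 kb).
#' @param ld_floor Minimum `|r|` treated as non-zero LD (default 0.01).
#' @param eqtl_fdr_max Significance filter on the eQTL records (default 0.05).
#' @return List of `locus_model` objects.
#' @export
build_loci <- function(gwas, eqtl, ld,
                       gwas_p_thresh = 5e-8, radius_bp = 5e5,
                       ld_floor = 0.01, eqtl_fdr_max = 0.05) {
  eqtl <- dplyr::filter(eqtl, .data$fdr < eqtl_fdr_max)
  eqtl_snps <- unique(eqtl$snp_id)
  sig <- gwas |>
    dplyr::filter(.data$snp_id %in% eqtl_snps, .data$p < gwas_p_thresh) |>
    dplyr::arrange(.data$p)
  if (nrow(sig) == 0) {
    return(list())
  }
  check_ld_coverage(ld)
  loci <- list()
  remaining <- sig
  while (nrow(remaining) > 0) {
    lead <- remaining[1, ]
    pos_tab <- eqtl |>
      dplyr::distinct(.data$snp_id, .data$chrom, .data$pos)
    in_window <- pos_tab |>
      dplyr::filter(
        .data$chrom == lead$chrom,
        .data$pos >= lead$pos - radius_bp,
        .data$pos <= lead$pos + radius_bp
      )
    need <- unique(c(lead$snp_id, in_window$snp_id))
    missing <- setdiff(need, rownames(ld))
    if (length(missing) > 0) {
      stop(
        "LD matrix is missing entries for SNP(s): ",
        paste(utils::head(missing, 10), collapse = ", "),
        call. = FALSE
      )
    }
    linked <- in_window$snp_id[
      abs(ld[lead$snp_id, in_window$snp_id]) > ld_floor
    ]
    snps <- unique(c(lead$snp_id, linked))
    locus <- new_locus_model(
      lead_snp = lead$snp_id, instruments = snps,
      eqtl = dplyr::filter(eqtl, .data$snp_id %in% snps),
      gwas = gwas, ld = ld, window_bp = radius_bp,
      center = c(chrom = lead$chrom, pos = lead$pos)
    )
    locus <- close_exposure_set(locus, eqtl)
    loci[[length(loci) + 1L]] <- locus
    remaining <- dplyr::filter(remaining, !(.data$snp_id %in% locus$instruments))
  }
  loci
}

check_ld_coverage <- function(ld) {
  if (is.null(rownames(ld)) || is.null(colnames(ld))) {
    stop("LD matrix must have SNP ids as dimnames", call. = FALSE)
  }
  if (max(abs(ld - t(ld))) > 1e-8) {
    stop("LD matrix is not symmetric", call. = FALSE)
  }
  invisible(TRUE)
}

new_locus_model <- function(lead_snp, instruments, eqtl, gwas, ld,
                            window_bp, center, flags = character(0)) {
  structure(
    list(
      lead_snp = lead_snp,
      instruments = instruments,
      exposures = dplyr::distinct(eqtl, .data$gene_id, .data$tissue),
      eqtl = eqtl,
      gwas = dplyr::filter(gwas, .data$snp_id %in% instruments),
      gwas_full = gwas,
      ld = ld[instruments, instruments, drop = FALSE],
      ld_full = ld,
      window_bp = window_bp,
      center = center,
      flags = flags
    ),
    class = "locus_model"
  )
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus_model> lead ", x$lead_snp, ": ", length(x$instruments),
    " instruments, ", length(unique(x$exposures$gene_id)), " genes in ",
    length(unique(x$exposures$tissue)), " tissue(s)",
    if (length(x$flags) > 0) paste0(" [", paste(x$flags, collapse = ","), "]"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Close the exposure set of a locus
#'
#' Alternately adds genes that share a cis-eQTL association with any
#' instrument already in the locus, and instruments (within the locus window)
#' associated with any included gene, until a fixed point is reached. The
#' resulting diagram is "closed": no further gene has a shared association
#' with any instrument in (or linked to) the locus. Idempotent.
#'
#' @param locus A `locus_model`.
#' @param eqtl The full eQTL record table (significant associations).
#' @return The closed `locus_model`.
#' @export
close_exposure_set <- function(locus, eqtl) {
  stopifnot(inherits(locus, "locus_model"))
  in_window <- eqtl |>
    dplyr::filter(
      .data$chrom == locus$center[["chrom"]],
      .data$pos >= as.numeric(locus$center[["pos"]]) - locus$window_bp,
      .data$pos <= as.numeric(locus$center[["pos"]]) + locus$window_bp
    )
  snps <- locus$instruments
  genes <- character(0)
  repeat {
    genes_new <- unique(in_window$gene_id[in_window$snp_id %in% snps])
    snps_new <- unique(in_window$snp_id[in_window$gene_id %in% genes_new])
    snps_new <- union(snps, snps_new)
    if (setequal(genes_new, genes) && setequal(snps_new, snps)) break
    genes <- genes_new
    snps <- snps_new
  }
  missing <- setdiff(snps, rownames(locus$ld_full))
  if (length(missing) > 0) {
    stop(
      "LD matrix is missing entries for SNP(s): ",
      paste(utils::head(missing, 10), collapse = ", "),
      call. = FALSE
    )
  }
  locus$instruments <- snps
  locus$eqtl <- dplyr::filter(in_window, .data$snp_id %in% snps)
  locus$exposures <- dplyr::distinct(locus$eqtl, .data$gene_id, .data$tissue)
  locus$ld <- locus$ld_full[snps, snps, drop = FALSE]
  locus$gwas <- dplyr::filter(locus$gwas_full, .data$snp_id %in% snps)
  locus
}

#' Prune near-duplicate instruments from a locus
#'
#' Iteratively removes one SNP from every pair with LD `r^2 >= r2_max`
#' (default 0.95, the threshold used for nearly identical SNPs), keeping from
#' each clashing pair the SNP with the smaller GWAS p-value (tie: smaller
#' position, then lexicographic id). Guarantees the retained LD matrix is
#' numerically invertible for any `r2_max < 1`.
#'
#' @param locus A `locus_model`.
#' @param r2_max Pruning threshold on r-squared, in (0, 1].
#' @return The pruned `locus_model`; a `under_determined` flag is attached if
#'   fewer instruments than exposures remain.
#' @export
prune_instruments <- function(locus, r2_max = 0.95) {
  stopifnot(inherits(locus, "locus_model"))
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]", call. = FALSE)
  snps <- locus$instruments
  gw <- locus$gwas
  priority <- function(snp) {
    i <- match(snp, gw$snp_id)
    p <- if (!is.na(i)) gw$p[i] else 1
    pos <- locus$eqtl$pos[match(snp, locus$eqtl$snp_id)]
    list(p = p, pos = ifelse(is.na(pos), Inf, pos), id = snp)
  }
  worse_of <- function(a, b) {
    pa <- priority(a)
    pb <- priority(b)
    if (pa$p != pb$p) {
      return(if (pa$p > pb$p) a else b)
    }
    if (pa$pos != pb$pos) {
      return(if (pa$pos > pb$pos) a else b)
    }
    if (pa$id > pb$id) a else b
  }
  repeat {
    R2 <- locus$ld_full[snps, snps, drop = FALSE]^2
    diag(R2) <- 0
    mx <- max(R2)
    if (mx < r2_max || length(snps) <= 1) break
    idx <- which(R2 == mx, arr.ind = TRUE)[1, ]
    drop <- worse_of(snps[idx[1]], snps[idx[2]])
    snps <- setdiff(snps, drop)
  }
  locus$instruments <- snps
  locus$ld <- locus$ld_full[snps, snps, drop = FALSE]
  locus$eqtl <- dplyr::filter(locus$eqtl, .data$snp_id %in% snps)
  locus$gwas <- dplyr::filter(locus$gwas, .data$snp_id %in% snps)
  if (length(snps) < length(unique(locus$eqtl$gene_id))) {
    locus$flags <- union(locus$flags, "under_determined")
    warning("pruning left fewer instruments than exposure genes", call. = FALSE)
  }
  locus
}

# Align eQTL effect alleles to the GWAS effect allele. Records without allele
# columns are assumed pre-harmonized. Returns the eQTL table with aligned
# betas; unresolvable or strand-ambiguous records are dropped with a warning.
harmonize_alleles <- function(eqtl, gwas) {
  if (!all(c("effect_allele", "other_allele") %in% names(eqtl))) {
    return(eqtl)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gw <- gwas |>
    dplyr::select("snp_id",
      gwas_ea = "effect_allele", gwas_oa = "other_allele"
    )
  merged <- dplyr::left_join(eqtl, gw, by = "snp_id")
  ea <- toupper(merged$effect_allele)
  oa <- toupper(merged$other_allele)
  gea <- toupper(merged$gwas_ea)
  goa <- toupper(merged$gwas_oa)
  ambiguous <- ea == unname(comp[oa]) & !is.na(ea) & !is.na(oa)
  same <- ea == gea & oa == goa
  flipped <- ea == goa & oa == gea
  strand_same <- unname(comp[ea]) == gea & unname(comp[oa]) == goa
  strand_flip <- unname(comp[ea]) == goa & unname(comp[oa]) == gea
  resolvable <- !ambiguous & (same | flipped | strand_same | strand_flip)
  resolvable[is.na(resolvable)] <- FALSE
  sign <- ifelse(!is.na(flipped) & (flipped | strand_flip), -1, 1)
  # keep records with no GWAS counterpart unchanged (nothing to harmonize to)
  mask <- is.na(gea) | resolvable
  dropped <- sum(!mask)
  if (dropped > 0) {
    warning(dropped, " eQTL record(s) dropped during allele harmonization",
      call. = FALSE
    )
  }
  out <- merged[mask, , drop = FALSE]
  out$beta <- out$beta * sign[mask]
  dplyr::select(out, -"gwas_ea", -"gwas_oa")
}

#' Run MVMR at a locus and predict causal genes
#'
#' Harmonizes effect alleles, converts per-allele summary betas to
#' standardized covariances (`beta * sqrt(2 maf (1 - maf))`), assembles the
#' summary covariances per tissue (exposures = genes with cis-eQTL
#' associations in the locus in that tissue) or for all gene-tissue pairs
#' jointly, runs the chosen estimator with summary-based inference, and
#' returns per-exposure predictions. A locus with fewer instruments than
#' exposures is reported as non-identifiable (no estimates).
#'
#' SNP-gene pairs with no recorded association contribute a zero
#' instrument-exposure covariance (no cis-eQTL effect).
#'
#' @param locus A `locus_model` (typically after [prune_instruments()]).
#' @param mode `"per_tissue"` or `"gene_tissue_pairs"`.
#' @param estimator `"LS"` or `"GMM"`.
#' @param sigma2 Residual outcome variance for standard errors (see
#'   [se_summary()]).
#' @return A tibble with columns `locus`, `gene`, `tissue`, `effect`, `se`,
#'   `p`, `n_instruments`, `identifiable`, plus diagnostics flags.
#' @export
run_locus_mvmr <- function(locus, mode = c("per_tissue", "gene_tissue_pairs"),
                           estimator = c("LS", "GMM"), sigma2 = 1) {
  stopifnot(inherits(locus, "locus_model"))
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  eq <- harmonize_alleles(locus$eqtl, locus$gwas)
  eq <- dplyr::mutate(eq,
    beta_std = beta_to_covariance(.data$beta, .data$maf)
  )
  maf_tab <- eq |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(maf = dplyr::first(.data$maf), .groups = "drop")
  gw <- locus$gwas |>
    dplyr::left_join(maf_tab, by = "snp_id") |>
    dplyr::mutate(beta_std = beta_to_covariance(.data$beta, .data$maf))
  snps <- locus$instruments
  n_gwas <- stats::median(gw$n, na.rm = TRUE)

  groups <- if (mode == "per_tissue") {
    split(eq, eq$tissue)
  } else {
    list(all = dplyr::mutate(eq,
      gene_id = paste(.data$gene_id, .data$tissue, sep = ":")
    ))
  }
  out <- purrr::map(names(groups), function(gname) {
    sub <- groups[[gname]]
    genes <- sort(unique(sub$gene_id))
    K <- length(genes)
    L <- length(snps)
    base <- tibble::tibble(
      locus = locus$lead_snp,
      gene = genes,
      tissue = if (mode == "per_tissue") gname else NA_character_,
      n_instruments = L
    )
    if (mode == "gene_tissue_pairs") {
      parts <- strsplit(genes, ":", fixed = TRUE)
      base$gene <- vapply(parts, `[[`, character(1), 1)
      base$tissue <- vapply(parts, `[[`, character(1), 2)
    }
    if (L < K) {
      return(dplyr::mutate(base,
        effect = NA_real_, se = NA_real_, p = NA_real_,
        identifiable = FALSE, flags = "under_determined"
      ))
    }
    EX <- matrix(0, L, K, dimnames = list(snps, genes))
    for (i in seq_len(nrow(sub))) {
      EX[sub$snp_id[i], sub$gene_id[i]] <- sub$beta_std[i]
    }
    EY <- stats::setNames(gw$beta_std[match(snps, gw$snp_id)], snps)
    EY[is.na(EY)] <- 0
    s <- summary_covariances(
      sigma_EX = EX, sigma_EY = EY,
      sigma_EE = locus$ld[snps, snps, drop = FALSE],
      n_exposure = NA_integer_, n_outcome = as.integer(n_gwas)
    )
    fit <- tryCatch(
      if (estimator == "LS") {
        ls_estimate(s, sigma2 = sigma2)
      } else {
        gmm_estimate(s, sigma2 = sigma2)
      },
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(dplyr::mutate(base,
        effect = NA_real_, se = NA_real_, p = NA_real_,
        identifiable = FALSE, flags = conditionMessage(fit)
      ))
    }
    dplyr::mutate(base,
      effect = unname(fit$effects[genes]),
      se = unname(fit$se[genes]),
      p = unname(fit$p[genes]),
      identifiable = TRUE,
      flags = paste(fit$diagnostics$flags, collapse = ";")
    )
  })
  dplyr::bind_rows(out)
}

#' Classify causal genes from locus predictions
#'
#' A gene-tissue prediction is called causal when its absolute effect is at
#' least `effect_thresh` (default 0.1, the empirical threshold anchored on the
#' smallest single-gene locus effect) and, when a p-value is available, it
#' passes the Bonferroni-corrected level `alpha / m_tests` (the denominator
#' defaults to the number of tested gene-tissue combinations in `preds`).
#'
#' @param preds Prediction tibble from [run_locus_mvmr()].
#' @param effect_thresh Absolute-effect threshold (default 0.1).
#' @param alpha Family-wise level (default 0.05).
#' @param m_tests Bonferroni denominator; defaults to the number of rows of
#'   `preds` with a p-value.
#' @return `preds` with an added logical column `causal_call`.
#' @export
classify_causal <- function(preds, effect_thresh = 0.1, alpha = 0.05,
                            m_tests = NULL) {
  if (effect_thresh <= 0 || alpha <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  m <- m_tests %||% max(1L, sum(!is.na(preds$p)))
  dplyr::mutate(preds,
    causal_call = !is.na(.data$effect) &
      abs(.data$effect) >= effect_thresh &
      (is.na(.data$p) | .data$p < alpha / m)
  )
}

#' Plot locus predictions
#'
#' @param preds Prediction tibble from [run_locus_mvmr()] (optionally after
#'   [classify_causal()]).
#' @return A ggplot object: per-gene effects with normal confidence intervals,
#'   faceted by tissue, causal calls highlighted when present.
#' @export
plot_locus_predictions <- function(preds) {
  preds$lo <- preds$effect - 1.96 * preds$se
  preds$hi <- preds$effect + 1.96 * preds$se
  p <- ggplot2::ggplot(preds, ggplot2::aes(
    x = .data$effect, y = .data$gene
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(
      xintercept = c(-0.1, 0.1), linetype = 3, colour = "grey70"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0.15, na.rm = TRUE
    ) +
    ggplot2::labs(x = "causal effect (per SD expression, log-odds outcome)", y = NULL)
  if ("causal_call" %in% names(preds)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$causal_call),
      size = 2, na.rm = TRUE
    ) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
        name = "causal call"
      )
  } else {
    p <- p + ggplot2::geom_point(size = 2, na.rm = TRUE)
  }
  p + ggplot2::facet_wrap(~tissue) + ggplot2::theme_minimal()
}
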