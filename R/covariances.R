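#' Summary covariances: the sufficient statistics for MVMR estimation
#'
#' Bundles the instrument-exposure covariance matrix, the instrument-outcome
#' covariance vector, the instrument correlation (LD) matrix and the sample
#' size(s). All estimators in the package operate on this object, which can be
#' computed from individual-level data ([covariances_from_samples()]), from
#' harmonized summary statistics ([run_locus_mvmr()]), or analytically from a
#' linear SEM ([implied_covariance()]).
#'
#' @param sigma_EX L x K numeric matrix of instrument-exposure covariances
#'   (rows = instruments, columns = exposures).
#' @param sigma_EY Length-L numeric vector of instrument-outcome covariances.
#' @param sigma_EE L x L symmetric instrument correlation (LD) matrix with
#'   unit diagonal.
#' @param n_exposure Sample size behind `sigma_EX` (and `sigma_EE`).
#' @param n_outcome Sample size behind `sigma_EY`; defaults to `n_exposure`
#'   (one-sample design).
#' @param instrument_ids,exposure_ids Optional label vectors; default to the
#'   dimnames of `sigma_EX`.
#' @return An object of class `summary_covariances`.
#' @export
summary_covariances <- function(sigma_EX, sigma_EY, sigma_EE,
                                n_exposure = NA_integer_,
                                n_outcome = n_exposure,
                                instrument_ids = NULL, exposure_ids = NULL) {
  sigma_EX <- as.matrix(sigma_EX)
  sigma_EY <- as.numeric(sigma_EY)
  sigma_EE <- as.matrix(sigma_EE)
  L <- nrow(sigma_EX)
  K <- ncol(sigma_EX)
  if (L < 1) stop("need at least one instrument", call. = FALSE)
  if (length(sigma_EY) != L || any(dim(sigma_EE) != L)) {
    stop("dimensions of sigma_EX, sigma_EY and sigma_EE disagree", call. = FALSE)
  }
  if (max(abs(sigma_EE - t(sigma_EE))) > 1e-8) {
    stop("sigma_EE must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(sigma_EE) - 1)) > 1e-6) {
    stop("sigma_EE must have unit diagonal (a correlation matrix)", call. = FALSE)
  }
  instrument_ids <- instrument_ids %||% rownames(sigma_EX) %||% paste0("E", seq_len(L))
  exposure_ids <- exposure_ids %||% colnames(sigma_EX) %||% paste0("X", seq_len(K))
  dimnames(sigma_EX) <- list(instrument_ids, exposure_ids)
  dimnames(sigma_EE) <- list(instrument_ids, instrument_ids)
  names(sigma_EY) <- instrument_ids
  structure(
    list(
      sigma_EX = sigma_EX, sigma_EY = sigma_EY, sigma_EE = sigma_EE,
      n_exposure = n_exposure, n_outcome = n_outcome,
      instrument_ids = instrument_ids, exposure_ids = exposure_ids
    ),
    class = "summary_covariances"
  )
}

#' @export
print.summary_covariances <- function(x, ...) {
  cat("<summary_covariances> L = ", length(x$instrument_ids),
    " instruments, K = ", length(x$exposure_ids), " exposures",
    if (!is.na(x$n_exposure)) paste0(", n = ", x$n_exposure) else "",
    if (!identical(x$n_exposure, x$n_outcome)) {
      paste0(" (outcome n = ", x$n_outcome, ")")
    } else {
      ""
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Compute summary covariances from individual-level data
#'
#' Genotypes are centered and scaled to unit variance, so that `sigma_EE` is
#' the empirical LD correlation matrix and the columns of `sigma_EX` match
#' standardized eQTL regression coefficients. Exposures and outcome are
#' centered; by default they are kept on their structural scale (the
#' convention under which the estimators recover the structural coefficients
#' of the generating model), and with `scale = "all"` they are additionally
#' scaled to unit variance.
#'
#' @param e N x L genotype (or instrument) matrix.
#' @param x N x K exposure matrix (a vector is treated as one column).
#' @param y Length-N outcome vector.
#' @param scale `"genotypes"` (default) or `"all"`; see Details.
#' @return A [summary_covariances()] object with `n_exposure = n_outcome = N`.
#' @export
covariances_from_samples <- function(e, x, y, scale = c("genotypes", "all")) {
  scale <- match.arg(scale)
  e <- as.matrix(e)
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(e)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  if (nrow(x) != n || length(y) != n) {
    stop("e, x and y must have the same number of rows", call. = FALSE)
  }
  check_nonconstant <- function(m, what) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      cols <- colnames(m) %||% as.character(seq_len(ncol(m)))
      stop("constant ", what, " column(s): ",
        paste(cols[sds == 0], collapse = ", "),
        call. = FALSE
      )
    }
  }
  check_nonconstant(e, "instrument")
  check_nonconstant(x, "exposure")
  if (stats::sd(y) == 0) stop("constant outcome", call. = FALSE)

  es <- base::scale(e)
  xs <- base::scale(x, scale = (scale == "all"))
  ys <- base::scale(y, scale = (scale == "all"))
  denom <- n - 1
  summary_covariances(
    sigma_EX = crossprod(es, xs) / denom,
    sigma_EY = as.numeric(crossprod(es, ys) / denom),
    sigma_EE = stats::cor(e),
    n_exposure = n, n_outcome = n,
    instrument_ids = colnames(e), exposure_ids = colnames(x)
  )
}

#' Extract summary covariances implied by a linear SEM
#'
#' Convenience wrapper around [implied_covariance()] that slices the implied
#' covariance matrix into a [summary_covariances()] object (rescaling the
#' instrument block to a correlation matrix).
#'
#' @param sem A [linear_sem()].
#' @param instruments,exposures,outcome Node labels.
#' @param n Nominal sample size to attach (population covariances have none).
#' @return A [summary_covariances()] object.
#' @export
sem_summary_covariances <- function(sem, instruments, exposures, outcome,
                                    n = NA_integer_) {
  S <- implied_covariance(sem)
  d <- sqrt(diag(S)[instruments])
  summary_covariances(
    sigma_EX = S[instruments, exposures, drop = FALSE] / d,
    sigma_EY = S[instruments, outcome] / d,
    sigma_EE = stats::cov2cor(S[instruments, instruments, drop = FALSE]),
    n_exposure = n,
    instrument_ids = instruments, exposure_ids = exposures
  )
}

#' Convert per-allele summary statistics to standardized covariances
#'
#' Approximates the covariance between a standardized genotype and a
#' standardized trait from a per-allele regression coefficient:
#' `cov = beta * sd_snp / sd_trait` with `sd_snp = sqrt(2 * maf * (1 - maf))`
#' under Hardy-Weinberg equilibrium.
#'
#' @param beta Per-allele regression coefficient(s).
#' @param maf Minor allele frequency (in (0, 0.5]).
#' @param sd_trait Standard deviation of the trait (1 if standardized; for a
#'   log-odds outcome the effect stays on the log-odds scale).
#' @return Standardized covariance(s).
#' @export
beta_to_covariance <- function(beta, maf, sd_trait = 1) {
  if (any(maf <= 0 | maf > 0.5, na.rm = TRUE)) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  beta * sqrt(2 * maf * (1 - maf)) / sd_trait
}
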