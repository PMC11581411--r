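#' Least-squares MVMR estimator ("regression of regression coefficients")
#'
#' Estimates the direct causal effects by replacing the population covariances
#' in the identification equation with their finite-sample estimates:
#' `c_LS = (S_EX' S_EX)^-1 S_EX' S_EY`. For `L = K` instruments this is the
#' exact solution of the sample moment conditions; for `L > K` it is the
#' unweighted GMM solution.
#'
#' @param s A [summary_covariances()] object.
#' @param sigma2 Residual outcome variance used for the summary-based standard
#'   errors: a number (default 1, conservative for a standardized outcome) or
#'   `"genetic"` to subtract the genetically explained variance.
#' @return An object of class `mvmr_fit`; see [tidy.mvmr_fit()].
#' @seealso [gmm_estimate()], [gmm_weighted()], [univariate_ratio()]
#' @export
ls_estimate <- function(s, sigma2 = 1) {
  stopifnot(inherits(s, "summary_covariances"))
  check_rank(s$sigma_EX)
  c_hat <- qr.solve(s$sigma_EX, s$sigma_EY)
  new_mvmr_fit(s, c_hat,
    estimator = "LS", sigma2 = sigma2,
    delta = diag(length(s$instrument_ids))
  )
}

#' Weighted GMM estimator for MVMR
#'
#' Minimizes the weighted quadratic form in the sample moments
#' `(S_EY - S_EX c)' Delta (S_EY - S_EX c)`, giving
#' `c = (S_EX' Delta S_EX)^-1 S_EX' Delta S_EY`. `Delta = I` reproduces
#' [ls_estimate()]; `Delta = S_EE^-1` reproduces [gmm_estimate()]. For a
#' square full-rank `S_EX` all weightings coincide.
#'
#' @inheritParams ls_estimate
#' @param delta Positive-definite L x L weighting matrix.
#' @return An object of class `mvmr_fit`.
#' @export
gmm_weighted <- function(s, delta, sigma2 = 1) {
  stopifnot(inherits(s, "summary_covariances"))
  delta <- as.matrix(delta)
  L <- length(s$instrument_ids)
  if (any(dim(delta) != L)) {
    stop("delta must be ", L, " x ", L, call. = FALSE)
  }
  if (max(abs(delta - t(delta))) > 1e-8) {
    stop("delta must be symmetric positive definite", call. = FALSE)
  }
  ev <- eigen(delta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("delta must be symmetric positive definite", call. = FALSE)
  }
  check_rank(s$sigma_EX)
  R <- chol(delta)
  c_hat <- qr.solve(R %*% s$sigma_EX, as.numeric(R %*% s$sigma_EY))
  new_mvmr_fit(s, c_hat, estimator = "GMM(Delta)", sigma2 = sigma2, delta = delta)
}

#' Optimal GMM (two-stage least squares) estimator for MVMR
#'
#' Uses the inverse of the instrument LD matrix as the weighting matrix, the
#' minimum-asymptotic-variance choice under homoskedastic errors:
#' `c_GMM = (S_EX' S_EE^-1 S_EX)^-1 S_EX' S_EE^-1 S_EY`. Equivalent to
#' two-stage least squares on individual-level data.
#'
#' @inheritParams ls_estimate
#' @return An object of class `mvmr_fit`.
#' @export
gmm_estimate <- function(s, sigma2 = 1) {
  stopifnot(inherits(s, "summary_covariances"))
  check_rank(s$sigma_EX)
  W <- ld_inverse_chol(s$sigma_EE)
  c_hat <- qr.solve(W %*% s$sigma_EX, as.numeric(W %*% s$sigma_EY))
  new_mvmr_fit(s, c_hat, estimator = "GMM", sigma2 = sigma2)
}

# Cholesky "half inverse" of the LD matrix: W'W = sigma_EE^-1, solved by
# decomposition rather than explicit inversion. Errors on (near-)singular LD.
ld_inverse_chol <- function(sigma_EE) {
  R <- tryCatch(chol(sigma_EE), error = function(e) NULL)
  if (is.null(R)) {
    stop(
      "the LD matrix sigma_EE is singular; prune instruments in perfect LD ",
      "(see `prune_instruments()`) before GMM estimation",
      call. = FALSE
    )
  }
  kap <- kappa(sigma_EE, exact = TRUE)
  if (kap > 1e8) {
    warning(
      "near-singular LD matrix (condition number ", format(kap, digits = 3),
      "); consider pruning high-LD instruments",
      call. = FALSE
    )
  }
  backsolve(R, diag(nrow(R)), transpose = TRUE)
}

check_rank <- function(sigma_EX, tol = 1e-8) {
  sv <- svd(as.matrix(sigma_EX), nu = 0, nv = 0)$d
  K <- ncol(as.matrix(sigma_EX))
  r <- sum(sv > tol * max(sv))
  if (r < K) {
    dt <- if (nrow(as.matrix(sigma_EX)) == K) {
      det(as.matrix(sigma_EX))
    } else {
      sqrt(abs(det(crossprod(sigma_EX))))
    }
    stop(
      "sigma_EX is rank-deficient (rank ", r, " < ", K, ", |det| = ",
      format(dt, digits = 3), "): under-determined system",
      call. = FALSE
    )
  }
  invisible(r)
}

#' Univariate instrumental-variable ratio estimator
#'
#' The classical single-instrument, single-exposure formula
#' `c = sigma_EY / sigma_EX`.
#'
#' @param sigma_EY Covariance between instrument and outcome.
#' @param sigma_EX Covariance between instrument and exposure.
#' @return The ratio estimate (a number).
#' @export
univariate_ratio <- function(sigma_EY, sigma_EX) {
  if (any(sigma_EX == 0)) {
    stop("sigma_EX is zero: the instrument carries no signal on the exposure",
      call. = FALSE
    )
  }
  sigma_EY / sigma_EX
}

# Internal constructor shared by the estimators: attaches inference and
# diagnostics when a sample size is available. `delta` is the weighting
# matrix the estimator used (NULL = optimal GMM weighting), so the standard
# errors match the estimator they accompany.
new_mvmr_fit <- function(s, c_hat, estimator, sigma2 = 1, delta = NULL) {
  c_hat <- stats::setNames(as.numeric(c_hat), s$exposure_ids)
  n <- s$n_outcome
  se <- p <- stat <- rep(NA_real_, length(c_hat))
  if (!is.na(n)) {
    se <- se_summary(s, c_hat, n, sigma2 = sigma2, delta = delta)
    p <- pvalues(c_hat, se)
    stat <- ifelse(se > 0, c_hat / se, ifelse(c_hat == 0, 0, Inf))
  }
  diag <- determinacy_check(s, quiet = TRUE)
  structure(
    list(
      effects = c_hat,
      se = stats::setNames(se, s$exposure_ids),
      statistic = stats::setNames(stat, s$exposure_ids),
      p = stats::setNames(p, s$exposure_ids),
      estimator = estimator,
      diagnostics = diag,
      sigma2 = sigma2,
      summary = s
    ),
    class = "mvmr_fit"
  )
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat("<mvmr_fit> estimator: ", x$estimator, "\n", sep = "")
  print(tidy(x), ...)
  if (length(x$diagnostics$flags) > 0) {
    cat("flags:", paste(x$diagnostics$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted MVMR estimate
#'
#' @param x An `mvmr_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per exposure: `exposure`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `estimator`.
#' @method tidy mvmr_fit
#' @export
tidy.mvmr_fit <- function(x, ...) {
  tibble::tibble(
    exposure = names(x$effects),
    estimate = unname(x$effects),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p),
    estimator = x$estimator
  )
}

#' One-row model summary of a fitted MVMR estimate
#'
#' @param x An `mvmr_fit` object.
#' @param ... Unused.
#' @return A tibble with instrument/exposure counts, sample sizes, LD and
#'   instrument-strength diagnostics and the flags raised.
#' @method glance mvmr_fit
#' @export
glance.mvmr_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    estimator = x$estimator,
    n_instruments = length(x$summary$instrument_ids),
    n_exposures = length(x$summary$exposure_ids),
    n_exposure_sample = x$summary$n_exposure,
    n_outcome_sample = x$summary$n_outcome,
    det_EE = d$det_EE,
    det_EX = d$det_A_proxy,
    min_conditional_F = if (length(d$cond_F) > 0) min(d$cond_F) else NA_real_,
    flags = paste(d$flags, collapse = ";")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Forest plot of MVMR effect estimates
#'
#' @param object An `mvmr_fit` object.
#' @param conf_level Confidence level for the normal-approximation intervals.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvmr_fit
#' @export
autoplot.mvmr_fit <- function(object, conf_level = 0.95, ...) {
  td <- tidy(object)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  td$lo <- td$estimate - z * td$std.error
  td$hi <- td$estimate + z * td$std.error
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$exposure, .data$estimate)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "causal effect (standardized)", y = NULL,
      title = paste0(object$estimator, " estimates")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
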