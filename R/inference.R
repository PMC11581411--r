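#' Summary-based standard errors for MVMR effect estimates
#'
#' Standard errors from the asymptotic covariance of the optimal GMM
#' (two-stage least squares) estimator,
#' `Var(c_hat) = sigma^2 (S_EX' S_EE^-1 S_EX)^-1 / n`,
#' using the outcome-study sample size `n`. By default the residual outcome
#' variance `sigma^2` is set to 1 (conservative for a standardized outcome);
#' `sigma2 = "genetic"` subtracts the genetically explained outcome variance
#' `c_hat' Q c_hat` with `Q = S_EX' S_EE^-1 S_EX`.
#'
#' @param s A [summary_covariances()] object.
#' @param c_hat Length-K vector of estimated effects.
#' @param n Outcome sample size.
#' @param sigma2 Residual outcome variance: a positive number or `"genetic"`.
#' @param delta Weighting matrix used by the estimator whose standard errors
#'   are required: `NULL` (default) for the optimal GMM / two-stage
#'   least-squares weighting, or the L x L matrix passed to [gmm_weighted()]
#'   (the identity for [ls_estimate()]), in which case the sandwich form
#'   `(B'DB)^-1 B'D S_EE D B (B'DB)^-1 sigma^2 / n` with `B = S_EX` is used.
#' @return Length-K vector of standard errors.
#' @export
se_summary <- function(s, c_hat, n, sigma2 = 1, delta = NULL) {
  stopifnot(inherits(s, "summary_covariances"))
  K <- length(s$exposure_ids)
  if (is.na(n) || n <= K) {
    stop("sample size n must exceed the number of exposures", call. = FALSE)
  }
  Q <- crossprod(s$sigma_EX, solve(s$sigma_EE, s$sigma_EX))
  if (identical(sigma2, "genetic")) {
    sigma2 <- max(0, 1 - as.numeric(t(c_hat) %*% Q %*% c_hat))
  }
  if (is.null(delta)) {
    V <- solve(Q) * sigma2 / n
  } else {
    B <- s$sigma_EX
    BD <- crossprod(B, delta)
    bread <- solve(BD %*% B)
    V <- bread %*% BD %*% s$sigma_EE %*% t(BD) %*% bread * sigma2 / n
  }
  sqrt(pmax(diag(V), 0))
}

#' Exact standard errors from individual-level data
#'
#' Classical homoskedastic two-stage least squares standard errors: residual
#' variance is estimated from `y - x c_hat` and the estimate covariance is
#' `sigma_hat^2 (x_hat' x_hat)^-1` where `x_hat` is the projection of the
#' exposures onto the instruments.
#'
#' @param e N x L instrument matrix.
#' @param x N x K exposure matrix.
#' @param y Length-N outcome vector.
#' @param c_hat Length-K vector of estimated effects.
#' @return Length-K vector of standard errors.
#' @export
se_individual <- function(e, x, y, c_hat) {
  e <- base::scale(as.matrix(e))
  x <- base::scale(as.matrix(x), scale = FALSE)
  y <- as.numeric(base::scale(y, scale = FALSE))
  n <- nrow(e)
  K <- ncol(x)
  if (n <= ncol(e) + K) stop("insufficient sample size", call. = FALSE)
  resid <- y - as.numeric(x %*% c_hat)
  sigma2 <- sum(resid^2) / (n - K)
  qe <- qr(e)
  x_hat <- qr.fitted(qe, x)
  V <- solve(crossprod(x_hat)) * sigma2
  sqrt(pmax(diag(V), 0))
}

#' Two-sided normal p-values for causal-effect estimates
#'
#' @param c_hat Vector of estimates.
#' @param se Vector of standard errors (same length).
#' @return Vector of p-values for the null hypothesis of zero effect.
#' @export
pvalues <- function(c_hat, se) {
  if (length(c_hat) != length(se)) {
    stop("c_hat and se must have the same length", call. = FALSE)
  }
  if (any(se < 0, na.rm = TRUE)) stop("se must be non-negative", call. = FALSE)
  zero_se <- !is.na(se) & se == 0
  if (any(zero_se & c_hat != 0)) {
    warning("zero standard error with non-zero estimate; p-value set to 0",
      call. = FALSE
    )
  }
  p <- 2 * stats::pnorm(-abs(c_hat / se))
  p[zero_se] <- ifelse(c_hat[zero_se] == 0, 1, 0)
  p
}

#' Conditional F-statistics for instrument strength in MVMR
#'
#' Measures, for each exposure, the strength of its instruments conditional on
#' the other exposures, computed from summary covariances. Writing
#' `Q = S_EX' S_EE^-1 S_EX` for the covariance matrix of the genetically
#' predicted exposures, the statistic for exposure `k` is
#' `F_k = (n - L) / (L - K + 1) * v_k / (1 - Q_kk)` where `v_k` is the
#' variance of predicted exposure `k` left after regressing on the other
#' predicted exposures. For `K = 1` the ordinary instrument F-statistic is
#' returned (with a message).
#'
#' @param s A [summary_covariances()] object.
#' @param n Exposure-study sample size; defaults to `s$n_exposure`.
#' @return Length-K named vector of (conditional) F-statistics.
#' @export
conditional_f <- function(s, n = s$n_exposure) {
  stopifnot(inherits(s, "summary_covariances"))
  if (is.na(n)) stop("sample size n required", call. = FALSE)
  L <- length(s$instrument_ids)
  K <- length(s$exposure_ids)
  Q <- crossprod(s$sigma_EX, solve(s$sigma_EE, s$sigma_EX))
  resid_var <- pmax(1 - diag(Q), 1e-12)
  if (K == 1) {
    message("single exposure: returning the ordinary F-statistic")
    f <- (n - L - 1) / L * diag(Q) / resid_var
    return(stats::setNames(pmax(as.numeric(f), 0), s$exposure_ids))
  }
  f <- numeric(K)
  for (k in seq_len(K)) {
    qkk <- Q[k, k]
    qko <- Q[k, -k, drop = FALSE]
    qoo <- Q[-k, -k, drop = FALSE]
    v_k <- qkk - as.numeric(qko %*% solve(qoo, t(qko)))
    f[k] <- (n - L) / (L - K + 1) * max(v_k, 0) / resid_var[k]
  }
  stats::setNames(pmax(f, 0), s$exposure_ids)
}

#' Determinacy and instrument-strength diagnostics
#'
#' Reports the determinant of the LD matrix, the determinant of the
#' instrument-exposure covariance matrix (or of its Gram matrix square root
#' when over-determined), the conditional F-statistics (when a sample size is
#' available), and raises flags:
#' \describe{
#'   \item{under_determined}{numerical rank of `S_EX` below the number of
#'     exposures, or the rank test fails: the minimum conditional F falls
#'     below `f_underdetermined` (the Sanderson-Windmeijer statistic is, up to
#'     scaling, the minimum-eigenvalue test of the rank of `S_EX`, so a tiny
#'     conditional F means the data cannot distinguish the system from a
#'     rank-deficient, non-identifiable one).}
#'   \item{weak_instruments}{minimum conditional F below `f_weak` (the
#'     conventional cut-off of 10).}
#'   \item{near_singular_LD}{LD-matrix condition number above 1e8.}
#' }
#'
#' @param s A [summary_covariances()] object.
#' @param f_underdetermined Critical conditional F for the rank test
#'   (default 30, a conservative chi-square cut-off).
#' @param f_weak Weak-instrument threshold (default 10).
#' @param quiet Suppress the single-exposure message from [conditional_f()].
#' @return An object of class `mvmr_diagnostics` with fields `det_EE`,
#'   `det_A_proxy`, `cond_F`, `rank_EX` and `flags`.
#' @export
determinacy_check <- function(s, f_underdetermined = 30, f_weak = 10,
                              quiet = FALSE) {
  stopifnot(inherits(s, "summary_covariances"))
  L <- length(s$instrument_ids)
  K <- length(s$exposure_ids)
  det_EE <- det(s$sigma_EE)
  det_A <- if (L == K) {
    det(s$sigma_EX)
  } else {
    sqrt(abs(det(crossprod(s$sigma_EX))))
  }
  sv <- svd(s$sigma_EX, nu = 0, nv = 0)$d
  rank_EX <- sum(sv > 1e-8 * max(sv, 1e-300))
  cond_F <- numeric(0)
  if (!is.na(s$n_exposure) && s$n_exposure > L + 1) {
    cond_F <- if (quiet) {
      suppressMessages(conditional_f(s))
    } else {
      conditional_f(s)
    }
  }
  flags <- character(0)
  if (rank_EX < K) flags <- c(flags, "under_determined")
  if (length(cond_F) > 0 && min(cond_F) < f_underdetermined) {
    flags <- union(flags, "under_determined")
  }
  if (length(cond_F) > 0 && min(cond_F) < f_weak) {
    flags <- c(flags, "weak_instruments")
  }
  if (kappa(s$sigma_EE, exact = TRUE) > 1e8) {
    flags <- c(flags, "near_singular_LD")
  }
  structure(
    list(
      det_EE = det_EE, det_A_proxy = det_A, cond_F = cond_F,
      rank_EX = rank_EX, flags = flags
    ),
    class = "mvmr_diagnostics"
  )
}

#' @export
print.mvmr_diagnostics <- function(x, ...) {
  cat("<mvmr_diagnostics>\n")
  cat("  det(LD):", format(x$det_EE, digits = 4), "\n")
  cat("  det(EX):", format(x$det_A_proxy, digits = 4), "\n")
  if (length(x$cond_F) > 0) {
    cat("  conditional F:", paste(
      paste0(names(x$cond_F), "=", format(x$cond_F, digits = 4)),
      collapse = ", "
    ), "\n")
  }
  cat(
    "  flags:",
    if (length(x$flags) > 0) paste(x$flags, collapse = ", ") else "none", "\n"
  )
  invisible(x)
}

#' @method tidy mvmr_diagnostics
#' @export
tidy.mvmr_diagnostics <- function(x, ...) {
  tibble::tibble(
    det_EE = x$det_EE,
    det_EX = x$det_A_proxy,
    rank_EX = x$rank_EX,
    min_conditional_F = if (length(x$cond_F) > 0) min(x$cond_F) else NA_real_,
    under_determined = "under_determined" %in% x$flags,
    weak_instruments = "weak_instruments" %in% x$flags,
    near_singular_LD = "near_singular_LD" %in% x$flags
  )
}
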