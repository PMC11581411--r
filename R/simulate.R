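#' Scenario configuration for the MVMR simulator
#'
#' Describes one generative experiment: the causal diagram family, numbers of
#' instruments and exposures, true direct effects, instrument-strength range,
#' LD structure (minor allele frequencies and successive-pair genotype
#' correlations of a Markov chain), determinant constraints on the
#' instrument-effect matrix, sample size(s), replicate count and master seed.
#'
#' Diagram families and their defaults (the study conditions; any field can be
#' overridden):
#' \describe{
#'   \item{single_IV}{one instrument, one exposure; strength 0.8 (strong),
#'     true effect 0.3.}
#'   \item{multi_IV}{ten instruments, one exposure, strengths 0.1-0.3, true
#'     effect 0.3.}
#'   \item{exact_K}{two instruments with pairwise correlation `alpha = 0.3`,
#'     two exposures, effect matrix with entries 0.1-0.3 and determinant
#'     > 0.05, true effects (0.2, 0.6).}
#'   \item{overdetermined}{seven instruments of which three randomly chosen
#'     ones are causal for all three exposures (effects 0.1-0.3); the
#'     remaining instruments associate with the exposures only through LD;
#'     true effects (0.15, -0.05, -0.27).}
#'   \item{underdetermined}{two instruments, two exposures, but a single
#'     causal variant (the second instrument linked only by LD): the effects
#'     are non-identifiable.}
#'   \item{pleiotropy_hidden}{eight instruments, three causal, three exposures
#'     with effects (`hidden_effect`, -0.05, -0.27); estimation drops the
#'     first exposure to emulate horizontal pleiotropy through an unmeasured
#'     gene.}
#'   \item{two_sample}{five instruments, two causal, two exposures with true
#'     effects (0.208, -0.294); independent exposure- and outcome-study
#'     samples whose LD matrices are drawn from Wishart distributions centred
#'     on the reference LD.}
#' }
#'
#' @param diagram One of `"single_IV"`, `"multi_IV"`, `"exact_K"`,
#'   `"overdetermined"`, `"underdetermined"`, `"pleiotropy_hidden"`,
#'   `"two_sample"`.
#' @param n Sample size (one-sample designs).
#' @param reps Number of replicates for [replicate_experiment()].
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param L,K Numbers of instruments and exposures.
#' @param true_effects Length-K vector of true direct effects.
#' @param strength_range Range for the entries of the instrument-effect
#'   matrix.
#' @param n_causal Number of causal variants (instruments with non-zero rows
#'   in the effect matrix); defaults to `K` except where the diagram dictates
#'   otherwise.
#' @param maf Minor allele frequencies: length-L vector, or length-2 range
#'   drawn once per configuration.
#' @param succ_r Successive-pair genotype correlations: length-(L-1) vector or
#'   length-2 range drawn once per configuration.
#' @param det_min,det_max Determinant constraints for the causal block of the
#'   effect matrix (see [random_instrument_matrix()]).
#' @param causal_assignment `"shared"` (every causal variant affects every
#'   exposure, as at loci with widespread regulatory pleiotropy) or
#'   `"dedicated"` (each exposure has its own causal variant, the structure of
#'   the basic multi-exposure identification diagram; requires
#'   `n_causal == K`). The two-sample diagram defaults to `"dedicated"`,
#'   everything else to `"shared"`.
#' @param noise_sd Structural error standard deviation (default 1).
#' @param hidden_effect Effect of the hidden exposure (pleiotropy diagram).
#' @param n_eqtl,n_gwas Sample sizes of the two samples (two-sample diagram).
#' @param wishart_df Degrees of freedom for the Wishart LD perturbation in the
#'   two-sample diagram; `NULL` uses the respective sample sizes.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(diagram = c(
                              "single_IV", "multi_IV", "exact_K",
                              "overdetermined", "underdetermined",
                              "pleiotropy_hidden", "two_sample"
                            ),
                            n = 10000, reps = 1000, seed = 1,
                            L = NULL, K = NULL, true_effects = NULL,
                            strength_range = NULL, n_causal = NULL,
                            maf = NULL, succ_r = NULL,
                            det_min = NULL, det_max = NULL,
                            causal_assignment = NULL,
                            noise_sd = 1, hidden_effect = NULL,
                            n_eqtl = 4000, n_gwas = 140000,
                            wishart_df = NULL) {
  diagram <- match.arg(diagram)
  defaults <- switch(diagram,
    single_IV = list(
      L = 1L, K = 1L, true_effects = 0.3, strength_range = c(0.8, 0.8),
      n_causal = 1L, maf = 0.3, succ_r = numeric(0)
    ),
    multi_IV = list(
      L = 10L, K = 1L, true_effects = 0.3, strength_range = c(0.1, 0.3),
      n_causal = 10L, maf = 0.3, succ_r = c(0.3, 0.3)
    ),
    exact_K = list(
      L = 2L, K = 2L, true_effects = c(0.2, 0.6),
      strength_range = c(0.1, 0.3), n_causal = 2L, maf = 0.3,
      succ_r = 0.3, det_min = 0.05
    ),
    overdetermined = list(
      L = 7L, K = 3L, true_effects = c(0.15, -0.05, -0.27),
      strength_range = c(0.1, 0.3), n_causal = 3L,
      maf = c(0.1, 0.4), succ_r = c(0.3, 0.8)
    ),
    underdetermined = list(
      L = 2L, K = 2L, true_effects = c(0.2, 0.6),
      strength_range = c(0.1, 0.3), n_causal = 1L, maf = 0.3, succ_r = 0.3
    ),
    pleiotropy_hidden = list(
      L = 8L, K = 3L, true_effects = c(0.2, -0.05, -0.27),
      strength_range = c(0.1, 0.3), n_causal = 3L,
      maf = c(0.1, 0.4), succ_r = c(0.3, 0.8)
    ),
    two_sample = list(
      L = 5L, K = 2L, true_effects = c(0.208, -0.294),
      strength_range = c(0.1, 0.3), n_causal = 2L,
      maf = c(0.1, 0.4), succ_r = c(0.3, 0.8),
      causal_assignment = "dedicated"
    )
  )
  L <- as.integer(L %||% defaults$L)
  K <- as.integer(K %||% defaults$K)
  true_effects <- true_effects %||% defaults$true_effects
  strength_range <- strength_range %||% defaults$strength_range
  n_causal <- as.integer(n_causal %||% defaults$n_causal)
  maf <- maf %||% defaults$maf
  succ_r <- succ_r %||% defaults$succ_r
  det_min <- det_min %||% defaults$det_min
  det_max <- det_max %||% defaults$det_max
  causal_assignment <- match.arg(
    causal_assignment %||% defaults$causal_assignment %||% "shared",
    c("shared", "dedicated")
  )
  if (causal_assignment == "dedicated" && n_causal != K) {
    stop("dedicated causal assignment requires n_causal == K", call. = FALSE)
  }
  if (!is.null(hidden_effect)) true_effects[1] <- hidden_effect

  if (length(true_effects) != K) stop("true_effects must have length K", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (reps < 1) stop("reps must be at least 1", call. = FALSE)
  if (n_causal > L) stop("n_causal cannot exceed L", call. = FALSE)

  # resolve LD structure once per configuration: the "locus" is fixed, the
  # instrument-effect matrix is redrawn per replicate
  resolved <- with_seed(seed, {
    m <- if (length(maf) == L) {
      maf
    } else if (length(maf) %in% c(1, 2)) {
      stats::runif(L, min(maf), max(maf))
    } else {
      stop("maf must be length L, or a range", call. = FALSE)
    }
    r <- if (L == 1) {
      numeric(0)
    } else if (length(succ_r) == L - 1) {
      succ_r
    } else if (length(succ_r) %in% c(1, 2)) {
      stats::runif(L - 1, min(succ_r), max(succ_r))
    } else {
      stop("succ_r must be length L - 1, or a range", call. = FALSE)
    }
    # clamp each successive correlation into its feasible range given the
    # adjacent allele frequencies (high LD requires similar MAFs); drawn
    # structures therefore always satisfy the bivariate-Bernoulli constraints
    if (L > 1) {
      for (l in seq_len(L - 1)) {
        b <- feasible_r_range(m[l], m[l + 1])
        r[l] <- min(max(r[l], 0.95 * b[1]), 0.95 * b[2])
      }
    }
    causal <- sort(sample.int(L, n_causal))
    list(maf = m, succ_r = r, causal = causal)
  })
  if (any(resolved$maf <= 0 | resolved$maf >= 0.5)) {
    stop("maf values must lie in (0, 0.5)", call. = FALSE)
  }
  if (L > 1 && any(abs(resolved$succ_r) >= 1)) {
    stop("successive correlations must lie in (-1, 1)", call. = FALSE)
  }

  structure(
    list(
      diagram = diagram, L = L, K = K, true_effects = true_effects,
      strength_range = strength_range, n_causal = n_causal,
      maf = resolved$maf, succ_r = resolved$succ_r,
      causal = resolved$causal,
      causal_assignment = causal_assignment,
      det_min = det_min, det_max = det_max,
      n = n, n_eqtl = n_eqtl, n_gwas = n_gwas, wishart_df = wishart_df,
      reps = as.integer(reps), seed = as.integer(seed), noise_sd = noise_sd
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$diagram, ": L = ", x$L, ", K = ", x$K,
    ", causal = {", paste(x$causal, collapse = ","), "}",
    ", c = (", paste(format(x$true_effects), collapse = ", "), ")",
    ", n = ", x$n, ", reps = ", x$reps, ", seed = ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Run code with a temporary RNG state seeded by `seed` (NULL = use current
# stream); restores the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Feasible genotype-correlation range for adjacent SNPs with allele
# frequencies p1, p2 (Frechet bounds of the bivariate Bernoulli).
feasible_r_range <- function(p1, p2) {
  s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  c((max(0, p1 + p2 - 1) - p1 * p2) / s, (min(p1, p2) - p1 * p2) / s)
}

# Counter-based per-replicate seed derivation from a master seed.
derive_seeds <- function(seed, reps) {
  (as.double(seed) * 48271 + 1e6 * seq_len(reps)) %% 2147483629 + 1
}

#' Sample correlated binomial genotypes from a Markov chain
#'
#' Genotypes are Binomial(2, maf) allele counts built from two independent
#' allele chains. The first SNP's alleles are Bernoulli(maf); each subsequent
#' SNP's alleles are drawn conditional on the previous SNP's alleles with the
#' conditional success probabilities of a bivariate Bernoulli chosen so that
#' both the marginal allele frequency and the genotype correlation with the
#' previous SNP match their targets. Non-adjacent SNP correlations follow the
#' Markov product `r_ij = prod(r_k)` (an emergent property of the chain).
#' Infeasible (maf, r) corners are clipped to the Frechet bounds.
#'
#' @param maf Length-L vector of minor allele frequencies in (0, 0.5).
#' @param succ_r Length-(L-1) vector of successive genotype correlations in
#'   (-1, 1).
#' @param n Number of individuals.
#' @param seed Optional seed (RNG state is restored afterwards).
#' @param strict If `TRUE`, error instead of clipping infeasible conditional
#'   probabilities.
#' @return n x L integer matrix with entries in {0, 1, 2} and columns
#'   `snp1..snpL`.
#' @export
markov_genotypes <- function(maf, succ_r, n, seed = NULL, strict = FALSE) {
  L <- length(maf)
  if (L > 1 && length(succ_r) != L - 1) {
    stop("succ_r must have length L - 1", call. = FALSE)
  }
  if (any(maf <= 0 | maf >= 0.5)) stop("maf must lie in (0, 0.5)", call. = FALSE)
  if (L > 1 && any(abs(succ_r) >= 1)) {
    stop("succ_r must lie in (-1, 1)", call. = FALSE)
  }
  with_seed(seed, {
    draw_chain <- function() {
      a <- matrix(0L, n, L)
      a[, 1] <- stats::rbinom(n, 1L, maf[1])
      for (l in seq_len(L - 1) + 1) {
        p_prev <- maf[l - 1]
        p_cur <- maf[l]
        # allele-level correlation equals the genotype-level correlation
        # because genotypes are sums of two iid allele pairs
        cv <- succ_r[l - 1] * sqrt(p_prev * (1 - p_prev) * p_cur * (1 - p_cur))
        p11 <- p_prev * p_cur + cv
        lo <- max(0, p_prev + p_cur - 1)
        hi <- min(p_prev, p_cur)
        if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
          if (strict) {
            stop("infeasible (maf, r) combination at SNP ", l, call. = FALSE)
          }
          warning("clipping infeasible (maf, r) combination at SNP ", l,
            " to the Frechet bound",
            call. = FALSE
          )
        }
        p11 <- min(max(p11, lo), hi)
        cond1 <- p11 / p_prev
        cond0 <- (p_cur - p11) / (1 - p_prev)
        prev <- a[, l - 1]
        a[, l] <- stats::rbinom(n, 1L, ifelse(prev == 1L, cond1, cond0))
      }
      a
    }
    g <- draw_chain() + draw_chain()
    colnames(g) <- paste0("snp", seq_len(L))
    g
  })
}

#' LD correlation matrix implied by the Markov genotype chain
#'
#' @param succ_r Length-(L-1) vector of successive genotype correlations.
#' @return L x L correlation matrix with `r_ij = prod(succ_r[i..j-1])`.
#' @export
markov_ld_matrix <- function(succ_r) {
  L <- length(succ_r) + 1L
  R <- diag(L)
  for (i in seq_len(L - 1)) {
    for (j in seq(i + 1, L)) {
      R[i, j] <- R[j, i] <- prod(succ_r[i:(j - 1)])
    }
  }
  dimnames(R) <- list(paste0("snp", 1:L), paste0("snp", 1:L))
  R
}

#' Rejection-sample an instrument-effect matrix
#'
#' Draws an L x K matrix with entries uniform in `strength_range` until the
#' determinant of its K x K causal block (the first K rows) satisfies the
#' constraint.
#'
#' @param L,K Dimensions.
#' @param strength_range Length-2 range for the entries.
#' @param det_min,det_max Lower/upper bound on `|det|` of the causal block
#'   (either or both may be `NULL`; ignored when `L < K`).
#' @param seed Optional seed.
#' @param max_tries Rejection-sampling cap.
#' @return L x K numeric matrix.
#' @export
random_instrument_matrix <- function(L, K, strength_range,
                                     det_min = NULL, det_max = NULL,
                                     seed = NULL, max_tries = 10000) {
  lo <- min(strength_range)
  hi <- max(strength_range)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      A <- matrix(stats::runif(L * K, lo, hi), L, K)
      if (L >= K && (!is.null(det_min) || !is.null(det_max))) {
        d <- det(A[seq_len(K), , drop = FALSE])
        # lower bound is on the signed determinant (well-oriented block);
        # upper bound caps the magnitude (near-singular block)
        if (!is.null(det_min) && d <= det_min) next
        if (!is.null(det_max) && abs(d) >= det_max) next
      }
      return(A)
    }
    stop("could not satisfy the determinant constraint in ", max_tries,
      " draws",
      call. = FALSE
    )
  })
}

#' Simulate one dataset from a scenario configuration
#'
#' Genotypes come from the Markov chain ([markov_genotypes()]) and are
#' standardized; exposures follow `X_j = sum_i A[i,j] E_i + noise` and the
#' outcome `Y = sum_k c_k X_k + noise`, with independent normal errors of
#' standard deviation `noise_sd`. Only the causal instruments of the
#' configuration get non-zero rows in the effect matrix, which is redrawn for
#' every dataset.
#'
#' @param cfg A [scenario_config()].
#' @param seed Optional seed for this dataset.
#' @param n Sample-size override.
#' @return An object of class `mvmr_dataset`: list with `genotypes` (n x L,
#'   0/1/2), `exposures` (n x K), `outcome` (length n), the instrument-effect
#'   matrix `A`, the configuration echo `truth` and `sample_tag`.
#' @export
simulate_dataset <- function(cfg, seed = NULL, n = cfg$n) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(seed, {
    g <- markov_genotypes(cfg$maf, cfg$succ_r, n)
    es <- base::scale(g)
    A <- matrix(0, cfg$L, cfg$K)
    nc <- length(cfg$causal)
    if (identical(cfg$causal_assignment, "dedicated")) {
      A[cbind(cfg$causal, seq_len(cfg$K))] <-
        stats::runif(cfg$K, min(cfg$strength_range), max(cfg$strength_range))
    } else {
      block <- random_instrument_matrix(
        nc, cfg$K, cfg$strength_range,
        det_min = cfg$det_min, det_max = cfg$det_max
      )
      A[cfg$causal, ] <- block
    }
    x <- es %*% A +
      matrix(stats::rnorm(n * cfg$K, 0, cfg$noise_sd), n, cfg$K)
    colnames(x) <- paste0("X", seq_len(cfg$K))
    y <- as.numeric(x %*% cfg$true_effects) + stats::rnorm(n, 0, cfg$noise_sd)
    structure(
      list(
        genotypes = g, exposures = x, outcome = y, A = A,
        truth = cfg, sample_tag = "shared"
      ),
      class = "mvmr_dataset"
    )
  })
}

#' @export
print.mvmr_dataset <- function(x, ...) {
  cat("<mvmr_dataset> n = ", nrow(x$genotypes), ", L = ", ncol(x$genotypes),
    ", K = ", ncol(x$exposures), " (", x$sample_tag, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Estimate causal effects from a simulated dataset
#'
#' @param data An `mvmr_dataset` (or a list with `genotypes`, `exposures`,
#'   `outcome`).
#' @param estimator `"LS"` or `"GMM"`.
#' @return An `mvmr_fit`.
#' @export
estimate_dataset <- function(data, estimator = c("LS", "GMM")) {
  estimator <- match.arg(estimator)
  s <- covariances_from_samples(data$genotypes, data$exposures, data$outcome)
  if (estimator == "LS") ls_estimate(s) else gmm_estimate(s)
}

#' Simulate a horizontal-pleiotropy scenario with a hidden exposure
#'
#' Generates the full dataset (all exposures present, the first one playing
#' the role of the unmeasured gene with direct effect `hidden_effect`), and a
#' misspecified "observed" view in which that exposure is dropped, so that the
#' instruments act on the outcome through an unmodeled path.
#'
#' @param cfg A [scenario_config()] with `diagram = "pleiotropy_hidden"` (any
#'   configuration with `K >= 2` works).
#' @param hidden_effect Direct effect of the hidden exposure on the outcome.
#' @param seed Optional seed.
#' @return List with `full` (complete `mvmr_dataset`) and `observed` (the
#'   view missing the hidden exposure).
#' @export
pleiotropy_scenario <- function(cfg, hidden_effect, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$K < 2) stop("pleiotropy scenario needs K >= 2", call. = FALSE)
  cfg$true_effects[1] <- hidden_effect
  full <- simulate_dataset(cfg, seed = seed)
  observed <- full
  observed$exposures <- full$exposures[, -1, drop = FALSE]
  observed$A <- full$A[, -1, drop = FALSE]
  list(full = full, observed = observed)
}

#' Perturb a reference LD matrix with Wishart sampling noise
#'
#' Draws `W ~ Wishart(df, sigma_ref / df)` (so `E[W] = sigma_ref`) and
#' rescales to unit diagonal, emulating the sampling error of an LD matrix
#' estimated from `df` individuals.
#'
#' @param sigma_ref Positive-definite reference correlation matrix.
#' @param df Degrees of freedom (must be at least `nrow(sigma_ref)`).
#' @param seed Optional seed.
#' @return Perturbed correlation matrix of the same dimension.
#' @export
wishart_perturb_ld <- function(sigma_ref, df, seed = NULL) {
  sigma_ref <- as.matrix(sigma_ref)
  L <- nrow(sigma_ref)
  if (df < L) stop("df must be at least the matrix dimension", call. = FALSE)
  with_seed(seed, {
    W <- stats::rWishart(1, df, sigma_ref / df)[, , 1]
    R <- stats::cov2cor(W)
    dimnames(R) <- dimnames(sigma_ref)
    R
  })
}

#' Simulate a two-sample MVMR design
#'
#' Generates independent exposure-study and outcome-study datasets whose LD
#' matrices are drawn from Wishart distributions centred on the same reference
#' LD (degrees of freedom default to the respective sample sizes, so the
#' smaller study has the noisier LD), and assembles the cross-sample summary
#' covariances: instrument-exposure covariances and LD from the exposure
#' sample, instrument-outcome covariances from the outcome sample.
#'
#' @param cfg A [scenario_config()] with `n_eqtl` and `n_gwas` set.
#' @param seed Optional seed.
#' @return List with `exposure_sample`, `outcome_sample` (both
#'   `mvmr_dataset`), and `summary` (a [summary_covariances()] with the two
#'   sample sizes).
#' @export
two_sample_scenario <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(seed, {
    ref <- markov_ld_matrix(cfg$succ_r)
    df_e <- cfg$wishart_df %||% cfg$n_eqtl
    df_g <- cfg$wishart_df %||% cfg$n_gwas
    ld_e <- wishart_perturb_ld(ref, df_e)
    ld_g <- wishart_perturb_ld(ref, df_g)
    sample_one <- function(ld, n, tag) {
      cfg_s <- cfg
      # the Markov chain is parameterized by successive correlations; use the
      # perturbed matrix's superdiagonal (its longer-range entries then follow
      # the Markov product approximately), clamped to the feasible range of
      # the bivariate-Bernoulli construction
      r_pert <- ld[cbind(seq_len(cfg$L - 1), seq_len(cfg$L - 1) + 1)]
      for (l in seq_len(cfg$L - 1)) {
        bnd <- feasible_r_range(cfg$maf[l], cfg$maf[l + 1])
        r_pert[l] <- min(max(r_pert[l], 0.95 * bnd[1]), 0.95 * bnd[2])
      }
      cfg_s$succ_r <- r_pert
      b <- simulate_dataset(cfg_s, n = n)
      b$sample_tag <- tag
      b
    }
    eqtl <- sample_one(ld_e, cfg$n_eqtl, "exposure_sample")
    gwas <- sample_one(ld_g, cfg$n_gwas, "outcome_sample")
    s_e <- covariances_from_samples(eqtl$genotypes, eqtl$exposures, eqtl$outcome)
    s_g <- covariances_from_samples(gwas$genotypes, gwas$exposures, gwas$outcome)
    s <- summary_covariances(
      sigma_EX = s_e$sigma_EX,
      sigma_EY = s_g$sigma_EY,
      sigma_EE = s_e$sigma_EE,
      n_exposure = cfg$n_eqtl, n_outcome = cfg$n_gwas
    )
    list(exposure_sample = eqtl, outcome_sample = gwas, summary = s)
  })
}

#' Replicate a simulation scenario and summarize estimator performance
#'
#' Runs `reps` independent datasets from the configuration (per-replicate
#' seeds derived deterministically from the master seed by a counter scheme),
#' estimates with each requested estimator, and tabulates bias, empirical SD,
#' RMSE, Monte-Carlo standard error of the mean, and the rejection rate of the
#' nominal-level test of zero effect (type-I error under a null configuration,
#' power otherwise).
#'
#' Two-sample configurations are replicated through [two_sample_scenario()];
#' in that mode the summary-based standard errors ignore the extra variability
#' induced by the two samples (a warning is emitted once).
#'
#' @param cfg A [scenario_config()].
#' @param estimators Character subset of `c("LS", "GMM")`.
#' @param reps Number of replicates (defaults to `cfg$reps`).
#' @param alpha Nominal test level for the rejection rate.
#' @return A tibble of class `mvmr_replicates` with one row per estimator and
#'   exposure; the per-replicate estimates are attached as attribute `draws`.
#' @export
replicate_experiment <- function(cfg, estimators = c("LS", "GMM"),
                                 reps = cfg$reps, alpha = 0.05) {
  stopifnot(inherits(cfg, "scenario_config"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  seeds <- derive_seeds(cfg$seed, reps)
  two_sample <- cfg$diagram == "two_sample"
  if (two_sample) {
    warning(
      "two-sample mode: summary-based standard errors do not account for ",
      "between-sample variability",
      call. = FALSE
    )
  }
  draws <- vector("list", reps)
  for (i in seq_len(reps)) {
    s <- if (two_sample) {
      two_sample_scenario(cfg, seed = seeds[i])$summary
    } else {
      d <- simulate_dataset(cfg, seed = seeds[i])
      covariances_from_samples(d$genotypes, d$exposures, d$outcome)
    }
    fits <- lapply(estimators, function(est) {
      fit <- if (est == "LS") ls_estimate(s) else gmm_estimate(s)
      td <- tidy(fit)
      td$rep <- i
      td
    })
    draws[[i]] <- dplyr::bind_rows(fits)
  }
  draws <- dplyr::bind_rows(draws)
  truth <- tibble::tibble(
    exposure = paste0("X", seq_len(cfg$K)),
    true = cfg$true_effects
  )
  out <- draws |>
    dplyr::left_join(truth, by = "exposure") |>
    dplyr::group_by(.data$estimator, .data$exposure) |>
    dplyr::summarise(
      true = .data$true[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$true),
      sd = stats::sd(.data$estimate),
      rmse = sqrt(mean((.data$estimate - .data$true)^2)),
      mc_se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
      reject_rate = mean(.data$p.value < alpha, na.rm = TRUE),
      reps = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "draws") <- draws
  attr(out, "config") <- cfg
  class(out) <- c("mvmr_replicates", class(out))
  out
}

#' Distribution plot of replicate estimation error
#'
#' @param object An `mvmr_replicates` summary (from [replicate_experiment()]).
#' @param ... Unused.
#' @return A ggplot object showing the distribution of `estimate - true` per
#'   estimator and exposure.
#' @method autoplot mvmr_replicates
#' @export
autoplot.mvmr_replicates <- function(object, ...) {
  draws <- attr(object, "draws")
  cfg <- attr(object, "config")
  truth <- tibble::tibble(
    exposure = paste0("X", seq_len(cfg$K)),
    true = cfg$true_effects
  )
  dd <- dplyr::left_join(draws, truth, by = "exposure")
  ggplot2::ggplot(dd, ggplot2::aes(
    x = .data$exposure, y = .data$estimate - .data$true,
    fill = .data$estimator
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.4, position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "estimate - truth",
      title = paste0(cfg$diagram, " scenario (n = ", cfg$n, ")")
    ) +
    ggplot2::theme_minimal()
}
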