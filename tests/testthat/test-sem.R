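# Linear-SEM layer: implied covariances, Wright's path rule, d-separation,
# instrumental sets, identification.

test_that("implied covariance matches the matrix formula in simple cases", {
  p <- 4
  sem <- linear_sem(matrix(0, p, p), diag(p))
  expect_equal(implied_covariance(sem), diag(p), ignore_attr = TRUE)

  sem2 <- two_exposure_sem()
  S <- implied_covariance(sem2)
  # identification identity: Sigma_EX c = Sigma_EY
  expect_equal(
    as.numeric(S[c("E1", "E2"), c("X1", "X2")] %*% c(0.2, 0.6)),
    as.numeric(S[c("E1", "E2"), "Y"]),
    tolerance = 1e-12
  )
  expect_true(isSymmetric(S))
  expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
})

test_that("constructors reject cyclic, asymmetric and mismatched inputs", {
  C <- matrix(0, 2, 2)
  C[1, 2] <- 0.5
  C[2, 1] <- 0.5
  expect_error(linear_sem(C, diag(2)), "cyclic")
  expect_error(linear_sem(diag(0.1, 2), matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  expect_error(
    causal_graph(data.frame(from = "a", kind = "->", to = "b", value = 1),
      nodes = "a"
    ),
    "not declared"
  )
  expect_error(
    causal_graph(data.frame(
      from = c("a", "b"), kind = "->", to = c("b", "a"), value = 1
    )),
    "cyclic"
  )
  expect_error(
    causal_graph(data.frame(
      from = c("a", "a"), kind = "->", to = c("b", "b"), value = 1
    )),
    "duplicate"
  )
})

test_that("Wright path sum handles chains, d-separated pairs, and a == b", {
  g <- causal_graph(data.frame(
    from = c("E", "X"), kind = "->", to = c("X", "Y"), value = c(0.8, 0.3)
  ))
  expect_equal(wright_path_sum(g, "E", "Y"), 0.8 * 0.3)
  g2 <- causal_graph(
    data.frame(from = "a", kind = "->", to = "b", value = 0.5),
    nodes = c("a", "b", "c")
  )
  expect_identical(wright_path_sum(g2, "a", "c"), 0)
  expect_identical(wright_path_sum(g2, "a", "a"), 1)
  expect_error(wright_path_sum(g2, "a", "zz"), "unknown node")
})

test_that("path rule equals the covariance matrix formula on random standardized SEMs", {
  for (s in 1:25) {
    sem <- random_standardized_sem(sample(3:8, 1), seed = s)
    S <- implied_covariance(sem)
    g <- as_causal_graph(sem)
    for (a in sem$nodes) {
      for (b in sem$nodes) {
        expect_equal(wright_path_sum(g, a, b), S[a, b], tolerance = 1e-10)
      }
    }
  }
})

test_that("root-variance form of the path rule matches unstandardized SEMs", {
  sem <- two_exposure_sem()
  S <- implied_covariance(sem)
  g <- as_causal_graph(sem)
  v <- diag(S)
  for (a in sem$nodes) {
    for (b in sem$nodes) {
      if (a == b) next
      expect_equal(wright_path_sum(g, a, b, variances = v), S[a, b],
        tolerance = 1e-10
      )
    }
  }
})

test_that("d-separation matches brute-force path enumeration and is symmetric", {
  for (s in 1:20) {
    g <- random_mixed_graph(sample(4:7, 1), seed = 100 + s)
    nodes <- g$nodes
    for (a in nodes) {
      for (b in setdiff(nodes, a)) {
        expect_identical(
          d_separated(g, a, b),
          brute_force_d_separated(g, a, b),
          info = paste("seed", s, a, b)
        )
        expect_identical(d_separated(g, a, b), d_separated(g, b, a))
      }
    }
  }
})

test_that("d-separation basics: direct edges connect, removed edges separate", {
  g <- as_causal_graph(two_exposure_sem())
  expect_false(d_separated(g, "X1", "Y"))
  expect_false(d_separated(g, "E1", "Y"))
  gbar <- causal_graph(
    g$edges[!(g$edges$from %in% c("X1", "X2") & g$edges$to == "Y"), ],
    nodes = g$nodes
  )
  expect_true(d_separated(gbar, "E1", "Y"))
  expect_true(d_separated(gbar, "E2", "Y"))
  expect_error(d_separated(g, "E1", "nope"), "unknown node")
})

test_that("instrumental set verified for the multi-exposure diagram with LD", {
  g <- as_causal_graph(two_exposure_sem())
  cert <- check_instrumental_set(g, c("E1", "E2"), c("X1", "X2"), "Y")
  expect_true(cert$satisfied)
  expect_identical(sort(cert$pairing$exposure), c("X1", "X2"))
  expect_identical(anyDuplicated(cert$pairing$instrument), 0L)
})

test_that("instrumental set refused when causal variants are too few", {
  g <- one_causal_variant_graph()
  cert <- check_instrumental_set(g, c("E1", "E2"), c("X1", "X2"), "Y")
  expect_false(cert$satisfied)
  expect_identical(cert$condition, 3L)
})

test_that("classical single-instrument graph yields the canonical certificate", {
  g <- causal_graph(data.frame(
    from = c("E", "X"), kind = "->", to = c("X", "Y"), value = c(0.8, 0.3)
  ))
  cert <- check_instrumental_set(g, "E", "X", "Y")
  expect_true(cert$satisfied)
  expect_match(cert$pairing$path, "E -> X -> Y", fixed = TRUE)
  expect_error(
    check_instrumental_set(g, c("E", "X"), "X", "Y"),
    "equal size"
  )
})

test_that("instrument that descends from the outcome is refused on condition 1", {
  g <- causal_graph(data.frame(
    from = c("X", "Y"), kind = "->", to = c("Y", "E"), value = c(0.3, 0.2)
  ))
  cert <- check_instrumental_set(g, "E", "X", "Y")
  expect_false(cert$satisfied)
  expect_identical(cert$condition, 1L)
})

test_that("identification recovers true effects from population covariances", {
  sem <- two_exposure_sem()
  S <- implied_covariance(sem)
  c_hat <- identify_effects(
    S[c("E1", "E2"), c("X1", "X2")], S[c("E1", "E2"), "Y"]
  )
  expect_equal(unname(c_hat), c(0.2, 0.6), tolerance = 1e-12)

  # zero outcome covariances identify zero effects
  expect_equal(
    unname(identify_effects(S[c("E1", "E2"), c("X1", "X2")], c(0, 0))),
    c(0, 0)
  )
})

test_that("overdetermined population system agrees with the causal subsystem", {
  # 5 instruments in LD, 2 causal ones (E1, E2) driving the exposures
  nodes <- c(paste0("E", 1:5), "X1", "X2", "Y")
  C <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  C["X1", c("E1", "E2")] <- c(0.3, 0.12)
  C["X2", c("E1", "E2")] <- c(0.1, 0.28)
  C["Y", c("X1", "X2")] <- c(0.2, 0.6)
  Psi <- diag(8)
  dimnames(Psi) <- list(nodes, nodes)
  r <- 0.5
  for (i in 1:5) {
    for (j in 1:5) {
      if (i != j) Psi[i, j] <- r^abs(i - j)
    }
  }
  sem <- linear_sem(C, Psi, nodes)
  S <- implied_covariance(sem)
  full <- identify_effects(S[paste0("E", 1:5), c("X1", "X2")], S[paste0("E", 1:5), "Y"])
  sub <- identify_effects(S[c("E1", "E2"), c("X1", "X2")], S[c("E1", "E2"), "Y"])
  expect_equal(unname(full), unname(sub), tolerance = 1e-10)
  expect_equal(unname(full), c(0.2, 0.6), tolerance = 1e-10)
})

test_that("rank-deficient instrument-exposure covariances are refused", {
  sem_graph <- one_causal_variant_graph()
  sem <- as_linear_sem(sem_graph)
  S <- implied_covariance(sem)
  EX <- S[c("E1", "E2"), c("X1", "X2")]
  expect_lt(abs(det(EX)), 1e-12)
  expect_error(
    identify_effects(EX, S[c("E1", "E2"), "Y"]),
    "under-determined"
  )
})
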