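# Shared generators and independent oracles used across test files.

# Random standardized linear SEM: random DAG coefficients, a few bidirected
# error covariances, and error variances solved (in topological order) so
# every variable has unit variance. On such SEMs Wright's simple-path rule is
# exact, so they serve as the oracle ground for the path-rule tests.
random_standardized_sem <- function(p, seed, edge_prob = 0.4,
                                    n_bidirected = 2) {
  set.seed(seed)
  repeat {
    nodes <- paste0("V", seq_len(p))
    C <- matrix(0, p, p, dimnames = list(nodes, nodes))
    for (i in seq_len(p)) {
      for (j in seq_len(i - 1)) {
        if (stats::runif(1) < edge_prob) C[i, j] <- stats::runif(1, -0.5, 0.5)
      }
    }
    Psi <- matrix(0, p, p, dimnames = list(nodes, nodes))
    pairs <- which(upper.tri(Psi), arr.ind = TRUE)
    sel <- pairs[sample(nrow(pairs), min(n_bidirected, nrow(pairs))), ,
      drop = FALSE
    ]
    for (r in seq_len(nrow(sel))) {
      v <- stats::runif(1, -0.15, 0.15)
      Psi[sel[r, 1], sel[r, 2]] <- Psi[sel[r, 2], sel[r, 1]] <- v
    }
    B <- solve(diag(p) - C)
    ok <- TRUE
    for (i in seq_len(p)) {
      other <- 0
      for (j in seq_len(p)) {
        for (k in seq_len(p)) {
          if (j == i && k == i) next
          other <- other + B[i, j] * Psi[j, k] * B[i, k]
        }
      }
      psi_ii <- 1 - other
      if (psi_ii <= 0.05) {
        ok <- FALSE
        break
      }
      Psi[i, i] <- psi_ii
    }
    if (!ok) next
    ev <- min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-6) next
    return(linear_sem(C, Psi, nodes))
  }
}

# The two-instrument, two-exposure SEM with instrument correlation alpha,
# instrument-effect matrix A (a_ij = effect of E_i on X_j) and outcome
# effects cc, all on the standardized-instrument scale with unit error
# variances.
two_exposure_sem <- function(alpha = 0.3,
                             A = matrix(c(0.2, 0.1, 0.1, 0.3), 2, 2),
                             cc = c(0.2, 0.6)) {
  nodes <- c("E1", "E2", "X1", "X2", "Y")
  C <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  C["X1", c("E1", "E2")] <- A[, 1]
  C["X2", c("E1", "E2")] <- A[, 2]
  C["Y", c("X1", "X2")] <- cc
  Psi <- diag(5)
  dimnames(Psi) <- list(nodes, nodes)
  Psi["E1", "E2"] <- Psi["E2", "E1"] <- alpha
  linear_sem(C, Psi, nodes)
}

# Independent brute-force d-separation oracle: enumerate every simple path in
# the mixed graph and test it for colliders, using only the edge table.
brute_force_d_separated <- function(graph, a, b) {
  ed <- graph$edges
  # adjacency as (neighbor, head_at_here, head_at_there) triples
  neighbors <- function(v) {
    out <- list()
    for (i in seq_len(nrow(ed))) {
      e <- ed[i, ]
      if (e$kind == "->") {
        if (e$from == v) out[[length(out) + 1]] <- list(n = e$to, h_here = FALSE, h_there = TRUE)
        if (e$to == v) out[[length(out) + 1]] <- list(n = e$from, h_here = TRUE, h_there = FALSE)
      } else {
        if (e$from == v) out[[length(out) + 1]] <- list(n = e$to, h_here = TRUE, h_there = TRUE)
        if (e$to == v) out[[length(out) + 1]] <- list(n = e$from, h_here = TRUE, h_there = TRUE)
      }
    }
    out
  }
  found <- FALSE
  recurse <- function(v, visited, head_into_v) {
    if (found) {
      return()
    }
    for (step in neighbors(v)) {
      if (step$n %in% visited) next
      # collider at v: previous edge points at v and this edge points at v
      if (!is.null(head_into_v) && head_into_v && step$h_here) next
      if (step$n == b) {
        found <<- TRUE
        return()
      }
      recurse(step$n, c(visited, step$n), step$h_there)
    }
  }
  recurse(a, c(a), NULL)
  !found
}

# Random mixed acyclic graph (tibble edge list) for d-separation tests.
random_mixed_graph <- function(p, seed, edge_prob = 0.3, bidir_prob = 0.15) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(p))
  rows <- list()
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j >= i) next
      if (stats::runif(1) < edge_prob) {
        rows[[length(rows) + 1]] <- data.frame(
          from = nodes[j], kind = "->", to = nodes[i],
          value = stats::runif(1, -0.5, 0.5)
        )
      } else if (stats::runif(1) < bidir_prob) {
        rows[[length(rows) + 1]] <- data.frame(
          from = nodes[j], kind = "<->", to = nodes[i],
          value = stats::runif(1, -0.2, 0.2)
        )
      }
    }
  }
  if (length(rows) == 0) {
    rows[[1]] <- data.frame(
      from = nodes[1], kind = "->", to = nodes[2], value = 0.1
    )
  }
  causal_graph(do.call(rbind, rows), nodes = nodes)
}

# Fig-1C-style graph: two instruments in LD but only one causal variant for
# two exposures; effects are non-identifiable.
one_causal_variant_graph <- function(alpha = 0.3) {
  causal_graph(data.frame(
    from = c("E1", "E1", "X1", "X2", "E1"),
    kind = c("->", "->", "->", "->", "<->"),
    to = c("X1", "X2", "Y", "Y", "E2"),
    value = c(0.25, 0.2, 0.2, 0.6, alpha)
  ), nodes = c("E1", "E2", "X1", "X2", "Y"))
}
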