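#' Construct a causal graph for a linear structural equation model
#'
#' A causal graph is a mixed graph with directed edges (`"->"`, direct causal
#' effects with a path coefficient) and bidirected edges (`"<->"`, error
#' covariances due to unobserved confounding, including linkage disequilibrium
#' between genetic instruments). The directed part must be acyclic.
#'
#' @param edges A data frame with columns `from`, `kind` (`"->"` or `"<->"`),
#'   `to` and `value` (the edge parameter: path coefficient for directed edges,
#'   error covariance for bidirected edges).
#' @param nodes Optional character vector of node labels. Defaults to all
#'   labels appearing in `edges`, in order of appearance.
#' @param roles Optional named character vector mapping node labels to roles
#'   (`"instrument"`, `"exposure"`, `"outcome"`, `"other"`). Purely descriptive.
#'
#' @return An object of class `causal_graph` with elements `nodes`, `edges`
#'   (a tibble) and `roles`.
#' @examples
#' g <- causal_graph(data.frame(
#'   from = c("E", "X"), kind = c("->", "->"), to = c("X", "Y"),
#'   value = c(0.8, 0.3)
#' ))
#' wright_path_sum(g, "E", "Y")
#' @export
causal_graph <- function(edges, nodes = NULL, roles = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("from", "kind", "to", "value")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop("`edges` is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(edges$kind %in% c("->", "<->"))) {
    stop("edge `kind` must be \"->\" or \"<->\"", call. = FALSE)
  }
  if (!is.numeric(edges$value)) stop("edge `value` must be numeric", call. = FALSE)
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$from, edges$to)))
  }
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(bad) > 0) {
    stop("edge endpoint(s) not declared as nodes: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  # canonicalize bidirected edges so duplicates are caught regardless of order
  key <- ifelse(
    edges$kind == "<->",
    paste(pmin(edges$from, edges$to), "<->", pmax(edges$from, edges$to)),
    paste(edges$from, "->", edges$to)
  )
  if (anyDuplicated(key)) {
    stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "),
      call. = FALSE
    )
  }
  g <- structure(
    list(nodes = nodes, edges = edges, roles = roles),
    class = "causal_graph"
  )
  if (is.null(topological_order(g))) {
    stop("directed part of the graph is cyclic", call. = FALSE)
  }
  g
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("<causal_graph> ", length(x$nodes), " nodes, ",
    sum(x$edges$kind == "->"), " directed / ",
    sum(x$edges$kind == "<->"), " bidirected edges\n",
    sep = ""
  )
  print(x$edges, ...)
  invisible(x)
}

# Topological order of the directed part, or NULL if cyclic (Kahn's algorithm).
topological_order <- function(graph) {
  nodes <- graph$nodes
  de <- graph$edges[graph$edges$kind == "->", ]
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in de$to) indeg[[v]] <- indeg[[v]] + 1L
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, v)
    children <- de$to[de$from == v]
    for (w in children) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' Construct a linear SEM from parameter matrices
#'
#' @param C Square matrix of direct effects; `C[i, j]` is the coefficient of
#'   parent `j` in the structural equation of child `i`. The directed graph it
#'   encodes must be acyclic.
#' @param Psi Symmetric positive-semidefinite error covariance matrix of the
#'   structural disturbances.
#' @param nodes Character vector of variable labels (row/column order of `C`
#'   and `Psi`).
#' @return An object of class `linear_sem`.
#' @export
linear_sem <- function(C, Psi, nodes = NULL) {
  C <- as.matrix(C)
  Psi <- as.matrix(Psi)
  p <- nrow(C)
  if (ncol(C) != p || nrow(Psi) != p || ncol(Psi) != p) {
    stop("C and Psi must be square matrices of the same dimension", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- rownames(C) %||% paste0("V", seq_len(p))
  if (length(nodes) != p) stop("`nodes` length must match dim(C)", call. = FALSE)
  if (max(abs(Psi - t(Psi))) > 1e-8) {
    stop("Psi must be symmetric", call. = FALSE)
  }
  ev <- eigen(Psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("Psi must be positive semi-definite", call. = FALSE)
  }
  dimnames(C) <- dimnames(Psi) <- list(nodes, nodes)
  sem <- structure(list(C = C, Psi = Psi, nodes = nodes), class = "linear_sem")
  if (is.null(topological_order(as_causal_graph(sem)))) {
    stop("directed part encoded by C is cyclic", call. = FALSE)
  }
  sem
}

#' @export
print.linear_sem <- function(x, ...) {
  cat("<linear_sem> ", length(x$nodes), " variables: ",
    paste(x$nodes, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Convert between causal graphs and linear SEMs
#'
#' `as_linear_sem()` assembles the coefficient matrix `C` and error covariance
#' `Psi` from the edge list; `as_causal_graph()` extracts the edge list of a
#' `linear_sem`.
#'
#' @param graph A [causal_graph()].
#' @param error_var Named numeric vector of error variances (diagonal of
#'   `Psi`); unnamed scalar recycles. Default 1 for every node.
#' @return A [linear_sem()] or [causal_graph()].
#' @export
as_linear_sem <- function(graph, error_var = 1) {
  nodes <- graph$nodes
  p <- length(nodes)
  C <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Psi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (is.null(names(error_var))) {
    diag(Psi) <- rep_len(error_var, p)
  } else {
    diag(Psi) <- unname(error_var[nodes])
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    if (e$kind == "->") {
      C[e$to, e$from] <- e$value
    } else {
      Psi[e$from, e$to] <- Psi[e$to, e$from] <- e$value
    }
  }
  linear_sem(C, Psi, nodes)
}

#' @rdname as_linear_sem
#' @param sem A [linear_sem()].
#' @export
as_causal_graph <- function(sem) {
  nodes <- sem$nodes
  C <- sem$C
  Psi <- sem$Psi
  idx <- which(C != 0, arr.ind = TRUE)
  de <- tibble::tibble(
    from = nodes[idx[, 2]], kind = "->", to = nodes[idx[, 1]],
    value = C[idx]
  )
  iu <- which(upper.tri(Psi) & Psi != 0, arr.ind = TRUE)
  be <- tibble::tibble(
    from = nodes[iu[, 1]], kind = "<->", to = nodes[iu[, 2]],
    value = Psi[iu]
  )
  structure(
    list(nodes = nodes, edges = dplyr::bind_rows(de, be), roles = NULL),
    class = "causal_graph"
  )
}

#' Model-implied covariance matrix of a linear SEM
#'
#' Computes `Sigma = (I - C)^-1 Psi (I - C^T)^-1`, the covariance matrix of the
#' variables implied by the structural equations `X_i = sum_j C[i,j] X_j + U_i`
#' with `Cov(U) = Psi`.
#'
#' @param sem A [linear_sem()].
#' @return A symmetric covariance matrix with the SEM's node labels.
#' @export
implied_covariance <- function(sem) {
  stopifnot(inherits(sem, "linear_sem"))
  p <- length(sem$nodes)
  IC <- diag(p) - sem$C
  inv <- tryCatch(solve(IC), error = function(e) NULL)
  if (is.null(inv)) {
    stop("(I - C) is singular; implied covariance (and identification) impossible",
      call. = FALSE
    )
  }
  S <- inv %*% sem$Psi %*% t(inv)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(sem$nodes, sem$nodes)
  S
}

# Internal: adjacency list of a mixed graph for path enumeration.
# Each entry: to, value, head_at_from, head_at_to (arrowhead indicators).
mixed_adjacency <- function(graph) {
  adj <- stats::setNames(
    replicate(length(graph$nodes), list(), simplify = FALSE), graph$nodes
  )
  add <- function(a, b, value, head_a, head_b) {
    adj[[a]][[length(adj[[a]]) + 1L]] <<- list(
      to = b, value = value, head_from = head_a, head_to = head_b
    )
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    if (e$kind == "->") {
      add(e$from, e$to, e$value, FALSE, TRUE) # tail at from, head at to
      add(e$to, e$from, e$value, TRUE, FALSE)
    } else {
      add(e$from, e$to, e$value, TRUE, TRUE)
      add(e$to, e$from, e$value, TRUE, TRUE)
    }
  }
  adj
}

# Internal: enumerate simple unblocked (collider-free) paths between a and b.
# Returns a list of paths; each path is a list of traversed-edge records with
# fields to/value/head_from/head_to plus the start node attribute.
unblocked_paths <- function(graph, a, b, max_paths = 1e5) {
  check_nodes(graph, c(a, b))
  adj <- mixed_adjacency(graph)
  paths <- list()
  count <- 0L
  walk <- function(node, visited, trail, prev_head) {
    for (e in adj[[node]]) {
      if (e$to %in% visited) next
      # collider at `node`: previous edge and this edge both point at it
      if (!is.null(prev_head) && prev_head && e$head_from) next
      new_trail <- c(trail, list(e))
      if (e$to == b) {
        count <<- count + 1L
        if (count > max_paths) {
          stop("more than ", max_paths, " unblocked paths; raise `max_paths`",
            call. = FALSE
          )
        }
        paths[[length(paths) + 1L]] <<- new_trail
      } else {
        walk(e$to, c(visited, e$to), new_trail, e$head_to)
      }
    }
  }
  walk(a, c(a, b_guard = character(0)), list(), NULL)
  attr(paths, "start") <- a
  paths
}

check_nodes <- function(graph, nodes) {
  bad <- setdiff(nodes, graph$nodes)
  if (length(bad) > 0) {
    stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Covariance between two variables by Wright's method of path coefficients
#'
#' Sums, over all unblocked (collider-free) simple paths connecting `a` and
#' `b`, the product of the edge parameters along each path. For standardized
#' variables (unit variances) this equals the model-implied covariance; for
#' unstandardized variables each term is additionally multiplied by the
#' variance of the path's root variable, supplied via `variances`.
#'
#' @param graph A [causal_graph()].
#' @param a,b Node labels.
#' @param variances Optional named vector of node variances for the
#'   unstandardized ("root variance") form of the rule. When `NULL` (default)
#'   variables are assumed standardized to unit variance.
#' @param max_paths Abort if more than this many unblocked paths are found.
#' @return The path-rule covariance (0 when `a` and `b` are d-separated;
#'   the variance of `a` when `a == b`).
#' @export
wright_path_sum <- function(graph, a, b, variances = NULL, max_paths = 1e5) {
  check_nodes(graph, c(a, b))
  if (a == b) {
    return(if (is.null(variances)) 1 else unname(variances[[a]]))
  }
  paths <- unblocked_paths(graph, a, b, max_paths = max_paths)
  if (length(paths) == 0) {
    return(0)
  }
  total <- 0
  for (p in paths) {
    term <- prod(vapply(p, function(e) e$value, numeric(1)))
    if (!is.null(variances)) {
      root <- path_root(p, a)
      if (!is.na(root)) term <- term * variances[[root]]
    }
    total <- total + term
  }
  total
}

# Root of an unblocked path: the unique node with no arrowhead pointing at it.
# A path whose "top" is a bidirected edge has no root (returns NA); its error
# covariance parameter already carries the scale.
path_root <- function(path, start) {
  nodes <- c(start, vapply(path, function(e) e$to, character(1)))
  n <- length(nodes)
  heads <- logical(n) # arrowhead at node i along the path?
  for (i in seq_along(path)) {
    if (path[[i]]$head_from) heads[i] <- TRUE
    if (path[[i]]$head_to) heads[i + 1] <- TRUE
  }
  root <- nodes[!heads]
  if (length(root) == 1) root else NA_character_
}

#' Test marginal d-separation of two nodes
#'
#' Two nodes are d-separated (with an empty conditioning set) when no
#' collider-free path connects them, which in a mixed acyclic graph is
#' equivalent to their ancestor sets being disjoint and not linked by any
#' bidirected edge.
#'
#' @inheritParams wright_path_sum
#' @return `TRUE` if `a` and `b` are d-separated, `FALSE` otherwise.
#' @export
d_separated <- function(graph, a, b) {
  check_nodes(graph, c(a, b))
  if (a == b) {
    return(FALSE)
  }
  anc_a <- ancestors(graph, a)
  anc_b <- ancestors(graph, b)
  if (length(intersect(anc_a, anc_b)) > 0) {
    return(FALSE)
  }
  be <- graph$edges[graph$edges$kind == "<->", ]
  if (nrow(be) > 0) {
    linked <- (be$from %in% anc_a & be$to %in% anc_b) |
      (be$from %in% anc_b & be$to %in% anc_a)
    if (any(linked)) {
      return(FALSE)
    }
  }
  TRUE
}

# Ancestors of a node (including itself) through directed edges.
ancestors <- function(graph, node) {
  de <- graph$edges[graph$edges$kind == "->", ]
  out <- node
  frontier <- node
  while (length(frontier) > 0) {
    parents <- unique(de$from[de$to %in% frontier])
    frontier <- setdiff(parents, out)
    out <- c(out, frontier)
  }
  out
}

# Descendants of a node (including itself) through directed edges.
descendants <- function(graph, node) {
  de <- graph$edges[graph$edges$kind == "->", ]
  out <- node
  frontier <- node
  while (length(frontier) > 0) {
    children <- unique(de$to[de$from %in% frontier])
    frontier <- setdiff(children, out)
    out <- c(out, frontier)
  }
  out
}

#' Verify the instrumental-set condition for a set of candidate instruments
#'
#' Checks whether the instruments `E` form an instrumental set relative to the
#' exposures `X` for outcome `y`: there must exist a pairing of instruments to
#' exposures with unblocked paths `p_i` from `E_i` to `y` whose final edge is
#' `X_i -> y`, such that (1) each `E_i` is a non-descendant of `y`, (2) each
#' `E_i` is d-separated from `y` in the graph with all `X_j -> y` edges
#' removed, and (3) for `j > i`, `E_j` does not lie on `p_i` and any variable
#' shared by `p_i` and `p_j` is a collider of the respective path segments.
#' When the condition holds, the direct effects of the exposures on `y` are
#' identifiable from the joint covariances.
#'
#' All orderings of the instruments are searched for `length(E) <= 6`
#' (condition 3 is order-dependent); beyond that a fixed-order greedy search
#' with backtracking over path choices is used.
#'
#' @param graph A [causal_graph()].
#' @param E Character vector of instrument node labels.
#' @param X Character vector of exposure node labels (same length as `E`).
#' @param y Outcome node label.
#' @param max_paths Cap on enumerated candidate paths per instrument.
#' @return An object of class `path_certificate` with elements `satisfied`
#'   (logical), `pairing` (tibble of instrument, exposure and path for each
#'   pair) when satisfied, and otherwise `reason` naming the first violated
#'   condition.
#' @export
check_instrumental_set <- function(graph, E, X, y, max_paths = 1e4) {
  check_nodes(graph, c(E, X, y))
  if (length(E) != length(X)) {
    stop("instrument set and exposure set must have equal size", call. = FALSE)
  }
  K <- length(E)

  # condition 1a: instruments are non-descendants of y
  desc_y <- descendants(graph, y)
  bad <- intersect(E, desc_y)
  if (length(bad) > 0) {
    return(refusal(1L, paste0(
      "instrument(s) ", paste(bad, collapse = ", "), " are descendants of ", y
    )))
  }

  # condition 2: d-separation from y after removing all X_j -> y edges
  gbar <- remove_edges(graph, from = X, to = y)
  sep_ok <- vapply(E, function(e) d_separated(gbar, e, y), logical(1))
  if (!all(sep_ok)) {
    return(refusal(2L, paste0(
      "instrument(s) ", paste(E[!sep_ok], collapse = ", "),
      " not d-separated from ", y, " after removing exposure->outcome edges"
    )))
  }

  # candidate paths: unblocked E_i ~ X_k paths (avoiding y) extended by X_k -> y
  has_edge <- function(xk) {
    any(graph$edges$kind == "->" & graph$edges$from == xk & graph$edges$to == y)
  }
  g_no_y <- remove_node(graph, y)
  candidates <- vector("list", K)
  for (i in seq_len(K)) {
    cand <- list()
    for (k in seq_len(K)) {
      if (!has_edge(X[k])) next
      if (E[i] == X[k]) next
      ps <- unblocked_paths(g_no_y, E[i], X[k], max_paths = max_paths)
      c_yk <- graph$edges$value[
        graph$edges$kind == "->" & graph$edges$from == X[k] & graph$edges$to == y
      ]
      for (p in ps) {
        # appending X_k -> y never creates a collider at X_k (tail at X_k),
        # so every unblocked E_i ~ X_k path extends to an unblocked path to y
        full <- c(p, list(list(
          to = y, value = c_yk, head_from = FALSE, head_to = TRUE
        )))
        cand[[length(cand) + 1L]] <- list(exposure = X[k], path = full)
      }
    }
    candidates[[i]] <- cand
  }
  if (any(vapply(candidates, length, integer(1)) == 0)) {
    idx <- which(vapply(candidates, length, integer(1)) == 0)[1]
    return(refusal(1L, paste0(
      "no unblocked path from ", E[idx], " to ", y,
      " ending in an exposure->outcome edge"
    )))
  }

  orderings <- if (K <= 6) {
    permutations(K)
  } else {
    list(seq_len(K))
  }
  for (ord in orderings) {
    res <- search_pairing(E, candidates, ord)
    if (!is.null(res)) {
      pairing <- tibble::tibble(
        instrument = E[ord],
        exposure = vapply(res, function(r) r$exposure, character(1)),
        path = vapply(seq_along(res), function(i) {
          format_path(res[[i]]$path, E[ord[i]])
        }, character(1))
      )
      if (anyDuplicated(pairing$exposure) == 0) {
        return(structure(
          list(satisfied = TRUE, pairing = pairing, reason = NULL),
          class = "path_certificate"
        ))
      }
    }
  }
  refusal(3L, "no instrument ordering and path choice satisfies condition 3")
}

refusal <- function(condition, message) {
  structure(
    list(satisfied = FALSE, pairing = NULL, condition = condition, reason = message),
    class = "path_certificate"
  )
}

#' @export
print.path_certificate <- function(x, ...) {
  if (x$satisfied) {
    cat("<path_certificate> instrumental set condition satisfied\n")
    print(x$pairing, ...)
  } else {
    cat(
      "<path_certificate> REFUSED (condition ", x$condition, "): ",
      x$reason, "\n",
      sep = ""
    )
  }
  invisible(x)
}

# Depth-first search for a condition-3-compatible assignment of candidate
# paths to the instruments taken in order `ord`; exposures must end distinct.
search_pairing <- function(E, candidates, ord) {
  K <- length(ord)
  chosen <- vector("list", K)
  dfs <- function(pos) {
    if (pos > K) {
      return(TRUE)
    }
    i <- ord[pos]
    for (cand in candidates[[i]]) {
      used <- vapply(
        chosen[seq_len(pos - 1L)],
        function(x) x$exposure, character(1)
      )
      if (cand$exposure %in% used) next
      ok <- TRUE
      for (q in seq_len(pos - 1L)) {
        if (!condition3_ok(
          chosen[[q]]$path, E[ord[q]],
          cand$path, E[i]
        )) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      chosen[[pos]] <<- cand
      if (dfs(pos + 1L)) {
        return(TRUE)
      }
      chosen[pos] <<- list(NULL)
    }
    FALSE
  }
  if (dfs(1L)) chosen else NULL
}

# Condition 3 for an earlier pair (p_i from E_i) and later pair (p_j from E_j):
# E_j must not appear on p_i, and for any shared variable V, the segment of
# p_i from V towards y and the segment of p_j from E_j up to V must both have
# an arrowhead at V.
condition3_ok <- function(p_i, e_i, p_j, e_j) {
  nodes_i <- c(e_i, vapply(p_i, function(e) e$to, character(1)))
  nodes_j <- c(e_j, vapply(p_j, function(e) e$to, character(1)))
  if (e_j %in% nodes_i) {
    return(FALSE)
  }
  y <- nodes_i[length(nodes_i)]
  shared <- setdiff(intersect(nodes_i, nodes_j), y)
  for (v in shared) {
    ii <- match(v, nodes_i)
    jj <- match(v, nodes_j)
    # arrowhead at v on p_i's edge leaving v towards y (edge ii in p_i list
    # connects nodes_i[ii] -> nodes_i[ii+1]); "points to V" means head at v.
    head_i <- if (ii <= length(p_i)) p_i[[ii]]$head_from else FALSE
    # arrowhead at v on p_j's edge arriving at v from the E_j side
    head_j <- if (jj >= 2) p_j[[jj - 1L]]$head_to else FALSE
    if (!(head_i && head_j)) {
      return(FALSE)
    }
  }
  TRUE
}

format_path <- function(path, start) {
  out <- start
  for (e in path) {
    arrow <- if (e$head_from && e$head_to) {
      "<->"
    } else if (e$head_to) {
      "->"
    } else {
      "<-"
    }
    out <- paste(out, arrow, e$to)
  }
  out
}

remove_edges <- function(graph, from, to) {
  keep <- !(graph$edges$kind == "->" &
    graph$edges$from %in% from &
    graph$edges$to %in% to)
  g <- graph
  g$edges <- graph$edges[keep, ]
  g
}

remove_node <- function(graph, node) {
  g <- graph
  g$nodes <- setdiff(graph$nodes, node)
  g$edges <- graph$edges[graph$edges$from != node & graph$edges$to != node, ]
  g
}

permutations <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  sub <- permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Identify causal effects from population covariances
#'
#' Solves the identification equation `Sigma_EX c = Sigma_EY` in the
#' least-squares sense, `c = (Sigma_EX' Sigma_EX)^-1 Sigma_EX' Sigma_EY`. When
#' the inputs are population covariances of a linear SEM in which the
#' instruments form an instrumental set for the exposures, the solution equals
#' the true direct effects exactly.
#'
#' @param sigma_EX L x K matrix of instrument-exposure covariances.
#' @param sigma_EY Length-L vector of instrument-outcome covariances.
#' @param tol Relative singular-value tolerance for the rank check.
#' @return Length-K vector of identified effects (named after the columns of
#'   `sigma_EX` when present).
#' @export
identify_effects <- function(sigma_EX, sigma_EY, tol = 1e-8) {
  sigma_EX <- as.matrix(sigma_EX)
  sigma_EY <- as.numeric(sigma_EY)
  if (nrow(sigma_EX) != length(sigma_EY)) {
    stop("sigma_EX and sigma_EY dimensions disagree", call. = FALSE)
  }
  K <- ncol(sigma_EX)
  sv <- svd(sigma_EX, nu = 0, nv = 0)$d
  if (sum(sv > tol * max(sv)) < K) {
    stop(
      "sigma_EX is rank-deficient (rank ", sum(sv > tol * max(sv)), " < ", K,
      "): the system is under-determined and the effects are not identifiable",
      call. = FALSE
    )
  }
  fit <- qr.solve(sigma_EX, sigma_EY)
  stats::setNames(as.numeric(fit), colnames(sigma_EX))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
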