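# Markov Cluster algorithm (MCL), implemented from scratch on sparse
# column-stochastic matrices. Flow is simulated by alternating expansion
# (matrix power) and inflation (entrywise power + column renormalization)
# until the matrix is (numerically) idempotent; clusters are read off the
# attractor rows of the limit matrix.

#' MCL parameters
#'
#' @param inflation Entrywise-power parameter controlling granularity
#'   (> 1; larger gives finer clusters). Default 2.
#' @param expansion Matrix-power parameter (integer >= 2). Default 2.
#' @param self_loop_weight Weight added on the diagonal before
#'   normalization; prevents period-2 oscillation on bipartite-like graphs.
#'   Either a non-negative number or `"max-degree"`, which gives every node
#'   a self-loop equal to its largest incident edge weight (making the
#'   clustering invariant to a uniform rescaling of the edge weights).
#'   Default 1.
#' @param prune_threshold Entries below this value are zeroed (then columns
#'   renormalized) to keep the matrix sparse. Default 1e-5.
#' @param max_iterations Iteration cap. Default 200.
#' @param convergence_tolerance Stop when the largest absolute entry change
#'   between successive iterations falls below this. Default 1e-8.
#' @return List of validated parameters.
#' @export
mcl_parameters <- function(inflation = 2, expansion = 2L,
                           self_loop_weight = 1, prune_threshold = 1e-5,
                           max_iterations = 200L,
                           convergence_tolerance = 1e-8) {
  if (is.character(self_loop_weight)) {
    self_loop_weight <- match.arg(self_loop_weight, "max-degree")
  } else {
    stopifnot(self_loop_weight >= 0)
  }
  stopifnot(inflation > 1, expansion >= 2,
            prune_threshold >= 0, max_iterations >= 1,
            convergence_tolerance > 0)
  list(inflation = inflation, expansion = as.integer(expansion),
       self_loop_weight = self_loop_weight,
       prune_threshold = prune_threshold,
       max_iterations = as.integer(max_iterations),
       convergence_tolerance = convergence_tolerance)
}

col_normalize <- function(m) {
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) stop("column with zero sum during normalization")
  m %*% Matrix::Diagonal(x = 1 / cs)
}

apply_colmax <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  vapply(seq_len(ncol(m)), function(j) {
    if (m@p[j + 1L] > m@p[j]) max(m@x[(m@p[j] + 1L):m@p[j + 1L]]) else 0
  }, 0)
}

prune_matrix <- function(m, threshold) {
  if (threshold <= 0) return(m)
  m <- methods::as(m, "CsparseMatrix")
  colmax <- vapply(seq_len(ncol(m)), function(j) {
    idx <- (m@p[j] + 1L):m@p[j + 1L]
    if (m@p[j + 1L] > m@p[j]) max(m@x[idx]) else 0
  }, 0)
  # never prune a column's largest entry, so no column can empty out
  x <- m@x
  j <- rep(seq_len(ncol(m)), diff(m@p))
  x[x < threshold & x < colmax[j]] <- 0
  m@x <- x
  Matrix::drop0(m)
}

#' Cluster a weighted network with MCL
#'
#' Runs the Markov Cluster algorithm on the integrated network and returns
#' a disjoint module set covering every network node. The computation is
#' deterministic: nodes are processed in lexicographic order and the limit
#' matrix is interpreted by [interpret_limit_matrix()].
#'
#' @param network An igraph with positive edge weights.
#' @param params Parameters from [mcl_parameters()].
#' @return A `module_set` whose modules partition the node set. Modules are
#'   labelled `M1, M2, ...` in lexicographic order of their smallest member.
#' @export
mcl_cluster <- function(network, params = mcl_parameters()) {
  stopifnot(inherits(network, "igraph"))
  n <- igraph::vcount(network)
  if (n == 0L) stop("cannot cluster an empty network")
  w <- igraph::E(network)$weight
  if (igraph::ecount(network) > 0L && (is.null(w) || any(w <= 0))) {
    stop("all edge weights must be positive")
  }
  nodes <- sort(igraph::V(network)$name, method = "radix")
  A <- igraph::as_adjacency_matrix(network, attr = if (is.null(w)) NULL else "weight",
                                   sparse = TRUE)
  A <- A[nodes, nodes, drop = FALSE]
  A <- methods::as(A, "dMatrix")
  mcl_core(A, nodes, params)
}

# the actual MCL iteration, on a symmetric sparse adjacency matrix whose
# dimnames order matches `nodes` (already lexicographic)
mcl_core <- function(A, nodes, params = mcl_parameters()) {
  loop <- params$self_loop_weight
  if (identical(loop, "max-degree")) {
    colmax <- apply_colmax(A)
    colmax[colmax == 0] <- 1  # isolated node: unit self-loop
    Matrix::diag(A) <- Matrix::diag(A) + colmax
  } else if (loop > 0) {
    Matrix::diag(A) <- Matrix::diag(A) + loop
  } else if (any(Matrix::colSums(A) == 0)) {
    stop("isolated node with no self-loop weight")
  }
  M <- methods::as(col_normalize(A), "CsparseMatrix")
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    Mprev <- M
    Mexp <- M
    for (e in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    Mexp <- methods::as(Mexp, "CsparseMatrix")
    Mexp@x <- Mexp@x^params$inflation
    M <- col_normalize(Mexp)
    M <- prune_matrix(M, params$prune_threshold)
    M <- col_normalize(M)
    M <- methods::as(M, "CsparseMatrix")
    # max |M - Mprev|; avoid a sparse subtraction when the patterns agree
    delta <- if (identical(M@p, Mprev@p) && identical(M@i, Mprev@i)) {
      if (length(M@x)) max(abs(M@x - Mprev@x)) else 0
    } else {
      max(abs(M - Mprev))
    }
    if (delta < params$convergence_tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iterations,
            " iterations; interpreting the current matrix")
  }
  interpret_limit_matrix(M, nodes)
}

#' Read clusters off an (approximately) idempotent MCL limit matrix
#'
#' Attractors are the rows with a positive diagonal entry. Attractors
#' supporting each other (positive mass between them) form an attractor
#' system; every node is assigned to the system from which it receives the
#' largest incoming mass, ties broken by lexicographically smallest cluster
#' label (a cluster is labelled by its smallest attractor). The result is a
#' disjoint partition of the node set.
#'
#' @param limit Column-stochastic matrix (dense or sparse).
#' @param nodes Character vector naming rows/columns, in matrix order.
#' @param stochastic_tolerance Maximum allowed deviation of a column sum
#'   from 1.
#' @return A `module_set` partitioning `nodes`.
#' @export
interpret_limit_matrix <- function(limit, nodes,
                                   stochastic_tolerance = 1e-6) {
  n <- length(nodes)
  stopifnot(nrow(limit) == n, ncol(limit) == n)
  cs <- Matrix::colSums(limit)
  if (any(abs(cs - 1) > stochastic_tolerance)) {
    stop("matrix is not column-stochastic (column sum off by ",
         fmt_double(max(abs(cs - 1))), ")")
  }
  L <- as.matrix(limit)
  diag_pos <- diag(L) > 1e-9
  attractors <- which(diag_pos)
  if (!length(attractors)) {
    # no diagonal mass at all (non-converged input): every node a singleton
    attractors <- seq_len(n)
  }
  # attractor systems: connected components of mutual support among
  # attractor rows/columns
  sub <- L[attractors, attractors, drop = FALSE]
  adj <- (sub > 1e-9) | (t(sub) > 1e-9)
  comp <- integer(length(attractors))
  cur <- 0L
  for (s in seq_along(attractors)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  # label each system by its lexicographically smallest attractor node
  sys_label <- vapply(seq_len(cur), function(cc) {
    min(nodes[attractors[comp == cc]])
  }, "")
  # incoming mass from each system to each node (rows of L are sources)
  mass <- matrix(0, nrow = cur, ncol = n)
  for (cc in seq_len(cur)) {
    rows <- attractors[comp == cc]
    mass[cc, ] <- colSums(L[rows, , drop = FALSE])
  }
  assign_sys <- integer(n)
  for (j in seq_len(n)) {
    mj <- mass[, j]
    pos <- which(mj > 1e-9)
    if (!length(pos)) {
      assign_sys[j] <- 0L  # orphan: becomes a singleton below
    } else {
      topm <- max(mj[pos])
      cand <- pos[mj[pos] >= topm - 1e-12]
      assign_sys[j] <- cand[order(sys_label[cand], method = "radix")[1L]]
    }
  }
  groups <- split(nodes, ifelse(assign_sys == 0L,
                                paste0("\rorphan\r", nodes),
                                sys_label[pmax(assign_sys, 1L)]))
  groups <- groups[order(vapply(groups, min, ""), method = "radix")]
  module_set(stats::setNames(lapply(groups, sort),
                             sprintf("M%d", seq_along(groups))),
             name = "mcl")
}
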