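# Naive Bayesian evidence combination: each dataset p carries one confidence
# score S_p in [0,1]; the integrated similarity of a protein pair is
#   1 - prod_p (1 - S_p)   over the datasets containing the pair.
# Fixed-role datasets contribute at S_p = 1, so their pairs always reach
# full confidence; pairs supported only by zero-weight datasets score 0 and
# are dropped from the network.

#' Combine per-dataset evidence for one protein pair
#'
#' Applies the naive Bayesian formula `1 - prod(1 - w)` to the effective
#' weights of the datasets containing the pair. The result is 0 for an empty
#' or all-zero list, 1 as soon as any weight is 1, and is invariant under
#' permutation of the weights.
#'
#' @param weights Numeric vector of effective dataset weights in `[0, 1]`,
#'   one per dataset containing the pair (possibly empty).
#' @return Combined similarity in `[0, 1]`.
#' @export
combine_pair_score <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) == 0L) return(0)
  if (anyNA(weights) || any(weights < 0 | weights > 1)) {
    stop("dataset weights must lie in [0, 1]")
  }
  1 - prod(1 - weights)
}

check_weight_vector <- function(datasets, weights) {
  roles <- vapply(datasets, `[[`, "", "role")
  free <- vapply(datasets, `[[`, "", "name")[roles == "free"]
  if (length(free)) {
    if (is.null(names(weights))) stop("weights must be a named vector")
    missing <- setdiff(free, names(weights))
    if (length(missing)) {
      stop("free dataset(s) missing from the weight vector: ",
           paste(missing, collapse = ", "))
    }
    w <- weights[free]
    if (anyNA(w) || any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  }
  free
}

# Precompute the pair-by-dataset incidence structure once; the returned
# closure rebuilds the integrated network for any weight vector. The fit
# loop calls this hundreds of times per run, so the per-call work is one
# sparse matrix-vector product.
weighted_network_builder <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, TRUE, "interaction_dataset")))
  names(datasets) <- vapply(datasets, `[[`, "", "name")
  roles <- vapply(datasets, `[[`, "", "role")
  keys_per_ds <- lapply(datasets, function(d) pair_keys(d$pairs))
  all_keys <- sort(unique(unlist(keys_per_ds, use.names = FALSE)))
  npair <- length(all_keys)
  k <- length(datasets)
  i <- unlist(lapply(keys_per_ds, function(kk) match(kk, all_keys)),
              use.names = FALSE)
  j <- rep(seq_len(k), lengths(keys_per_ds))
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(npair, k))
  ab <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  function(weights, as_graph = TRUE) {
    check_weight_vector(datasets, weights)
    eff <- ifelse(roles == "fixed", 1,
                  pmin(pmax(as.numeric(weights[names(datasets)]), 0), 1))
    empty <- function() {
      if (as_graph) igraph::make_empty_graph(0, directed = FALSE)
      else data.frame(a = character(), b = character(), weight = numeric())
    }
    if (npair == 0L) return(empty())
    # log1p(-1) = -Inf propagates through the sparse product (structural
    # zeros are skipped), so weight-1 datasets yield exactly 1.
    combined <- 1 - exp(as.numeric(inc %*% log1p(-eff)))
    keep <- combined > 0
    if (!any(keep)) return(empty())
    if (!as_graph) {
      return(data.frame(a = ab[keep, 1L], b = ab[keep, 2L],
                        weight = combined[keep], stringsAsFactors = FALSE))
    }
    igraph::graph_from_data_frame(
      data.frame(from = ab[keep, 1L], to = ab[keep, 2L],
                 weight = combined[keep], stringsAsFactors = FALSE),
      directed = FALSE
    )
  }
}

# sparse symmetric adjacency straight from an edge table; nodes sorted
# lexicographically to match mcl_core's contract
edges_to_adjacency <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)), method = "radix")
  i <- match(edges$a, nodes)
  j <- match(edges$b, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(edges$weight, 2L),
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  list(A = A, nodes = nodes)
}

#' Build the integrated weighted PPI network
#'
#' Combines a list of interaction datasets into a single undirected weighted
#' network. Fixed-role datasets contribute with effective weight 1; each
#' free dataset contributes with its entry of `weights`. Pairs whose
#' combined score is 0 are omitted, and the node set is the set of endpoints
#' of retained edges (proteins supported only by zero-weight datasets drop
#' out of the graph).
#'
#' @param datasets List of `interaction_dataset` objects.
#' @param weights Named numeric vector covering every free dataset.
#' @return An igraph with node names = protein identifiers and edge
#'   attribute `weight` in `(0, 1]`.
#' @export
build_weighted_network <- function(datasets, weights = numeric()) {
  weighted_network_builder(datasets)(weights)
}
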