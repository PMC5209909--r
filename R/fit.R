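# Outer optimization loop: weight vector -> integrated network -> MCL
# modules -> NMI against reference modules -> Harmony update. The free
# dataset weights are the optimization variables over [0,1]^k.

#' Objective: module similarity at a given weight vector
#'
#' Builds the integrated network at `weights`, clusters it with MCL and
#' scores the detected modules against the reference module set with NMI.
#' The score is evaluated over the union of the reference universe and the
#' network's node set, with uncovered members completed as singletons on
#' either side — so recruiting unannotated proteins into modules, or losing
#' reference proteins from the network, both move the objective (see the
#' methods vignette). An empty integrated network (all free weights 0 and
#' no fixed datasets) scores 0 with a warning.
#'
#' @param weights Named numeric vector over the free datasets.
#' @param datasets List of `interaction_dataset` objects.
#' @param reference Reference `module_set` (e.g. co-expression modules).
#' @param mcl_params Parameters from [mcl_parameters()].
#' @param nmi_variant `"partition"` (default) or `"overlap"`.
#' @return NMI in `[0, 1]`.
#' @export
ppi_objective <- function(weights, datasets, reference,
                          mcl_params = mcl_parameters(),
                          nmi_variant = c("partition", "overlap")) {
  nmi_variant <- match.arg(nmi_variant)
  net <- build_weighted_network(datasets, weights)
  score_network(net, reference, mcl_params, nmi_variant)
}

score_network <- function(net, reference, mcl_params, nmi_variant) {
  if (igraph::vcount(net) == 0L) {
    warning("integrated network is empty; objective is 0")
    return(0)
  }
  detected <- mcl_cluster(net, mcl_params)
  score_modules(detected, reference, nmi_variant)
}

# Objective universe: reference universe plus network nodes. Detected
# modules and reference modules are both completed with singletons over
# this union, so recruiting a non-reference protein into a module, or
# losing a reference protein from the network, both move the score.
score_modules <- function(detected, reference, nmi_variant) {
  if (!length(intersect(module_universe(detected),
                        module_universe(reference)))) {
    return(0)
  }
  universe <- sort(unique(c(module_universe(detected),
                            module_universe(reference))))
  if (nmi_variant == "overlap") {
    overlapping_nmi(detected, reference, universe = universe)
  } else {
    nmi(detected, reference, universe = universe)
  }
}

#' Fit dataset confidence weights by Harmony search
#'
#' Maximizes [ppi_objective()] over `[0, 1]^k`, where `k` is the number of
#' free datasets, then re-evaluates the best weights to produce the final
#' module set (so the returned modules are exactly recomputable from the
#' returned weights). Objective values are cached on the weight vector
#' rounded to 12 decimals; the objective is deterministic, so caching never
#' changes results.
#'
#' Additional reference module sets can be supplied for cross-evaluation:
#' the NMI of the best-so-far modules against each extra reference is
#' reported per iteration without ever feeding back into the optimization.
#'
#' @param datasets List of `interaction_dataset` objects; at least one must
#'   have role `"free"`.
#' @param reference Reference `module_set` driving the optimization.
#' @param hs_control Parameters from [harmony_control()].
#' @param mcl_params Parameters from [mcl_parameters()].
#' @param nmi_variant `"partition"` or `"overlap"`.
#' @param extra_references Optional named list of `module_set` objects for
#'   per-iteration cross-evaluation.
#' @return Object of class `ppi_fit`: `weights` (named, best), `best_nmi`,
#'   `modules` (final `module_set`), `trace`, `extra_nmi` (data frame,
#'   one column per extra reference, per iteration), `roles`, `hs` (the
#'   full `harmony_fit`, including the evaluated initial memory).
#' @export
fit_weights <- function(datasets, reference,
                        hs_control = harmony_control(),
                        mcl_params = mcl_parameters(),
                        nmi_variant = c("partition", "overlap"),
                        extra_references = list()) {
  nmi_variant <- match.arg(nmi_variant)
  stopifnot(all(vapply(datasets, inherits, TRUE, "interaction_dataset")))
  roles <- stats::setNames(vapply(datasets, `[[`, "", "role"),
                           vapply(datasets, `[[`, "", "name"))
  free <- names(roles)[roles == "free"]
  k <- length(free)
  if (k == 0L) stop("no free datasets: nothing to optimize")

  builder <- weighted_network_builder(datasets)
  cache <- new.env(parent = emptyenv())
  empty_warned <- FALSE
  cluster_at <- function(x) {
    edges <- builder(stats::setNames(x, free), as_graph = FALSE)
    if (nrow(edges) == 0L) return(NULL)
    adj <- edges_to_adjacency(edges)
    mcl_core(adj$A, adj$nodes, mcl_params)
  }
  objective <- function(x) {
    key <- paste(sprintf("%.12f", x), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    mods <- cluster_at(x)
    val <- if (is.null(mods)) {
      if (!empty_warned) {
        warning("integrated network is empty; objective is 0")
        empty_warned <<- TRUE
      }
      0
    } else {
      score_modules(mods, reference, nmi_variant)
    }
    cache[[key]] <- val
    val
  }

  hs <- harmony_search(objective, lower = rep(0, k), upper = rep(1, k),
                       control = hs_control)
  best <- stats::setNames(hs$best_par, free)
  final_net <- builder(best)
  final_modules <- if (igraph::vcount(final_net) > 0L) {
    mcl_cluster(final_net, mcl_params)
  } else {
    module_set(list(), name = "mcl")
  }

  extra_nmi <- NULL
  if (length(extra_references)) {
    if (is.null(names(extra_references))) {
      names(extra_references) <- paste0("ref", seq_along(extra_references))
    }
    bw <- as.matrix(hs$trace[, paste0("best_w_", seq_len(k)), drop = FALSE])
    keys <- apply(bw, 1L, function(x) paste(sprintf("%.12f", x), collapse = ","))
    uniq <- !duplicated(keys)
    per_key <- lapply(which(uniq), function(i) {
      mods <- cluster_at(bw[i, ])
      if (is.null(mods)) {
        return(stats::setNames(rep(0, length(extra_references)),
                               names(extra_references)))
      }
      vapply(extra_references, function(r) {
        score_modules(mods, r, nmi_variant)
      }, 0)
    })
    names(per_key) <- keys[uniq]
    vals <- do.call(rbind, per_key[keys])
    extra_nmi <- data.frame(iteration = hs$trace$iteration, vals,
                            row.names = NULL, check.names = FALSE)
  }

  structure(
    list(weights = best, best_nmi = hs$best_value, modules = final_modules,
         trace = hs$trace, extra_nmi = extra_nmi, roles = roles, hs = hs,
         mcl_params = mcl_params, nmi_variant = nmi_variant),
    class = "ppi_fit"
  )
}

#' @export
print.ppi_fit <- function(x, ...) {
  cat(sprintf("<ppi_fit> best NMI %.4f over %d iterations\n",
              x$best_nmi, nrow(x$trace)))
  cat("fitted weights:\n")
  for (nm in names(x$weights)) {
    cat(sprintf("  %-20s %.4f\n", nm, x$weights[[nm]]))
  }
  fixed <- names(x$roles)[x$roles == "fixed"]
  if (length(fixed)) {
    cat("fixed at 1:", paste(fixed, collapse = ", "), "\n")
  }
  cat(sprintf("final modules: %d (universe %d)\n",
              n_modules(x$modules), length(module_universe(x$modules))))
  invisible(x)
}
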