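# Downstream module analyses: hub/central proteins, co-expression overlay
# and empirical cutoff, module-to-complex mapping, and overlap reporting
# against an external interaction dataset.

#' Central (hub) proteins of one module
#'
#' A module member is central iff its within-module degree — the unweighted
#' number of neighbours inside the module's induced subgraph — is strictly
#' greater than twice the mean within-module degree over all module
#' members. Members absent from the network count with degree 0.
#'
#' @param members Character vector of module members (non-empty).
#' @param network The integrated igraph network.
#' @return Character vector of hub members (possibly empty), sorted.
#' @export
detect_central_proteins <- function(members, network) {
  deg <- module_degrees(members, network)
  threshold <- 2 * mean(deg)
  sort(names(deg)[deg > threshold])
}

module_degrees <- function(members, network) {
  stopifnot(length(members) >= 1L, inherits(network, "igraph"))
  members <- unique(as.character(members))
  present <- intersect(members, igraph::V(network)$name)
  deg <- stats::setNames(rep(0L, length(members)), members)
  if (length(present) >= 2L) {
    sub <- igraph::induced_subgraph(network, present)
    deg[igraph::V(sub)$name] <- igraph::degree(sub)
  }
  deg
}

#' Hub report over all modules
#'
#' @param modules A `module_set`.
#' @param network The integrated igraph network.
#' @return Data frame with one row per (module, member): `module`,
#'   `member`, `degree`, `mean_degree`, `threshold`, `is_hub`.
#' @export
hub_report <- function(modules, network) {
  stopifnot(inherits(modules, "module_set"))
  rows <- lapply(names(modules$modules), function(label) {
    deg <- module_degrees(modules$modules[[label]], network)
    data.frame(module = label, member = names(deg),
               degree = as.integer(deg),
               mean_degree = mean(deg), threshold = 2 * mean(deg),
               is_hub = deg > 2 * mean(deg),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Pairwise co-expression (Pearson correlation) for given gene pairs
#'
#' Correlations are computed over all conditions of the expression matrix.
#' Pairs with a gene missing from the matrix, or with a zero-variance
#' profile (undefined correlation), are reported as absent — not as 0 —
#' with a warning for the zero-variance case.
#'
#' @param expr Numeric matrix, genes in rows (rownames), conditions in
#'   columns; needs at least 3 conditions.
#' @param pairs Two-column character data frame (or matrix) of gene pairs.
#' @return Data frame `a`, `b`, `correlation` covering the computable
#'   pairs; the number of skipped pairs is attached as attribute
#'   `n_missing`.
#' @export
pairwise_coexpression <- function(expr, pairs) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3L) stop("need at least 3 conditions for correlation")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  present <- a %in% rownames(expr) & b %in% rownames(expr)
  sds <- apply(expr, 1L, stats::sd)
  flat_gene <- rownames(expr)[sds == 0]
  flat <- present & (a %in% flat_gene | b %in% flat_gene)
  if (any(flat)) {
    warning(sum(flat), " pair(s) involve a zero-variance profile; reported as absent")
  }
  ok <- present & !flat
  r <- vapply(which(ok), function(i) {
    stats::cor(expr[a[i], ], expr[b[i], ])
  }, 0)
  out <- data.frame(a = a[ok], b = b[ok], correlation = r,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_missing") <- sum(!ok)
  out
}

#' Empirical co-expression cutoff from co-complex pair correlations
#'
#' Returns the largest value `c` such that at least `exceed_fraction` of
#' the input correlations are `>= c`: the empirical
#' `(1 - exceed_fraction)`-quantile with the "lower" interpolation rule,
#' i.e. the `ceiling(exceed_fraction * n)`-th largest input. With this rule
#' the postcondition holds exactly on any finite sample.
#'
#' @param correlations Non-empty numeric vector (co-complex pair
#'   correlations).
#' @param exceed_fraction Required fraction in `(0, 1)`; default 0.70.
#' @return The cutoff value.
#' @export
coexpression_cutoff <- function(correlations, exceed_fraction = 0.70) {
  correlations <- as.numeric(correlations)
  if (!length(correlations)) stop("empty correlation list")
  stopifnot(exceed_fraction > 0, exceed_fraction < 1)
  k <- ceiling(exceed_fraction * length(correlations))
  sort(correlations, decreasing = TRUE)[k]
}

#' Within-module co-expressed pairs above a cutoff
#'
#' For each module, lists the within-module gene pairs whose Pearson
#' correlation is strictly greater than the cutoff (pairs missing from the
#' expression matrix are skipped). The output is an edge-attribute table
#' suitable for graph-visualization tools.
#'
#' @param modules A `module_set`.
#' @param expr Expression matrix (genes in rows).
#' @param cutoff Finite correlation cutoff, e.g. from
#'   [coexpression_cutoff()].
#' @return Data frame `node1`, `node2`, `module`, `correlation`.
#' @export
overlay_coexpression <- function(modules, expr, cutoff) {
  stopifnot(inherits(modules, "module_set"), is.finite(cutoff))
  rows <- lapply(names(modules$modules), function(label) {
    m <- sort(modules$modules[[label]])
    if (length(m) < 2L) return(NULL)
    idx <- utils::combn(length(m), 2L)
    pairs <- data.frame(a = m[idx[1L, ]], b = m[idx[2L, ]],
                        stringsAsFactors = FALSE)
    cc <- suppressWarnings(pairwise_coexpression(expr, pairs))
    cc <- cc[cc$correlation > cutoff, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    data.frame(node1 = cc$a, node2 = cc$b, module = label,
               correlation = cc$correlation,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(node1 = character(), node2 = character(),
                      module = character(), correlation = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Map reference complexes onto detected modules
#'
#' For each reference complex, reports the detected module containing the
#' plurality of its members (ties broken by the lexicographically smaller
#' module label), the coverage fraction (plurality count over complex
#' size), and how many modules the complex is split across.
#'
#' @param modules Detected `module_set` (disjoint).
#' @param complexes Reference complex catalogue (`module_set`).
#' @return Data frame `complex`, `size`, `best_module`, `coverage`,
#'   `n_modules_split`.
#' @export
map_modules_to_complexes <- function(modules, complexes) {
  stopifnot(inherits(modules, "module_set"), inherits(complexes, "module_set"))
  memb <- as_partition_membership(modules, module_universe(modules))
  rows <- lapply(names(complexes$modules), function(label) {
    members <- complexes$modules[[label]]
    hit <- memb[intersect(members, names(memb))]
    if (!length(hit)) {
      return(data.frame(complex = label, size = length(members),
                        best_module = NA_character_, coverage = 0,
                        n_modules_split = 0L, stringsAsFactors = FALSE))
    }
    counts <- table(hit)
    top <- max(counts)
    cand <- sort(names(counts)[counts == top], method = "radix")
    data.frame(complex = label, size = length(members),
               best_module = cand[1L], coverage = top / length(members),
               n_modules_split = length(counts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap report against an external interaction dataset
#'
#' Mirrors the usual validation of a newly published interaction set
#' against an integrated-network study. "Annotated" external pairs are
#' those whose both endpoints occur in the analysis universe (union of
#' used-dataset proteins and module members). Counts are cumulative:
#' (1) pairs found in any used dataset; (2) additionally pairs whose
#' endpoints share a detected module; (3) additionally pairs touching a
#' hub protein.
#'
#' @param external `interaction_dataset` to evaluate.
#' @param used List of `interaction_dataset` objects employed in the
#'   integration.
#' @param modules Detected `module_set`.
#' @param hubs Character vector of hub proteins (e.g. all hubs from
#'   [hub_report()]).
#' @param expr Optional expression matrix; if supplied, the mean pairwise
#'   co-expression of the annotated external pairs is reported.
#' @return List of class `overlap_report` with counts, cumulative counts
#'   and fractions.
#' @export
compare_external_dataset <- function(external, used, modules,
                                     hubs = character(), expr = NULL) {
  stopifnot(inherits(external, "interaction_dataset"),
            inherits(modules, "module_set"))
  universe <- sort(unique(c(
    unlist(lapply(used, dataset_proteins), use.names = FALSE),
    module_universe(modules)
  )))
  p <- external$pairs
  annotated <- p$a %in% universe & p$b %in% universe
  pa <- p[annotated, , drop = FALSE]
  n_annot <- nrow(pa)

  used_keys <- unique(unlist(lapply(used, function(d) pair_keys(d$pairs)),
                             use.names = FALSE))
  in_used <- pair_keys(pa) %in% used_keys

  memb <- as_partition_membership(modules, module_universe(modules))
  co_modular <- !is.na(memb[pa$a]) & !is.na(memb[pa$b]) &
    memb[pa$a] == memb[pa$b]
  co_modular[is.na(co_modular)] <- FALSE

  hub_touch <- pa$a %in% hubs | pa$b %in% hubs

  c1 <- sum(in_used)
  c2 <- sum(in_used | co_modular)
  c3 <- sum(in_used | co_modular | hub_touch)
  frac <- function(x) if (n_annot > 0L) x / n_annot else 0

  mean_coexpr <- NA_real_
  if (!is.null(expr) && n_annot > 0L) {
    cc <- suppressWarnings(pairwise_coexpression(expr, pa))
    if (nrow(cc)) mean_coexpr <- mean(cc$correlation)
  }

  structure(
    list(n_external = nrow(p), n_annotated = n_annot,
         n_in_datasets = c1, frac_in_datasets = frac(c1),
         n_plus_comodular = c2, frac_plus_comodular = frac(c2),
         n_plus_hub = c3, frac_plus_hub = frac(c3),
         mean_coexpression = mean_coexpr),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  cat(sprintf("  external pairs:            %d (%d annotated)\n",
              x$n_external, x$n_annotated))
  cat(sprintf("  in used datasets:          %d (%.1f%%)\n",
              x$n_in_datasets, 100 * x$frac_in_datasets))
  cat(sprintf("  ... or co-modular:         %d (%.1f%%)\n",
              x$n_plus_comodular, 100 * x$frac_plus_comodular))
  cat(sprintf("  ... or touching a hub:     %d (%.1f%%)\n",
              x$n_plus_hub, 100 * x$frac_plus_hub))
  if (!is.na(x$mean_coexpression)) {
    cat(sprintf("  mean co-expression:        %.4f\n", x$mean_coexpression))
  }
  invisible(x)
}
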