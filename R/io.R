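# On-disk formats: whitespace/TSV edge lists, GMT gene sets, expression TSV,
# weights TSV, optimization-trace TSV. All writers are atomic (temp file in
# the target directory, then rename) and every format round-trips through its
# matching reader.

# shortest decimal representation that reparses to the identical double
fmt_double <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- is.finite(x) & (as.numeric(s) != x)
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}

atomic_write <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("cannot write ", path)
  invisible(path)
}

#' Read a pairwise interaction dataset from an edge list
#'
#' The file is whitespace- or tab-delimited with at least two columns;
#' columns beyond the second are ignored. The result is order-normalized,
#' deduplicated and free of self-pairs (see [interaction_dataset()]).
#'
#' @param path Path to the edge-list file.
#' @param role Weight role for the dataset, `"free"` or `"fixed"`.
#' @param name Dataset name; defaults to the file name without extension.
#' @param quiet Suppress the normalization summary.
#' @return An `interaction_dataset`.
#' @export
read_edge_list <- function(path, role = c("free", "fixed"), name = NULL,
                           quiet = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  short <- which(lengths(fields) < 2L)
  if (length(short)) {
    stop(sprintf("line %d of %s has fewer than 2 fields",
                 which(keep)[short[1L]], path))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  interaction_dataset(name, a, b, role = role, quiet = quiet)
}

#' Write an interaction dataset as a two-column edge list
#' @param x An `interaction_dataset`.
#' @param path Output path.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "interaction_dataset"))
  atomic_write(paste(x$pairs$a, x$pairs$b, sep = "\t"), path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>member...` with at least one
#' member. Duplicate members within a line are collapsed; duplicate set
#' labels are an error. Descriptions are preserved as an attribute but
#' otherwise unused.
#'
#' @param path Path to the GMT file.
#' @param name Name for the resulting collection.
#' @return A `module_set`.
#' @export
read_gene_sets <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("line %d of %s has fewer than 3 fields (GMT needs name, description, >=1 member)",
                 short[1L], path))
  }
  labels <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(labels)) {
    stop("duplicate module label in ", path, ": ",
         labels[duplicated(labels)][1L])
  }
  descr <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  ms <- module_set(stats::setNames(members, labels), name = name)
  attr(ms, "descriptions") <- stats::setNames(descr, labels)
  ms
}

#' Write a module set in GMT format
#' @param x A `module_set`.
#' @param path Output path.
#' @param descriptions Optional named character vector of per-module
#'   descriptions; defaults to `"na"`.
#' @export
write_gene_sets <- function(x, path, descriptions = NULL) {
  stopifnot(inherits(x, "module_set"))
  labels <- names(x$modules)
  if (is.null(descriptions)) {
    descriptions <- attr(x, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(labels)), labels)
  }
  lines <- vapply(labels, function(l) {
    paste(c(l, descriptions[[l]], x$modules[[l]]), collapse = "\t")
  }, "")
  atomic_write(lines, path)
}

#' Write a weighted PPI network as a three-column TSV
#'
#' Columns are `protein_a`, `protein_b`, `weight` with `protein_a <
#' protein_b`; weights are printed with enough digits to round-trip
#' losslessly through [read_weighted_network()].
#'
#' @param network An igraph with a `weight` edge attribute (see
#'   [build_weighted_network()]).
#' @param path Output path.
#' @param header Emit a header line for empty networks too (default TRUE).
#' @export
write_weighted_network <- function(network, path, header = TRUE) {
  stopifnot(inherits(network, "igraph"))
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  a <- el[, 1L]; b <- el[, 2L]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b, method = "radix")
  body <- if (length(w)) paste(a[ord], b[ord], fmt_double(w[ord]), sep = "\t") else character()
  lines <- if (header) c("protein_a\tprotein_b\tweight", body) else body
  atomic_write(lines, path)
}

#' Read a weighted network written by [write_weighted_network()]
#' @param path Path to the three-column TSV.
#' @return An igraph with edge attribute `weight`.
#' @export
read_weighted_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], "protein_a\t")) {
    lines <- lines[-1L]
  }
  if (!length(lines)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) stop("malformed network file: ", path)
  df <- data.frame(
    from = vapply(fields, `[[`, "", 1L),
    to = vapply(fields, `[[`, "", 2L),
    weight = as.numeric(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Read an expression matrix
#'
#' Expects a TSV whose first column holds gene identifiers and whose header
#' row names the conditions. Gene identifiers must be unique.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, genes in rows, conditions in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus >=1 condition")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix with gene rownames and condition colnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  header <- paste(c("gene", colnames(expr)), collapse = "\t")
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], fmt_double(expr[i, ])), collapse = "\t")
  }, "")
  atomic_write(c(header, body), path)
}

#' Write per-dataset confidence weights
#'
#' Three-column TSV: `dataset`, `weight`, `role`. Fixed-role datasets are
#' written with weight 1.
#'
#' @param weights Named numeric vector of free-dataset weights.
#' @param roles Named character vector mapping every dataset to its role.
#' @param path Output path.
#' @export
write_weights <- function(weights, roles, path) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  nm <- names(roles)
  w <- ifelse(roles == "fixed", 1, weights[nm])
  lines <- c("dataset\tweight\trole",
             paste(nm, fmt_double(unname(w)), roles, sep = "\t"))
  atomic_write(lines, path)
}

#' Read a weights file written by [write_weights()]
#' @param path Path to the weights TSV.
#' @return List with `weights` (named numeric, free datasets only) and
#'   `roles` (named character, all datasets).
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("dataset", "weight", "role") %in% names(df)))
  roles <- stats::setNames(df$role, df$dataset)
  free <- df$role == "free"
  list(weights = stats::setNames(df$weight[free], df$dataset[free]),
       roles = roles)
}

#' Write an optimization trace as TSV
#'
#' One row per iteration: `iteration`, `candidate_value`, `best_value`,
#' the candidate vector `w_1..w_k` and the best-so-far vector
#' `best_w_1..best_w_k`.
#'
#' @param trace Data frame as produced by [harmony_search()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  header <- paste(names(trace), collapse = "\t")
  cols <- lapply(trace, function(col) {
    if (is.double(col)) fmt_double(col) else as.character(col)
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  atomic_write(c(header, body), path)
}

#' Read an optimization trace written by [write_trace()]
#' @param path Path to the trace TSV.
#' @return Data frame with the original column types.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if ("iteration" %in% names(df)) df$iteration <- as.integer(df$iteration)
  df
}
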