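#' Construct an interaction dataset
#'
#' An interaction dataset is a named collection of unordered protein pairs
#' together with a weight role. Datasets with role `"free"` receive an
#' optimizable confidence score in `[0, 1]`; datasets with role `"fixed"`
#' (curated interactions, co-complex pair expansions) always contribute at
#' full confidence 1 to the integrated network.
#'
#' Pairs are normalized on construction: self-pairs are dropped, each pair is
#' stored as `(a, b)` with `a < b` lexicographically, and duplicates collapse
#' to a single pair. Rows are sorted so that two datasets with the same pairs
#' compare equal.
#'
#' @param name Dataset identifier (single string).
#' @param a,b Character vectors of equal length: the two interaction partners.
#' @param role `"free"` or `"fixed"`.
#' @param quiet Suppress the normalization summary message.
#' @return An object of class `interaction_dataset` with elements `name`,
#'   `pairs` (two-column character data frame `a`, `b`), and `role`.
#' @export
interaction_dataset <- function(name, a = character(), b = character(),
                                role = c("free", "fixed"), quiet = FALSE) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same length")
  }
  n_raw <- length(a)
  self <- a == b
  a2 <- a[!self]
  b2 <- b[!self]
  swap <- a2 > b2
  tmp <- a2[swap]
  a2[swap] <- b2[swap]
  b2[swap] <- tmp
  key <- paste(a2, b2, sep = "\r")
  dup <- duplicated(key)
  a2 <- a2[!dup]
  b2 <- b2[!dup]
  ord <- order(a2, b2, method = "radix")
  pairs <- data.frame(a = a2[ord], b = b2[ord], stringsAsFactors = FALSE)
  if (!quiet && n_raw > 0L) {
    message(sprintf(
      "dataset '%s': %d raw pairs, %d self-pairs dropped, %d duplicates collapsed, %d kept",
      name, n_raw, sum(self), sum(dup), nrow(pairs)
    ))
  }
  structure(
    list(name = name, pairs = pairs, role = role),
    class = "interaction_dataset"
  )
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(
    "<interaction_dataset '%s'> %d pairs, %d proteins, role=%s\n",
    x$name, nrow(x$pairs), length(dataset_proteins(x)), x$role
  ))
  invisible(x)
}

#' Proteins appearing in an interaction dataset
#' @param x An `interaction_dataset`.
#' @return Sorted character vector of distinct protein identifiers.
#' @export
dataset_proteins <- function(x) {
  stopifnot(inherits(x, "interaction_dataset"))
  sort(unique(c(x$pairs$a, x$pairs$b)))
}

pair_keys <- function(pairs) paste(pairs$a, pairs$b, sep = "\r")

#' Construct a module set
#'
#' A module set is an ordered, labelled collection of protein/gene sets:
#' either a clustering result (disjoint modules) or a reference catalogue
#' (co-expression modules, complexes), which may overlap.
#'
#' @param modules Named list of character vectors. Labels must be unique and
#'   every module must have at least one member; duplicate members within a
#'   module are collapsed.
#' @param name Name for the collection.
#' @return An object of class `module_set`.
#' @export
module_set <- function(modules, name = "modules") {
  stopifnot(is.list(modules))
  labels <- names(modules)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("every module must have a non-empty label")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate module label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  modules <- lapply(modules, function(m) {
    m <- as.character(m)
    m[!duplicated(m)]
  })
  if (any(lengths(modules) == 0L)) {
    stop("every module must have at least one member")
  }
  structure(list(name = name, modules = modules), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sz <- lengths(x$modules)
  cat(sprintf(
    "<module_set '%s'> %d modules, %d members in universe (sizes %s..%s)\n",
    x$name, length(x$modules), length(module_universe(x)),
    if (length(sz)) min(sz) else 0, if (length(sz)) max(sz) else 0
  ))
  invisible(x)
}

#' Universe of a module set
#' @param x A `module_set`.
#' @return Sorted character vector: the union of all module members.
#' @export
module_universe <- function(x) {
  stopifnot(inherits(x, "module_set"))
  sort(unique(unlist(x$modules, use.names = FALSE)))
}

#' Number of modules in a module set
#' @param x A `module_set`.
#' @export
n_modules <- function(x) length(x$modules)
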