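# Normalized Mutual Information between module sets.
#
# Two variants:
#  * partition NMI, 2 I(A;B) / (H(A) + H(B)) with natural-log entropies from
#    the contingency table — the default, appropriate for MCL output;
#  * cover NMI (normalized variation of information) for module sets that
#    may overlap, computed module-by-module from binary membership
#    indicators.
# Both are preceded by restriction to the common universe; members a set
# leaves uncovered become singletons, and (under the partition variant)
# members listed in several reference modules are assigned to the
# first-listed one.

#' Restrict two module sets to their common universe
#'
#' Both sets are intersected with the shared member universe; modules that
#' empty out are dropped.
#'
#' @param a,b `module_set` objects.
#' @return List with the restricted sets (`a`, `b`) and the common
#'   `universe` (sorted character vector).
#' @export
restrict_to_common_universe <- function(a, b) {
  stopifnot(inherits(a, "module_set"), inherits(b, "module_set"))
  universe <- intersect(module_universe(a), module_universe(b))
  if (!length(universe)) stop("module sets share no members")
  restrict <- function(ms) {
    mods <- lapply(ms$modules, intersect, universe)
    mods <- mods[lengths(mods) > 0L]
    module_set(mods, name = ms$name)
  }
  list(a = restrict(a), b = restrict(b), universe = sort(universe))
}

# Membership vector of a module set over a universe (partition semantics):
# members in several modules go to the first-listed module, uncovered
# members become fresh singleton labels.
as_partition_membership <- function(ms, universe, quiet = TRUE) {
  memb <- stats::setNames(rep(NA_character_, length(universe)), universe)
  reassigned <- 0L
  for (label in names(ms$modules)) {
    hit <- intersect(ms$modules[[label]], universe)
    new <- hit[is.na(memb[hit])]
    reassigned <- reassigned + (length(hit) - length(new))
    memb[new] <- label
  }
  if (!quiet && reassigned > 0L) {
    message(reassigned, " overlapping members assigned to their first-listed module")
  }
  uncovered <- is.na(memb)
  if (any(uncovered)) {
    memb[uncovered] <- paste0("\rsingleton\r", universe[uncovered])
  }
  memb
}

#' Partition NMI between two module sets
#'
#' Computes `2 I(A;B) / (H(A) + H(B))` over the given universe (by default
#' the common universe of the two sets), with natural-log entropies. The
#' value is 1 for identical partitions (up to relabelling) and 0 when one
#' side is the trivial single-module partition; when both sides are
#' single-module (total entropy 0) the partitions are identical and the
#' value is defined as 1.
#'
#' @param a,b `module_set` objects. Overlapping modules are resolved to a
#'   partition (first-listed module wins); uncovered members of the
#'   universe become singletons.
#' @param universe Optional explicit universe; default: common universe.
#' @param quiet Suppress the overlap-resolution message.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b, universe = NULL, quiet = TRUE) {
  if (is.null(universe)) {
    r <- restrict_to_common_universe(a, b)
    a <- r$a; b <- r$b; universe <- r$universe
  }
  if (!length(universe)) stop("empty universe")
  pa <- as_partition_membership(a, universe, quiet = quiet)
  pb <- as_partition_membership(b, universe, quiet = quiet)
  N <- length(universe)
  tab <- table(pa, pb)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  Ha <- -sum((ai / N) * log(ai / N))
  Hb <- -sum((bj / N) * log(bj / N))
  if (Ha + Hb == 0) return(1)  # both trivial single-module: identical
  nz <- tab > 0
  nij <- tab[nz]
  outer_ab <- outer(ai, bj)[nz]
  I <- sum((nij / N) * log(nij * N / outer_ab))
  val <- 2 * I / (Ha + Hb)
  min(max(val, 0), 1)
}

# -p log p with 0 log 0 := 0 (natural log)
h_term <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- -p[pos] * log(p[pos])
  out
}

#' Cover NMI between two (possibly overlapping) module sets
#'
#' Normalized-variation-of-information NMI for covers: each module is a
#' binary membership indicator over the universe; the conditional entropy
#' of a module given the best-matching module on the other side is averaged
#' after normalization, and the result is `1 - (H(A|B)_norm + H(B|A)_norm)/2`.
#' Identical covers score 1; duplicated modules carry no information and do
#' not change the value. For two partitions the value is consistent with,
#' but not numerically forced to equal, [nmi()].
#'
#' @param a,b `module_set` objects (modules may overlap).
#' @param universe Optional explicit universe; default: common universe.
#' @return Value in `[0, 1]`.
#' @export
overlapping_nmi <- function(a, b, universe = NULL) {
  if (is.null(universe)) {
    r <- restrict_to_common_universe(a, b)
    a <- r$a; b <- r$b; universe <- r$universe
  }
  if (!length(universe)) stop("empty universe")
  N <- length(universe)
  ind <- function(ms) {
    vapply(ms$modules, function(m) universe %in% m, logical(N))
  }
  A <- ind(a)  # N x ka logical
  B <- ind(b)
  cond_norm <- function(X, Y) {
    kx <- ncol(X); ky <- ncol(Y)
    terms <- numeric(kx)
    for (k in seq_len(kx)) {
      x <- X[, k]
      px1 <- mean(x)
      Hx <- sum(h_term(c(px1, 1 - px1)))
      if (Hx == 0) { terms[k] <- 0; next }
      best <- Hx
      for (l in seq_len(ky)) {
        y <- Y[, l]
        d <- sum(x & y) / N     # both
        c_ <- sum(x & !y) / N   # only x
        b_ <- sum(!x & y) / N   # only y
        a_ <- 1 - d - c_ - b_   # neither
        # reject complementary-looking matches (standard cover-NMI guard)
        if (h_term(d) + h_term(a_) < h_term(b_) + h_term(c_)) next
        Hxy <- h_term(a_) + h_term(b_) + h_term(c_) + h_term(d)
        Hy <- sum(h_term(c(b_ + d, a_ + c_)))
        best <- min(best, Hxy - Hy)
      }
      terms[k] <- best / Hx
    }
    mean(terms)
  }
  val <- 1 - (cond_norm(A, B) + cond_norm(B, A)) / 2
  min(max(val, 0), 1)
}
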