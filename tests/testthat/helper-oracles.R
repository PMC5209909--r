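# Independent oracles, written before (and kept independent of) the
# implementation paths they check. Everything here is dense base-R code
# with no shortcuts through the package internals.

# --- naive Bayes combination, literal product loop ------------------------
oracle_combine <- function(weights) {
  acc <- 1
  for (w in weights) acc <- acc * (1 - w)
  1 - acc
}

# --- dense MCL oracle: normalize -> expand -> inflate until idempotent ----
# adj: dense symmetric matrix with dimnames; returns canonical partition
# (list of sorted member vectors, sorted by first member).
oracle_mcl <- function(adj, inflation = 2, expansion = 2, self_loop = 1,
                       max_iter = 1000, tol = 1e-12) {
  nodes <- rownames(adj)
  ord <- order(nodes)
  adj <- adj[ord, ord, drop = FALSE]
  nodes <- nodes[ord]
  diag(adj) <- diag(adj) + self_loop
  M <- sweep(adj, 2, colSums(adj), "/")
  for (it in seq_len(max_iter)) {
    Mp <- M
    Me <- M
    for (e in seq_len(expansion - 1)) Me <- Me %*% M
    Me <- Me^inflation
    M <- sweep(Me, 2, colSums(Me), "/")
    if (max(abs(M - Mp)) < tol) break
  }
  oracle_interpret(M, nodes)
}

# attractor interpretation: same stated policy (largest incoming mass,
# ties to the lexicographically smallest system label), independent code
oracle_interpret <- function(L, nodes) {
  n <- length(nodes)
  att <- which(diag(L) > 1e-9)
  if (!length(att)) att <- seq_len(n)
  # attractor systems by repeated label propagation on mutual support
  sys <- seq_along(att)
  repeat {
    changed <- FALSE
    for (i in seq_along(att)) {
      for (j in seq_along(att)) {
        linked <- L[att[i], att[j]] > 1e-9 || L[att[j], att[i]] > 1e-9
        if (linked && sys[j] != sys[i]) {
          s <- min(sys[i], sys[j])
          sys[sys == sys[i] | sys == sys[j]] <- s
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sys_ids <- unique(sys)
  labels <- vapply(sys_ids, function(s) min(nodes[att[sys == s]]), "")
  assign <- character(n)
  for (j in seq_len(n)) {
    mass <- vapply(sys_ids, function(s) sum(L[att[sys == s], j]), 0)
    pos <- which(mass > 1e-9)
    if (!length(pos)) {
      assign[j] <- nodes[j]  # orphan singleton
    } else {
      top <- max(mass[pos])
      cand <- pos[mass[pos] >= top - 1e-12]
      assign[j] <- labels[cand[order(labels[cand])[1L]]]
    }
  }
  canon_partition(split(nodes, assign))
}

# canonical form for comparing partitions/module sets
canon_partition <- function(groups) {
  groups <- lapply(groups, function(g) sort(unname(g)))
  groups <- groups[order(vapply(groups, `[[`, "", 1L))]
  unname(groups)
}

canon_modules <- function(ms) canon_partition(ms$modules)

# --- partition NMI from explicit membership vectors -----------------------
# written from the contingency-table definition, natural logs
oracle_nmi <- function(memb_a, memb_b) {
  stopifnot(length(memb_a) == length(memb_b))
  N <- length(memb_a)
  la <- unique(memb_a); lb <- unique(memb_b)
  nij <- matrix(0, length(la), length(lb))
  for (i in seq_len(N)) {
    nij[match(memb_a[i], la), match(memb_b[i], lb)] <-
      nij[match(memb_a[i], la), match(memb_b[i], lb)] + 1
  }
  ai <- rowSums(nij); bj <- colSums(nij)
  Ha <- 0; for (x in ai) if (x > 0) Ha <- Ha - (x / N) * log(x / N)
  Hb <- 0; for (x in bj) if (x > 0) Hb <- Hb - (x / N) * log(x / N)
  if (Ha + Hb == 0) return(1)
  I <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      if (nij[i, j] > 0) {
        I <- I + (nij[i, j] / N) * log(nij[i, j] * N / (ai[i] * bj[j]))
      }
    }
  }
  2 * I / (Ha + Hb)
}

# --- cover NMI (normalized variation of information), term by term --------
oracle_cover_nmi <- function(mods_a, mods_b, universe) {
  N <- length(universe)
  h <- function(p) if (p > 0) -p * log(p) else 0
  side <- function(A, B) {
    terms <- numeric(length(A))
    for (k in seq_along(A)) {
      x <- universe %in% A[[k]]
      p1 <- sum(x) / N
      Hx <- h(p1) + h(1 - p1)
      if (Hx == 0) { terms[k] <- 0; next }
      best <- Hx
      for (l in seq_along(B)) {
        y <- universe %in% B[[l]]
        d <- sum(x & y) / N
        conly <- sum(x & !y) / N
        bonly <- sum(!x & y) / N
        aa <- 1 - d - conly - bonly
        if (h(d) + h(aa) < h(bonly) + h(conly)) next
        Hxy <- h(aa) + h(bonly) + h(conly) + h(d)
        Hy <- h(bonly + d) + h(aa + conly)
        if (Hxy - Hy < best) best <- Hxy - Hy
      }
      terms[k] <- best / Hx
    }
    mean(terms)
  }
  1 - (side(mods_a, mods_b) + side(mods_b, mods_a)) / 2
}

# --- shared fixture builders ----------------------------------------------
make_network <- function(a, b, w = 1) {
  igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE),
    directed = FALSE
  )
}

clique_edges <- function(members) {
  idx <- utils::combn(length(members), 2L)
  list(a = members[idx[1L, ]], b = members[idx[2L, ]])
}

# random weighted graph as both igraph and dense adjacency
random_weighted_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(idx)) < p_edge
  if (!any(keep)) keep[sample(ncol(idx), 1L)] <- TRUE
  a <- nodes[idx[1L, keep]]
  b <- nodes[idx[2L, keep]]
  w <- stats::runif(sum(keep), 0.1, 1)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(a)) {
    adj[a[i], b[i]] <- w[i]
    adj[b[i], a[i]] <- w[i]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes
  )
  list(graph = g, adj = adj, nodes = nodes)
}

# membership vector of a (partition) module set over a universe
membership_of <- function(ms, universe) {
  memb <- rep(NA_integer_, length(universe))
  for (i in seq_along(ms$modules)) {
    memb[universe %in% ms$modules[[i]]] <- i
  }
  memb
}

# random partition of a universe into at most k blocks
random_partition <- function(universe, k, seed) {
  set.seed(seed)
  memb <- sample(seq_len(k), length(universe), replace = TRUE)
  groups <- split(universe, memb)
  module_set(stats::setNames(groups, sprintf("B%d", seq_along(groups))))
}
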