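# Synthetic planted-complex benchmark. The generator states a small world
# with the statistical structure the integration method assumes: proteins
# grouped into ground-truth complexes, interaction datasets that detect
# within-complex pairs at a true-positive rate and add background edges at
# a false-positive rate, expression profiles with elevated within-complex
# correlation, and a reference module set that is a perturbed copy of the
# truth (so a perfect fit cannot reach NMI 1, as with real functional
# modules).

#' Specify a synthetic benchmark
#'
#' Defaults describe the standard recovery scenario: 200 proteins, 20
#' planted complexes of size 5-10, three informative datasets (within-
#' complex detection probability `tp = 0.8`, background false-edge
#' probability `fp = 0.005`) and two pure-noise datasets (`tp = fp =
#' 0.01`), an expression compendium of 200 conditions with latent-factor
#' loading `rho = 0.8` (expected within-complex pairwise correlation
#' `rho^2 = 0.64`), and a reference module set perturbed from the truth at
#' member-swap rate 0.1.
#'
#' @param n_proteins Total number of proteins.
#' @param n_complexes Number of planted complexes.
#' @param size_range Length-2 integer vector: complex size bounds.
#' @param datasets Data frame with columns `name`, `tp`, `fp`, `role`
#'   describing each generated dataset. Datasets with `tp > fp` are
#'   informative; `tp == fp` is noise by definition.
#' @param n_conditions Number of expression conditions.
#' @param rho Latent-factor loading in `[0, 1)`; member profiles are
#'   `rho * latent + sqrt(1 - rho^2) * noise`, so the expected
#'   within-complex pairwise correlation is exactly `rho^2`.
#' @param swap_rate Member-swap rate for the reference module set.
#' @param overlap Fraction of complexes (beyond the first) that share one
#'   member with a previously drawn complex.
#' @param seed Optional integer seed; the whole benchmark is reproducible
#'   from (spec, seed).
#' @return List of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_proteins = 200L, n_complexes = 20L,
                           size_range = c(5L, 10L),
                           datasets = default_benchmark_datasets(),
                           n_conditions = 200L, rho = 0.8,
                           swap_rate = 0.1, overlap = 0,
                           seed = NULL) {
  stopifnot(n_proteins >= 2, n_complexes >= 1, length(size_range) == 2L,
            size_range[1L] >= 2, size_range[2L] >= size_range[1L],
            is.data.frame(datasets),
            all(c("name", "tp", "fp", "role") %in% names(datasets)),
            all(datasets$tp >= 0 & datasets$tp <= 1),
            all(datasets$fp >= 0 & datasets$fp <= 1),
            all(datasets$role %in% c("free", "fixed")),
            n_conditions >= 3, rho >= 0, rho < 1,
            swap_rate >= 0, swap_rate < 1, overlap >= 0, overlap <= 1)
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_complexes = as.integer(n_complexes),
         size_range = as.integer(size_range),
         datasets = datasets, n_conditions = as.integer(n_conditions),
         rho = rho, swap_rate = swap_rate, overlap = overlap, seed = seed),
    class = "benchmark_spec"
  )
}

#' Default dataset roster for the synthetic benchmark
#' @return Data frame with three informative and two noise datasets, all
#'   free.
#' @export
default_benchmark_datasets <- function() {
  data.frame(
    name = c("apms_a", "apms_b", "ortho", "dbnoise_a", "dbnoise_b"),
    tp = c(0.8, 0.8, 0.8, 0.01, 0.01),
    fp = c(0.005, 0.005, 0.005, 0.01, 0.01),
    role = "free",
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic benchmark
#'
#' Samples planted complexes, per-dataset noisy edge lists, an expression
#' matrix with elevated within-complex correlation, and a perturbed
#' reference module set. Fully reproducible from the spec's seed.
#'
#' @param spec A [benchmark_spec()].
#' @return List with elements `datasets` (list of `interaction_dataset`),
#'   `truth` (planted complexes as a `module_set`), `reference` (perturbed
#'   truth), `expression` (matrix), `true_pairs` (data frame `a`, `b`),
#'   `labels` (data frame: dataset name, role, tp, fp, informative flag),
#'   and `proteins`.
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_proteins
  proteins <- sprintf("P%0*d", nchar(n), seq_len(n))

  sizes <- sample(seq(spec$size_range[1L], spec$size_range[2L]),
                  spec$n_complexes, replace = TRUE)
  if (sum(sizes) > n && spec$overlap == 0) {
    stop("infeasible spec: complex sizes sum to ", sum(sizes),
         " > ", n, " proteins with no overlap")
  }
  pool <- sample(proteins)
  complexes <- vector("list", spec$n_complexes)
  used <- 0L
  for (i in seq_len(spec$n_complexes)) {
    take <- sizes[i]
    members <- pool[used + seq_len(take)]
    used <- used + take
    if (i > 1L && spec$overlap > 0 && stats::runif(1) < spec$overlap) {
      donor <- unlist(complexes[seq_len(i - 1L)], use.names = FALSE)
      members[1L] <- sample(donor, 1L)
      members <- unique(members)
    }
    complexes[[i]] <- members
  }
  names(complexes) <- sprintf("C%0*d", nchar(spec$n_complexes),
                              seq_len(spec$n_complexes))
  truth <- module_set(complexes, name = "truth")

  within_pairs <- function(members) {
    m <- sort(members)
    idx <- utils::combn(length(m), 2L)
    data.frame(a = m[idx[1L, ]], b = m[idx[2L, ]], stringsAsFactors = FALSE)
  }
  tp_df <- unique(do.call(rbind, lapply(complexes, within_pairs)))
  tp_df <- tp_df[order(tp_df$a, tp_df$b, method = "radix"), , drop = FALSE]
  rownames(tp_df) <- NULL
  tp_keys <- pair_keys(tp_df)

  all_idx <- utils::combn(n, 2L)
  all_df <- data.frame(a = proteins[all_idx[1L, ]],
                       b = proteins[all_idx[2L, ]],
                       stringsAsFactors = FALSE)
  is_true <- pair_keys(all_df) %in% tp_keys

  ds <- lapply(seq_len(nrow(spec$datasets)), function(i) {
    row <- spec$datasets[i, ]
    take_true <- stats::runif(sum(is_true)) < row$tp
    take_bg <- stats::runif(sum(!is_true)) < row$fp
    sel <- all_df[c(which(is_true)[take_true], which(!is_true)[take_bg]), ,
                  drop = FALSE]
    interaction_dataset(row$name, sel$a, sel$b, role = row$role, quiet = TRUE)
  })
  names(ds) <- spec$datasets$name

  # expression: one latent condition-profile per complex; members load on
  # it with rho so pairwise within-complex correlation has expectation rho^2
  expr <- matrix(stats::rnorm(n * spec$n_conditions), nrow = n,
                 dimnames = list(proteins,
                                 sprintf("cond%03d", seq_len(spec$n_conditions))))
  assigned <- character(0)
  for (label in names(complexes)) {
    latent <- stats::rnorm(spec$n_conditions)
    fresh <- setdiff(complexes[[label]], assigned)
    for (g in fresh) {
      expr[g, ] <- spec$rho * latent +
        sqrt(1 - spec$rho^2) * stats::rnorm(spec$n_conditions)
    }
    assigned <- c(assigned, fresh)
  }

  reference <- perturb_reference(truth, spec$swap_rate, universe = proteins)
  reference$name <- "reference"

  labels <- data.frame(dataset = spec$datasets$name,
                       role = spec$datasets$role,
                       tp = spec$datasets$tp, fp = spec$datasets$fp,
                       informative = spec$datasets$tp > spec$datasets$fp,
                       stringsAsFactors = FALSE)

  list(datasets = ds, truth = truth, reference = reference,
       expression = expr, true_pairs = tp_df, labels = labels,
       proteins = proteins, spec = spec)
}

#' Perturb a module set by random member swaps
#'
#' Each member is independently replaced, with probability `swap_rate`, by
#' a protein drawn from the universe outside the module. Module count and
#' sizes are preserved. Uses the current RNG state (seed upstream for
#' reproducibility).
#'
#' @param truth A `module_set`.
#' @param swap_rate Probability in `[0, 1)` of swapping each member.
#' @param universe Character vector of proteins to draw replacements from;
#'   defaults to the module-set universe.
#' @return A perturbed `module_set`.
#' @export
perturb_reference <- function(truth, swap_rate, universe = NULL) {
  stopifnot(inherits(truth, "module_set"), swap_rate >= 0, swap_rate < 1)
  if (is.null(universe)) universe <- module_universe(truth)
  if (swap_rate == 0) return(truth)
  mods <- lapply(truth$modules, function(members) {
    out <- members
    for (i in seq_along(out)) {
      if (stats::runif(1) < swap_rate) {
        candidates <- setdiff(universe, out)
        if (length(candidates)) out[i] <- sample(candidates, 1L)
      }
    }
    out
  })
  module_set(mods, name = paste0(truth$name, "_perturbed"))
}
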