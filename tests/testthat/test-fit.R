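# small helper: clique-expanded dataset from a module set
cliques_dataset <- function(ms, name = "cliq", role = "free") {
  pairs <- do.call(rbind, lapply(ms$modules, function(m) {
    e <- clique_edges(sort(m))
    data.frame(a = e$a, b = e$b, stringsAsFactors = FALSE)
  }))
  interaction_dataset(name, pairs$a, pairs$b, role = role, quiet = TRUE)
}

ref4 <- module_set(list(C1 = c("a", "b", "c", "d"),
                        C2 = c("e", "f", "g"),
                        C3 = c("h", "i", "j", "k")), name = "ref")

test_that("objective is 1 when one dataset holds exactly the reference cliques", {
  ds <- cliques_dataset(ref4)
  expect_equal(ppi_objective(c(cliq = 1), list(ds), ref4), 1, tolerance = 1e-12)
  # uniform scaling of a single dataset leaves the modules, hence the
  # objective, unchanged
  expect_identical(ppi_objective(c(cliq = 0.5), list(ds), ref4),
                   ppi_objective(c(cliq = 1), list(ds), ref4))
})

test_that("an empty integrated network scores 0 with a warning", {
  ds <- cliques_dataset(ref4)
  expect_warning(val <- ppi_objective(c(cliq = 0), list(ds), ref4),
                 "empty")
  expect_identical(val, 0)
  expect_error(fit_weights(list(cliques_dataset(ref4, role = "fixed")), ref4),
               "no free datasets")
})

test_that("the optimizer runs in one dimension per free dataset", {
  # the classic roster: six free sources, curated interactions and
  # co-complex pairs fixed at 1
  mk <- function(name, role) {
    interaction_dataset(name, c("a", "b"), c("b", "c"), role = role,
                        quiet = TRUE)
  }
  roster <- list(mk("hu", "free"), mk("arifuzzaman", "free"),
                 mk("butland", "free"), mk("intact", "free"),
                 mk("bind", "free"), mk("ortho", "free"),
                 mk("dip", "fixed"), mk("cocomplex", "fixed"))
  fit <- fit_weights(roster, module_set(list(M = c("a", "b", "c"))),
                     hs_control = harmony_control(memory_size = 5,
                                                  iterations = 10, seed = 1))
  expect_length(fit$weights, 6L)
  expect_identical(sort(names(fit$weights)),
                   sort(c("hu", "arifuzzaman", "butland", "intact", "bind",
                          "ortho")))
  expect_true(all(paste0("w_", 1:6) %in% names(fit$trace)))
  expect_identical(unname(fit$roles[c("dip", "cocomplex")]),
                   c("fixed", "fixed"))
})

test_that("fit is deterministic and its modules are recomputable", {
  bench <- generate_benchmark(benchmark_spec(
    n_proteins = 60L, n_complexes = 6L, size_range = c(4L, 6L),
    datasets = data.frame(name = c("good", "junk"), tp = c(0.9, 0.02),
                          fp = c(0, 0.02), role = "free",
                          stringsAsFactors = FALSE),
    n_conditions = 20L, seed = 5
  ))
  ctrl <- harmony_control(memory_size = 15, iterations = 40, seed = 8)
  f1 <- fit_weights(bench$datasets, bench$reference, hs_control = ctrl)
  f2 <- fit_weights(bench$datasets, bench$reference, hs_control = ctrl)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$modules, f2$modules)
  expect_false(is.unsorted(f1$trace$best_value))

  recomputed <- mcl_cluster(
    build_weighted_network(bench$datasets, f1$weights), f1$mcl_params)
  expect_identical(canon_modules(f1$modules), canon_modules(recomputed))
  expect_equal(f1$best_nmi, max(f1$trace$best_value), tolerance = 1e-15)
})

test_that("noise datasets are down-weighted relative to informative ones", {
  roster <- data.frame(
    name = c("inf_a", "inf_b", "noise_a", "noise_b"),
    tp = c(0.75, 0.75, 0.02, 0.02),
    fp = c(0, 0, 0.02, 0.02),
    role = "free", stringsAsFactors = FALSE
  )
  for (seed in c(7, 19)) {
    bench <- generate_benchmark(benchmark_spec(
      n_proteins = 100L, n_complexes = 10L, size_range = c(5L, 8L),
      datasets = roster, n_conditions = 20L, swap_rate = 0.1, seed = seed
    ))
    fit <- suppressWarnings(fit_weights(
      bench$datasets, bench$reference,
      hs_control = harmony_control(memory_size = 30, iterations = 150,
                                   seed = seed)
    ))
    informative <- fit$weights[c("inf_a", "inf_b")]
    noise <- fit$weights[c("noise_a", "noise_b")]
    expect_true(max(noise) < min(informative),
                label = sprintf("seed %d ordering (inf %s, noise %s)", seed,
                                paste(round(informative, 3), collapse = "/"),
                                paste(round(noise, 3), collapse = "/")))
  }
})

test_that("extra references ride along without steering the fit", {
  bench <- generate_benchmark(benchmark_spec(
    n_proteins = 80L, n_complexes = 8L, size_range = c(4L, 7L),
    datasets = data.frame(name = c("good", "junk"), tp = c(0.85, 0.02),
                          fp = c(0, 0.02), role = "free",
                          stringsAsFactors = FALSE),
    n_conditions = 20L, swap_rate = 0.15, seed = 21
  ))
  set.seed(22)
  extra <- perturb_reference(bench$truth, 0.15, universe = bench$proteins)
  ctrl <- harmony_control(memory_size = 20, iterations = 120, seed = 23)
  plain <- fit_weights(bench$datasets, bench$reference, hs_control = ctrl)
  with_extra <- fit_weights(bench$datasets, bench$reference, hs_control = ctrl,
                            extra_references = list(gofunc = extra))
  expect_identical(plain$weights, with_extra$weights)   # no feedback
  expect_identical(nrow(with_extra$extra_nmi), nrow(with_extra$trace))

  # the cross-reference curve trends with the optimized objective
  steps <- !duplicated(with_extra$trace$best_value)
  if (sum(steps) >= 3) {
    rho <- stats::cor(with_extra$trace$best_value[steps],
                      with_extra$extra_nmi$gofunc[steps], method = "spearman")
    expect_gt(rho, 0)
  }
})
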