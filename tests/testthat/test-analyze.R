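test_that("hub rule: star, clique and path forced answers", {
  star <- make_network(rep("hub", 5), paste0("leaf", 1:5))
  expect_identical(detect_central_proteins(c("hub", paste0("leaf", 1:5)), star),
                   "hub")

  cl <- clique_edges(letters[1:5])
  clique <- make_network(cl$a, cl$b)
  expect_identical(detect_central_proteins(letters[1:5], clique), character())

  path3 <- make_network(c("a", "b"), c("b", "c"))
  expect_identical(detect_central_proteins(c("a", "b", "c"), path3),
                   character())
})

test_that("hub sets ignore edge-weight scale and members outside the network", {
  g <- random_weighted_graph(n = 12, p_edge = 0.35, seed = 17)$graph
  members <- igraph::V(g)$name
  base <- detect_central_proteins(members, g)
  scaled <- g
  igraph::E(scaled)$weight <- igraph::E(scaled)$weight * 7.5
  expect_identical(detect_central_proteins(members, scaled), base)

  # absent members count with degree zero in the mean
  star <- make_network(rep("hub", 5), paste0("leaf", 1:5))
  with_ghost <- detect_central_proteins(c("hub", paste0("leaf", 1:5), "ghost"),
                                        star)
  expect_identical(with_ghost, "hub")

  rep_df <- hub_report(module_set(list(M1 = members)), g)
  expect_identical(sort(rep_df$member[rep_df$is_hub]), base)
  expect_true(all(rep_df$threshold == 2 * rep_df$mean_degree))
})

test_that("pairwise co-expression: identities, hand value, absence policy", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 5),
                g3 = -c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  colnames(expr) <- paste0("c", 1:4)

  cc <- pairwise_coexpression(expr, data.frame(a = "g1", b = "g1"))
  expect_identical(cc$correlation, 1)
  cc <- pairwise_coexpression(expr, data.frame(a = "g1", b = "g3"))
  expect_identical(cc$correlation, -1)

  # hand-computed: cov terms 6.5, ss_x 5, ss_y 8.75
  cc <- pairwise_coexpression(expr, data.frame(a = "g1", b = "g2"))
  expect_equal(cc$correlation, 6.5 / sqrt(5 * 8.75), tolerance = 1e-15)

  # missing gene -> absent row, not zero; flat gene -> warned absent
  expect_warning(
    cc <- pairwise_coexpression(expr, data.frame(a = c("g1", "g1", "g1"),
                                                 b = c("gX", "flat", "g2"))),
    "zero-variance"
  )
  expect_identical(nrow(cc), 1L)
  expect_identical(attr(cc, "n_missing"), 2L)

  expect_error(pairwise_coexpression(expr[, 1:2], data.frame(a = "g1", b = "g2")),
               "at least 3 conditions")
})

test_that("coexpression_cutoff is the exact lower-quantile rule", {
  expect_identical(coexpression_cutoff(rep(0.5, 9), 0.7), 0.5)
  expect_identical(coexpression_cutoff((0:9) / 10, 0.7), 0.3)
  expect_error(coexpression_cutoff(numeric()), "empty")

  set.seed(41)
  for (rep in 1:20) {
    x <- runif(sample(5:200, 1), -1, 1)
    frac <- runif(1, 0.05, 0.95)
    cut <- coexpression_cutoff(x, frac)
    expect_gte(mean(x >= cut), frac)               # postcondition, by counting
    expect_lt(mean(x >= cut + 1e-9) , frac + 1e-9) # and it is the largest such
  }
})

test_that("overlay lists within-module pairs strictly above the cutoff", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 4, 6, 8, 10),
                g3 = c(5, 3, 4, 1, 2))
  colnames(expr) <- paste0("c", 1:5)
  mods <- module_set(list(M1 = c("g1", "g2"), M2 = c("g3", "gX")))
  out <- overlay_coexpression(mods, expr, 0.5)
  expect_identical(nrow(out), 1L)
  expect_identical(out$node1, "g1")
  expect_identical(out$module, "M1")

  # mutually uncorrelated noise, cutoff near 1: (almost) nothing linked
  set.seed(4)
  noise <- matrix(rnorm(10 * 30), nrow = 10,
                  dimnames = list(paste0("n", 1:10), paste0("c", 1:30)))
  out <- overlay_coexpression(module_set(list(M = paste0("n", 1:10))),
                              noise, 0.9)
  expect_identical(nrow(out), 0L)
})

test_that("benchmark overlay: cutoff keeps >=70% of co-complex pairs linked", {
  bench <- generate_benchmark(benchmark_spec(
    n_proteins = 80L, n_complexes = 8L, size_range = c(5L, 8L),
    n_conditions = 200L, rho = 0.8, seed = 13
  ))
  pairs <- bench$true_pairs
  cors <- pairwise_coexpression(bench$expression, pairs)
  cut <- coexpression_cutoff(cors$correlation, 0.7)
  expect_gte(mean(cors$correlation >= cut), 0.7)
  linked <- overlay_coexpression(bench$truth, bench$expression, cut - 1e-12)
  expect_gte(nrow(linked) / nrow(pairs), 0.7)
})

test_that("module-to-complex mapping: coverage, splits and tie-break", {
  mods <- module_set(list(M1 = c("a", "b", "c"), M2 = c("d", "e"),
                          M3 = c("f", "g")))
  complexes <- module_set(list(
    exact = c("d", "e"),
    split = c("b", "c", "d"),
    even = c("e", "f")     # 1 member in M2, 1 in M3 -> tie, smaller label
  ))
  rep_df <- map_modules_to_complexes(mods, complexes)
  expect_identical(rep_df$best_module[rep_df$complex == "exact"], "M2")
  expect_identical(rep_df$coverage[rep_df$complex == "exact"], 1)
  expect_identical(rep_df$n_modules_split[rep_df$complex == "exact"], 1L)

  expect_identical(rep_df$best_module[rep_df$complex == "split"], "M1")
  expect_equal(rep_df$coverage[rep_df$complex == "split"], 2 / 3)
  expect_identical(rep_df$n_modules_split[rep_df$complex == "split"], 2L)

  expect_identical(rep_df$best_module[rep_df$complex == "even"], "M2")
  expect_identical(rep_df$coverage[rep_df$complex == "even"], 0.5)
})

test_that("external-dataset overlap report counts cumulatively", {
  used <- list(interaction_dataset("u", c("a", "c"), c("b", "d"),
                                   role = "free", quiet = TRUE))
  mods <- module_set(list(M1 = c("a", "b", "e", "f"), M2 = c("c", "d", "g")))
  hubs <- "e"
  # 10 external pairs over the annotated universe {a..g}:
  # 2 in used datasets, 2 more co-modular, 2 more touch hub e, 4 neither
  ext <- interaction_dataset("y2h",
    a = c("a", "c", "e", "a", "e", "c", "a", "b", "f", "d"),
    b = c("b", "d", "f", "e", "g", "e", "c", "d", "g", "f"),
    role = "free", quiet = TRUE)
  rep_out <- compare_external_dataset(ext, used, mods, hubs = hubs)
  expect_identical(rep_out$n_annotated, 10L)
  expect_identical(rep_out$n_in_datasets, 2L)
  expect_identical(rep_out$n_plus_comodular, 4L)
  expect_identical(rep_out$n_plus_hub, 6L)
  expect_equal(c(rep_out$frac_in_datasets, rep_out$frac_plus_comodular,
                 rep_out$frac_plus_hub), c(0.2, 0.4, 0.6))
  expect_true(rep_out$n_in_datasets <= rep_out$n_plus_comodular &&
              rep_out$n_plus_comodular <= rep_out$n_plus_hub &&
              rep_out$n_plus_hub <= rep_out$n_annotated)

  # external subset of a used dataset -> fraction 1
  sub <- interaction_dataset("sub", "a", "b", role = "free", quiet = TRUE)
  expect_identical(compare_external_dataset(sub, used, mods)$frac_in_datasets, 1)

  # fully disjoint external set -> all-zero fractions
  far <- interaction_dataset("far", "x1", "x2", role = "free", quiet = TRUE)
  rep_far <- compare_external_dataset(far, used, mods)
  expect_identical(rep_far$n_annotated, 0L)
  expect_identical(rep_far$frac_plus_hub, 0)
})
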