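test_that("sweep grids form the expected cartesian products", {
  g4 <- sweep_grid(motility = "segmentation", intensity = c("light", "vigorous"),
                   fluid = "water_37C", pocket_volume = 2,
                   occlusion_ratio = c(0.3, 0.7), release = "most_occluded")
  expect_equal(nrow(g4), 4)
  gseg <- sweep_grid(motility = "segmentation")
  expect_equal(nrow(gseg), 3 * 2 * 2 * 3 * 2)   # 72 segmentation cases
  expect_equal(anyDuplicated(gseg[, 1:6]), 0)
})

test_that("rank tests: identical groups give p ~ 1; n=3 extreme separation
           attains the exact two-sided minimum 0.1", {
  tab <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                        y = c(1, 2, 3, 4, 1, 2, 3, 4))
  out <- multifactor_compare(tab, "g", "y")
  expect_gt(out$test$p.value, 0.85)
  tab2 <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                         y = c(1, 2, 3, 101, 102, 103))
  out2 <- multifactor_compare(tab2, "g", "y")
  expect_equal(out2$test$p.value, 0.1, tolerance = 1e-12)
})

test_that("Kruskal-Wallis + Dunn reject a large planted shift", {
  set.seed(11)
  tab <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 12),
    y = c(rnorm(12), rnorm(12), rnorm(12, mean = 6))
  )
  out <- multifactor_compare(tab, "g", "y")
  expect_equal(out$test$method, "Kruskal-Wallis")
  expect_lt(out$test$p.value, 0.05)
  dn <- out$pairwise
  expect_lt(dn$p_adj[dn$group1 == "a" & dn$group2 == "c"], 0.05)
  expect_lt(dn$p_adj[dn$group1 == "b" & dn$group2 == "c"], 0.05)
  expect_gt(dn$p_adj[dn$group1 == "a" & dn$group2 == "b"], 0.05)
  expect_error(multifactor_compare(tab[tab$g == "a", ], "g", "y"), "groups")
})

test_that("1-D K-means: trivial separations and agreement with the exact
           dynamic-programming oracle", {
  tab <- tibble::tibble(cs = c(0.1, 0.1, 0.9, 0.9))
  cl <- cluster_cases(tab, k = 2, seed = 1)
  expect_equal(sort(cl$cluster_mean_cs), c(0.1, 0.9))
  expect_equal(cl$sizes, c(2, 2))
  # k = n: every case its own cluster
  tabn <- tibble::tibble(cs = c(0.1, 0.3, 0.6, 0.9))
  cln <- cluster_cases(tabn, k = 4, seed = 1)
  expect_equal(sort(cln$centers), sort(tabn$cs))
  expect_error(cluster_cases(tab, k = 3), "distinct")
  # DP oracle comparison on <= 20 points
  set.seed(5)
  for (k in 2:4) {
    x <- round(runif(18), 3)
    km <- cluster_cases(tibble::tibble(cs = x), k = k, seed = 2, nstart = 100)
    dp <- optimal_1d_clustering(x, k)
    expect_equal(km$withinss, dp$withinss, tolerance = 1e-10)
  }
})

test_that("clustering is deterministic given the seed", {
  tab <- synthetic_sweep_fixture(seed = 3)
  a <- cluster_cases(tab, k = 4, seed = 9)
  b <- cluster_cases(tab, k = 4, seed = 9)
  expect_identical(a$table$cluster, b$table$cluster)
})

test_that("attribution recovers a dominant planted factor, scales features
           to [0,1], and satisfies SHAP additivity", {
  tab <- synthetic_sweep_fixture(seed = 7)
  at <- attribute_factors(tab, seed = 7, train_on = "all")
  expect_equal(at$ranking$feature[1], "pocket_volume")
  expect_true(all(at$features >= 0 & at$features <= 1))
  expect_lt(at$additivity_error, 1e-6)
  expect_gt(at$metrics$r2, 0.5)   # planted signal is strong
  # degenerate target rejected
  tab0 <- tab; tab0$cs <- 0.5
  expect_error(attribute_factors(tab0, seed = 1, train_on = "all"),
               "degenerate")
})

test_that("attribution is deterministic given the seed", {
  tab <- synthetic_sweep_fixture(seed = 2)
  small_grid <- expand.grid(nrounds = 100L, eta = 0.1, max_depth = 4L,
                            subsample = 1.0)
  a <- attribute_factors(tab, seed = 4, train_on = "all",
                         param_grid = small_grid)
  b <- attribute_factors(tab, seed = 4, train_on = "all",
                         param_grid = small_grid)
  expect_identical(a$ranking, b$ranking)
  expect_identical(a$shap, b$shap)
})

test_that("synthetic sweep generator is reproducible and covers the grid", {
  a <- synthetic_sweep_fixture(seed = 1)
  b <- synthetic_sweep_fixture(seed = 1)
  expect_identical(a$cs, b$cs)
  expect_equal(nrow(a), 144)
  expect_true(all(a$cs >= 0 & a$cs <= 1))
})
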