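test_that("build_interaction_matrix fills a symmetric zero-diagonal matrix", {
  rec <- tibble::tibble(
    parameter = "auc",
    strain_1 = c("s1", "s1", "s2"), strain_2 = c("s2", "s3", "s3"),
    species_1 = "X", species_2 = "X",
    index = c(0.1, -0.2, 0), outcome = c("D", "C", "A")
  )
  m <- build_interaction_matrix(rec, "auc")
  expect_equal(dim(m), c(3, 3))
  expect_true(isSymmetric(unname(m)))
  expect_equal(unname(diag(m)), c(0, 0, 0))
  expect_equal(m["s1", "s3"], -0.2)
  sig <- attr(m, "significant")
  expect_true(sig["s1", "s2"] && !sig["s2", "s3"])

  # missing pair is an error naming it
  expect_error(build_interaction_matrix(rec[-3, ], "auc"), "s2\\|s3")
  # conflicting duplicates are an error
  rec2 <- rbind(rec, rec[1, ])
  rec2$index[4] <- 0.5
  expect_error(build_interaction_matrix(rec2, "auc"), "conflict")
})

test_that("full design yields a 15x15 matrix with 105 pair values", {
  ds <- simulate_dataset(scenario_species_block(seed = 13))
  params <- dplyr::inner_join(ds$layout, fit_growth(ds$curves), by = "well")
  rec <- analyze_interactions(params)
  m <- build_interaction_matrix(rec, "auc")
  expect_equal(dim(m), c(15, 15))
  expect_equal(sum(upper.tri(m)), 105)
  expect_true(isSymmetric(unname(m)))
})

test_that("complete-linkage clustering recovers planted blocks exactly", {
  m <- planted_block_matrix(seed = 5)
  cl <- cluster_matrix(m, k = 5)
  sp <- attr(m, "species")
  expect_equal(adjusted_rand_index(cl$assignments, sp[names(cl$assignments)]),
               1)

  # invariant under input row permutation (up to label renaming)
  set.seed(9)
  perm <- sample(nrow(m))
  cl2 <- cluster_matrix(m[perm, perm], k = 5)
  expect_equal(
    adjusted_rand_index(cl$assignments[names(cl2$assignments)],
                        cl2$assignments), 1)

  # duplicate row-blocks at k = 2 are recovered exactly
  dup <- rbind(matrix(0, 3, 6), matrix(1, 3, 6))
  rownames(dup) <- colnames(dup) <- paste0("s", 1:6)
  cl3 <- cluster_matrix(dup, 2)
  expect_equal(unname(cl3$assignments), rep(1:2, each = 3))

  expect_error(cluster_matrix(m, 1), "k")
  expect_error(cluster_matrix(m, 16), "k")

  # newick export contains every strain
  nwk <- tree_newick(cl)
  expect_true(all(vapply(rownames(m), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("adjusted Rand index matches the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(21)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})

test_that("bootstrap stability scores planted structure high and is deterministic", {
  m <- planted_block_matrix(seed = 6)
  # bootstrap keeps all well-separated clusters near-perfectly stable;
  # subset resampling (half the strains) is intrinsically noisier
  st_boot <- bootstrap_stability(m, 5, B = 100, method = "bootstrap", seed = 4)
  expect_true(all(st_boot$jaccard >= 0.95))
  st_sub <- bootstrap_stability(m, 5, B = 100, method = "subset", seed = 4)
  expect_true(all(st_sub$jaccard >= 0.85))
  for (st in list(st_boot, st_sub)) {
    expect_true(all(st$jaccard <= 1))
    expect_false(any(st$dissolved))
  }
  # bit-identical under the same seed
  expect_identical(st_boot,
                   bootstrap_stability(m, 5, B = 100, method = "bootstrap",
                                       seed = 4))
  expect_error(bootstrap_stability(m, 5, B = 0), "B")
})

test_that("a borderline intermediate strain forms a less stable singleton", {
  m <- planted_block_matrix(seed = 8, n_species = 5)
  # a strain just outside species E, nudged toward species A by a hair more
  # than the within-block diameters: it cuts off as a singleton but
  # re-clusters inconsistently under resampling
  x <- 0.955 * m["E1", ] + 0.045 * m["A1", ]
  m2 <- rbind(cbind(m, X1 = x[rownames(m)]), X1 = c(x, X1 = 0))
  rownames(m2)[nrow(m2)] <- "X1"
  cl <- cluster_matrix(m2, 6)$assignments
  singleton <- cl[["X1"]]
  expect_equal(sum(cl == singleton), 1)
  st <- bootstrap_stability(m2, k = 6, B = 200, method = "bootstrap",
                            seed = 3)
  others <- setdiff(seq_len(6), singleton)
  expect_lt(st$jaccard[singleton], 0.9)
  expect_lt(st$jaccard[singleton], median(st$jaccard[others]))
})

test_that("stability never decreases when block separation grows tenfold", {
  base <- planted_block_matrix(seed = 10, sep = 0.12)
  wide <- planted_block_matrix(seed = 10, sep = 1.2)
  st_base <- bootstrap_stability(base, 5, B = 100, seed = 2)
  st_wide <- bootstrap_stability(wide, 5, B = 100, seed = 2)
  # align clusters via species labels: same seed -> same block layout
  expect_true(all(st_wide$jaccard >= st_base$jaccard - 1e-12))
})
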