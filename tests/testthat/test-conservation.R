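test_that("mask projection maps residues and gaps onto columns", {
  expect_equal(project_mask("A-C", c(TRUE, FALSE)),
               c("disordered", "gap", "ordered"))
  expect_equal(project_mask("---", logical(0)), rep("gap", 3))
  expect_equal(project_mask("ACD", rep(TRUE, 3)), rep("disordered", 3))
  expect_error(project_mask("A-C", c(TRUE, FALSE, TRUE)), "does not match")
})

test_that("disorder Jaccard follows the overlap arithmetic", {
  mk <- function(n, dis) {
    x <- rep("ordered", n); x[dis] <- "disordered"; x
  }
  expect_equal(jaccard_disorder(mk(20, 1:10), mk(20, 1:10)), 1.0)
  expect_equal(jaccard_disorder(mk(20, 1:5), mk(20, 10:15)), 0.0)
  expect_equal(jaccard_disorder(mk(20, 1:10), mk(20, 6:15)), 5 / 15)
  # both masks empty: identical (empty) disorder scores 1
  expect_equal(jaccard_disorder(mk(10, integer(0)), mk(10, integer(0))), 1.0)
  # disordered-vs-gap columns count in the union only
  a <- c("disordered", "disordered", "ordered")
  b <- c("disordered", "gap", "ordered")
  expect_equal(jaccard_disorder(a, b), 1 / 2)
  expect_error(jaccard_disorder(a, b[1:2]), "mismatch")
})

test_that("Jaccard is symmetric, bounded, and equals the set oracle", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(5:80, 1)
    mk <- function() {
      x <- sample(c("disordered", "ordered", "gap"), n, replace = TRUE,
                  prob = c(runif(1, 0.1, 0.6), 0.3, 0.2))
      x
    }
    a <- mk(); b <- mk()
    j <- jaccard_disorder(a, b)
    expect_equal(j, jaccard_disorder(b, a))
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(j, oracle_jaccard(a, b))
  }
})

test_that("adding shared or one-sided disordered columns shifts Jaccard monotonically", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    a <- sample(c("disordered", "ordered"), n, replace = TRUE)
    b <- sample(c("disordered", "ordered"), n, replace = TRUE)
    j0 <- jaccard_disorder(a, b)
    # shared disordered column appended: never decreases
    expect_gte(jaccard_disorder(c(a, "disordered"), c(b, "disordered")), j0)
    # one-sided disordered column appended: never increases
    expect_lte(jaccard_disorder(c(a, "disordered"), c(b, "ordered")), j0)
  }
})

test_that("pairwise identity ignores gapped columns", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("A-CD", "AG-D"), 1.0)
  expect_error(pairwise_identity("A---", "-AAA"), "no mutually ungapped")
  expect_error(pairwise_identity("AA", "AAA"), "length mismatch")
})

test_that("conservation matrix recovers planted Jaccard values through MSAs", {
  set.seed(41)
  o <- simulate_ortholog_set(n_groups = 12, archetype_sd = 0.05,
                             ref_length = 220, idr_length = 60, seed = 41)
  masks <- annotate_proteome(o$tracks)
  flags <- lapply(masks, `[[`, "flags")
  cm <- build_conservation_matrix(o$alignments, flags, o$orthologs)
  expect_equal(dim(cm$jaccard), c(12L, 4L))
  expect_true(all(cm$jaccard >= 0 & cm$jaccard <= 1))
  # planted (realised) per-group values are reproduced exactly
  for (r in seq_len(nrow(o$truth))) {
    tr <- o$truth[r, ]
    expect_equal(cm$jaccard[tr$group_id, tr$species_id],
                 tr$realized_jaccard, tolerance = 1e-9)
  }
  # single group
  one <- simulate_ortholog_set(n_groups = 2, ref_length = 220,
                               idr_length = 60, seed = 2)
  cm1 <- build_conservation_matrix(one$alignments[1], lapply(
    annotate_proteome(one$tracks), `[[`, "flags"), one$orthologs)
  expect_equal(dim(cm1$jaccard), c(1L, 4L))
  # missing mask is reported by protein
  expect_error(build_conservation_matrix(o$alignments, flags[-1],
                                         o$orthologs),
               "no disorder mask for protein")
})

test_that("conservation and identity are uncorrelated when planted independently", {
  o <- simulate_ortholog_set(n_groups = 200, archetype_sd = 0.25,
                             ref_length = 220, idr_length = 60, seed = 99)
  masks <- annotate_proteome(o$tracks)
  cm <- build_conservation_matrix(o$alignments, lapply(masks, `[[`, "flags"),
                                  o$orthologs)
  # identity is driven by substitution rates, conservation by archetypes;
  # within species the two are independent draws
  expect_true(all(abs(cm$identity_correlation) < 0.2))
})

test_that("complete-linkage clustering recovers planted structure deterministically", {
  set.seed(61)
  centers <- rbind(c(0.9, 0.9, 0.9, 0.9), c(0.1, 0.1, 0.1, 0.1))
  mat <- do.call(rbind, lapply(1:2, function(k)
    sweep(matrix(rnorm(30 * 4, 0, 0.03), 30), 2, centers[k, ], `+`)))
  rownames(mat) <- sprintf("g%03d", 1:60)
  truth <- rep(1:2, each = 30)
  a <- cluster_rows(mat, k = 2)
  expect_equal(cluster_agreement(truth, a$labels[rownames(mat)]), 1.0)

  # identical rows collapse to one cluster at any positive height
  same <- matrix(0.5, 5, 4, dimnames = list(letters[1:5], NULL))
  expect_equal(cluster_rows(same, h = 0.1)$k, 1L)

  # k equal to the number of rows: every row its own cluster
  expect_equal(cluster_rows(mat, k = 60)$k, 60L)
  expect_error(cluster_rows(mat, k = 61), "between 1 and")
  expect_error(cluster_rows(mat[1, , drop = FALSE], k = 1), "at least 2")

  # permutation invariance
  perm <- sample(nrow(mat))
  b <- cluster_rows(mat[perm, ], k = 2)
  expect_equal(b$labels[rownames(mat)], a$labels[rownames(mat)])
})

test_that("cluster disorder profiles report per-species IDP fractions", {
  labels <- setNames(c(1L, 1L, 2L, 2L), paste0("g", 1:4))
  a <- structure(list(labels = labels, hclust = NULL, k = 2L, h = NULL),
                 class = "cluster_assignment")
  idp <- rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE), c(TRUE, TRUE))
  dimnames(idp) <- list(paste0("g", 1:4), c("human", "fly"))
  prof <- cluster_disorder_profile(a, idp)
  expect_equal(prof["1", ], c(human = 1, fly = 1))
  expect_equal(prof["2", ], c(human = 1, fly = 0.5))
  expect_error(cluster_disorder_profile(a, idp[1:3, ]), "lacks groups")
})
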