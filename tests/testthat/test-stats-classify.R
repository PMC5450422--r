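# Group statistics, k-means / neural-network classification, GA feature
# selection and morphospace ellipsoids.

make_groups <- function(centers, n = 25, sd = 1, seed = 11, extra_noise = 0) {
  with_seed <- leafletkit:::with_seed
  with_seed(seed, {
    k <- nrow(centers)
    X <- do.call(rbind, lapply(seq_len(k), function(g)
      matrix(rnorm(n * ncol(centers), mean = rep(centers[g, ], each = n), sd = sd),
             n, ncol(centers))))
    if (extra_noise > 0) X <- cbind(X, matrix(rnorm(nrow(X) * extra_noise), nrow(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    cbind(data.frame(group = rep(paste0("G", seq_len(k)), each = n)),
          as.data.frame(X))
  })
}

test_that("compare_groups holds its size under the null and has power at 5 SD", {
  set.seed(42)
  rej <- replicate(60, {
    x <- rnorm(60, 10, 1)
    cg <- compare_groups(data.frame(v = x, group = rep(c("a", "b"), each = 30)), "v")
    cg$anova_p < 0.05 || cg$kruskal_p < 0.05
  })
  expect_lte(mean(rej), 0.15)

  set.seed(7)
  cg <- compare_groups(data.frame(v = c(rnorm(30), rnorm(30, 5)),
                                  group = rep(c("a", "b"), each = 30)), "v")
  expect_lt(cg$anova_p, 1e-6)
  expect_lt(cg$kruskal_p, 1e-6)
  expect_true(cg$significant["a", "b"])

  expect_error(compare_groups(data.frame(v = rnorm(10), group = "a"), "v"),
               "two groups")
  expect_error(compare_groups(data.frame(v = rnorm(10), group = "a"), "nope"),
               "not found")
})

test_that("k-means classification is exact on separated groups and honest on degenerate ones", {
  tab <- make_groups(matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10), 4, 3,
                            byrow = TRUE))
  res <- kmeans_classify(tab, c("f1", "f2", "f3"), seed = 2)
  expect_equal(res$accuracy, 1)
  expect_true(all(rowSums(res$confusion_matrix) == 25))

  # identical samples: best constant assignment (oracle: max group size / total)
  dg <- data.frame(group = rep(c("a", "b", "c"), c(10, 6, 4)), x = 1, y = 1, z = 1)
  expect_equal(suppressWarnings(kmeans_classify(dg, c("x", "y", "z"), seed = 1))$accuracy,
               0.5)

  # determinism and rescaling invariance (standardization contract)
  r1 <- kmeans_classify(tab, c("f1", "f2", "f3"), seed = 9)
  r2 <- kmeans_classify(tab, c("f1", "f2", "f3"), seed = 9)
  expect_identical(r1$confusion_matrix, r2$confusion_matrix)
  tab2 <- tab
  tab2$f1 <- tab2$f1 * 1000; tab2$f3 <- tab2$f3 / 50
  expect_equal(kmeans_classify(tab2, c("f1", "f2", "f3"), seed = 9)$accuracy,
               r1$accuracy)
  expect_error(kmeans_classify(tab[1:3, ], c("f1", "f2", "f3"), k = 5), "exceeds")
})

test_that("the feedforward classifier separates, guesses at chance, and repeats exactly", {
  tab <- data.frame(group = rep(c("a", "b"), each = 40),
                    x = c(rnorm(40), rnorm(40, 8)), y = rnorm(80), z = rnorm(80))
  res <- ann_classify(tab, c("x", "y", "z"), seed = 2)
  expect_gte(res$accuracy, 0.99)
  expect_equal(res$n_repeats, 30)
  # row sums of the aggregated confusion equal group sizes summed over repeats
  expect_true(all(rowSums(res$confusion_matrix) == 10 * 30))

  set.seed(5)
  perm <- cbind(data.frame(group = sample(rep(paste0("g", 1:6), 20))),
                as.data.frame(matrix(rnorm(360), 120, 3,
                                     dimnames = list(NULL, c("a", "b", "c")))))
  chance <- ann_classify(perm, c("a", "b", "c"), seed = 2)
  expect_lt(abs(chance$accuracy - 1 / 6), 0.05)

  expect_identical(ann_classify(tab, c("x", "y", "z"), seed = 4)$accuracy,
                   ann_classify(tab, c("x", "y", "z"), seed = 4)$accuracy)

  small <- data.frame(group = rep(c("a", "b"), c(40, 3)), x = rnorm(43),
                      y = rnorm(43), z = rnorm(43))
  expect_error(ann_classify(small, c("x", "y", "z")), "b")
})

test_that("GA feature selection matches exhaustive search on a small candidate set", {
  tab <- make_groups(matrix(c(0, 0, 0, 6, 0, 0, 0, 6, 0, 0, 0, 6), 4, 3,
                            byrow = TRUE), extra_noise = 3)
  ga <- ga_select_features(tab, classifier = "kmeans", subset_size = 3, seed = 3,
                           pop_size = 20, generations = 25)
  combs <- utils::combn(6, 3)
  best <- 0
  for (i in seq_len(ncol(combs))) {
    a <- kmeans_classify(tab, paste0("f", combs[, i]), seed = 3)$accuracy
    best <- max(best, a)
  }
  expect_equal(ga$accuracy[1], best)

  none <- ga_select_features(tab, classifier = "kmeans", subset_size = 3,
                             min_accuracy = 1.01, seed = 3,
                             pop_size = 10, generations = 5)
  expect_equal(nrow(none), 0)
})

test_that("morphospace ellipsoids carry chi-square geometry", {
  pt <- data.frame(group = rep("g", 6), a = 1, b = 2, c = 3)
  e0 <- morphospace_ellipsoids(pt, c("a", "b", "c"))
  expect_equal(unname(e0$g$center), c(1, 2, 3))
  expect_true(all(e0$g$covariance == 0))

  set.seed(2)
  tab <- data.frame(group = "g1", a = rnorm(500), b = rnorm(500), c = rnorm(500))
  ell <- morphospace_ellipsoids(tab, c("a", "b", "c"))
  semi <- ell$g1$radius * sqrt(eigen(ell$g1$covariance)$values)
  # oracle: chi-square quantile sqrt(qchisq(.95, 3)) = 2.7955 for unit sd
  expect_true(all(abs(semi - sqrt(qchisq(0.95, 3))) / sqrt(qchisq(0.95, 3)) < 0.1))

  # two groups 10 SD apart: ellipsoids disjoint
  tab2 <- rbind(tab, data.frame(group = "g2", a = rnorm(500, 10),
                                b = rnorm(500, 10), c = rnorm(500, 10)))
  e2 <- morphospace_ellipsoids(tab2, c("a", "b", "c"))
  gap <- sqrt(sum((e2$g1$center - e2$g2$center)^2))
  r1 <- e2$g1$radius * sqrt(max(eigen(e2$g1$covariance)$values))
  r2 <- e2$g2$radius * sqrt(max(eigen(e2$g2$covariance)$values))
  expect_gt(gap, r1 + r2)

  expect_warning(morphospace_ellipsoids(
    data.frame(group = rep(c("g", "h"), c(10, 3)), a = rnorm(13), b = rnorm(13),
               c = rnorm(13)), c("a", "b", "c")), "skipped")
})
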