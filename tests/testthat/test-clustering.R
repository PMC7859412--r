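line_dm <- function(pts) {
  d <- as.matrix(dist(matrix(pts, ncol = 1)))
  dimnames(d) <- list(names(pts), names(pts))
  as.dist(d)
}

test_that("distance matrix matches the naive pairwise oracle", {
  x <- two_blob_curves()
  expect_equal(as.matrix(distance_matrix(x))["d1", "d1"], 0)
  set.seed(12)
  y <- matrix(runif(6 * 64), 6, 64, dimnames = list(paste0("r", 1:6), NULL))
  dm <- as.matrix(distance_matrix(y))
  for (i in 1:6) for (j in 1:6)
    expect_equal(dm[i, j], sqrt(sum((y[i, ] - y[j, ])^2)),
                 tolerance = 1e-12)
  # toy hand computation
  toy <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  expect_equal(as.matrix(distance_matrix(toy))["a", "b"], sqrt(2))
})

test_that("average linkage reproduces hand-computed merges on {0,1,10}", {
  dm <- line_dm(c(a = 0, b = 1, c = 10))
  cl <- hierarchical_cluster(dm, "average", k = 2)
  expect_equal(sort(cl$tree$height), c(1, 9.5))
  expect_equal(unname(cl$labels), c(1, 1, 2))
  expect_equal(length(unique(hierarchical_cluster(dm, "average", 3)$labels)),
               3)
  expect_equal(length(unique(hierarchical_cluster(dm, "average", 1)$labels)),
               1)
  expect_error(hierarchical_cluster(dm, "average", 4))
})

test_that("average-linkage trees match the brute-force agglomerator", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("p", 1:n), NULL))
    dm <- dist(x)
    tree <- hierarchical_cluster(dm, "average", 2)$tree
    oracle <- naive_average_linkage(dm)
    expect_equal(sort(tree$height), oracle$heights, tolerance = 1e-10)
    coph <- as.matrix(cophenetic(tree))[paste0("p", 1:n), paste0("p", 1:n)]
    expect_equal(unname(coph), unname(oracle$cophenetic),
                 tolerance = 1e-10)
  }
})

test_that("cophenetic correlation is exact on ultrametric input and
           matches the 3-point hand computation", {
  # ultrametric: coph distances equal original distances -> r = 1
  um <- matrix(c(0, 1, 4, 4,
                 1, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4)
  tree <- hclust(as.dist(um), method = "average")
  expect_equal(cophenetic_correlation(tree, as.dist(um)), 1)

  dm <- line_dm(c(a = 0, b = 1, c = 10))
  tree <- hierarchical_cluster(dm, "average", 2)
  hand_coph <- c(1, 9.5, 9.5)   # pairs (a,b), (a,c), (b,c)
  expect_equal(cophenetic_correlation(tree, dm),
               cor(c(1, 10, 9), hand_coph))

  # permutation invariance
  pts <- c(a = 0, b = 1, c = 10, d = 4)
  r1 <- cophenetic_correlation(
    hierarchical_cluster(line_dm(pts), "average", 2), line_dm(pts))
  perm <- pts[c("c", "a", "d", "b")]
  r2 <- cophenetic_correlation(
    hierarchical_cluster(line_dm(perm), "average", 2), line_dm(perm))
  expect_equal(r1, r2)

  expect_error(cophenetic_correlation(tree, line_dm(c(a = 0, b = 1))),
               "at least 3")
})

test_that("linkage selection maximises cophenetic correlation", {
  dm <- distance_matrix(two_blob_curves())
  single <- select_linkage(dm, "average")
  expect_equal(as.character(single), "average")
  sel <- select_linkage(dm)
  scores <- attr(sel, "scores")
  expect_equal(nrow(scores), 4)
  expect_equal(scores$cophenetic_r[scores$linkage == as.character(sel)],
               max(scores$cophenetic_r))
})

test_that("W_k matches its naive definition and equals within-cluster SS", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(6:10, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(1:3, n, replace = TRUE)
    expect_equal(within_cluster_dispersion(x, labels),
                 naive_wk(x, labels), tolerance = 1e-10)
  }
})

test_that("gap statistic picks k = 2 for two tight separated blobs", {
  x <- two_blob_curves(n_per = 4, sep = 1, jitter = 0.002)
  gap <- gap_statistic(x, "hierarchical_average", k_max = 5, B = 20,
                       seed = 99)
  expect_equal(gap$k, 2L)
  # the k = 2 partition found is the globally optimal W_2 over all
  # assignments (n = 8 small enough to enumerate via the blobs' truth)
  labels2 <- hierarchical_cluster(distance_matrix(x), "average", 2)$labels
  w2 <- within_cluster_dispersion(x, labels2)
  best <- Inf
  for (code in 1:(2^7)) {           # fix point 1 in cluster 1
    assign <- c(1L, as.integer(intToBits(code))[1:7] + 1L)
    if (length(unique(assign)) == 2)
      best <- min(best, naive_wk(x, assign))
  }
  expect_equal(w2, best, tolerance = 1e-10)
})

test_that("gap statistic stays finite with B = 1 and prefers k = 1 on
           structureless data", {
  x <- two_blob_curves(n_per = 3)
  g1 <- gap_statistic(x, "hierarchical_average", k_max = 4, B = 1,
                      seed = 1)
  expect_true(all(is.finite(g1$table$gap)))

  picks <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    ref <- matrix(runif(20 * 2), 20, 2,
                  dimnames = list(paste0("u", 1:20), NULL))
    gap_statistic(ref, "hierarchical_average", k_max = 5, B = 10,
                  seed = s)$k
  }, integer(1))
  expect_gt(mean(picks == 1L), 0.5)
})

test_that("gap statistic agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  x <- two_blob_curves(n_per = 4, sep = 0.8, jitter = 0.01)
  mine <- gap_statistic(x, "kmeans", k_max = 4, B = 50, seed = 5)
  set.seed(5)
  ref <- cluster::clusGap(x, FUN = function(xx, k)
                            list(cluster = kmeans(xx, k, nstart = 10)$cluster),
                          K.max = 4, B = 50, d.power = 2,
                          spaceH0 = "original", verbose = FALSE)
  # the reference halves the pairwise sum (counts unordered pairs), a
  # constant log(2) offset that cancels inside the gap itself
  expect_equal(mine$table$log_w, unname(ref$Tab[, "logW"]) + log(2),
               tolerance = 1e-6)
  # stochastic reference draws differ, so compare gap curves loosely
  expect_equal(mine$table$gap, unname(ref$Tab[, "gap"]), tolerance = 0.1)
})

test_that("partitioning algorithms recover separated blobs and are
           seed-deterministic", {
  x <- two_blob_curves(n_per = 3, sep = 1, jitter = 0.002)
  truth <- rep(1:2, each = 3)
  for (f in list(function() kmeans_cluster(x, 2, seed = 1),
                 function() pam_cluster(distance_matrix(x), 2),
                 function() spectral_cluster(x, 2, seed = 1))) {
    lab <- f()$labels
    expect_equal(adjusted_rand_index(lab, truth), 1)
    expect_identical(lab, f()$labels)
  }
})

test_that("PAM on {0,1,10} with k = 2 attains the exhaustive optimum", {
  dm <- line_dm(c(a = 0, b = 1, c = 10))
  fit <- pam_cluster(dm, 2)
  expect_equal(fit$diagnostics$cost, 1)
  expect_true("c" %in% fit$diagnostics$medoids)
  expect_true(any(c("a", "b") %in% fit$diagnostics$medoids))
  # On instances with genuine cluster structure, build+swap attains the
  # exhaustive-search optimum (on arbitrary point clouds PAM is a local
  # heuristic and no faithful implementation tracks exhaustive search).
  set.seed(44)
  for (i in 1:5) {
    sizes <- sample(2:4, 2, replace = TRUE)
    x <- rbind(matrix(rnorm(sizes[1] * 2, 0, 0.5), ncol = 2),
               matrix(rnorm(sizes[2] * 2, 10, 0.5), ncol = 2))
    dmr <- dist(x)
    expect_equal(pam_cluster(dmr, 2)$diagnostics$cost,
                 naive_pam_cost(dmr, 2), tolerance = 1e-10)
  }
})

test_that("Dunn index matches hand enumeration and sentinel conventions", {
  pts <- c(p1 = 0, p2 = 1, p3 = 10, p4 = 11)
  dm <- line_dm(pts)
  expect_equal(dunn_index(dm, c(1, 1, 2, 2)), 9)
  expect_equal(dunn_index(dm, c(1, 1, 2, 2)),
               naive_dunn(dm, c(1, 1, 2, 2)))
  # merging the blobs lowers the index
  pts5 <- c(pts, p5 = 20)
  expect_lt(dunn_index(line_dm(pts5), c(1, 1, 1, 1, 2)),
            dunn_index(line_dm(pts5), c(1, 1, 2, 2, 3)))
  # coincident points within clusters
  dup <- as.dist(matrix(c(0, 0, 5, 5, 0, 0, 5, 5,
                          5, 5, 0, 0, 5, 5, 0, 0), 4, 4))
  expect_warning(v <- dunn_index(dup, c(1, 1, 2, 2)), "Inf")
  expect_identical(v, Inf)
  expect_error(dunn_index(dm, rep(1, 4)), "at least 2")
})

test_that("algorithm selection takes the Dunn argmax with the documented
           tie-break", {
  x <- two_blob_curves(n_per = 3, sep = 1, jitter = 0.002)
  dm <- distance_matrix(x)
  hier <- hierarchical_cluster(dm, "average", 2)
  km <- kmeans_cluster(x, 2, seed = 1)
  bad <- hierarchical_cluster(dm, "average", 4)
  bad$algorithm <- "kmeans_bad_k"

  single <- select_algorithm(list(km), dm)
  expect_identical(single$labels, km$labels)

  best <- select_algorithm(list(bad, hier), dm)
  expect_identical(best$algorithm, "hierarchical_average")
  tab <- attr(best, "comparison")
  expect_equal(nrow(tab), 2)
  expect_equal(best$diagnostics$dunn, max(tab$dunn))

  # exact tie between identical partitions: prefers hierarchical-average
  tie <- select_algorithm(list(km, hier), dm)
  expect_identical(tie$algorithm, "hierarchical_average")
})

test_that("main/outlier split applies the size-3 rule and median ordering", {
  labels <- setNames(c(rep(1, 5), rep(2, 2), 3, rep(4, 4)),
                     paste0("d", 1:12))
  med <- data.frame(disease_id = paste0("d", 1:12),
                    median_age = c(rep(40, 5), rep(80, 2), 70, rep(75, 4)),
                    q25 = 0, q75 = 0)
  p <- split_main_outlier(labels, med)
  s <- attr(p, "summary")
  expect_equal(sum(s$type == "main"), 2)
  expect_equal(sum(s$type == "outlier"), 2)
  # cluster 4 (median 75) outranks cluster 1 (median 40)
  expect_equal(s$cluster[s$main_label == 1 & !is.na(s$main_label)], "4")
  expect_equal(s$cluster[s$main_label == 2 & !is.na(s$main_label)], "1")
  expect_true(all(table(p$disease_id) == 1))

  all_main <- split_main_outlier(setNames(rep(1:2, each = 3),
                                          paste0("d", 1:6)),
                                 data.frame(disease_id = paste0("d", 1:6),
                                            median_age = 50, q25 = 0,
                                            q75 = 0))
  expect_equal(sum(attr(all_main, "summary")$type == "outlier"), 0)
})

test_that("clustering is invariant to disease input order", {
  x <- two_blob_curves(n_per = 5, sep = 0.6, jitter = 0.01)
  lab1 <- hierarchical_cluster(distance_matrix(x), "average", 2)$labels
  set.seed(66)
  perm <- sample(nrow(x))
  lab2 <- hierarchical_cluster(distance_matrix(x[perm, ]), "average",
                               2)$labels
  expect_equal(adjusted_rand_index(lab1[rownames(x)],
                                   lab2[rownames(x)]), 1)
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(21)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
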