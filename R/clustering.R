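#' Euclidean distance matrix between standardised onset curves
#'
#' @param x Either a diseases-by-ages matrix (see [curve_matrix()]) or a
#'   long standardised-rates data frame from [standardise_curves()]. All
#'   curves must share the full 21-84 grid.
#' @return A `stats::dist` object labelled by disease id.
#' @export
distance_matrix <- function(x) {
  if (is.data.frame(x)) x <- curve_matrix(x)
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop(errorCondition(
    "curves with missing ages cannot be compared on a common grid",
    class = c("ardkit_grid_error", "error")))
  stats::dist(x, method = "euclidean")
}

as_dist <- function(dm) if (inherits(dm, "dist")) dm else stats::as.dist(dm)

new_clustering <- function(algorithm, k, labels, tree = NULL,
                           diagnostics = list()) {
  structure(list(algorithm = algorithm, k = as.integer(k), labels = labels,
                 tree = tree, diagnostics = diagnostics),
            class = "ard_clustering")
}

#' @export
print.ard_clustering <- function(x, ...) {
  cat(sprintf("<ard_clustering> %s, k = %d, sizes: %s\n", x$algorithm, x$k,
              paste(sort(table(x$labels), decreasing = TRUE),
                    collapse = " ")))
  invisible(x)
}

#' Hierarchical agglomerative clustering of onset curves
#'
#' Builds the merge tree bottom-up under the requested linkage and cuts it
#' into `k` clusters. The tree is retained for cophenetic diagnostics.
#'
#' @param dm Distance matrix (`dist` or symmetric matrix).
#' @param linkage One of `"average"`, `"single"`, `"complete"`,
#'   `"mcquitty"` (weighted average), `"ward.D2"`.
#' @param k Number of clusters, between 1 and the number of diseases.
#' @return An `ard_clustering` object; `$labels` is a named integer vector,
#'   `$tree` the `hclust` merge tree.
#' @export
hierarchical_cluster <- function(dm, linkage = "average", k) {
  dm <- as_dist(dm)
  linkage <- match.arg(linkage,
                       c("average", "single", "complete", "mcquitty",
                         "ward.D2"))
  n <- attr(dm, "Size")
  if (k < 1 || k > n) stop("k must be between 1 and the number of diseases")
  tree <- stats::hclust(dm, method = linkage)
  labels <- stats::cutree(tree, k = k)
  new_clustering(paste0("hierarchical_", linkage), k, labels, tree = tree)
}

#' Cophenetic correlation of a merge tree
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances (the merge height at which each pair first joins a
#' common cluster). Values near 1 mean the hierarchy reproduces the
#' distances faithfully.
#'
#' @param tree An `hclust` tree or an `ard_clustering` holding one.
#' @param dm The distance matrix the tree was built from.
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(tree, dm) {
  if (inherits(tree, "ard_clustering")) tree <- tree$tree
  dm <- as_dist(dm)
  if (attr(dm, "Size") < 3)
    stop("cophenetic correlation needs at least 3 diseases")
  stats::cor(as.vector(dm), as.vector(stats::cophenetic(tree)))
}

#' Choose the linkage with the highest cophenetic correlation
#'
#' @param dm Distance matrix.
#' @param candidates Character vector of linkage names (>= 2 recommended).
#' @return The winning linkage name; the full score table is attached as
#'   attribute `"scores"` (a data frame `linkage`, `cophenetic_r`). Ties are
#'   broken in favour of `"average"` if it is among the winners, else the
#'   first candidate.
#' @export
select_linkage <- function(dm, candidates = c("average", "single",
                                              "complete", "mcquitty")) {
  stopifnot(length(candidates) >= 1)
  dm <- as_dist(dm)
  r <- vapply(candidates, function(lk) {
    cophenetic_correlation(stats::hclust(dm, method = lk), dm)
  }, numeric(1))
  best <- candidates[r >= max(r) - 1e-12]
  winner <- if ("average" %in% best) "average" else best[1]
  structure(winner, scores = data.frame(linkage = candidates,
                                        cophenetic_r = unname(r)))
}

#' Pooled within-cluster dispersion W_k
#'
#' \eqn{W_k = \sum_r D_r / (2 n_r)} where \eqn{D_r} is the sum of all
#' pairwise squared Euclidean distances inside cluster \eqn{r}. This is the
#' dispersion the gap statistic compares against its reference
#' distribution; it equals the total within-cluster sum of squares about
#' cluster centroids.
#'
#' @param x Observation matrix (rows = diseases).
#' @param labels Cluster labels, one per row.
#' @return Nonnegative scalar.
#' @export
within_cluster_dispersion <- function(x, labels) {
  stopifnot(nrow(x) == length(labels))
  d2 <- as.matrix(stats::dist(x))^2
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
}

# Labels for one algorithm at one k, used by the gap statistic and the
# pipeline. Stochastic algorithms consume the current RNG stream.
cluster_labels_for <- function(x, algorithm, k, linkage = "average") {
  if (k == 1) return(stats::setNames(rep(1L, nrow(x)), rownames(x)))
  switch(algorithm,
    hierarchical = ,
    hierarchical_average = hierarchical_cluster(stats::dist(x),
                                                linkage, k)$labels,
    kmeans = kmeans_cluster(x, k)$labels,
    pam = pam_cluster(stats::dist(x), k)$labels,
    spectral = spectral_cluster(x, k)$labels,
    stop("unknown clustering algorithm: ", algorithm))
}

#' Gap statistic for choosing the number of clusters
#'
#' For each \eqn{k = 1..k_{max}} the within-cluster dispersion \eqn{W_k} of
#' the clustered data is compared with its expectation under a reference
#' null of no cluster structure: \eqn{Gap(k) = E^*[\log W_k^*] - \log W_k},
#' with the expectation estimated over `B` reference datasets drawn
#' uniformly over the per-feature range of the data. The standard error is
#' \eqn{s_k = sd^*(\log W_k^*)\sqrt{1 + 1/B}}, and the chosen \eqn{k} is
#' the smallest one with \eqn{Gap(k) \ge Gap(k+1) - s_{k+1}} (falling back
#' to `k_max`, with a warning, if no k qualifies).
#'
#' @param x Diseases-by-ages matrix of (standardised) curves.
#' @param algorithm `"hierarchical_average"`, `"kmeans"`, `"pam"` or
#'   `"spectral"`.
#' @param k_max Largest k to evaluate (>= 2; capped at n - 1).
#' @param B Number of reference datasets (>= 1).
#' @param seed Integer seed making the reference draws (and any stochastic
#'   clustering) reproducible.
#' @param linkage Linkage for the hierarchical algorithm.
#' @return List of class `ard_gap`: `k` (chosen), and a data frame `table`
#'   with columns `k`, `log_w`, `log_w_ref`, `gap`, `se`.
#' @export
gap_statistic <- function(x, algorithm = "hierarchical_average",
                          k_max = 10L, B = 50L, seed = 1L,
                          linkage = "average") {
  stopifnot(is.matrix(x), k_max >= 2, B >= 1)
  n <- nrow(x)
  k_max <- min(as.integer(k_max), n - 1L)
  set.seed(as.integer(seed))
  log_w <- function(data, k) {
    w <- within_cluster_dispersion(data,
                                   cluster_labels_for(data, algorithm, k,
                                                      linkage))
    if (w < .Machine$double.eps) {
      warning("within-cluster dispersion underflow at k = ", k,
              "; flooring at machine epsilon")
      w <- .Machine$double.eps
    }
    log(w)
  }
  lw <- vapply(1:k_max, function(k) log_w(x, k), numeric(1))
  rng <- apply(x, 2, range)
  lw_ref <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    ref <- apply(rng, 2, function(r) stats::runif(n, r[1], r[2]))
    lw_ref[b, ] <- vapply(1:k_max, function(k) log_w(ref, k), numeric(1))
  }
  gap <- colMeans(lw_ref) - lw
  se <- apply(lw_ref, 2, stats::sd) * sqrt(1 + 1 / B)
  if (B == 1) se[] <- 0
  ok <- which(gap[-k_max] >= gap[-1] - se[-1])
  k_hat <- if (length(ok)) min(ok) else {
    warning("no k satisfied the gap criterion; returning k_max")
    k_max
  }
  structure(list(k = as.integer(k_hat),
                 table = data.frame(k = 1:k_max, log_w = lw,
                                    log_w_ref = colMeans(lw_ref),
                                    gap = gap, se = se)),
            class = "ard_gap")
}

#' @export
print.ard_gap <- function(x, ...) {
  cat(sprintf("<ard_gap> chosen k = %d (k_max = %d)\n",
              x$k, max(x$table$k)))
  invisible(x)
}

#' k-means clustering of onset curves
#'
#' Standard k-means on the 64-dimensional standardised curves with 10
#' random restarts (best within-cluster sum of squares kept). Deterministic
#' given the seed.
#'
#' @param x Observation matrix.
#' @param k Number of clusters.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside [gap_statistic()]).
#' @param nstart Number of restarts.
#' @return An `ard_clustering`.
#' @export
kmeans_cluster <- function(x, k, seed = NULL, nstart = 10L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L)
  new_clustering("kmeans", k, stats::setNames(km$cluster, rownames(x)),
                 diagnostics = list(tot_withinss = km$tot.withinss))
}

#' PAM (partitioning around medoids) clustering
#'
#' Classic build + swap PAM on the distance matrix via [cluster::pam()];
#' deterministic.
#'
#' @param dm Distance matrix.
#' @param k Number of clusters.
#' @return An `ard_clustering`; `$diagnostics$medoids` holds the medoid
#'   ids and `$diagnostics$cost` the total distance of points to their
#'   medoids.
#' @export
pam_cluster <- function(dm, k) {
  dm <- as_dist(dm)
  fit <- cluster::pam(dm, k = k, diss = TRUE)
  d <- as.matrix(dm)
  med <- fit$medoids
  cost <- sum(apply(d[, med, drop = FALSE], 1, min))
  new_clustering("pam", k, fit$clustering,
                 diagnostics = list(medoids = med, cost = cost))
}

#' Spectral clustering of onset curves
#'
#' Gaussian affinity on Euclidean distances with bandwidth equal to the
#' median pairwise distance, symmetric normalised Laplacian, top-k
#' eigenvector embedding with row normalisation, then k-means on the
#' embedding (10 restarts).
#'
#' @param x Observation matrix.
#' @param k Number of clusters.
#' @param seed Optional seed for the embedded k-means; `NULL` uses the
#'   current stream.
#' @return An `ard_clustering`.
#' @export
spectral_cluster <- function(x, k, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(x)
  if (k == 1) return(new_clustering("spectral", 1,
                                    stats::setNames(rep(1L, n),
                                                    rownames(x))))
  d <- as.matrix(stats::dist(x))
  sigma <- stats::median(d[upper.tri(d)])
  if (sigma <= 0) sigma <- 1  # all points coincide; any labels equivalent
  a <- exp(-d^2 / (2 * sigma^2))
  diag(a) <- 0
  deg <- rowSums(a)
  deg[deg <= 0] <- .Machine$double.eps
  s <- 1 / sqrt(deg)
  m <- a * tcrossprod(s)               # D^{-1/2} A D^{-1/2}
  u <- eigen(m, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms <= 0] <- 1
  km <- stats::kmeans(u / norms, centers = k, nstart = 10L, iter.max = 100L)
  new_clustering("spectral", k, stats::setNames(km$cluster, rownames(x)))
}

#' Dunn validation index
#'
#' Minimum between-cluster point-pair distance divided by the maximum
#' within-cluster diameter. Higher values mean compact, well-separated
#' clusters. If every cluster has zero diameter while clusters are
#' distinct, the index is `Inf` (a flagged sentinel).
#'
#' @param dm Distance matrix.
#' @param labels Cluster labels (>= 2 nonempty clusters).
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
dunn_index <- function(dm, labels) {
  d <- as.matrix(as_dist(dm))
  stopifnot(nrow(d) == length(labels))
  groups <- split(seq_len(nrow(d)), labels)
  if (length(groups) < 2) stop("Dunn index needs at least 2 clusters")
  diam <- max(vapply(groups, function(idx) {
    if (length(idx) < 2) 0 else max(d[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(utils::combn(length(groups), 2, simplify = FALSE),
                    function(pr) min(d[groups[[pr[1]]], groups[[pr[2]]]]),
                    numeric(1)))
  if (diam == 0) {
    warning("all clusters have zero diameter; Dunn index is Inf")
    return(Inf)
  }
  sep / diam
}

#' Pick the clustering with the highest Dunn index
#'
#' Each candidate is expected to have been evaluated at its own gap-chosen
#' k. Ties are broken in favour of hierarchical clustering with average
#' linkage if present, otherwise the first of the tied candidates.
#'
#' @param results List of `ard_clustering` objects.
#' @param dm Distance matrix used to (re)compute any missing Dunn values.
#' @return The winning `ard_clustering`, with the comparison table (data
#'   frame `algorithm`, `k`, `dunn`) attached as attribute `"comparison"`.
#' @export
select_algorithm <- function(results, dm) {
  stopifnot(length(results) >= 1)
  dunn <- vapply(results, function(r) {
    if (!is.null(r$diagnostics$dunn)) r$diagnostics$dunn
    else dunn_index(dm, r$labels)
  }, numeric(1))
  tab <- data.frame(algorithm = vapply(results, `[[`, "", "algorithm"),
                    k = vapply(results, `[[`, 1L, "k"),
                    dunn = dunn)
  tied <- which(dunn >= max(dunn) - 1e-12)
  pick <- tied[1]
  hier <- tied[tab$algorithm[tied] == "hierarchical_average"]
  if (length(hier)) pick <- hier[1]
  best <- results[[pick]]
  best$diagnostics$dunn <- dunn[pick]
  attr(best, "comparison") <- tab
  best
}

#' Split a clustering into main and outlier clusters
#'
#' Clusters with three or more diseases become "main" clusters, relabelled
#' 1..M in descending order of the within-cluster median of their members'
#' median onset ages (so main cluster 1 holds the oldest-onset diseases).
#' Clusters of one or two diseases become "outlier" clusters, ordered the
#' same way.
#'
#' @param clustering An `ard_clustering` (or bare named label vector).
#' @param onset_medians Data frame from [median_age_of_onset()] covering
#'   every clustered disease.
#' @return Data frame of class `ard_partition`: `disease_id`, `cluster`
#'   (original label), `type` (`"main"`/`"outlier"`), `main_label` (1..M or
#'   `NA`), `outlier_label`. Attribute `"summary"` holds per-cluster size
#'   and median-onset summaries.
#' @export
split_main_outlier <- function(clustering, onset_medians) {
  labels <- if (inherits(clustering, "ard_clustering")) clustering$labels
            else clustering
  ids <- names(labels)
  if (is.null(ids)) stop("cluster labels must be named by disease id")
  med <- stats::setNames(onset_medians$median_age, onset_medians$disease_id)
  if (!all(ids %in% names(med)))
    stop("onset medians missing for: ",
         paste(setdiff(ids, names(med)), collapse = ", "))
  groups <- split(ids, labels)
  info <- data.frame(
    cluster = names(groups),
    size = lengths(groups),
    median_onset = vapply(groups, function(g) stats::median(med[g]),
                          numeric(1)))
  info <- info[order(-info$median_onset, info$cluster), ]
  info$type <- ifelse(info$size >= 3, "main", "outlier")
  info$main_label <- NA_integer_
  info$main_label[info$type == "main"] <- seq_len(sum(info$type == "main"))
  info$outlier_label <- NA_integer_
  info$outlier_label[info$type == "outlier"] <-
    seq_len(sum(info$type == "outlier"))
  rownames(info) <- NULL
  i <- match(as.character(labels), info$cluster)
  out <- data.frame(disease_id = ids,
                    cluster = as.character(labels),
                    type = info$type[i],
                    main_label = info$main_label[i],
                    outlier_label = info$outlier_label[i])
  rownames(out) <- NULL
  structure(out, summary = info, class = c("ard_partition", "data.frame"))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical up to label permutation, 0 is the expected agreement
#' of random partitions.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
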