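# Independent brute-force oracles, deliberately naive. They share no code
# with the package internals they check.

# Naive average-linkage agglomeration on a distance matrix. Returns merge
# heights (sorted) and the full cophenetic matrix.
naive_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    heights <- c(heights, best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  list(heights = sort(heights), cophenetic = coph)
}

# Dunn index by full pair enumeration.
naive_dunn <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  sep <- Inf; diam <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) diam <- max(diam, d[i, j])
    else sep <- min(sep, d[i, j])
  }
  sep / diam
}

# Pooled within-cluster dispersion, straight from its definition.
naive_wk <- function(x, labels) {
  total <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- 0
    for (i in idx) for (j in idx)
      s <- s + sum((x[i, ] - x[j, ])^2)
    total <- total + s / (2 * length(idx))
  }
  total
}

# Minimum PAM cost over every medoid subset of size k (exhaustive).
naive_pam_cost <- function(d, k) {
  d <- as.matrix(d)
  subsets <- utils::combn(nrow(d), k, simplify = FALSE)
  min(vapply(subsets, function(med) {
    sum(apply(d[, med, drop = FALSE], 1, min))
  }, numeric(1)))
}

# Counts table from hazards with depletion, mirroring the generator's
# bookkeeping but deterministic (expected counts): used for noise-free
# curve fixtures where q must equal the hazard exactly.
hazard_counts <- function(id, hazard, l0 = 1e6) {
  ages <- 21:84
  # constant at-risk pool: d chosen so d / l equals the hazard exactly
  data.frame(disease_id = id, age = ages,
             d = hazard * l0, l = rep(l0, length(ages)))
}

# Small two-blob curve matrix on the 64-age grid (standardised-curve-like).
two_blob_curves <- function(n_per = 5, sep = 0.5, jitter = 0.005,
                            seed = 42) {
  set.seed(seed)
  base1 <- rep(1 / 64, 64)
  base2 <- base1 + sep * sin(seq(0, pi, length.out = 64)) / 64
  x <- rbind(
    t(replicate(n_per, base1 + rnorm(64, 0, jitter / 64))),
    t(replicate(n_per, base2 + rnorm(64, 0, jitter / 64))))
  rownames(x) <- paste0("d", seq_len(2 * n_per))
  x
}
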