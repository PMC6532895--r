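# Independent oracles used across tests.  These deliberately share no code
# with the package: brute-force enumeration for PAM, a direct textbook
# silhouette, replicate expansion for weights, and a naive O(n^3)
# agglomerative clusterer.

# Globally optimal weighted k-medoids cost by exhaustive enumeration of all
# C(n, k) medoid subsets.
brute_pam_cost <- function(d, w, k) {
  n <- nrow(d)
  subsets <- utils::combn(n, k)
  best <- Inf
  for (j in seq_len(ncol(subsets))) {
    cost <- sum(w * apply(d[, subsets[, j], drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# Textbook unweighted silhouette (Rousseeuw): a_i averages over |C|-1
# others, singleton clusters get s = 0.
silhouette_ref <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, setdiff(own, i)]) / (length(own) - 1L)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1L)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Expand an integer-weighted instance into replicates.
expand_replicates <- function(d, w, labels) {
  idx <- rep(seq_len(nrow(d)), times = w)
  list(d = d[idx, idx, drop = FALSE], labels = labels[idx])
}

# Naive agglomerative hierarchical clustering on a Euclidean data matrix.
# Returns merge heights (increasing) and the partition after each merge.
naive_agglom <- function(X, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  n <- nrow(X)
  d0 <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      pd <- d0[clusters[[i]], clusters[[j]], drop = FALSE]
      h <- if (linkage == "complete") max(pd) else mean(pd)
      if (h < best[1L]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1L])
    merged <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters <- c(clusters[-c(best[2L], best[3L])], list(merged))
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}
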