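#' Weighted k-medoids (PAM) on a dissimilarity matrix
#'
#' Partitioning around medoids with case weights: the objective is the
#' weighted total cost \eqn{\sum_i w_i d(i, medoid(i))}.  Weights enter
#' only through the objective, exactly as if each case were replicated in
#' proportion to its weight; this is what makes clustering aggregated
#' asset-answer profiles equivalent to clustering households.
#'
#' Small instances — those with at most `exact_limit` candidate medoid
#' subsets \eqn{\binom{n}{k}} — are solved *exactly* by enumerating every
#' subset, so the returned cost is the certified global optimum.  Larger
#' instances use the classic BUILD+SWAP search: BUILD seeds k medoids
#' greedily (each new medoid maximizes the weighted cost reduction), SWAP
#' repeatedly applies the single best (medoid, non-medoid) exchange while
#' the cost strictly decreases.  Local search can stop short of the global
#' optimum, which is why small instances are certified instead.  All
#' tie-breaks are deterministic in both paths: equal-cost candidates
#' resolve to the lexicographically first medoid set, equal-cost swaps are
#' rejected, and each observation is labeled to its nearest medoid with
#' ties going to the lowest-indexed medoid.  Results are therefore
#' reproducible for a fixed input order.
#'
#' @param d square symmetric dissimilarity matrix (zero diagonal).
#' @param weights positive finite case weights, one per row of `d`.
#' @param k number of clusters, `2 <= k <= nrow(d)` (`k = nrow(d)` yields
#'   the trivial zero-cost solution).
#' @param exact_limit enumerate all medoid subsets when
#'   `choose(n, k) <= exact_limit`; set to 0 to force BUILD+SWAP.
#' @return an object of class `ec_pam`: list with `medoid_indices`
#'   (increasing), `labels` (cluster 1..k per case, medoids labeled to their
#'   own cluster), `total_cost`, `k`, `method` (`"exact"` or
#'   `"build_swap"`) and the number of swap iterations.
#' @export
weighted_pam <- function(d, weights, k, exact_limit = 5000L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (ncol(d) != n) stop("`d` must be square", call. = FALSE)
  if (length(weights) != n)
    stop("`weights` length must equal the matrix order", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must be in 1..n_profiles", call. = FALSE)

  if (choose(n, k) <= exact_limit) {
    subsets <- utils::combn(n, k)
    costs <- vapply(seq_len(ncol(subsets)), function(j) {
      cols <- subsets[, j]
      dd <- d[, cols[1L]]
      for (c in cols[-1L]) dd <- pmin(dd, d[, c])
      sum(weights * dd)
    }, numeric(1L))
    best <- which.min(costs)          # ties: first = lexicographic subset
    return(finish_pam(d, weights, sort(subsets[, best]), k,
                      method = "exact", iterations = 0L))
  }

  ## BUILD
  medoids <- integer(0)
  dn <- rep(Inf, n)
  for (step in seq_len(k)) {
    if (step == 1L) {
      gain <- -as.vector(weights %*% d)
    } else {
      gain <- colSums(weights * pmax(dn - d, 0))
      gain[medoids] <- -Inf
    }
    new <- which.max(gain)
    medoids <- c(medoids, new)
    dn <- pmin(dn, d[, new])
  }

  ## SWAP (best improvement, strict decrease)
  eps <- 1e-12
  iterations <- 0L
  repeat {
    dm <- d[, medoids, drop = FALSE]
    near_pos <- max.col(-dm, ties.method = "first")
    d1 <- dm[cbind(seq_len(n), near_pos)]
    d2 <- if (k >= 2L) apply(dm, 1L, function(r) sort(r, partial = 2)[2L])
          else rep(Inf, n)
    cost <- sum(weights * d1)
    best <- list(cost = cost)
    non_med <- setdiff(seq_len(n), medoids)
    for (m in sort(medoids)) {
      pos <- match(m, medoids)
      base <- ifelse(near_pos == pos, d2, d1)
      for (h in non_med) {
        newcost <- sum(weights * pmin(base, d[, h]))
        if (newcost < best$cost - eps) best <- list(cost = newcost, m = m, h = h)
      }
    }
    if (is.null(best$m)) break
    medoids[match(best$m, medoids)] <- best$h
    iterations <- iterations + 1L
  }

  finish_pam(d, weights, sort(medoids), k, method = "build_swap",
             iterations = iterations)
}

finish_pam <- function(d, weights, medoids, k, method, iterations) {
  n <- nrow(d)
  dm <- d[, medoids, drop = FALSE]
  labels <- max.col(-dm, ties.method = "first")
  labels[medoids] <- seq_len(k)
  total_cost <- sum(weights * dm[cbind(seq_len(n), labels)])
  structure(list(medoid_indices = medoids, labels = labels,
                 total_cost = total_cost, k = k, method = method,
                 iterations = iterations),
            class = "ec_pam")
}

#' @export
print.ec_pam <- function(x, ...) {
  cat(sprintf("Weighted PAM: k = %d, total cost %.6g, medoids [%s]\n",
              x$k, x$total_cost, paste(x$medoid_indices, collapse = ", ")))
  invisible(x)
}

#' Weighted average silhouette width
#'
#' Silhouette widths under case weights, with weights interpreted as
#' replicate counts.  For case i in cluster C with cluster weight
#' \eqn{W_C}: \eqn{a_i = \sum_{j \in C} w_j d(i,j) / (W_C - 1)} (the j = i
#' term contributes 0, and one "replicate" of i itself is excluded from the
#' denominator), \eqn{b_i = \min_{C' \neq C} \sum_{j \in C'} w_j d(i,j) /
#' W_{C'}}, and \eqn{s_i = (b_i - a_i) / \max(a_i, b_i)}.  When
#' \eqn{\max(a_i, b_i) = 0} or the case's cluster weight is at most 1
#' (an effective singleton), \eqn{s_i = 0}.  The ASW is the weighted mean
#' \eqn{\sum w_i s_i / \sum w_i}.  For integer weights this equals the
#' textbook unweighted silhouette on the replicate-expanded matrix, and for
#' unit weights it is exactly the textbook silhouette.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param weights positive finite case weights.
#' @param labels integer cluster labels (at least 2 non-empty clusters).
#' @return an object of class `ec_silhouette`: list with `widths` (a
#'   data.frame of cluster, neighbor, a, b, s per case) and `asw`.
#' @export
weighted_asw <- function(d, weights, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(weights) == n, length(labels) == n)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  labels <- as.integer(factor(labels))
  ks <- max(labels)
  if (ks < 2L) stop("need at least 2 non-empty clusters", call. = FALSE)
  Z <- matrix(0, n, ks)
  Z[cbind(seq_len(n), labels)] <- 1
  Wc <- as.vector(weights %*% Z)
  if (any(Wc <= 0)) stop("cluster with zero total weight", call. = FALSE)
  M <- d %*% (weights * Z)                 # M[i, c] = sum_{j in c} w_j d(i,j)
  own <- M[cbind(seq_len(n), labels)]
  denom_a <- Wc[labels] - 1
  a <- ifelse(denom_a > 0, own / denom_a, NA_real_)
  Mo <- M / rep(Wc, each = n)
  Mo[cbind(seq_len(n), labels)] <- Inf
  nb_pos <- max.col(-Mo, ties.method = "first")
  b <- Mo[cbind(seq_len(n), nb_pos)]
  s <- numeric(n)
  ok <- Wc[labels] > 1 & pmax(a, b) > 0
  s[ok] <- (b[ok] - a[ok]) / pmax(a[ok], b[ok])
  widths <- data.frame(cluster = labels, neighbor = nb_pos,
                       a = a, b = b, s = s)
  structure(list(widths = widths, asw = sum(weights * s) / sum(weights)),
            class = "ec_silhouette")
}

#' @export
print.ec_silhouette <- function(x, ...) {
  cat(sprintf("Weighted silhouette: ASW = %.4f over %d cases, %d clusters\n",
              x$asw, nrow(x$widths), max(x$widths$cluster)))
  invisible(x)
}
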