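#' Partition habitat nodes into connectivity clusters separated by barriers
#'
#' Deterministic greedy agglomeration with a tunable crossing-probability
#' penalty: starting from singleton clusters, repeatedly merge the cluster
#' pair with the largest mean inter-cluster crossing probability while that
#' maximum exceeds the threshold `theta`. The mean crossing probability
#' between clusters A and B is the mean of the symmetrized connectivity
#' matrix over all cross pairs. On return every remaining inter-cluster mean
#' is at most `theta`, so cluster boundaries mark partial dispersal barriers;
#' raising `theta` demands weaker residual exchange and yields more, smaller
#' clusters. Ties are broken deterministically by the smallest pair of
#' cluster ids (a cluster's id is the smallest node index it contains).
#'
#' @param M a symmetrized [ConnectivityMatrix-class] or symmetric matrix
#'   (symmetrize first; mean mode is the usual choice).
#' @param theta positive mean crossing-probability threshold.
#' @return A [ClusterAssignment-class]; labels are renumbered 1..K in order
#'   of each cluster's first node.
#' @export
clusterConnectivity <- function(M, theta) {
  if (length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    stop("theta must be a single positive number")
  }
  m <- as_conn_matrix(M)
  check_symmetric(m, "connectivity matrix")
  n <- nrow(m)
  ids <- rownames(m) %||% as.character(seq_len(n))

  members <- as.list(seq_len(n))
  # cross-pair sums between current clusters (upper storage, symmetric use)
  S <- m
  diag(S) <- 0
  sizes <- rep(1L, n)
  alive <- rep(TRUE, n)

  pair_mean <- function(a, b) S[a, b] / (sizes[a] * sizes[b])

  repeat {
    act <- which(alive)
    if (length(act) < 2L) break
    best <- c(NA_integer_, NA_integer_); bestVal <- -Inf
    for (ai in seq_along(act)[-length(act)]) {
      a <- act[ai]
      for (b in act[(ai + 1):length(act)]) {
        v <- pair_mean(a, b)
        if (v > bestVal + 1e-15) {
          bestVal <- v; best <- c(a, b)
        }
        # ties: (a, b) scanned in increasing (min id, second id) order, keep first
      }
    }
    if (bestVal <= theta) break
    a <- best[1]; b <- best[2]
    members[[a]] <- c(members[[a]], members[[b]])
    for (k in which(alive)) {
      if (k == a || k == b) next
      S[a, k] <- S[a, k] + S[b, k]
      S[k, a] <- S[a, k]
    }
    sizes[a] <- sizes[a] + sizes[b]
    alive[b] <- FALSE
  }

  act <- which(alive)
  first <- vapply(members[act], min, integer(1))
  ord <- order(first)
  labels <- integer(n)
  for (k in seq_along(ord)) labels[members[[act[ord[k]]]]] <- k
  names(labels) <- ids
  asg <- new("ClusterAssignment", labels = labels, threshold = theta,
             strengths = data.frame(), K = length(act))
  asg@strengths <- barrierStrengths(m, asg)
  validObject(asg)
  asg
}

#' Mean crossing probabilities between clusters
#'
#' One entry per unordered cluster pair: the mean of the symmetrized
#' connectivity matrix over the cross block, i.e. the residual mean barrier
#' crossing probability. For any assignment returned by
#' [clusterConnectivity()], all values are at most the threshold used.
#'
#' @param M the symmetrized connectivity matrix (or [ConnectivityMatrix-class]).
#' @param assignment a [ClusterAssignment-class].
#' @return data.frame with `cluster_a`, `cluster_b`, `mean_crossing`.
#' @export
barrierStrengths <- function(M, assignment) {
  m <- as_conn_matrix(M)
  lab <- assignment@labels
  K <- assignment@K
  if (K < 2L) {
    return(data.frame(cluster_a = integer(), cluster_b = integer(),
                      mean_crossing = numeric()))
  }
  pairs <- utils::combn(seq_len(K), 2)
  data.frame(
    cluster_a = pairs[1, ],
    cluster_b = pairs[2, ],
    mean_crossing = apply(pairs, 2, function(pr) {
      mean(m[lab == pr[1], lab == pr[2], drop = FALSE])
    })
  )
}

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d nodes in %d clusters at theta = %g\n",
              length(object@labels), object@K, object@threshold))
})

#' Cluster counts over a threshold grid
#'
#' Convenience sweep of [clusterConnectivity()] over a grid of thresholds
#' (default 0.001, 0.002, 0.003). Cluster counts are monotone non-decreasing
#' in the threshold.
#'
#' @param M symmetrized connectivity matrix.
#' @param thetas numeric thresholds.
#' @return data.frame with `theta` and `K`.
#' @export
clusterCountSweep <- function(M, thetas = c(0.001, 0.002, 0.003)) {
  data.frame(theta = thetas,
             K = vapply(thetas, function(t) clusterConnectivity(M, t)@K,
                        integer(1)))
}
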