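
# draw one sample from Dirichlet(alpha_vec) via normalized gammas
rdirichlet1 <- function(alpha_vec) {
  g <- stats::rgamma(length(alpha_vec), shape = alpha_vec, rate = 1)
  if (all(g == 0)) g[which.max(alpha_vec)] <- 1
  g / sum(g)
}

# categorical draw of n values from probabilities p (1-based integer labels)
rcat <- function(n, p) {
  sample.int(length(p), size = n, replace = TRUE, prob = p)
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q Non-negative numeric vectors of equal length (normalized
#'   internally).
#' @return A scalar in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p)
  q <- q / sum(q)
  sum(abs(p - q)) / 2
}

#' Match fitted topics to reference topics by total-variation distance
#'
#' Finds the assignment of fitted rows to reference rows minimizing the mean
#' pairwise total-variation distance. Exhaustive over permutations for up to
#' 8 topics, greedy beyond that.
#'
#' @param phi_hat,phi_ref Row-stochastic matrices with the same dimensions.
#' @return A list with `perm` (for each reference row, the matched fitted
#'   row), `tv` (per-pair TV distances in reference order) and `mean_tv`.
#' @export
match_topics <- function(phi_hat, phi_ref) {
  stopifnot(nrow(phi_hat) == nrow(phi_ref), ncol(phi_hat) == ncol(phi_ref))
  K <- nrow(phi_ref)
  cost <- matrix(0, K, K) # cost[i, j] = TV(ref i, fitted j)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) cost[i, j] <- tv_distance(phi_ref[i, ], phi_hat[j, ])
  }
  if (K <= 8) {
    perms <- permutations_of(K)
    costs <- vapply(perms, function(pm) sum(cost[cbind(seq_len(K), pm)]),
                    numeric(1))
    perm <- perms[[which.min(costs)]]
  } else {
    perm <- integer(K)
    free <- rep(TRUE, K)
    for (i in order(apply(cost, 1, min))) {
      j <- which(free)[which.min(cost[i, free])]
      perm[i] <- j
      free[j] <- FALSE
    }
  }
  tv <- cost[cbind(seq_len(K), perm)]
  list(perm = perm, tv = tv, mean_tv = mean(tv))
}

# all permutations of 1..n as a list (n small)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1)
  out <- vector("list", n * length(sub))
  idx <- 1
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1)
      idx <- idx + 1
    }
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] with input checks, used
#' for planted-cluster recovery checks.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI (1 = identical partitions up to relabelling).
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
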