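# k-means++ seeding on rows of x, using the current RNG stream
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

# squared Euclidean distances from every row of x to every center row
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

lloyd <- function(x, centers, max_iter, tol) {
  k <- nrow(centers)
  n <- nrow(x)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) {
        # empty-cluster repair: seize the point farthest from its center
        far <- which.max(d2[cbind(seq_len(n), labels)])
        labels[far] <- j
        members <- labels == j
      }
      new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- dist2_to_centers(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  for (j in seq_len(k)) { # keep every cluster non-empty in the final labelling
    if (!any(labels == j)) {
      far <- which.max(d2[cbind(seq_len(n), labels)])
      labels[far] <- j
      centers[j, ] <- x[far, ]
      d2[, j] <- rowSums((x - matrix(x[far, ], n, ncol(x), byrow = TRUE))^2)
    }
  }
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = inertia, iter = it)
}

#' K-means clustering of encounter embeddings
#'
#' Lloyd's algorithm with k-means++ seeding, `n_init` restarts (best by
#' within-cluster sum of squares), empty-cluster repair by reassigning the
#' point farthest from its centroid, and Euclidean distance on the raw
#' simplex embedding. Deterministic given `seed`.
#'
#' @param embeddings A tibble with `encounter_id` plus numeric embedding
#'   columns (as from [embed_encounters()]), or a bare numeric matrix.
#' @param k Number of clusters (>= 2, at most the number of distinct points).
#' @param seed Integer seed.
#' @param n_init Restarts; default 10.
#' @param max_iter Lloyd iteration cap; default 300.
#' @param tol Centroid-shift convergence tolerance; default 1e-6.
#' @return An object of class `cluster_assignment`: tibble `assignments`
#'   (`encounter_id`, `cluster` 1-based), `centroids`, `inertia`,
#'   `silhouette` (mean), `per_point_silhouette`, `dunn`, and the run
#'   parameters.
#' @export
cluster_embeddings <- function(embeddings, k, seed = 1L, n_init = 10,
                               max_iter = 300, tol = 1e-6) {
  em <- as_embedding_matrix(embeddings)
  x <- em$x
  if (nrow(x) < 2) stop("need at least 2 points", call. = FALSE)
  n_distinct_pts <- nrow(unique(as.data.frame(x)))
  if (k > n_distinct_pts) {
    stop("k (", k, ") exceeds the number of distinct points (",
         n_distinct_pts, ")", call. = FALSE)
  }
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- lloyd(x, kmeanspp_init(x, k), max_iter, tol)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  sil <- silhouette_score(x, best$labels)
  dn <- tryCatch(dunn_index(x, best$labels), error = function(e) NA_real_)
  structure(list(
    assignments = tibble(encounter_id = em$ids, cluster = best$labels),
    k = as.integer(k), centroids = best$centers, inertia = best$inertia,
    silhouette = sil$mean, per_point_silhouette = sil$per_point,
    dunn = dn, seed = as.integer(seed), n_init = n_init,
    iterations = best$iter),
    class = "cluster_assignment")
}

as_embedding_matrix <- function(embeddings) {
  if (is.matrix(embeddings)) {
    ids <- rownames(embeddings)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(embeddings)))
    return(list(x = unname(embeddings), ids = ids))
  }
  stopifnot(is.data.frame(embeddings))
  num_cols <- names(embeddings)[vapply(embeddings, is.numeric, logical(1))]
  ids <- if ("encounter_id" %in% names(embeddings)) {
    as.character(embeddings$encounter_id)
  } else {
    as.character(seq_len(nrow(embeddings)))
  }
  list(x = as.matrix(embeddings[num_cols]), ids = ids)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k =", x$k, "|",
      nrow(x$assignments), "points | inertia", signif(x$inertia, 5),
      "| mean silhouette", signif(x$silhouette, 4),
      "| Dunn", signif(x$dunn, 4), "\n")
  invisible(x)
}

#' Silhouette coefficients
#'
#' Per-point silhouette s = (b - a) / max(a, b), where a is the mean
#' Euclidean distance to other members of the point's cluster (excluding
#' itself) and b the minimum over other clusters of the mean distance to
#' that cluster's members. Points in singleton clusters, and the degenerate
#' case a = b = 0, get s = 0 by convention.
#'
#' @param x Numeric matrix of points (or a tibble of embeddings).
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return List with `mean` and `per_point`.
#' @export
silhouette_score <- function(x, labels) {
  if (is.data.frame(x)) x <- as_embedding_matrix(x)$x
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette needs at least 2 clusters", call. = FALSE)
  }
  n <- nrow(x)
  dm <- as.matrix(stats::dist(x))
  clusters <- sort(unique(labels))
  # mean distance from every point to every cluster
  mean_to <- vapply(clusters, function(cl) {
    members <- labels == cl
    rowSums(dm[, members, drop = FALSE]) / sum(members)
  }, numeric(n))
  sizes <- tabulate(match(labels, clusters))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], clusters)
    ni <- sizes[ci]
    if (ni == 1) { s[i] <- 0; next }
    a <- mean_to[i, ci] * ni / (ni - 1) # exclude self from the average
    b <- min(mean_to[i, -ci])
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  list(mean = mean(s), per_point = s)
}

#' Dunn index
#'
#' Minimum inter-cluster point distance divided by the maximum intra-cluster
#' diameter (both Euclidean). Higher values mean better-separated, more
#' compact clusters; the index is invariant to global rescaling.
#'
#' @inheritParams silhouette_score
#' @return Scalar Dunn index.
#' @export
dunn_index <- function(x, labels) {
  if (is.data.frame(x)) x <- as_embedding_matrix(x)$x
  labels <- as.integer(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("Dunn index needs at least 2 clusters", call. = FALSE)
  dm <- as.matrix(stats::dist(x))
  diam <- max(vapply(clusters, function(cl) {
    members <- which(labels == cl)
    if (length(members) < 2) 0 else max(dm[members, members])
  }, numeric(1)))
  inter <- Inf
  for (i in seq_along(clusters)) {
    for (j in seq_along(clusters)) {
      if (j <= i) next
      mi <- labels == clusters[i]
      mj <- labels == clusters[j]
      inter <- min(inter, min(dm[mi, mj]))
    }
  }
  if (diam == 0) {
    if (inter == 0) stop("Dunn index undefined: coincident zero-diameter clusters",
                         call. = FALSE)
    return(Inf)
  }
  inter / diam
}

#' Choose the number of clusters
#'
#' Fits K-means for every k in the grid and picks the k maximizing the mean
#' silhouette; ties are broken by higher Dunn index, then by smaller k.
#'
#' @param embeddings Embeddings tibble or matrix.
#' @param k_grid Integer vector of candidate cluster counts (each >= 2).
#' @param seed Integer seed (each k uses the same seed policy).
#' @param ... Passed to [cluster_embeddings()].
#' @return An object of class `k_selection`: `metrics` tibble (`k`,
#'   `silhouette`, `dunn`, `inertia`), `chosen_k`, and the winning
#'   `cluster_assignment` as `best_fit`.
#' @export
select_k <- function(embeddings, k_grid, seed = 1L, ...) {
  if (length(k_grid) == 0) stop("k_grid is empty", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 1) warning("k_grid has a single value; choosing k = ", k_grid)
  fits <- purrr::map(k_grid, function(k) {
    cluster_embeddings(embeddings, k = k, seed = seed, ...)
  })
  metrics <- tibble(
    k = k_grid,
    silhouette = vapply(fits, function(f) f$silhouette, numeric(1)),
    dunn = vapply(fits, function(f) f$dunn, numeric(1)),
    inertia = vapply(fits, function(f) f$inertia, numeric(1))
  )
  ord <- order(-metrics$silhouette, -metrics$dunn, metrics$k)
  chosen <- ord[1]
  structure(list(metrics = metrics, chosen_k = k_grid[chosen],
                 best_fit = fits[[chosen]], seed = as.integer(seed)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> chosen k =", x$chosen_k, "\n")
  print(x$metrics)
  invisible(x)
}
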