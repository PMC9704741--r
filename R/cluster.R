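# K-means clustering of (FMA, TEMPA, WMFT) scale triples into ordered
# impairment levels, with silhouette-based selection of K.

# Lloyd iterations with WCSS trace; an emptied cluster is re-seeded at the
# point farthest from its current centroid (which strictly reduces WCSS).
lloyd_once <- function(X, k, iter_max) {
  n <- nrow(X)
  centers <- X[sample.int(n, k), , drop = FALSE]
  assign_pts <- function(centers) {
    d2 <- sapply(seq_len(k), function(j) {
      colSums((t(X) - centers[j, ])^2)
    })
    if (n == 1L) d2 <- matrix(d2, nrow = 1L)
    max.col(-d2, ties.method = "first")
  }
  cl <- assign_pts(centers)
  trace <- numeric(0)
  for (it in seq_len(iter_max)) {
    for (j in seq_len(k)) {
      pts <- which(cl == j)
      if (length(pts) == 0L) {
        # re-seed at the point farthest from its assigned centroid
        far <- which.max(rowSums((X - centers[cl, , drop = FALSE])^2))
        centers[j, ] <- X[far, ]
        cl[far] <- j
      } else {
        centers[j, ] <- colMeans(X[pts, , drop = FALSE])
      }
    }
    new_cl <- assign_pts(centers)
    trace <- c(trace, sum(rowSums((X - centers[new_cl, , drop = FALSE])^2)))
    if (all(new_cl == cl)) {
      cl <- new_cl
      break
    }
    cl <- new_cl
  }
  list(centers = centers, cluster = cl, wcss = tail(trace, 1),
       trace = trace, iter = length(trace))
}

lloyd_kmeans <- function(X, k, nstart = 10, iter_max = 300) {
  best <- NULL
  for (s in seq_len(nstart)) {
    fit <- lloyd_once(X, k, iter_max)
    if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
  }
  best
}

#' Silhouette widths for a clustering
#'
#' For point i with mean within-cluster distance `a(i)` (excluding i) and
#' smallest mean distance to another cluster `b(i)`, the silhouette width
#' is `(b - a) / max(a, b)`, in \[-1, 1\]. Points in singleton clusters
#' contribute 0 by convention. Plain O(n^2) Euclidean computation.
#'
#' @param X Numeric matrix (points in rows).
#' @param labels Integer cluster labels.
#' @return Numeric vector of per-point widths.
#' @export
silhouette_widths <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    others <- setdiff(unique(labels), labels[i])
    if (length(own) == 1L || length(others) == 0L) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(others, function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

scales_matrix <- function(scales, normalize = FALSE) {
  X <- as.matrix(scales[, c("fma", "tempa", "wmft")])
  if (normalize) X <- scale(X)
  X
}

#' K-means clustering of clinical scale triples
#'
#' Maps each (FMA, TEMPA, WMFT) triple to a point in 3-D scale space and
#' runs Lloyd's K-means (best of `nstart` seeded restarts by
#' within-cluster sum of squares, iterated to assignment stability).
#' Clusters are then ordered by ascending centroid score sum, so level 1
#' is the most impaired group; this severity ordering is what makes the
#' level usable as an ordinal target downstream.
#'
#' Scales are clustered in raw score units by default (`normalize =
#' FALSE`), matching a direct mapping of scores to coordinates.
#'
#' @param scales Scales tibble (see [read_scales()]).
#' @param k Number of clusters, `2 <= k <= n`.
#' @param seed Integer seed for the restarts.
#' @param normalize Standardize the three scales before clustering.
#' @param nstart Number of random restarts.
#' @return An object of class `vr_clusters`: centroids (raw units),
#'   per-row `level`, WCSS and its per-iteration trace, mean silhouette,
#'   and the inputs.
#' @seealso [select_k()], [cluster_scales()]
#' @export
kmeans_scales <- function(scales, k, seed = 1L, normalize = FALSE,
                          nstart = 10) {
  scales <- validate_scales(scales)
  X <- scales_matrix(scales, normalize)
  if (k > nrow(X)) abort("`k` cannot exceed the number of triples")
  if (k < 2L) abort("`k` must be at least 2")
  fit <- withr::with_seed(seed, lloyd_kmeans(X, k, nstart))
  # severity order: ascending raw score sum of the cluster means; a
  # cluster emptied by duplicate points keeps the nearest data point
  raw <- scales_matrix(scales)
  raw_centers <- t(vapply(seq_len(k), function(j) {
    pts <- which(fit$cluster == j)
    if (length(pts) > 0L) {
      colMeans(raw[pts, , drop = FALSE])
    } else {
      near <- which.min(colSums((t(X) - fit$centers[j, ])^2))
      raw[near, ]
    }
  }, numeric(3)))
  ord <- order(rowSums(raw_centers))
  level_of <- match(seq_len(k), ord)  # old cluster id -> severity level
  levels <- level_of[fit$cluster]
  sil <- silhouette_widths(X, levels)
  structure(
    list(k = k,
         centroids = tibble(level = seq_len(k),
                            fma = raw_centers[ord, 1],
                            tempa = raw_centers[ord, 2],
                            wmft = raw_centers[ord, 3]),
         data = mutate(scales, level = levels, silhouette = sil),
         wcss = fit$wcss, wcss_trace = fit$trace,
         mean_silhouette = mean(sil), silhouette_by_k = NULL,
         seed = seed, normalize = normalize),
    class = "vr_clusters"
  )
}

#' Select the number of impairment levels by mean silhouette
#'
#' Fits [kmeans_scales()] for each candidate K and scores it by the mean
#' silhouette coefficient; the best K maximises it (ties go to the
#' smaller K).
#'
#' @inheritParams kmeans_scales
#' @param k_candidates Integer candidates, each in `2..n-1`.
#' @return List with `k_best` and `silhouette_by_k` (tibble `k,
#'   mean_silhouette`).
#' @export
select_k <- function(scales, k_candidates = 2:6, seed = 1L,
                     normalize = FALSE) {
  scales <- validate_scales(scales)
  n <- nrow(scales)
  if (any(k_candidates < 2L | k_candidates > n - 1L)) {
    abort("`k_candidates` must lie in 2..(n-1)")
  }
  sil <- vapply(k_candidates, function(k) {
    kmeans_scales(scales, k, seed = seed, normalize = normalize)$mean_silhouette
  }, numeric(1))
  k_best <- k_candidates[order(-sil, k_candidates)[1L]]
  list(k_best = k_best,
       silhouette_by_k = tibble(k = as.integer(k_candidates),
                                mean_silhouette = sil))
}

#' Cluster scale triples into ordered impairment levels
#'
#' The full workflow: silhouette-based selection of K over
#' `k_candidates`, then the final K-means model at the selected K, with
#' the silhouette profile attached.
#'
#' @inheritParams select_k
#' @return A `vr_clusters` model with `silhouette_by_k` filled in.
#' @examples
#' spec <- cohort_spec(seed = 7)
#' coh <- simulate_cohort(spec, sessions = FALSE)
#' m <- cluster_scales(coh$scales)
#' m$k
#' @export
cluster_scales <- function(scales, k_candidates = 2:6, seed = 1L,
                           normalize = FALSE) {
  sel <- select_k(scales, k_candidates, seed, normalize)
  m <- kmeans_scales(scales, sel$k_best, seed = seed, normalize = normalize)
  m$silhouette_by_k <- sel$silhouette_by_k
  m
}

#' Impairment levels and cluster sizes from a fitted model
#'
#' Assigns triples to the nearest centroid (deterministically) and
#' reports per-sample ordered impairment levels plus cluster sizes. With
#' `scales = NULL` the training assignment is returned.
#'
#' @param model A `vr_clusters`.
#' @param scales Optional new scales tibble.
#' @return Tibble `subject, timepoint, level`, with the per-level counts
#'   in `attr(, "sizes")` (sizes sum to n).
#' @export
assign_levels <- function(model, scales = NULL) {
  stopifnot(inherits(model, "vr_clusters"))
  if (is.null(scales)) {
    out <- model$data[, c("subject", "timepoint", "level")]
  } else {
    scales <- validate_scales(scales)
    X <- scales_matrix(scales, model$normalize)
    C <- as.matrix(model$centroids[, c("fma", "tempa", "wmft")])
    if (model$normalize) {
      tr <- scales_matrix(model$data, TRUE)
      C <- scale(C, attr(tr, "scaled:center"), attr(tr, "scaled:scale"))
    }
    d2 <- sapply(seq_len(nrow(C)), function(j) colSums((t(X) - C[j, ])^2))
    if (nrow(X) == 1L) d2 <- matrix(d2, nrow = 1L)
    out <- tibble(subject = scales$subject, timepoint = scales$timepoint,
                  level = max.col(-d2, ties.method = "first"))
  }
  sizes <- tabulate(out$level, nbins = model$k)
  attr(out, "sizes") <- setNames(sizes, paste0("level", seq_len(model$k)))
  out
}

#' @export
print.vr_clusters <- function(x, ...) {
  cat(sprintf("<vr_clusters> k = %d, mean silhouette %.3f, WCSS %.2f (n = %d)\n",
              x$k, x$mean_silhouette, x$wcss, nrow(x$data)))
  print(x$centroids)
  invisible(x)
}

#' @export
tidy.vr_clusters <- function(x, ...) {
  x$data
}

#' @export
glance.vr_clusters <- function(x, ...) {
  tibble(k = x$k, mean_silhouette = x$mean_silhouette, wcss = x$wcss,
         n = nrow(x$data), normalized = x$normalize, seed = x$seed)
}

#' @export
autoplot.vr_clusters <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$fma, y = .data$tempa,
                               colour = factor(.data$level),
                               size = .data$wmft)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_point(data = object$centroids, shape = 4, size = 4,
                        stroke = 2, show.legend = FALSE) +
    ggplot2::labs(x = "FMA (0-22)", y = "TEMPA (0-27)",
                  colour = "Impairment\nlevel", size = "WMFT (0-5)",
                  title = sprintf("Scale-triple clusters (k = %d)",
                                  object$k)) +
    ggplot2::theme_minimal()
}
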