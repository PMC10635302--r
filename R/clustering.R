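#' Topological clustering with functional-mean centroids
#'
#' Lloyd-style k-centroids clustering of subjects by their heat-kernel
#' coefficient vectors.  Distances are the weighted L2 distance of the
#' heat-kernel representation, which is plain squared Euclidean distance in
#' the embedded space \eqn{x_k = e^{-\lambda_k \sigma/2} f_k}; centroids are
#' coordinate-wise means there, i.e. exactly the functional means of the
#' heat-kernel estimates.  Initial centroids are seeded k-means++ style
#' (first uniform, then each next centroid drawn among the subjects with
#' probability proportional to squared distance from the chosen set); an
#' empty cluster during iteration is
#' re-seeded at the subject farthest from its centroid.  The best of
#' `n_init` restarts by inertia is returned.
#'
#' @param coeff_list list of [fourier_coefficients()] sharing one basis.
#' @param K number of clusters (<= number of subjects).
#' @param sigma bandwidth.
#' @param eigenvalues basis eigenvalues (or an `lb_basis`).
#' @param n_init random restarts (default 100).
#' @param max_iter Lloyd iteration cap per restart.
#' @param seed integer RNG seed.
#' @return An object of class `pd_clusters`: `assignments`, `centroids`
#'   (K x (kappa+1), in embedded coordinates), `inertia`, `n_iter`, `seed`,
#'   `inertia_path` of the winning restart.
#' @export
fit_clusters <- function(coeff_list, K, sigma = 0.1, eigenvalues,
                         n_init = 100, max_iter = 100, seed = NULL) {
  if (inherits(eigenvalues, "lb_basis")) eigenvalues <- eigenvalues$eigenvalues
  X <- hk_embed(coeff_list, eigenvalues, sigma)
  N <- nrow(X)
  if (K < 1 || K > N) stop("'K' must be between 1 and the number of subjects")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    res <- lloyd_once(X, K, max_iter)
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }
  structure(
    list(assignments = best$assignments, centroids = best$centroids,
         inertia = best$inertia, n_iter = best$n_iter, seed = seed,
         inertia_path = best$path, K = K, sigma = sigma),
    class = "pd_clusters"
  )
}

# one Lloyd run with k-means++ seeding (next center drawn with probability
# proportional to squared distance from the chosen set) on embedded X
lloyd_once <- function(X, K, max_iter) {
  N <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  first <- sample.int(N, 1)
  centers[1, ] <- X[first, ]
  if (K > 1) {
    d2 <- colSums((t(X) - centers[1, ])^2)
    for (k in 2:K) {
      pick <- if (sum(d2) > 0) sample.int(N, 1, prob = d2) else sample.int(N, 1)
      centers[k, ] <- X[pick, ]
      d2 <- pmin(d2, colSums((t(X) - centers[k, ])^2))
    }
  }
  assign_step <- function(centers) {
    D <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(centers) +
      outer(rep(1, N), rowSums(centers^2))
    max.col(-D, ties.method = "first")
  }
  path <- numeric(0)
  asg <- assign_step(centers)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      idx <- which(asg == k)
      if (!length(idx)) {
        # empty cluster: re-seed at the subject farthest from its centroid
        dists <- rowSums((X - centers[asg, , drop = FALSE])^2)
        far <- which.max(dists)
        centers[k, ] <- X[far, ]
        asg[far] <- k
        idx <- far
      }
      centers[k, ] <- colMeans(X[idx, , drop = FALSE])
    }
    new_asg <- assign_step(centers)
    inertia <- sum(rowSums((X - centers[new_asg, , drop = FALSE])^2))
    path <- c(path, inertia)
    if (all(new_asg == asg)) { asg <- new_asg; break }
    asg <- new_asg
  }
  list(assignments = asg, centroids = centers,
       inertia = sum(rowSums((X - centers[asg, , drop = FALSE])^2)),
       n_iter = length(path), path = path)
}

#' @export
print.pd_clusters <- function(x, ...) {
  cat(sprintf("Topological clustering: K = %d, inertia = %.6g (%d iterations)\n",
              x$K, x$inertia, x$n_iter))
  cat("  sizes:", paste(tabulate(x$assignments, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Consistency of clustering across repetitions
#'
#' Repeats [fit_clusters()] with independent initializations and reports the
#' mean pairwise adjusted Rand index across repeat assignments
#' (label-permutation invariant; 1 = identical partitions, ~0 = chance).
#'
#' @param coeff_list list of [fourier_coefficients()].
#' @param K number of clusters.
#' @param n_repeats repetitions (>= 2).
#' @param sigma bandwidth.
#' @param eigenvalues basis eigenvalues (or an `lb_basis`).
#' @param n_init restarts per repetition (default 10 for speed; each
#'   repetition is already an independent run).
#' @param seed integer RNG seed.
#' @return list with `consistency` (mean pairwise ARI) and `assignments`
#'   (n_repeats x N matrix).
#' @export
consistency_over_repeats <- function(coeff_list, K, n_repeats = 100,
                                     sigma = 0.1, eigenvalues, n_init = 10,
                                     seed = NULL) {
  if (n_repeats < 2) stop("'n_repeats' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  asg <- t(vapply(seq_len(n_repeats), function(r) {
    fit_clusters(coeff_list, K, sigma, eigenvalues, n_init = n_init)$assignments
  }, integer(length(coeff_list))))
  pairs <- utils::combn(n_repeats, 2)
  ari <- apply(pairs, 2, function(pr)
    mclust::adjustedRandIndex(asg[pr[1], ], asg[pr[2], ]))
  list(consistency = mean(ari), assignments = asg)
}

#' Per-K clustering fit summary
#'
#' Reports inertia, mean silhouette width under the weighted L2 metric, and
#' repeat-consistency for each candidate K.  No winner is chosen: the report
#' is the output.
#'
#' @param coeff_list list of [fourier_coefficients()].
#' @param k_range integer vector of candidate K in `[2, N - 1]`.
#' @param sigma bandwidth.
#' @param eigenvalues basis eigenvalues (or an `lb_basis`).
#' @param n_repeats repetitions for the consistency column.
#' @param seed integer RNG seed.
#' @return data.frame with columns `K`, `inertia`, `silhouette`,
#'   `consistency`.
#' @export
select_k <- function(coeff_list, k_range, sigma = 0.1, eigenvalues,
                     n_repeats = 20, seed = NULL) {
  N <- length(coeff_list)
  if (any(k_range < 2 | k_range > N - 1))
    stop("'k_range' must lie in [2, N - 1]")
  if (inherits(eigenvalues, "lb_basis")) eigenvalues <- eigenvalues$eigenvalues
  D <- pairwise_distance_matrix(coeff_list, sigma, eigenvalues)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(k_range, function(K) {
    fit <- fit_clusters(coeff_list, K, sigma, eigenvalues, n_init = 20)
    cons <- consistency_over_repeats(coeff_list, K, n_repeats = n_repeats,
                                     sigma = sigma, eigenvalues = eigenvalues,
                                     n_init = 5)
    data.frame(K = K, inertia = fit$inertia,
               silhouette = mean_silhouette(D, fit$assignments),
               consistency = cons$consistency)
  })
  do.call(rbind, rows)
}

# mean silhouette width from a squared-distance matrix and assignments
mean_silhouette <- function(D, asg) {
  N <- nrow(D)
  s <- numeric(N)
  for (i in seq_len(N)) {
    own <- which(asg == asg[i]); own <- own[own != i]
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(asg), asg[i]),
                    function(g) mean(D[i, asg == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
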