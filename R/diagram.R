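#' Persistence diagram object
#'
#' A multiset of (birth, death) points of a fixed homology dimension.
#' Finite points must satisfy death > birth; violations are an error.
#'
#' @param points 2-column numeric matrix (birth, death); zero rows allowed.
#' @param dimension homology dimension, 0 or 1.
#' @param filtration_max the cap value used to finitize infinite bars (kept
#'   as metadata).
#' @return An object of class `persistence_diagram`.
#' @export
persistence_diagram <- function(points, dimension, filtration_max = Inf) {
  points <- matrix(as.numeric(points), ncol = 2)
  colnames(points) <- c("birth", "death")
  if (!dimension %in% c(0, 1)) stop("'dimension' must be 0 or 1")
  if (nrow(points) && any(points[, 2] <= points[, 1]))
    stop("all diagram points must satisfy death > birth")
  structure(
    list(points = points, dimension = as.integer(dimension),
         filtration_max = filtration_max),
    class = "persistence_diagram"
  )
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram (dimension %d): %d points\n",
              x$dimension, nrow(x$points)))
  if (nrow(x$points)) {
    pers <- x$points[, 2] - x$points[, 1]
    cat(sprintf("  max persistence %.4g, median %.4g\n",
                max(pers), stats::median(pers)))
  }
  invisible(x)
}

#' Point cloud object
#'
#' @param points 2-column numeric matrix of planar coordinates.
#' @param label free-text provenance tag.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, label = "") {
  points <- matrix(as.numeric(points), ncol = 2)
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  structure(list(points = points, label = label), class = "point_cloud")
}

#' Weighted undirected network object
#'
#' @param weights symmetric p x p numeric matrix of edge weights; the
#'   diagonal is ignored.
#' @param node_ids optional node labels (defaults to row names or indices).
#' @param tol symmetry tolerance.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, node_ids = NULL, tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("'weights' must be square")
  if (any(is.na(weights[row(weights) != col(weights)]))) {
    bad <- which(is.na(weights) & row(weights) != col(weights), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN/NA weight at (%d, %d)", bad[1], bad[2]))
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    bad <- which(abs(weights - t(weights)) == asym, arr.ind = TRUE)[1, ]
    stop(sprintf("weight matrix asymmetric beyond tolerance at (%d, %d): |w - t(w)| = %g",
                 bad[1], bad[2], asym))
  }
  if (is.null(node_ids)) node_ids <- rownames(weights)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(weights)))
  structure(list(node_ids = node_ids, weights = (weights + t(weights)) / 2),
            class = "weighted_network")
}

# shared driver over a pairwise filtration-value matrix
flag_diagrams <- function(dist, max_dimension, max_radius, filtration_max,
                          drop_infinite0 = TRUE) {
  res <- rips_pairs_cpp(dist, max_radius, max_dimension)
  out <- list()
  d0 <- cbind(birth = rep(0, length(res$dim0_deaths)), death = res$dim0_deaths)
  d0 <- d0[d0[, 2] > 0, , drop = FALSE]
  if (!drop_infinite0 && is.finite(filtration_max) && res$n_infinite0 > 0) {
    extra <- cbind(birth = rep(0, res$n_infinite0),
                   death = rep(filtration_max, res$n_infinite0))
    extra <- extra[extra[, 2] > 0, , drop = FALSE]
    d0 <- rbind(d0, extra)
  }
  out$dim0 <- persistence_diagram(d0, 0, filtration_max)
  if (max_dimension >= 1) {
    d1 <- res$dim1_pairs
    ub <- res$dim1_unpaired_births
    if (length(ub) && is.finite(filtration_max)) {
      extra <- cbind(ub, rep(filtration_max, length(ub)))
      extra <- extra[extra[, 2] > extra[, 1], , drop = FALSE]
      d1 <- rbind(d1, extra)
    }
    out$dim1 <- persistence_diagram(d1, 1, filtration_max)
  }
  out
}

#' Rips persistence diagrams of a point cloud
#'
#' Builds the Vietoris-Rips filtration on the Euclidean pairwise distances
#' and extracts persistence diagrams of dimensions 0 (components) and 1
#' (cycles).  Dimension-0 bars are all born at 0; the single component alive
#' at `max_radius` is dropped by default (configurable cap).  Dimension-1
#' cycles still open at `max_radius` are capped at `max_radius`.
#'
#' @param cloud a [point_cloud()] (or bare 2-column matrix).
#' @param max_dimension 0 or 1.
#' @param max_radius filtration cap; default is the enclosing-box diagonal,
#'   which guarantees every finite feature closes.
#' @param drop_infinite0 drop (TRUE, default) or cap the infinite
#'   dimension-0 bar.
#' @return Named list of `persistence_diagram`s (`dim0`, and `dim1` when
#'   requested).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' pd <- rips_diagram(point_cloud(cbind(cos(th), sin(th))), max_dimension = 1)
#' pd$dim1
#' @export
rips_diagram <- function(cloud, max_dimension = 1, max_radius = NULL,
                         drop_infinite0 = TRUE) {
  if (!inherits(cloud, "point_cloud")) cloud <- point_cloud(cloud)
  pts <- cloud$points
  if (nrow(pts) < 2) {
    warning("fewer than 2 points: returning empty diagrams")
    out <- list(dim0 = persistence_diagram(matrix(0, 0, 2), 0))
    if (max_dimension >= 1) out$dim1 <- persistence_diagram(matrix(0, 0, 2), 1)
    return(out)
  }
  if (is.null(max_radius)) {
    rng <- apply(pts, 2, range)
    max_radius <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  }
  if (max_radius <= 0) stop("'max_radius' must be positive")
  flag_diagrams(as.matrix(stats::dist(pts)), max_dimension, max_radius,
                filtration_max = max_radius, drop_infinite0 = drop_infinite0)
}

#' Persistence diagrams of a weighted network
#'
#' Treats transformed edge weights as pairwise filtration values of a flag
#' (Rips) filtration: an edge enters when its transformed weight drops below
#' the filtration value, so the subgraphs are nested as the filtration value
#' grows.
#'
#' @param network a [weighted_network()].
#' @param max_dimension 0 or 1.
#' @param transform `"identity"` thresholds raw weights from below (use for
#'   dissimilarity-like weights); `"one_minus_abs"` thresholds `1 - |w|`,
#'   the convention for correlation matrices where strong connections enter
#'   first.  There is no default: the weight semantics must be declared.
#' @param max_radius filtration cap; default is the maximum transformed
#'   weight.
#' @param drop_infinite0 see [rips_diagram()].
#' @return Named list of `persistence_diagram`s.
#' @export
network_diagram <- function(network, max_dimension = 1,
                            transform = c("identity", "one_minus_abs"),
                            max_radius = NULL, drop_infinite0 = TRUE) {
  if (!inherits(network, "weighted_network")) stop("'network' must be a weighted_network")
  transform <- match.arg(transform)
  w <- network$weights
  f <- switch(transform, identity = w, one_minus_abs = 1 - abs(w))
  diag(f) <- 0
  if (is.null(max_radius)) max_radius <- max(f)
  flag_diagrams(f, max_dimension, max_radius, filtration_max = max_radius,
                drop_infinite0 = drop_infinite0)
}

#' Standardize a persistence diagram into the triangular domain
#'
#' Applies the pooled min-max map fitted by [fit_standardization()] (fitted
#' on the whole analysis set, never per diagram).  Point order is preserved.
#'
#' @param pd a [persistence_diagram()].
#' @param domain a [triangle_domain()] with a fitted standardization.
#' @return The standardized `persistence_diagram` (same dimension tag).
#' @export
standardize_diagram <- function(pd, domain) {
  stopifnot(inherits(pd, "persistence_diagram"))
  if (is.null(domain$standardization))
    stop("standardization map has not been fitted; see fit_standardization()")
  if (!nrow(pd$points)) return(pd)
  mapped <- apply_standardization(domain, pd$points)
  if (!all(in_domain(domain, mapped, tol = 1e-9)))
    stop("standardized point falls outside the domain; the map was fitted on the wrong pool")
  out <- pd
  out$points <- mapped
  colnames(out$points) <- c("birth", "death")
  attr(out, "standardized") <- TRUE
  out
}
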