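#' Standardized triangular birth-death domain
#'
#' Persistence diagrams live in the open half plane above the diagonal
#' (death > birth).  For spectral smoothing the domain must be bounded, so
#' raw birth/death coordinates are standardized into a fixed right isosceles
#' triangle.  The default triangle has vertices (0,0), (0,1), (1,1), i.e.
#' \eqn{0 \le x \le y \le 1}, which is the image of any min-max rescaled
#' diagram because death always exceeds birth.
#'
#' @param vertices 3x2 numeric matrix of triangle vertices (rows).  The
#'   default is the standardized triangle above the diagonal of the unit
#'   square.
#' @return An object of class `triangle_domain` with fields `vertices` and
#'   `area`, plus an (initially unfitted) standardization map.
#' @seealso [fit_standardization()], [standardize_diagram()]
#' @export
triangle_domain <- function(vertices = rbind(c(0, 0), c(0, 1), c(1, 1))) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || any(dim(vertices) != c(3L, 2L)))
    stop("'vertices' must be a 3x2 numeric matrix")
  a <- signed_area2(vertices[1, ], vertices[2, ], vertices[3, ])
  if (abs(a) < 1e-12) stop("triangle vertices are collinear")
  structure(
    list(vertices = vertices, area = abs(a), standardization = NULL),
    class = "triangle_domain"
  )
}

# twice-signed-area helper: positive if a,b,c counterclockwise
signed_area2 <- function(a, b, c) {
  ((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
}

#' @export
print.triangle_domain <- function(x, ...) {
  cat("Standardized triangular domain\n")
  cat("  vertices:", paste(sprintf("(%g, %g)", x$vertices[, 1], x$vertices[, 2]),
                           collapse = " "), "\n")
  cat("  area:", format(x$area), "\n")
  if (is.null(x$standardization)) {
    cat("  standardization: <not fitted>\n")
  } else {
    s <- x$standardization
    cat(sprintf("  standardization: offset %g, scale %g, margin %g\n",
                s$offset, s$scale, s$margin))
  }
  invisible(x)
}

#' Fit the pooled min-max standardization map
#'
#' The affine map taking raw birth/death coordinates into the standardized
#' triangle is fitted once per analysis on the pooled coordinate range of all
#' diagrams entering that analysis (never per diagram, so that diagrams stay
#' comparable).  A small interior margin keeps standardized points off the
#' triangle boundary.
#'
#' @param pds a single `persistence_diagram` or a list of them.
#' @param domain a [triangle_domain()].
#' @param margin fraction of the unit range reserved on each side
#'   (default 0.01); the pooled range maps onto `[margin, 1 - margin]`.
#' @return The domain with a fitted `standardization` (offset, scale, margin).
#'   A degenerate pool (zero coordinate range) maps everything to the triangle
#'   centroid.
#' @export
fit_standardization <- function(pds, domain = triangle_domain(), margin = 0.01) {
  if (inherits(pds, "persistence_diagram")) pds <- list(pds)
  if (!length(pds)) stop("no diagrams supplied")
  if (margin < 0 || margin >= 0.5) stop("'margin' must be in [0, 0.5)")
  vals <- unlist(lapply(pds, function(d) as.vector(d$points)), use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    # all diagrams empty: identity-style placeholder map
    lo <- 0; hi <- 1
  } else {
    lo <- min(vals); hi <- max(vals)
  }
  rng <- hi - lo
  s <- if (rng > 0) {
    list(offset = lo, scale = 1 / rng, margin = margin, degenerate = FALSE)
  } else {
    list(offset = lo, scale = 1, margin = margin, degenerate = TRUE)
  }
  domain$standardization <- s
  domain
}

# apply the fitted map to a 2-column matrix of raw (birth, death) points
apply_standardization <- function(domain, xy) {
  s <- domain$standardization
  if (is.null(s)) stop("standardization map has not been fitted; see fit_standardization()")
  if (!nrow(xy)) return(xy)
  if (isTRUE(s$degenerate)) {
    ctr <- colMeans(domain$vertices)
    return(matrix(rep(ctr, each = nrow(xy)), ncol = 2))
  }
  u <- (xy - s$offset) * s$scale              # into [0,1], y > x preserved
  s$margin + u * (1 - 2 * s$margin)
}

#' Test whether points lie inside the standardized triangle
#'
#' @param domain a [triangle_domain()].
#' @param xy n x 2 matrix of points.
#' @param tol boundary tolerance.
#' @return logical vector.
#' @export
in_domain <- function(domain, xy, tol = 1e-9) {
  xy <- rbind(xy)
  v <- domain$vertices
  s1 <- apply(xy, 1, function(p) signed_area2(v[1, ], v[2, ], p))
  s2 <- apply(xy, 1, function(p) signed_area2(v[2, ], v[3, ], p))
  s3 <- apply(xy, 1, function(p) signed_area2(v[3, ], v[1, ], p))
  a <- signed_area2(v[1, ], v[2, ], v[3, ])
  sgn <- sign(a)
  (sgn * s1 >= -tol) & (sgn * s2 >= -tol) & (sgn * s3 >= -tol)
}
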