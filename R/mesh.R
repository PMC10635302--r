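#' Structured triangulation of the standardized domain
#'
#' Subdivides the triangle uniformly on a barycentric lattice: with `n`
#' subdivisions per leg the triangle splits into `n^2` congruent elements and
#' `(n+1)(n+2)/2` nodes.  Boundary nodes lie exactly on the triangle boundary
#' and element areas sum exactly to the domain area.
#'
#' @param domain a [triangle_domain()].
#' @param resolution target edge length along the triangle legs; `n` is the
#'   smallest integer with leg length / n <= resolution.
#' @return An object of class `triangle_mesh`: `nodes` (N x 2), `elements`
#'   (M x 3 node-index triples, counterclockwise), `n` (subdivision count),
#'   `resolution`, `domain`.
#' @export
build_triangle_mesh <- function(domain, resolution) {
  if (!inherits(domain, "triangle_domain")) stop("'domain' must be a triangle_domain")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("'resolution' must be a positive number")
  v <- domain$vertices
  edge_len <- c(sqrt(sum((v[2, ] - v[1, ])^2)),
                sqrt(sum((v[3, ] - v[2, ])^2)),
                sqrt(sum((v[3, ] - v[1, ])^2)))
  leg <- min(edge_len)
  n <- max(1L, as.integer(ceiling(leg / resolution - 1e-9)))

  e1 <- v[2, ] - v[1, ]
  e2 <- v[3, ] - v[1, ]
  # lattice nodes: v1 + (i*e1 + j*e2)/n for i + j <= n
  idx <- matrix(0L, n + 1L, n + 1L)   # idx[i+1, j+1] -> node id
  nodes <- matrix(0, (n + 1L) * (n + 2L) / 2L, 2L)
  k <- 0L
  for (i in 0:n) for (j in 0:(n - i)) {
    k <- k + 1L
    idx[i + 1L, j + 1L] <- k
    nodes[k, ] <- v[1, ] + (i * e1 + j * e2) / n
  }
  elements <- matrix(0L, n * n, 3L)
  m <- 0L
  for (i in 0:(n - 1L)) for (j in 0:(n - 1L - i)) {
    m <- m + 1L
    elements[m, ] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L], idx[i + 1L, j + 2L])
    if (i + j <= n - 2L) {
      m <- m + 1L
      elements[m, ] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L], idx[i + 1L, j + 2L])
    }
  }
  elements <- elements[seq_len(m), , drop = FALSE]
  # enforce counterclockwise orientation
  for (r in seq_len(nrow(elements))) {
    tri <- elements[r, ]
    if (signed_area2(nodes[tri[1], ], nodes[tri[2], ], nodes[tri[3], ]) < 0)
      elements[r, ] <- tri[c(1L, 3L, 2L)]
  }
  structure(
    list(nodes = nodes, elements = elements, n = n,
         resolution = resolution, domain = domain, lattice_index = idx),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d nodes, %d elements (n = %d per leg)\n",
              nrow(x$nodes), nrow(x$elements), x$n))
  invisible(x)
}

# P1 finite-element mass and stiffness matrices on a triangle_mesh.
# Returns list(mass, stiffness) as sparse symmetric matrices.
fem_matrices <- function(mesh, mass_lumping = FALSE) {
  nodes <- mesh$nodes
  el <- mesh$elements
  ne <- nrow(el)
  ii <- integer(9L * ne); jj <- integer(9L * ne)
  kv <- numeric(9L * ne); mv <- numeric(9L * ne)
  pos <- 0L
  for (e in seq_len(ne)) {
    tri <- el[e, ]
    p <- nodes[tri, , drop = FALSE]
    area <- signed_area2(p[1, ], p[2, ], p[3, ])
    # gradients of the barycentric basis functions
    b <- c(p[2, 2] - p[3, 2], p[3, 2] - p[1, 2], p[1, 2] - p[2, 2])
    c_ <- c(p[3, 1] - p[2, 1], p[1, 1] - p[3, 1], p[2, 1] - p[1, 1])
    Ke <- (outer(b, b) + outer(c_, c_)) / (4 * area)
    Me <- if (mass_lumping) diag(rep(area / 3, 3)) else
      area / 12 * (matrix(1, 3, 3) + diag(3))
    rng <- pos + 1:9
    ii[rng] <- rep(tri, times = 3)
    jj[rng] <- rep(tri, each = 3)
    kv[rng] <- as.vector(Ke)
    mv[rng] <- as.vector(Me)
    pos <- pos + 9L
  }
  N <- nrow(nodes)
  list(
    mass = Matrix::sparseMatrix(i = ii, j = jj, x = mv, dims = c(N, N)),
    stiffness = Matrix::sparseMatrix(i = ii, j = jj, x = kv, dims = c(N, N))
  )
}

# Locate points in the structured mesh.  Returns list(inside, tri, bary):
# tri holds the node indices of the containing element, bary the barycentric
# weights with respect to those nodes.
locate_points <- function(mesh, xy, tol = 1e-8) {
  xy <- rbind(xy)
  np <- nrow(xy)
  v <- mesh$domain$vertices
  e1 <- v[2, ] - v[1, ]
  e2 <- v[3, ] - v[1, ]
  A <- cbind(e1, e2)
  ab <- t(solve(A, t(sweep(xy, 2, v[1, ]))))    # lattice coordinates
  n <- mesh$n
  inside <- logical(np)
  tris <- matrix(0L, np, 3L)
  bary <- matrix(0, np, 3L)
  for (r in seq_len(np)) {
    a <- ab[r, 1]; b <- ab[r, 2]
    if (a < -tol || b < -tol || a + b > 1 + tol) next
    a <- min(max(a, 0), 1); b <- min(max(b, 0), 1)
    if (a + b > 1) { s <- a + b; a <- a / s; b <- b / s }
    i <- min(as.integer(floor(a * n)), n - 1L)
    j <- min(as.integer(floor(b * n)), n - 1L)
    while (i + j > n - 1L) { if (i >= j) i <- i - 1L else j <- j - 1L }
    u <- a * n - i; w <- b * n - j
    if (u + w <= 1 + 1e-12 || i + j == n - 1L) {
      if (u + w > 1) { s <- u + w; u <- u / s; w <- w / s }
      tris[r, ] <- c(mesh$lattice_index[i + 1L, j + 1L],
                     mesh$lattice_index[i + 2L, j + 1L],
                     mesh$lattice_index[i + 1L, j + 2L])
      bary[r, ] <- c(1 - u - w, u, w)
    } else {
      tris[r, ] <- c(mesh$lattice_index[i + 2L, j + 1L],
                     mesh$lattice_index[i + 2L, j + 2L],
                     mesh$lattice_index[i + 1L, j + 2L])
      bary[r, ] <- c(1 - w, u + w - 1, 1 - u)
    }
    inside[r] <- TRUE
  }
  list(inside = inside, tri = tris, bary = bary)
}
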