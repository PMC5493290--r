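#' Circumcenter of a triangle
#'
#' The dual Voronoi vertex of a Delaunay triangle is the centre of its
#' circumscribed circle.  Internally the equidistance conditions are solved
#' as a 2 x 2 linear system, the closed form equivalent to the barycentric
#' combination of the three corners with weights
#' \eqn{\lambda_i = \ell_i^2 (\ell_j^2 + \ell_k^2 - \ell_i^2)}.
#'
#' @param p1,p2,p3 numeric length-2 vectors (triangle corners).
#' @param ids optional length-3 labels used in the degeneracy error message.
#' @return numeric length-2 circumcenter.
#' @examples
#' circumcenter(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))  # equilateral: centroid
#' @export
circumcenter <- function(p1, p2, p3, ids = 1:3) {
  u <- p2 - p1
  w <- p3 - p1
  det <- 2 * (u[1] * w[2] - u[2] * w[1])
  if (abs(det) < 1e-14 * max(sum(u^2), sum(w^2), 1e-300))
    stop(sprintf("degenerate triangle: sites %s are collinear",
                 paste(ids, collapse = ", ")))
  u2 <- sum(u^2); w2 <- sum(w^2)
  c(p1[1] + (w[2] * u2 - u[2] * w2) / det,
    p1[2] + (u[1] * w2 - w[1] * u2) / det)
}

#' Build the Delaunay triangulation of a tissue from scratch
#'
#' Incremental (Bowyer-Watson) construction over all particles followed by a
#' certifying equiangulation pass.  Every interior particle must end up
#' completely surrounded by triangles; this is guaranteed when the boundary
#' ghosts enclose all interior particles.
#'
#' @param tissue a [Tissue-class] object.
#' @return the tissue with a current (non-stale) Delaunay mesh.
#' @export
buildTriangulation <- function(tissue) {
  tri <- cpp_delaunay(tissue@pos)
  res <- cpp_equiangulate(tissue@pos, tri)
  tissue@triangles <- res$triangles
  tissue@stale <- FALSE
  tissue
}

#' Restore the Delaunay property by equiangulation edge flips
#'
#' For every interior edge the sum of the two opposite angles is examined;
#' if it exceeds 180 degrees (strictly -- cocircular ties are not flipped)
#' the edge is flipped.  Flips are processed from a FIFO queue, re-queueing
#' the four quadrilateral edges after each flip, which is guaranteed to
#' converge to the Delaunay triangulation.  Each flip replaces one Voronoi
#' junction and is the elementary T1 neighbour-exchange event when all four
#' involved particles are interior cells.
#'
#' @param tissue a [Tissue-class] object with a (possibly stale) mesh.
#' @return list with elements `tissue` (updated, mesh current), `nFlips`,
#'   and `flipped`: an integer matrix with one row per flip giving the two
#'   sites that lost a junction (old1, old2) and the two that gained one
#'   (new1, new2).
#' @export
equiangulate <- function(tissue) {
  if (nrow(tissue@triangles) == 0L)
    stop("no triangulation to equiangulate; call buildTriangulation() first")
  res <- cpp_equiangulate(tissue@pos, tissue@triangles)
  tissue@triangles <- res$triangles
  tissue@stale <- FALSE
  list(tissue = tissue, nFlips = res$n_flips, flipped = res$flipped)
}

#' Dual Voronoi cells of all interior particles
#'
#' Each interior particle's cell polygon is the CCW-ordered sequence of
#' circumcenters of its incident Delaunay triangles.  Areas are shoelace
#' values of that polygon and perimeters the summed vertex distances.
#'
#' @param tissue a [Tissue-class] object with a current Delaunay mesh.
#' @return a list with components `site` (particle row index per cell),
#'   `area`, `perimeter`, `vertices` (list of m x 2 CCW polygon matrices),
#'   `neighbours` (list of the particle indices dual to each polygon edge,
#'   edge mu running from vertex mu to mu+1) and `circumcenters`.
#' @export
dualCells <- function(tissue) {
  checkMesh(tissue)
  g <- cpp_cell_geometry(tissue@pos, tissue@triangles, isInterior(tissue))
  nc <- length(g$site)
  verts <- nbrs <- vector("list", nc)
  for (c in seq_len(nc)) {
    idx <- (g$ptr[c] + 1L):g$ptr[c + 1L]
    verts[[c]] <- g$circumcenters[g$fan_tri[idx], , drop = FALSE]
    nbrs[[c]] <- g$fan_nbr[idx]
  }
  list(site = g$site, area = g$area, perimeter = g$perimeter,
       vertices = verts, neighbours = nbrs, circumcenters = g$circumcenters)
}

#' Jacobian of a Voronoi vertex with respect to one of its Delaunay sites
#'
#' Analytic derivative of the circumcenter of triangle `triangle` (row of
#' the mesh) with respect to the position of `site`.  The three per-site
#' Jacobians of one vertex sum to the identity (translating all three sites
#' translates the circumcenter).
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @param triangle triangle row index (the Voronoi vertex id).
#' @param site particle row index; must be a corner of the triangle.
#' @return a 2 x 2 numeric matrix d(circumcenter)/d(site position).
#' @export
vertexJacobian <- function(tissue, triangle, site) {
  tr <- tissue@triangles[triangle, ]
  if (!site %in% tr) stop("site is not a corner of this triangle")
  p <- tissue@pos
  corner <- match(site, tr)
  jacobianCircumcenter(p[tr[1], ], p[tr[2], ], p[tr[3], ], corner,
                       ids = tr)
}

# analytic circumcenter Jacobian for corner `which` of triangle (p1,p2,p3)
jacobianCircumcenter <- function(p1, p2, p3, which, ids = 1:3) {
  u <- p2 - p1; w <- p3 - p1
  M <- 2 * rbind(u, w)
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  scale <- max(sum(u^2), sum(w^2))
  if (abs(det) < 1e-12 * scale)
    stop(sprintf(
      "degenerate triangle over sites %s (condition ~ %.2e)",
      paste(ids, collapse = ", "), scale / abs(det)))
  cc <- circumcenter(p1, p2, p3, ids)
  rhs <- switch(which,
    2 * rbind(cc - p1, cc - p1),
    rbind(2 * (p2 - cc), c(0, 0)),
    rbind(c(0, 0), 2 * (p3 - cc)))
  J <- solve(M, rhs)
  dimnames(J) <- NULL
  J
}

# shared guard: operations needing an up-to-date Delaunay mesh
checkMesh <- function(tissue) {
  if (nrow(tissue@triangles) == 0L)
    stop("tissue has no triangulation; call buildTriangulation()")
  if (tissue@stale)
    stop("mesh is stale: sites moved since the last equiangulation; call equiangulate() or buildTriangulation()")
  invisible(TRUE)
}
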