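# expand MechParams into per-site vectors + type index into Lambda
siteParams <- function(tissue, mech) {
  types <- rownames(mech@Lambda)
  ti <- match(tissue@type, types)
  if (anyNA(ti))
    stop("tissue contains types absent from the Lambda matrix: ",
         paste(setdiff(unique(tissue@type), types), collapse = ", "))
  Kv <- unname(mech@K[tissue@type]); Kv[is.na(Kv)] <- 0
  Gv <- unname(mech@Gamma[tissue@type]); Gv[is.na(Gv)] <- 0
  A0 <- tissue@A0; A0[is.na(A0)] <- 0
  list(K = Kv, Gamma = Gv, A0 = A0, typeIdx = ti)
}

#' Vertex-model energy of a tissue
#'
#' Evaluates the area, perimeter, junction, soft-core and boundary-line
#' terms of the energy on the current dual tessellation.  The junction term
#' is accumulated per cell (each cell pays the tension of each of its own
#' Voronoi edges), so with uniform tension \eqn{\Lambda} and
#' \eqn{P_0 = -\Lambda/\Gamma} the energy differs from the preferred-
#' perimeter form \eqn{\sum \Gamma/2 (P_i - P_0)^2} only by the constant
#' \eqn{N \Lambda^2/(2\Gamma)}.
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @param mech a [MechParams-class] object.
#' @param bnd optional [BoundaryParams-class]; when supplied the boundary
#'   line-tension and bending terms are included.
#' @return a list (class `EnergyBreakdown`) with components `area_term`,
#'   `perimeter_term`, `junction_term`, `soft_core_term`,
#'   `boundary_line_term`, `boundary_bend_term`, `total`.
#' @export
vmEnergy <- function(tissue, mech, bnd = NULL) {
  checkMesh(tissue)
  sp <- siteParams(tissue, mech)
  r <- cpp_vm_forces(tissue@pos, tissue@triangles, isInterior(tissue),
                     sp$K, sp$Gamma, sp$A0, mech@Lambda, sp$typeIdx,
                     mech@kCore, mech@aCore, want_forces = FALSE)
  bl <- bb <- 0
  if (!is.null(bnd)) {
    be <- boundaryEnergy(tissue, bnd)
    bl <- be$line_term; bb <- be$bend_term
  }
  out <- list(area_term = r$area_term, perimeter_term = r$perimeter_term,
              junction_term = r$junction_term,
              soft_core_term = r$soft_core_term,
              boundary_line_term = bl, boundary_bend_term = bb)
  out$total <- sum(unlist(out))
  class(out) <- "EnergyBreakdown"
  out
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat("Vertex-model energy breakdown\n")
  for (nm in setdiff(names(x), "total"))
    cat(sprintf("  %-20s %12.6g\n", nm, x[[nm]]))
  cat(sprintf("  %-20s %12.6g\n", "total", x$total))
  invisible(x)
}

#' Forces on all particles from the vertex-model energy
#'
#' The force on every particle (interior cell centres and boundary ghosts
#' alike) is the exact negative gradient of the vertex-model energy with
#' respect to that particle's position, computed by chaining the per-cell
#' gradients with respect to the Voronoi vertices through the analytic
#' circumcenter Jacobians.  Includes the soft-core repulsion between
#' Delaunay-adjacent particle centres.  The force is local: only particles
#' sharing a triangle with one of a cell's vertices contribute, but it is
#' not a pairwise sum.
#'
#' @inheritParams vmEnergy
#' @param softCore logical; include the soft-core contribution (default TRUE).
#' @return n x 2 matrix of forces.
#' @export
vmForces <- function(tissue, mech, softCore = TRUE) {
  checkMesh(tissue)
  sp <- siteParams(tissue, mech)
  r <- cpp_vm_forces(tissue@pos, tissue@triangles, isInterior(tissue),
                     sp$K, sp$Gamma, sp$A0, mech@Lambda, sp$typeIdx,
                     if (softCore) mech@kCore else 0, mech@aCore,
                     want_forces = TRUE)
  if (isTRUE(r$capped))
    warning("coincident particle centres: soft-core force capped")
  r$forces
}

#' Soft-core repulsion forces between Delaunay-adjacent particle centres
#'
#' Harmonic half-spring: pair energy \eqn{k/2 (a - r)^2} and radial force of
#' magnitude \eqn{k (a - r)} for separations r below the core range a, zero
#' beyond.
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @param kCore stiffness; @param aCore range.
#' @return n x 2 matrix of forces.
#' @export
softCoreForces <- function(tissue, kCore = 1, aCore = 1) {
  checkMesh(tissue)
  n <- nrow(tissue@pos)
  zero <- rep(0, n)
  lam <- matrix(0, 2, 2, dimnames = list(c("c", "M"), c("c", "M")))
  r <- cpp_vm_forces(tissue@pos, tissue@triangles, rep(FALSE, n),
                     zero, zero, zero, lam, rep(1L, n),
                     kCore, aCore, want_forces = TRUE)
  if (isTRUE(r$capped))
    warning("coincident particle centres: soft-core force capped")
  r$forces
}

#' Dimensionless shape factor from the mechanical parameters
#'
#' The preferred perimeter is \eqn{P_0 = -\Lambda/\Gamma} and the shape
#' factor \eqn{p_0 = P_0/\sqrt{A_0}} controls the solid-liquid behaviour of
#' the tissue (critical value about 3.81, the regular pentagon).
#'
#' @param Gamma perimeter modulus (> 0).
#' @param Lambda junction tension.
#' @param A0 reference area (default pi).
#' @return the shape factor p0.
#' @examples
#' effectiveP0(Gamma = 1, Lambda = -5.5)  # 3.10
#' @export
effectiveP0 <- function(Gamma, Lambda, A0 = pi) {
  if (Gamma <= 0) stop("Gamma must be > 0: no preferred perimeter")
  if (A0 <= 0) stop("A0 must be > 0")
  (-Lambda / Gamma) / sqrt(A0)
}

#' Junction tension realising a target shape factor
#'
#' Inverts [effectiveP0()]: \eqn{\Lambda = -p_0 \Gamma \sqrt{A_0}}.
#'
#' @param p0 target shape factor.
#' @inheritParams effectiveP0
#' @export
lambdaForP0 <- function(p0, Gamma = 1, A0 = pi) -p0 * Gamma * sqrt(A0)

#' Shape factor of a regular polygon
#'
#' \eqn{p_0(n) = P/\sqrt{A} = \sqrt{4 n \tan(\pi/n)}} for the regular n-gon:
#' 3.722 for the hexagon, 3.812 for the pentagon (the solid-liquid critical
#' value), 4 for the square and 4.559 for the equilateral triangle.
#'
#' @param n number of sides (>= 3); vectorised.
#' @return the shape factor(s).
#' @export
regularPolygonP0 <- function(n) {
  if (any(n < 3)) stop("a polygon needs at least 3 sides")
  sqrt(4 * n * tan(pi / n))
}
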