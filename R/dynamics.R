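#' Cell shape tensor and principal axis
#'
#' The shape tensor of a cell is the average outer product of the
#' differences of consecutive Voronoi vertices,
#' \eqn{S = (1/m) \sum_\mu (r_\mu - r_{\mu+1}) \otimes (r_\mu - r_{\mu+1})};
#' its eigenvector of largest eigenvalue points along the cell's long axis
#' (defined up to sign).
#'
#' @param vertices m x 2 matrix of CCW polygon vertices.
#' @return list(matrix, axis, angle): the 2 x 2 tensor, the unit principal
#'   axis and its angle.
#' @export
shapeTensor <- function(vertices) {
  d <- vertices - vertices[c(2:nrow(vertices), 1), , drop = FALSE]
  S <- crossprod(d) / nrow(vertices)
  eg <- eigen(S, symmetric = TRUE)
  ax <- eg$vectors[, 1]
  list(matrix = S, axis = ax, angle = atan2(ax[2], ax[1]))
}

#' Alignment torque on every cell polarity
#'
#' Torque (z-component) from the enabled alignment energies: polar
#' (Vicsek-like neighbour coupling, \eqn{J_p \sum_j \sin(\theta_j -
#' \theta_i)} over Delaunay-neighbour cells), velocity (alignment with the
#' normalised migration direction, \eqn{J_v \sin(\theta_v - \theta_i)},
#' zero for a cell at rest) and shape (alignment with the principal axis of
#' the shape tensor, with the axis sign chosen so that the coupling is
#' nematic: \eqn{n \cdot p \ge 0}).  Models are additive when several are
#' enabled.
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @param active an [ActiveParams-class] object.
#' @param velocities optional n x 2 matrix of cell velocities (previous-step
#'   displacement / dt); required for the velocity model.
#' @param cells optional precomputed [dualCells()] result (shape model).
#' @return numeric vector of torques (0 for ghosts).
#' @export
alignmentTorque <- function(tissue, active, velocities = NULL, cells = NULL) {
  n <- nrow(tissue@pos)
  tau <- numeric(n)
  if (identical(active@alignment, "none")) return(tau)
  interior <- isInterior(tissue)
  th <- tissue@theta
  if ("polar" %in% active@alignment && active@Jp != 0) {
    checkMesh(tissue)
    e <- delaunayEdges(tissue@triangles)
    keep <- interior[e[, 1]] & interior[e[, 2]]
    e <- e[keep, , drop = FALSE]
    s <- sin(th[e[, 2]] - th[e[, 1]])
    tau <- tau + active@Jp *
      (accumAt(e[, 1], s, n) - accumAt(e[, 2], s, n))
  }
  if ("velocity" %in% active@alignment && active@Jv != 0 &&
      !is.null(velocities)) {
    # no velocities yet (first step) or a cell at rest: zero torque
    sp <- sqrt(rowSums(velocities^2))
    mov <- interior & sp > 1e-14
    thv <- atan2(velocities[mov, 2], velocities[mov, 1])
    tau[mov] <- tau[mov] + active@Jv * sin(thv - th[mov])
  }
  if ("shape" %in% active@alignment && active@Js != 0) {
    if (is.null(cells)) cells <- dualCells(tissue)
    for (c in seq_along(cells$site)) {
      i <- cells$site[c]
      st <- shapeTensor(cells$vertices[[c]])
      ang <- st$angle
      # nematic sign disambiguation: flip the axis so n . p >= 0
      if (cos(ang - th[i]) < 0) ang <- ang + pi
      tau[i] <- tau[i] + active@Js * sin(ang - th[i])
    }
  }
  tau[!interior] <- 0
  tau
}

#' One Euler-Maruyama step of the active dynamics
#'
#' Updates positions by \eqn{r \leftarrow r + (dt/\gamma)(f_a n + F) +
#' \sqrt{2 D dt}/\gamma\, \xi} (interior cells) and polarity angles by
#' \eqn{\theta \leftarrow \theta + (dt/\gamma_r)\tau + \sqrt{2 D_r
#' dt}/\gamma_r\, \xi^r}, then restores the Delaunay property by
#' equiangulation.  Boundary ghosts carry no activity, polarity or noise:
#' in "free" mode they move under the vertex-model and boundary-line forces
#' only; in "fixed" mode (and for "wall" ghosts always) they do not move.
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @param mech a [MechParams-class] object.
#' @param active an [ActiveParams-class] object.
#' @param bnd optional [BoundaryParams-class] (adds boundary-line forces and
#'   sets the ghost mobility mode; default fixed ghosts).
#' @param velocities previous-step velocities (for the velocity-alignment
#'   torque); omit on the first step.
#' @return list(tissue, nFlips, flipped, velocities, forces): the updated
#'   state, the T1 bookkeeping from the equiangulation pass, the realised
#'   velocities (displacement/dt) and the forces used.
#' @export
stepTissue <- function(tissue, mech, active, bnd = NULL, velocities = NULL) {
  checkMesh(tissue)
  F <- vmForces(tissue, mech)
  if (!is.null(bnd) && (bnd@lambda != 0 || bnd@zeta != 0))
    F <- F + boundaryForces(tissue, bnd)
  tau <- alignmentTorque(tissue, active, velocities = velocities)
  n <- nrow(tissue@pos)
  interior <- isInterior(tissue)
  dt <- active@dt
  disp <- matrix(0, n, 2)
  ni <- sum(interior)
  nvec <- cbind(cos(tissue@theta[interior]), sin(tissue@theta[interior]))
  noise <- if (active@D > 0)
    sqrt(2 * active@D * dt) / active@gamma * matrix(rnorm(2 * ni), ni, 2)
  else 0
  disp[interior, ] <- dt / active@gamma *
    (active@fa * nvec + F[interior, , drop = FALSE]) + noise
  if (!is.null(bnd) && bnd@mode == "free") {
    gb <- tissue@flag == "boundary"
    disp[gb, ] <- dt / active@gamma * F[gb, , drop = FALSE]
  }
  maxd <- sqrt(max(rowSums(disp^2)))
  if (maxd > 0.5 * mech@aCore)
    stop(sprintf("instability: step displacement %.3g exceeds 0.5 a; reduce dt",
                 maxd))
  tissue@pos <- tissue@pos + disp
  rnoise <- if (active@Dr > 0)
    sqrt(2 * active@Dr * dt) / active@gammaR * rnorm(ni) else 0
  tissue@theta[interior] <- tissue@theta[interior] +
    dt / active@gammaR * tau[interior] + rnoise
  tissue@stale <- TRUE
  eq <- equiangulate(tissue)
  list(tissue = eq$tissue, nFlips = eq$nFlips, flipped = eq$flipped,
       velocities = disp / dt, forces = F)
}

#' Rotational decorrelation of a torque-free polarity
#'
#' Evolves an ensemble of independent polarity angles under rotational noise
#' (plus an optional constant torque) and fits the autocorrelation
#' \eqn{\langle n(t) \cdot n(0)\rangle} to \eqn{\exp(-t/\tau)}.  For pure
#' rotational diffusion with \eqn{\gamma_r = 1} the decay time is
#' \eqn{1/D_r}; the conventional persistence time quoted alongside is
#' \eqn{\tau_r = \gamma_r/(2 D_r)}.
#'
#' @param Dr rotational diffusion constant.
#' @param gammaR rotational friction.
#' @param torque constant torque (default 0).
#' @param nWalkers ensemble size.
#' @param tMax,dt time grid.
#' @return list(t, C, tauFit, tauR, theta): autocorrelation curve, fitted
#'   decay time (NA when no decay), the tau_r convention value, and the
#'   final angles.
#' @export
polarityAutocorrelation <- function(Dr, gammaR = 1, torque = 0,
                                    nWalkers = 2000, tMax = 50, dt = 0.01) {
  nsteps <- round(tMax / dt)
  th0 <- runif(nWalkers, -pi, pi)
  th <- th0
  keepEvery <- max(1L, floor(nsteps / 200))
  tgrid <- Cs <- numeric()
  for (s in seq_len(nsteps)) {
    th <- th + dt / gammaR * torque +
      (if (Dr > 0) sqrt(2 * Dr * dt) / gammaR * rnorm(nWalkers) else 0)
    if (s %% keepEvery == 0L) {
      tgrid <- c(tgrid, s * dt)
      Cs <- c(Cs, mean(cos(th - th0)))
    }
  }
  ok <- Cs > 0.05
  tauFit <- if (Dr > 0 && sum(ok) > 2) {
    fit <- lm(log(Cs[ok]) ~ 0 + tgrid[ok])
    -1 / unname(coef(fit)[1])
  } else NA_real_
  list(t = tgrid, C = Cs, tauFit = tauFit,
       tauR = if (Dr > 0) gammaR / (2 * Dr) else Inf, theta = th)
}

# unique undirected Delaunay edges of a triangle matrix
delaunayEdges <- function(tri) {
  a <- c(tri[, 1], tri[, 2], tri[, 3])
  b <- c(tri[, 2], tri[, 3], tri[, 1])
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(lo * (max(hi) + 1) + hi)
  cbind(lo[keep], hi[keep])
}
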