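#' Tissue: cell centres, boundary ghosts and their Delaunay triangulation
#'
#' The central container of the package.  A tissue is a set of particles in
#' the plane: \emph{interior} particles are cell centres and own a finite
#' Voronoi cell; \emph{boundary} (or \emph{wall}) particles are ghosts that
#' mark the tissue edge, carry boundary-line connectivity, and bound the
#' Voronoi cells of their interior neighbours without owning a cell
#' themselves.  The Delaunay triangulation of all particles is cached in the
#' object and kept Delaunay by equiangulation edge flips as particles move;
#' operations that displace particles mark the mesh stale.
#'
#' @slot pos numeric matrix (n x 2) of particle positions, columns x, y,
#'   in units of the soft-core range a.
#' @slot flag character: "interior", "boundary" (mobile ghost) or "wall"
#'   (immobile ghost).
#' @slot type character cell type label per particle; ghosts carry type "M".
#' @slot theta numeric polarity angle (radians) per particle; NA for ghosts.
#' @slot A0 numeric native (target) cell area per particle; NA for ghosts.
#'   Mutable under growth.
#' @slot age numeric cell age in time units; NA for ghosts.
#' @slot id integer stable particle identifier (survives division/removal).
#' @slot bnext,bprev integer index (into rows) of the next/previous ghost
#'   along the boundary line; 0 for interior particles.
#' @slot triangles integer matrix (t x 3) of CCW triangles (row indices into
#'   pos); zero rows when no triangulation has been built.
#' @slot stale logical; TRUE when particles moved since the last
#'   triangulation update.
#' @export
setClass("Tissue", representation(
  pos = "matrix", flag = "character", type = "character",
  theta = "numeric", A0 = "numeric", age = "numeric", id = "integer",
  bnext = "integer", bprev = "integer",
  triangles = "matrix", stale = "logical"
))

setValidity("Tissue", function(object) {
  n <- nrow(object@pos)
  msg <- character()
  if (ncol(object@pos) != 2) msg <- c(msg, "pos must have two columns")
  if (!all(is.finite(object@pos))) msg <- c(msg, "non-finite coordinates")
  for (s in c("flag", "type", "theta", "A0", "age", "id", "bnext", "bprev")) {
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have length nrow(pos)", s))
  }
  if (!all(object@flag %in% c("interior", "boundary", "wall")))
    msg <- c(msg, "flag must be interior/boundary/wall")
  ghost <- object@flag != "interior"
  if (any(object@bnext[!ghost] != 0L) || any(object@bprev[!ghost] != 0L))
    msg <- c(msg, "interior particles must have no boundary links")
  if (any(ghost)) {
    g <- which(ghost)
    nx <- object@bnext[g]
    if (any(nx == 0L) || anyDuplicated(nx) ||
        !all(object@bprev[nx] == g))
      msg <- c(msg, "each ghost needs exactly two boundary neighbours (bprev/bnext inconsistent)")
  }
  if (anyDuplicated(object@id)) msg <- c(msg, "particle ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Mechanical parameters of the vertex-model energy
#'
#' Parameters of the energy
#' \deqn{E = \sum_i K_i/2 (A_i - A_i^0)^2 + \sum_i \Gamma_i/2 P_i^2 +
#'   \sum_i \sum_{e \in \partial\Omega_i} \Lambda_{e} l_e + E_{core},}
#' where the junction sum runs over each cell's own Voronoi edges (so an
#' interior junction is paid by both adjacent cells) and the tension
#' \eqn{\Lambda} of an edge is looked up by the (type, type) pair of the two
#' particles whose Delaunay edge it bisects, including the ghost type "M".
#' The soft repulsive core between particle centres,
#' \eqn{E_{core} = k/2 (a - r)^2} for \eqn{r < a}, stabilises the simulation.
#'
#' @slot K named numeric: area modulus per cell type (energy/length^4).
#' @slot Gamma named numeric: perimeter modulus per cell type
#'   (energy/length^2).
#' @slot Lambda symmetric numeric matrix of junction tensions
#'   (energy/length) with dimnames over cell types plus "M".
#' @slot kCore soft-core stiffness (energy/length^2).
#' @slot aCore soft-core range a (length; the unit of length).
#' @export
setClass("MechParams", representation(
  K = "numeric", Gamma = "numeric", Lambda = "matrix",
  kCore = "numeric", aCore = "numeric"
))

setValidity("MechParams", function(object) {
  msg <- character()
  if (any(object@K <= 0)) msg <- c(msg, "K must be > 0")
  if (any(object@Gamma < 0)) msg <- c(msg, "Gamma must be >= 0")
  if (object@aCore <= 0) msg <- c(msg, "aCore must be > 0")
  L <- object@Lambda
  if (is.null(dimnames(L)[[1]]) || !"M" %in% rownames(L))
    msg <- c(msg, "Lambda needs dimnames including boundary type 'M'")
  else if (max(abs(L - t(L))) > 1e-12) msg <- c(msg, "Lambda must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Active-dynamics parameters
#'
#' Parameters of the overdamped equations of motion
#' \deqn{\gamma \dot r_i = f_a n_i + F_i + \nu_i(t), \qquad
#'       \gamma_r \dot\theta_i = \tau_i + \nu^r_i(t),}
#' with white noises of strength 2D and 2D_r, integrated with the
#' Euler-Maruyama scheme.  The polarity decorrelation time quoted in
#' parameter tables is \eqn{\tau_r = \gamma_r/(2 D_r)}; use
#' [taurInverse()] to convert.
#'
#' @slot fa active self-propulsion force magnitude.
#' @slot gamma translational friction (> 0).
#' @slot gammaR rotational friction (> 0).
#' @slot D translational noise strength (>= 0).
#' @slot Dr rotational noise strength (>= 0).
#' @slot Jp,Jv,Js alignment strengths of the polar (neighbour), velocity and
#'   shape alignment models.
#' @slot alignment character subset of "polar", "velocity", "shape"
#'   (additive), or "none".
#' @slot dt integration time step.
#' @export
setClass("ActiveParams", representation(
  fa = "numeric", gamma = "numeric", gammaR = "numeric",
  D = "numeric", Dr = "numeric",
  Jp = "numeric", Jv = "numeric", Js = "numeric",
  alignment = "character", dt = "numeric"
))

setValidity("ActiveParams", function(object) {
  msg <- character()
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (object@gammaR <= 0) msg <- c(msg, "gammaR must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@D < 0 || object@Dr < 0) msg <- c(msg, "noise strengths must be >= 0")
  ok <- c("none", "polar", "velocity", "shape")
  if (!all(object@alignment %in% ok)) msg <- c(msg, "unknown alignment model")
  if (length(msg)) msg else TRUE
})

#' Population-dynamics parameters (growth, division, death)
#'
#' Native areas grow by a constant rate per step,
#' \eqn{A_0(t+\delta t) = (1 + \eta\,\delta t) A_0(t)}; a cell with actual
#' area A above the critical area divides with rate \eqn{\chi (A - A_c)}
#' (probability over a check interval of length T is min(rate T, 1), making
#' the division law independent of the time step); a cell is removed
#' instantaneously when its age exceeds maxAge.
#'
#' @slot eta growth rate (1/time).
#' @slot Ac critical division area (length^2).
#' @slot chi division-rate constant (1/(area time)).
#' @slot maxAge critical age for removal (time; Inf disables death).
#' @slot checkEvery steps between division/death checks.
#' @slot daughterOffset separation of the daughter centres (length).
#' @slot enableGrowth,enableDeath logical switches.
#' @export
setClass("PopulationParams", representation(
  eta = "numeric", Ac = "numeric", chi = "numeric", maxAge = "numeric",
  checkEvery = "integer", daughterOffset = "numeric",
  enableGrowth = "logical", enableDeath = "logical"
))

setValidity("PopulationParams", function(object) {
  msg <- character()
  if (object@eta < 0 || object@chi < 0 || object@Ac < 0)
    msg <- c(msg, "eta, chi, Ac must be non-negative")
  if (object@checkEvery < 1L) msg <- c(msg, "checkEvery must be >= 1")
  if (object@daughterOffset <= 0) msg <- c(msg, "daughterOffset must be > 0")
  if (length(msg)) msg else TRUE
})

#' Boundary-line parameters
#'
#' The ghost-particle boundary line carries a line tension
#' \eqn{E = 1/2 \sum \lambda (l - l_0)^2} over its edges and a bending
#' stiffness \eqn{E = 1/2 \sum \zeta (\theta - \pi)^2} over its sites, with
#' \eqn{\theta} the angle between the two boundary neighbours.  Edges longer
#' than lMax are split at their midpoint, edges shorter than lMin are
#' contracted, keeping the boundary resolution commensurate with the cell
#' size; the number of boundary loops never changes.
#'
#' @slot mode "fixed" (ghosts never move) or "free".
#' @slot lambda line tension (energy/length^2), uniform per run.
#' @slot l0 native edge length (length).
#' @slot zeta bending stiffness (energy).
#' @slot lMax,lMin refinement thresholds (defaults 2 l0 and 0.5 l0).
#' @slot refineEvery steps between refinement sweeps.
#' @export
setClass("BoundaryParams", representation(
  mode = "character", lambda = "numeric", l0 = "numeric", zeta = "numeric",
  lMax = "numeric", lMin = "numeric", refineEvery = "integer"
))

setValidity("BoundaryParams", function(object) {
  msg <- character()
  if (!object@mode %in% c("fixed", "free")) msg <- c(msg, "mode must be fixed/free")
  if (object@l0 <= 0) msg <- c(msg, "l0 must be > 0")
  if (object@lMin >= object@lMax) msg <- c(msg, "need lMin < lMax")
  if (length(msg)) msg else TRUE
})

#' Simulation trajectory
#'
#' Time-ordered snapshots of a run plus its event log.  Frames store particle
#' positions, ids and flags at the snapshot cadence; the event log records
#' every T1 flip, division, death and boundary edit with the step at which it
#' occurred; the boundary length is tracked every step for instability
#' detection.
#'
#' @slot times numeric times of the stored frames.
#' @slot frames list of data.frames (id, flag, type, x, y, theta, A0, age).
#' @slot events data.frame (step, time, event, id1..id4).
#' @slot boundaryLength numeric per-step boundary length (free runs).
#' @slot stepTimes numeric times corresponding to boundaryLength.
#' @slot finalTissue the final [Tissue-class] state.
#' @slot params list of the parameter objects used (run manifest).
#' @export
setClass("Trajectory", representation(
  times = "numeric", frames = "list", events = "data.frame",
  boundaryLength = "numeric", stepTimes = "numeric",
  finalTissue = "Tissue", params = "list"
))

setMethod("show", "Tissue", function(object) {
  cat("Tissue with", sum(object@flag == "interior"), "cells and",
      sum(object@flag != "interior"), "boundary ghosts\n")
  cat("  types:", paste(unique(object@type[object@flag == "interior"]),
                        collapse = ", "), "\n")
  cat("  mesh:", if (nrow(object@triangles)) paste(nrow(object@triangles),
      "triangles", if (object@stale) "(stale)" else "(current)")
      else "not built", "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@frames), "frames,",
      nrow(object@events), "events, t in [",
      if (length(object@times)) min(object@times) else NA, ",",
      if (length(object@times)) max(object@times) else NA, "]\n")
})
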