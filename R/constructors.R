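#' Construct a Tissue from particle positions
#'
#' @param pos n x 2 numeric matrix of positions.
#' @param flag character vector ("interior", "boundary", "wall"); default all
#'   interior.
#' @param type cell type labels (ghosts are forced to type "M").
#' @param theta polarity angles; defaults to uniform random would be a side
#'   effect, so the default is 0 for interior cells.
#' @param A0 native areas (default pi, the reference area scale).
#' @param age cell ages (default 0).
#' @param boundaryLoops list of integer vectors, each a cyclic sequence of
#'   row indices forming one boundary loop (order defines connectivity).
#' @param build logical; build the Delaunay triangulation now.
#' @return A [Tissue-class] object.
#' @export
Tissue <- function(pos, flag = NULL, type = NULL, theta = NULL, A0 = NULL,
                   age = NULL, boundaryLoops = list(), build = TRUE) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  colnames(pos) <- c("x", "y")
  n <- nrow(pos)
  if (is.null(flag)) flag <- rep("interior", n)
  interior <- flag == "interior"
  if (is.null(type)) type <- ifelse(interior, "c", "M")
  type[!interior] <- "M"
  if (is.null(theta)) theta <- ifelse(interior, 0, NA_real_)
  if (is.null(A0)) A0 <- ifelse(interior, pi, NA_real_)
  if (is.null(age)) age <- ifelse(interior, 0, NA_real_)
  bnext <- bprev <- integer(n)
  for (loop in boundaryLoops) {
    loop <- as.integer(loop)
    if (length(loop) < 3L) stop("a boundary loop needs at least 3 ghosts")
    if (any(flag[loop] == "interior"))
      stop("boundary loops may only contain ghost particles")
    nx <- c(loop[-1L], loop[1L])
    bnext[loop] <- nx
    bprev[nx] <- loop
  }
  ghosts <- which(!interior)
  if (length(ghosts) && any(bnext[ghosts] == 0L))
    stop("every ghost particle must belong to a boundary loop")
  tis <- new("Tissue", pos = pos, flag = flag, type = as.character(type),
             theta = as.numeric(theta), A0 = as.numeric(A0),
             age = as.numeric(age), id = seq_len(n),
             bnext = bnext, bprev = bprev,
             triangles = matrix(integer(), 0, 3), stale = TRUE)
  validObject(tis)
  if (build) tis <- buildTriangulation(tis)
  tis
}

#' @describeIn MechParams-class Constructor.  K and Gamma may be scalars
#'   (applied to all types) or named per-type vectors; Lambda may be a scalar
#'   (uniform tension, including cell-boundary contacts) or a full named
#'   matrix over types plus "M".
#' @param K,Gamma,Lambda,kCore,aCore see slots.
#' @param types character vector of cell types in use.
#' @export
MechParams <- function(K = 1, Gamma = 1, Lambda = 0, kCore = 1, aCore = 1,
                       types = "c") {
  all_t <- c(types, "M")
  expand <- function(x, nm) {
    if (is.null(names(x))) x <- setNames(rep_len(x, length(types)), types)
    x <- x[types]
    if (anyNA(x)) stop("missing per-type value for ", nm)
    x
  }
  K <- expand(K, "K"); Gamma <- expand(Gamma, "Gamma")
  if (!is.matrix(Lambda)) {
    Lambda <- matrix(Lambda[1L], length(all_t), length(all_t),
                     dimnames = list(all_t, all_t))
  } else {
    if (is.null(dimnames(Lambda))) stop("Lambda matrix needs dimnames")
    Lambda <- Lambda[all_t, all_t]
  }
  new("MechParams", K = K, Gamma = Gamma, Lambda = Lambda,
      kCore = kCore, aCore = aCore)
}

#' @describeIn ActiveParams-class Constructor.
#' @param fa,gamma,gammaR,D,Dr,Jp,Jv,Js,alignment,dt see slots.
#' @export
ActiveParams <- function(fa = 0, gamma = 1, gammaR = 1, D = 0, Dr = 0,
                         Jp = 0, Jv = 0, Js = 0, alignment = "none",
                         dt = 0.01) {
  new("ActiveParams", fa = fa, gamma = gamma, gammaR = gammaR, D = D, Dr = Dr,
      Jp = Jp, Jv = Jv, Js = Js, alignment = alignment, dt = dt)
}

#' Convert an inverse polarity-persistence time to a rotational diffusion
#' constant
#'
#' Parameter tables quote the inverse decorrelation time
#' \eqn{\tau_r^{-1}}; with \eqn{\tau_r = \gamma_r/(2 D_r)} this maps to
#' \eqn{D_r = \gamma_r \tau_r^{-1}/2}.
#'
#' @param taur_inv inverse decorrelation time.
#' @param gammaR rotational friction.
#' @return the rotational diffusion constant Dr.
#' @export
taurInverse <- function(taur_inv, gammaR = 1) gammaR * taur_inv / 2

#' @describeIn PopulationParams-class Constructor.
#' @param eta,Ac,chi,maxAge,checkEvery,daughterOffset,enableGrowth,enableDeath
#'   see slots.
#' @export
PopulationParams <- function(eta = 0, Ac = 2.8, chi = 0, maxAge = Inf,
                             checkEvery = 25L, daughterOffset = 0.5,
                             enableGrowth = FALSE, enableDeath = FALSE) {
  new("PopulationParams", eta = eta, Ac = Ac, chi = chi, maxAge = maxAge,
      checkEvery = as.integer(checkEvery), daughterOffset = daughterOffset,
      enableGrowth = enableGrowth, enableDeath = enableDeath)
}

#' @describeIn BoundaryParams-class Constructor.
#' @param mode,lambda,l0,zeta,lMax,lMin,refineEvery see slots.
#' @export
BoundaryParams <- function(mode = "fixed", lambda = 0, l0 = 1, zeta = 0,
                           lMax = 2 * l0, lMin = 0.5 * l0,
                           refineEvery = 25L) {
  new("BoundaryParams", mode = mode, lambda = lambda, l0 = l0, zeta = zeta,
      lMax = lMax, lMin = lMin, refineEvery = as.integer(refineEvery))
}

# ---- accessors -------------------------------------------------------------

#' Tissue accessors
#'
#' @param tissue a [Tissue-class] object.
#' @return `positions`: the n x 2 coordinate matrix; `isInterior`: logical
#'   vector; `nCells`: number of interior cells; `cellTypes`: type labels of
#'   interior cells; `polarity`: n x 2 matrix of unit polarity vectors (NA
#'   rows for ghosts); `triangulation`: the cached triangle matrix;
#'   `boundarySites`: indices of ghost particles in boundary-line order.
#' @export
positions <- function(tissue) tissue@pos

#' @rdname positions
#' @export
isInterior <- function(tissue) tissue@flag == "interior"

#' @rdname positions
#' @export
nCells <- function(tissue) sum(tissue@flag == "interior")

#' @rdname positions
#' @export
cellTypes <- function(tissue) tissue@type[isInterior(tissue)]

#' @rdname positions
#' @export
polarity <- function(tissue) cbind(cos(tissue@theta), sin(tissue@theta))

#' @rdname positions
#' @export
triangulation <- function(tissue) tissue@triangles

#' @rdname positions
#' @export
boundaryLoops <- function(tissue) {
  ghosts <- which(tissue@flag != "interior")
  loops <- list()
  seen <- logical(nrow(tissue@pos))
  for (g in ghosts) {
    if (seen[g]) next
    loop <- integer()
    cur <- g
    repeat {
      loop <- c(loop, cur)
      seen[cur] <- TRUE
      cur <- tissue@bnext[cur]
      if (cur == g) break
      if (seen[cur]) stop("corrupted boundary connectivity")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Replace particle positions (marks the mesh stale)
#'
#' @param tissue a [Tissue-class] object.
#' @param value n x 2 coordinate matrix.
#' @export
`positions<-` <- function(tissue, value) {
  stopifnot(identical(dim(value), dim(tissue@pos)))
  tissue@pos[] <- value
  tissue@stale <- TRUE
  tissue
}
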