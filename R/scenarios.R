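#' Generate an initial condition: minimised soft-disk packing plus ghosts
#'
#' Cells start as slightly polydisperse soft disks packed at packing
#' fraction phi inside the requested geometry and relaxed with a FIRE
#' minimiser until residual net forces vanish, so that cells are evenly
#' spaced without being on a grid and the mean Voronoi cell area matches
#' the reference area A0 = pi (radii are rescaled so the region area is
#' N <A>/phi).  Boundary ghosts are placed on the rim of the geometry at
#' spacing about one core range a, one cell-scale arc per ghost.
#'
#' @param geometry one of "disk", "annulus", "rectangle_strips", "cavity".
#' @param N number of cells (>= 3).
#' @param polydispersity relative radius spread (default 0.1).
#' @param packingFraction phi (default 1; "cavity" admits phi < 1, giving a
#'   tissue patch inside a larger fixed wall).
#' @param typeFractions named fractions of cell types (default single type
#'   "c"); must sum to 1.
#' @param seed optional integer seed.
#' @param innerFraction annulus: inner radius / outer radius (default 0.5).
#' @param nStrips rectangle_strips: number of separate strips (default 3).
#' @param aspect rectangle_strips: height/width of each strip (default 4).
#' @param maxIter,fTol minimiser controls.
#' @return a [Tissue-class] object with a current mesh; the attribute
#'   "packing" records the minimiser residual.
#' @export
initPacking <- function(geometry = c("disk", "annulus", "rectangle_strips",
                                     "cavity"),
                        N, polydispersity = 0.1, packingFraction = 1,
                        typeFractions = c(c = 1), seed = NULL,
                        innerFraction = 0.5, nStrips = 3, aspect = 4,
                        maxIter = 20000, fTol = 1e-6) {
  geometry <- match.arg(geometry)
  if (N < 3) stop("N must be >= 3")
  if (abs(sum(typeFractions) - 1) > 1e-8) stop("type fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  rad <- rnorm(N, 1, polydispersity)
  rad <- pmax(rad, 0.2)
  rad <- rad * sqrt(N / sum(rad^2))          # sum pi r^2 = N pi
  regionArea <- sum(pi * rad^2) / packingFraction

  if (geometry %in% c("disk", "cavity")) {
    Rp <- sqrt(regionArea / pi)
    pos <- scatterInDisk(N, Rp - rad)
    pos <- fireMinimise(pos, rad, wallForce = diskWall(Rp), maxIter, fTol)
    loopsXY <- list(circleLoop(Rp + 1))
  } else if (geometry == "annulus") {
    Rout <- sqrt(regionArea / (pi * (1 - innerFraction^2)))
    Rin <- innerFraction * Rout
    if (Rin < 3) stop("N too small for an annulus at this inner fraction")
    pos <- scatterInAnnulus(N, Rin + rad, Rout - rad)
    pos <- fireMinimise(pos, rad, wallForce = annulusWall(Rin, Rout),
                        maxIter, fTol)
    loopsXY <- list(circleLoop(Rout + 1), circleLoop(Rin - 1))
  } else {  # rectangle_strips
    perStrip <- diff(round(seq(0, N, length.out = nStrips + 1)))
    stripArea <- regionArea / N * perStrip
    W <- sqrt(stripArea / aspect)
    H <- aspect * W
    gap <- 4
    x0 <- cumsum(c(0, head(W, -1) + gap + 2))
    pos <- NULL
    loopsXY <- list()
    idx0 <- 0
    radAll <- rad
    for (s in seq_len(nStrips)) {
      ii <- (idx0 + 1):(idx0 + perStrip[s])
      rs <- radAll[ii]
      ps <- cbind(runif(perStrip[s], rs, W[s] - rs) + x0[s],
                  runif(perStrip[s], rs, H[s] - rs))
      ps <- fireMinimise(ps, rs,
                         wallForce = rectWall(x0[s], x0[s] + W[s], 0, H[s]),
                         maxIter, fTol)
      pos <- rbind(pos, ps)
      loopsXY[[s]] <- rectLoop(x0[s] - 1, x0[s] + W[s] + 1, -1, H[s] + 1)
      idx0 <- idx0 + perStrip[s]
    }
  }

  ghostFlag <- if (geometry == "cavity") "wall" else "boundary"
  allPos <- pos
  flags <- rep("interior", N)
  loops <- list()
  for (L in loopsXY) {
    i0 <- nrow(allPos)
    allPos <- rbind(allPos, L)
    flags <- c(flags, rep(ghostFlag, nrow(L)))
    loops[[length(loops) + 1L]] <- i0 + seq_len(nrow(L))
  }
  types <- sample(rep(names(typeFractions),
                      times = diff(round(N * cumsum(c(0, typeFractions))))))
  theta <- runif(N, -pi, pi)
  tis <- Tissue(allPos, flag = flags,
                type = c(types, rep("M", nrow(allPos) - N)),
                theta = c(theta, rep(NA_real_, nrow(allPos) - N)),
                A0 = c(rep(pi, N), rep(NA_real_, nrow(allPos) - N)),
                age = c(rep(0, N), rep(NA_real_, nrow(allPos) - N)),
                boundaryLoops = loops)
  attr(tis, "packing") <- attr(pos, "residual")
  tis
}

scatterInDisk <- function(N, rmax) {
  th <- runif(N, -pi, pi)
  rr <- sqrt(runif(N)) * rmax
  cbind(rr * cos(th), rr * sin(th))
}

scatterInAnnulus <- function(N, rmin, rmax) {
  th <- runif(N, -pi, pi)
  rr <- sqrt(runif(N, (rmin / rmax)^2, 1)) * rmax
  cbind(rr * cos(th), rr * sin(th))
}

circleLoop <- function(R, spacing = 1) {
  m <- max(8L, round(2 * pi * R / spacing))
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  cbind(R * cos(th), R * sin(th))
}

rectLoop <- function(x0, x1, y0, y1, spacing = 1) {
  side <- function(a, b) {
    m <- max(2L, ceiling(sqrt(sum((b - a)^2)) / spacing))
    t <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  rbind(side(c(x0, y0), c(x1, y0)), side(c(x1, y0), c(x1, y1)),
        side(c(x1, y1), c(x0, y1)), side(c(x0, y1), c(x0, y0)))
}

diskWall <- function(Rp) function(pos, rad) {
  d <- sqrt(rowSums(pos^2))
  over <- d + rad - Rp
  coef <- ifelse(over > 0 & d > 1e-12, -over / pmax(d, 1e-12), 0)
  pos * coef
}

annulusWall <- function(Rin, Rout) function(pos, rad) {
  d <- sqrt(rowSums(pos^2))
  overOut <- d + rad - Rout
  overIn <- (Rin + rad) - d
  coef <- ifelse(overOut > 0, -overOut / pmax(d, 1e-12), 0) +
    ifelse(overIn > 0, overIn / pmax(d, 1e-12), 0)
  pos * coef
}

rectWall <- function(x0, x1, y0, y1) function(pos, rad) {
  fx <- pmax(x0 + rad - pos[, 1], 0) - pmax(pos[, 1] + rad - x1, 0)
  fy <- pmax(y0 + rad - pos[, 2], 0) - pmax(pos[, 2] + rad - y1, 0)
  cbind(fx, fy)
}

# pairwise harmonic soft-disk forces, naive O(N^2)
softDiskForces <- function(pos, rad) {
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  diag(d) <- Inf
  sig <- outer(rad, rad, "+")
  over <- sig - d
  act <- over > 0
  coef <- ifelse(act, over / d, 0)
  cbind(rowSums(coef * dx), rowSums(coef * dy))
}

# FIRE energy minimisation of the soft-disk packing
fireMinimise <- function(pos, rad, wallForce, maxIter = 20000, fTol = 1e-6) {
  v <- matrix(0, nrow(pos), 2)
  dt <- 0.02; dtmax <- 0.2; alpha <- 0.1
  nMin <- 5; good <- 0
  res <- Inf
  for (it in seq_len(maxIter)) {
    F <- softDiskForces(pos, rad) + wallForce(pos, rad)
    res <- sqrt(max(rowSums(F^2)))
    if (res < fTol) break
    P <- sum(F * v)
    if (P > 0) {
      good <- good + 1
      nv <- sqrt(sum(v^2)); nf <- sqrt(sum(F^2))
      v <- (1 - alpha) * v + alpha * (if (nf > 0) nv / nf else 0) * F
      if (good > nMin) { dt <- min(dt * 1.1, dtmax); alpha <- alpha * 0.99 }
    } else {
      v[] <- 0; dt <- dt * 0.5; alpha <- 0.1; good <- 0
    }
    v <- v + dt * F
    pos <- pos + dt * v
  }
  attr(pos, "residual") <- res
  pos
}

#' Run an active-vertex-model simulation
#'
#' Orchestrates the per-step loop: forces and torques, Euler-Maruyama
#' update, equiangulation (recording T1 flips), optional population events
#' (growth every step; division/death at the check cadence) and boundary
#' refinement, with snapshots at a fixed cadence.  Any topology violation
#' aborts the run.
#'
#' @param tissue starting [Tissue-class] state (mesh is built if absent).
#' @param mech,active,bnd,pop parameter objects ([MechParams-class],
#'   [ActiveParams-class], [BoundaryParams-class], [PopulationParams-class];
#'   bnd / pop optional).
#' @param nSteps number of time steps.
#' @param snapshotEvery frame cadence in steps (default 100).
#' @param seed optional integer seed (set before the loop).
#' @param outDir optional directory: manifest is written first, snapshots
#'   and the event log as the run progresses.
#' @param guardEvery steps between boundary topology checks (default 500).
#' @return a [Trajectory-class] object.
#' @export
runSimulation <- function(tissue, mech, active, bnd = NULL, pop = NULL,
                          nSteps, snapshotEvery = 100, seed = NULL,
                          outDir = NULL, guardEvery = 500) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeManifest(file.path(outDir, "manifest.yaml"), tissue = tissue,
                  mech = mech, active = active, bnd = bnd, pop = pop,
                  nSteps = nSteps, snapshotEvery = snapshotEvery,
                  seed = seed)
  }
  if (nrow(tissue@triangles) == 0L || tissue@stale)
    tissue <- buildTriangulation(tissue)
  refLoops <- length(boundaryLoops(tissue))
  dt <- active@dt
  events <- list()
  frames <- list(tissueFrame(tissue))
  times <- 0
  blen <- numeric(nSteps)
  stimes <- numeric(nSteps)
  vel <- NULL
  freeB <- !is.null(bnd) && bnd@mode == "free"
  for (s in seq_len(nSteps)) {
    st <- stepTissue(tissue, mech, active, bnd = bnd, velocities = vel)
    tissue <- st$tissue
    vel <- st$velocities
    if (st$nFlips > 0) {
      fl <- st$flipped
      allInt <- matrix(tissue@flag[fl] == "interior", nrow(fl))
      t1 <- which(rowSums(allInt) == 4L)
      for (k in t1) {
        events[[length(events) + 1L]] <- data.frame(
          step = s, time = s * dt, event = "T1",
          id1 = tissue@id[fl[k, 1]], id2 = tissue@id[fl[k, 2]],
          id3 = tissue@id[fl[k, 3]], id4 = tissue@id[fl[k, 4]])
      }
    }
    if (!is.null(pop)) {
      if (pop@enableGrowth && pop@eta > 0)
        tissue <- growCells(tissue, pop@eta, dt)
      else
        tissue@age[isInterior(tissue)] <-
          tissue@age[isInterior(tissue)] + dt
      if (s %% pop@checkEvery == 0L && (pop@chi > 0 || pop@enableDeath)) {
        sw <- populationSweep(tissue, pop, pop@checkEvery * dt)
        tissue <- sw$tissue
        vel <- NULL  # particle indices changed
        if (!is.null(sw$events) && nrow(sw$events)) {
          sw$events$step <- s; sw$events$time <- s * dt
          events[[length(events) + 1L]] <-
            sw$events[, c("step", "time", "event", "id1", "id2", "id3", "id4")]
        }
      }
    }
    if (freeB && s %% bnd@refineEvery == 0L) {
      rf <- refineBoundary(tissue, bnd)
      if (nrow(rf$events)) {
        tissue <- rf$tissue
        vel <- NULL
        rf$events$step <- s; rf$events$time <- s * dt
        events[[length(events) + 1L]] <-
          rf$events[, c("step", "time", "event", "id1", "id2", "id3", "id4")]
      }
    }
    blen[s] <- boundaryLength(tissue)
    stimes[s] <- s * dt
    if (guardEvery > 0 && s %% guardEvery == 0L) {
      tg <- topologyGuard(tissue, refLoops)
      if (!tg$ok)
        stop("boundary topology violation at step ", s, ": ",
             paste(tg$violations, collapse = "; "))
    }
    if (s %% snapshotEvery == 0L) {
      frames[[length(frames) + 1L]] <- tissueFrame(tissue)
      times <- c(times, s * dt)
      if (!is.null(outDir))
        writeSnapshot(tissue, file.path(outDir, sprintf("frame_%06d", s)))
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(), time = numeric(), event = character(),
               id1 = integer(), id2 = integer(), id3 = integer(),
               id4 = integer())
  traj <- new("Trajectory", times = times, frames = frames, events = ev,
              boundaryLength = blen, stepTimes = stimes,
              finalTissue = tissue,
              params = list(mech = mech, active = active, bnd = bnd,
                            pop = pop, nSteps = nSteps, seed = seed))
  if (!is.null(outDir)) {
    write.table(ev, file.path(outDir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeSnapshot(tissue, file.path(outDir, "final"))
  }
  traj
}

#' Relax a tissue by zero-noise, zero-activity overdamped descent
#'
#' @param tissue a [Tissue-class] object.
#' @param mech a [MechParams-class] object.
#' @param bnd optional boundary parameters.
#' @param nSteps,dt descent schedule.
#' @return the relaxed tissue.
#' @export
relaxTissue <- function(tissue, mech, bnd = NULL, nSteps = 500, dt = 0.01) {
  if (nrow(tissue@triangles) == 0L || tissue@stale)
    tissue <- buildTriangulation(tissue)
  interior <- isInterior(tissue)
  freeGhost <- !is.null(bnd) && bnd@mode == "free"
  for (s in seq_len(nSteps)) {
    F <- vmForces(tissue, mech)
    if (!is.null(bnd) && (bnd@lambda != 0 || bnd@zeta != 0))
      F <- F + boundaryForces(tissue, bnd)
    disp <- matrix(0, nrow(F), 2)
    disp[interior, ] <- dt * F[interior, , drop = FALSE]
    if (freeGhost) {
      gb <- tissue@flag == "boundary"
      disp[gb, ] <- dt * F[gb, , drop = FALSE]
    }
    # descent with a trust-region cap so unrelaxed packings cannot blow up
    maxd <- sqrt(max(rowSums(disp^2)))
    if (maxd > 0.2 * mech@aCore)
      disp <- disp * (0.2 * mech@aCore / maxd)
    tissue@pos <- tissue@pos + disp
    tissue@stale <- TRUE
    tissue <- equiangulate(tissue)$tissue
  }
  tissue
}

#' Phase scan over shape factor and activity
#'
#' One run per (p0, fa, seed) on a fixed-boundary disk; the junction
#' tension is set from p0 by \eqn{\Lambda = -p_0 \Gamma \sqrt{A_0}}.
#' Individual run failures are recorded and the sweep continues.
#'
#' @param p0Grid,faGrid numeric grids.
#' @param seeds integer vector of replicate seeds.
#' @param N cells per run.
#' @param Gamma perimeter modulus.
#' @param Dr rotational diffusion constant.
#' @param nSteps,dt,snapshotEvery run schedule.
#' @param after transient discarded before measuring.
#' @param bnd boundary parameters (default fixed).
#' @return data.frame (p0, fa, seed, tauAlpha, t1Rate, tauInst,
#'   classification, error).
#' @export
sweepPhase <- function(p0Grid, faGrid, seeds = 1L, N = 100, Gamma = 1,
                       Dr = 0.005, nSteps = 20000, dt = 0.025,
                       snapshotEvery = 200, after = NULL,
                       bnd = BoundaryParams(mode = "fixed")) {
  if (is.null(after)) after <- 0.2 * nSteps * dt
  rows <- list()
  for (p0 in p0Grid) for (fa in faGrid) for (sd in seeds) {
    row <- data.frame(p0 = p0, fa = fa, seed = sd, tauAlpha = NA_real_,
                      t1Rate = NA_real_, tauInst = NA_real_,
                      classification = NA_character_, error = NA_character_)
    ok <- tryCatch({
      tis <- initPacking("disk", N = N, seed = sd)
      mech <- MechParams(K = 1, Gamma = Gamma,
                         Lambda = lambdaForP0(p0, Gamma), kCore = 1, aCore = 1)
      act <- ActiveParams(fa = fa, D = 0, Dr = Dr, dt = dt)
      tis <- relaxTissue(tis, mech, nSteps = 200, dt = dt)
      traj <- runSimulation(tis, mech, act, bnd = bnd, nSteps = nSteps,
                            snapshotEvery = snapshotEvery, seed = sd + 1000L)
      pm <- classifyPhase(traj, after = after)
      row$tauAlpha <- pm$tauAlphaSentinel
      row$t1Rate <- t1Statistics(traj, after = after)$rate
      row$tauInst <- pm$tauInst
      row$classification <- pm$classification
      TRUE
    }, error = function(e) { row$error <<- conditionMessage(e); FALSE })
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Cell-sorting experiment with two cell types
#'
#' Half the cells are labelled "r", half "b" at random; junction tensions
#' are set per type pair and the tissue evolves under small positional
#' noise with no active driving.  Sorting (rising demixing index) is
#' expected when \eqn{\Lambda_{rb} > (\Lambda_{rr} + \Lambda_{bb})/2};
#' the reverse favours a checkerboard.
#'
#' @param Lrr,Lbb,Lrb,LrM,LbM junction tensions.
#' @param N number of cells.
#' @param D positional noise strength.
#' @param nSteps,dt,measureEvery schedule.
#' @param seed integer seed.
#' @return data.frame (time, demix) with attribute "trajectory".
#' @export
sortingExperiment <- function(Lrr = -6.8, Lbb = -6.2, Lrb = -6.4,
                              LrM = -6.2, LbM = -6.2, N = 100, D = 0.02,
                              nSteps = 10000, dt = 0.01, measureEvery = 250,
                              seed = 1) {
  set.seed(seed)
  tis <- initPacking("disk", N = N, typeFractions = c(r = 0.5, b = 0.5))
  L <- matrix(0, 3, 3, dimnames = list(c("r", "b", "M"), c("r", "b", "M")))
  L["r", "r"] <- Lrr; L["b", "b"] <- Lbb
  L["r", "b"] <- L["b", "r"] <- Lrb
  L["r", "M"] <- L["M", "r"] <- LrM
  L["b", "M"] <- L["M", "b"] <- LbM
  mech <- MechParams(K = 1, Gamma = 1, Lambda = L, kCore = 1, aCore = 1,
                     types = c("r", "b"))
  act <- ActiveParams(fa = 0, D = D, Dr = 0, dt = dt)
  tis <- relaxTissue(tis, mech, nSteps = 200, dt = dt)
  out <- data.frame(time = 0, demix = demixingIndex(tis))
  for (blk in seq_len(nSteps / measureEvery)) {
    traj <- runSimulation(tis, mech, act, nSteps = measureEvery,
                          snapshotEvery = measureEvery)
    tis <- traj@finalTissue
    out <- rbind(out, data.frame(time = blk * measureEvery * dt,
                                 demix = demixingIndex(tis)))
  }
  attr(out, "tissue") <- tis
  out
}
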