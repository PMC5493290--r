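#' Self-intermediate scattering function and alpha-relaxation time
#'
#' \eqn{F(q,t) = \langle \exp(i q \cdot (r(t) - r(0))) \rangle} averaged
#' over interior cells, multiple time origins and equally spaced q
#' directions at fixed magnitude (isotropic average; the real part is
#' reported).  The alpha-relaxation time is the first time F drops below
#' one half (linear interpolation between grid points; Inf when it never
#' does).  Cells created or destroyed within a window are excluded from
#' that window's average.
#'
#' @param traj a [Trajectory-class] object.
#' @param q wave-number magnitude; the conventional choice is 2 pi / a.
#' @param nDirections number of q directions averaged (default 8).
#' @param nOrigins number of time origins averaged (default 10).
#' @return list (class `ScatteringResult`) with `q`, `t`, `F`, `tauAlpha`.
#' @export
selfIntermediate <- function(traj, q = 2 * pi, nDirections = 8,
                             nOrigins = 10) {
  m <- length(traj@frames)
  if (m < 2) stop("need at least 2 snapshots")
  phis <- (seq_len(nDirections) - 1) * 2 * pi / nDirections
  qx <- q * cos(phis); qy <- q * sin(phis)
  times <- traj@times
  lags <- seq(0, m - 1)
  Fq <- numeric(length(lags))
  Fq[1] <- 1
  getInt <- function(f) f[f$flag == "interior", c("id", "x", "y")]
  ints <- lapply(traj@frames, getInt)
  for (li in seq_along(lags)[-1]) {
    L <- lags[li]
    origins <- unique(round(seq(1, m - L, length.out = min(nOrigins, m - L))))
    acc <- 0; nacc <- 0
    for (o in origins) {
      a <- ints[[o]]; b <- ints[[o + L]]
      idx <- match(a$id, b$id)
      ok <- !is.na(idx)
      if (!any(ok)) next
      dx <- b$x[idx[ok]] - a$x[ok]
      dy <- b$y[idx[ok]] - a$y[ok]
      # mean over cells and directions of cos(q . dr)
      acc <- acc + sum(cos(outer(dx, qx) + outer(dy, qy))) /
        (length(dx) * nDirections)
      nacc <- nacc + 1
    }
    Fq[li] <- if (nacc > 0) acc / nacc else NA_real_
  }
  tgrid <- times[lags + 1] - times[1]
  tauAlpha <- firstCrossing(tgrid, Fq, 0.5)
  out <- list(q = q, t = tgrid, F = Fq, tauAlpha = tauAlpha)
  class(out) <- "ScatteringResult"
  out
}

# linear-interpolated first downward crossing of `level`
firstCrossing <- function(t, y, level) {
  below <- which(y < level)
  if (!length(below)) return(Inf)
  k <- below[1]
  if (k == 1) return(t[1])
  t[k - 1] + (level - y[k - 1]) * (t[k] - t[k - 1]) / (y[k] - y[k - 1])
}

#' T1-event statistics of a run
#'
#' T1 flips involving any boundary ghost are excluded when the trajectory is
#' recorded, so the event log contains cell-cell neighbour exchanges only.
#'
#' @param traj a [Trajectory-class] object (or its events data.frame).
#' @param nCellsRef number of interior cells (defaults to the final state).
#' @param duration run duration (defaults to the trajectory span).
#' @param after count only events at time > after (discard transient).
#' @return list(count, rate, perCell): rate in events/(cell time).
#' @export
t1Statistics <- function(traj, nCellsRef = NULL, duration = NULL, after = 0) {
  ev <- if (is(traj, "Trajectory")) traj@events else traj
  if (is.null(nCellsRef)) nCellsRef <- nCells(traj@finalTissue)
  if (is.null(duration)) duration <- max(traj@times) - max(after, min(traj@times))
  t1 <- ev[ev$event == "T1" & ev$time > after, , drop = FALSE]
  ids <- c(t1$id1, t1$id2, t1$id3, t1$id4)
  list(count = nrow(t1),
       rate = nrow(t1) / (nCellsRef * duration),
       perCell = table(ids[!is.na(ids)]))
}

#' Per-cell virial (Hardy) stress and pressure
#'
#' Each cell's stress tensor is assembled from the scalar tensions of the
#' two edge classes whose lengths determine the tissue energy: Voronoi
#' junction edges (carrying the perimeter-modulus and junction-tension
#' derivatives plus the area-term derivative through the kite decomposition
#' A_i = 1/4 sum_j r_ij l_ij) and Delaunay triangulation edges (carrying
#' the complementary area-term derivative and the soft-core force):
#' \deqn{\sigma_i = \frac{1}{2 A_i} \sum_e \phi_e\, t_e\, l_e\,
#'   \hat r_e \otimes \hat r_e, \qquad t_e = \partial E / \partial l_e,}
#' with weight \eqn{\phi_e = 1/2} for edges shared between two cells and 1
#' for edges involving a boundary ghost.  With this weighting the
#' area-weighted mean of \eqn{\mathrm{tr}\,\sigma} equals
#' \eqn{(1/A_{tot})\, dE/d\ln A_{tot}} under an affine dilation exactly.
#' Pressure is reported as \eqn{p = -\frac12 \mathrm{tr}\,\sigma}
#' (tensile stress positive in sigma, so compression gives positive
#' pressure).
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @param mech a [MechParams-class] object.
#' @return data.frame (site, sxx, sxy, syy, pressure, area) plus attribute
#'   "tensors" (list of 2 x 2 matrices).
#' @export
hardyStress <- function(tissue, mech) {
  checkMesh(tissue)
  g <- cpp_cell_geometry(tissue@pos, tissue@triangles, isInterior(tissue))
  sp <- siteParams(tissue, mech)
  n <- nrow(tissue@pos)
  nc <- length(g$site)
  siteCell <- integer(n); siteCell[g$site] <- seq_len(nc)
  kfac <- numeric(n)  # K_i (A_i - A0_i) per interior site
  gfac <- numeric(n)  # Gamma_i P_i
  kfac[g$site] <- sp$K[g$site] * (g$area - sp$A0[g$site])
  gfac[g$site] <- sp$Gamma[g$site] * g$perimeter
  pos <- tissue@pos
  circ <- g$circumcenters
  interior <- isInterior(tissue)
  tensors <- vector("list", nc)
  out <- data.frame(site = g$site, sxx = 0, sxy = 0, syy = 0,
                    pressure = 0, area = g$area)
  for (c in seq_len(nc)) {
    i <- g$site[c]
    idx <- (g$ptr[c] + 1L):g$ptr[c + 1L]
    fan <- g$fan_tri[idx]
    nbr <- g$fan_nbr[idx]
    m <- length(fan)
    S <- matrix(0, 2, 2)
    for (q in seq_len(m)) {
      j <- nbr[q]
      t1 <- fan[q]; t2 <- fan[if (q == m) 1L else q + 1L]
      # Voronoi junction edge dual to Delaunay edge (i, j)
      dv <- circ[t2, ] - circ[t1, ]
      lv <- sqrt(sum(dv^2))
      dd <- pos[j, ] - pos[i, ]
      ld <- sqrt(sum(dd^2))
      jInt <- interior[j]
      lam <- mech@Lambda[tissue@type[i], tissue@type[j]]
      tV <- gfac[i] + gfac[j] + lam * (if (jInt) 2 else 1) +
        0.25 * ld * (kfac[i] + kfac[j])
      tD <- 0.25 * lv * (kfac[i] + kfac[j])
      if (mech@kCore > 0 && ld < mech@aCore)
        tD <- tD - mech@kCore * (mech@aCore - ld)
      phi <- if (jInt) 0.5 else 1
      if (lv > 1e-14) {
        rv <- dv / lv
        S <- S + phi * tV * lv * tcrossprod(rv)
      }
      rd <- dd / ld
      S <- S + phi * tD * ld * tcrossprod(rd)
    }
    S <- S / (2 * g$area[c])
    tensors[[c]] <- S
    out$sxx[c] <- S[1, 1]; out$sxy[c] <- S[1, 2]; out$syy[c] <- S[2, 2]
    out$pressure[c] <- -0.5 * (S[1, 1] + S[2, 2])
  }
  attr(out, "tensors") <- tensors
  out
}

#' Distribution of the number of Voronoi neighbours
#'
#' Neighbours are counted among interior cells only; contacts with boundary
#' ghosts are excluded.
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @param bulkOnly drop cells that touch the boundary.
#' @return a named numeric vector (normalised histogram) with attribute
#'   "counts".
#' @export
neighbourDistribution <- function(tissue, bulkOnly = FALSE) {
  checkMesh(tissue)
  cells <- dualCells(tissue)
  interior <- isInterior(tissue)
  nn <- vapply(cells$neighbours, function(nb) sum(interior[nb]), 0L)
  touches <- vapply(cells$neighbours, function(nb) any(!interior[nb]), FALSE)
  if (bulkOnly) nn <- nn[!touches]
  tb <- table(nn)
  h <- as.numeric(tb) / sum(tb)
  names(h) <- names(tb)
  attr(h, "counts") <- tb
  h
}

#' Demixing index of a two-type tissue
#'
#' Fraction of the cell-cell junction length joining same-type cells
#' (boundary contacts excluded); rises towards 1 during sorting, falls
#' towards the checkerboard value when opposite-type contacts are
#' favourable.
#'
#' @param tissue a [Tissue-class] object with a current mesh.
#' @return scalar in [0, 1]; 1 for a single-type tissue.
#' @export
demixingIndex <- function(tissue) {
  checkMesh(tissue)
  g <- cpp_cell_geometry(tissue@pos, tissue@triangles, isInterior(tissue))
  interior <- isInterior(tissue)
  circ <- g$circumcenters
  same <- tot <- 0
  for (c in seq_along(g$site)) {
    i <- g$site[c]
    idx <- (g$ptr[c] + 1L):g$ptr[c + 1L]
    fan <- g$fan_tri[idx]
    nbr <- g$fan_nbr[idx]
    m <- length(fan)
    nxt <- c(fan[-1], fan[1])
    l <- sqrt(rowSums((circ[nxt, , drop = FALSE] - circ[fan, , drop = FALSE])^2))
    keep <- interior[nbr]
    if (!any(keep)) next
    tot <- tot + sum(l[keep])
    same <- same + sum(l[keep & tissue@type[nbr] == tissue@type[i]])
  }
  if (tot == 0) return(NA_real_)
  same / tot
}

#' Boundary-instability time of a run
#'
#' First time at which the boundary length exceeds `threshold` times its
#' reference (initial) value; Inf when the run stays below.
#'
#' @param traj a [Trajectory-class] object.
#' @param threshold relative growth threshold (default 1.05, i.e. 5 pct).
#' @export
tauInstability <- function(traj, threshold = 1.05) {
  L <- traj@boundaryLength
  if (!length(L)) return(Inf)
  ref <- L[1]
  k <- which(L > threshold * ref)
  if (!length(k)) return(Inf)
  traj@stepTimes[k[1]]
}

#' Classify the dynamical phase of a run
#'
#' Solid-like: no cell-cell T1 events and no relaxation (tau_alpha infinite
#' or beyond the run length).  Unstable: the boundary length grew past the
#' instability threshold at a finite tau_inst.  Otherwise liquid-like.
#'
#' @param traj a [Trajectory-class] object.
#' @param q wave number for the scattering function.
#' @param after transient time discarded before counting T1 events.
#' @param threshold boundary-instability threshold.
#' @return list (class `PhaseMetrics`): t1Rate, tauAlpha, tauInst,
#'   classification; the infinite tau_alpha sentinel used in tables is
#'   10 x the run length with `censored = TRUE`.
#' @export
classifyPhase <- function(traj, q = 2 * pi, after = 0, threshold = 1.05) {
  runLength <- max(traj@times) - min(traj@times)
  t1 <- t1Statistics(traj, after = after)
  fq <- selfIntermediate(traj, q = q)
  ti <- tauInstability(traj, threshold)
  cls <- if (is.finite(ti)) "unstable"
    else if (t1$count == 0 && (!is.finite(fq$tauAlpha) ||
                               fq$tauAlpha > runLength)) "solid"
    else "liquid"
  out <- list(t1Rate = t1$rate, tauAlpha = fq$tauAlpha, tauInst = ti,
              censored = !is.finite(fq$tauAlpha),
              tauAlphaSentinel = if (is.finite(fq$tauAlpha)) fq$tauAlpha
                                 else 10 * runLength,
              classification = cls)
  class(out) <- "PhaseMetrics"
  out
}
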