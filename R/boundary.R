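# boundary edge list: one row per ghost g, edge (g, bnext[g])
boundaryEdges <- function(tissue) {
  i <- which(tissue@flag != "interior")
  cbind(i = i, j = tissue@bnext[i])
}

#' Boundary length of a tissue
#'
#' Total length of all boundary loops (sum over ghost-ghost edges).
#' @param tissue a [Tissue-class] object.
#' @export
boundaryLength <- function(tissue) {
  e <- boundaryEdges(tissue)
  if (!nrow(e)) return(0)
  d <- tissue@pos[e[, 1], , drop = FALSE] - tissue@pos[e[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Boundary-line energy: line tension and bending terms
#'
#' Line term \eqn{\frac12 \sum_{edges} \lambda (l - l_0)^2}; bending term
#' \eqn{\frac12 \sum_i \zeta (\theta_i - \pi)^2} with
#' \eqn{\theta_i = \arccos(\hat r_{ji} \cdot \hat r_{ki})} the angle at
#' ghost i between its left and right boundary neighbours.
#'
#' @param tissue a [Tissue-class] object.
#' @param bnd a [BoundaryParams-class] object.
#' @return list(line_term, bend_term, angles).
#' @export
boundaryEnergy <- function(tissue, bnd) {
  e <- boundaryEdges(tissue)
  if (!nrow(e)) return(list(line_term = 0, bend_term = 0, angles = numeric()))
  p <- tissue@pos
  d <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  line <- 0.5 * bnd@lambda * sum((l - bnd@l0)^2)
  g <- e[, 1]
  u <- p[tissue@bprev[g], , drop = FALSE] - p[g, , drop = FALSE]
  w <- p[tissue@bnext[g], , drop = FALSE] - p[g, , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
  if (any(nu < 1e-12) || any(nw < 1e-12))
    stop("coincident boundary neighbours: bending angle undefined")
  ct <- pmin(1, pmax(-1, rowSums(u * w) / (nu * nw)))
  theta <- acos(ct)
  bend <- 0.5 * bnd@zeta * sum((theta - pi)^2)
  list(line_term = line, bend_term = bend, angles = theta)
}

#' Forces on boundary ghosts from the boundary-line energy
#'
#' Analytic negative gradient of [boundaryEnergy()] with respect to the
#' ghost positions (zero rows for interior particles).
#'
#' @inheritParams boundaryEnergy
#' @return n x 2 force matrix.
#' @export
boundaryForces <- function(tissue, bnd) {
  n <- nrow(tissue@pos)
  F <- matrix(0, n, 2)
  e <- boundaryEdges(tissue)
  if (!nrow(e)) return(F)
  p <- tissue@pos
  # line tension
  d <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  if (bnd@lambda != 0) {
    coef <- bnd@lambda * (l - bnd@l0) / pmax(l, 1e-12)
    fx <- coef * d[, 1]; fy <- coef * d[, 2]
    F[, 1] <- F[, 1] + accumAt(e[, 1], fx, n) - accumAt(e[, 2], fx, n)
    F[, 2] <- F[, 2] + accumAt(e[, 1], fy, n) - accumAt(e[, 2], fy, n)
  }
  # bending
  if (bnd@zeta != 0) {
    g <- e[, 1]
    jp <- tissue@bprev[g]; kn <- tissue@bnext[g]
    u <- p[jp, , drop = FALSE] - p[g, , drop = FALSE]
    w <- p[kn, , drop = FALSE] - p[g, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nw <- sqrt(rowSums(w^2))
    uh <- u / nu; wh <- w / nw
    ct <- pmin(1, pmax(-1, rowSums(uh * wh)))
    st <- sqrt(pmax(0, 1 - ct^2))
    theta <- acos(ct)
    ok <- st > 1e-8
    coefE <- ifelse(ok, -bnd@zeta * (theta - pi) / st, 0)  # -dE/dtheta / sin
    dthj <- (uh * ct - wh) / nu   # sin(theta) * dtheta/dr_j
    dthk <- (wh * ct - uh) / nw
    Fj <- coefE * dthj
    Fk <- coefE * dthk
    for (col in 1:2) {
      F[, col] <- F[, col] +
        accumAt(jp, Fj[, col], n) +
        accumAt(kn, Fk[, col], n) -
        accumAt(g, Fj[, col] + Fk[, col], n)
    }
  }
  F
}

# scatter-add helper
accumAt <- function(idx, val, n) {
  out <- numeric(n)
  a <- rowsum(val, idx)
  out[as.integer(rownames(a))] <- a[, 1]
  out
}

#' Refine the boundary line: split long edges, contract short ones
#'
#' Edges longer than `lMax` are split by inserting a new ghost at the
#' midpoint; edges shorter than `lMin` are contracted by merging their
#' endpoints at the midpoint (skipped if the loop would drop below three
#' ghosts, or if the merged configuration would self-intersect).  The
#' number of boundary loops never changes.
#'
#' @param tissue a [Tissue-class] object.
#' @param bnd a [BoundaryParams-class] object.
#' @return list(tissue, events): tissue has a rebuilt mesh when edits
#'   occurred; events is a data.frame of boundary_add / boundary_remove rows.
#' @export
refineBoundary <- function(tissue, bnd) {
  events <- list()
  changed <- FALSE
  # --- splits ---------------------------------------------------------------
  repeat {
    e <- boundaryEdges(tissue)
    d <- tissue@pos[e[, 2], , drop = FALSE] - tissue@pos[e[, 1], , drop = FALSE]
    l <- sqrt(rowSums(d^2))
    k <- which(l > bnd@lMax)
    if (!length(k)) break
    k <- k[1]
    i <- e[k, 1]; j <- e[k, 2]
    mid <- (tissue@pos[i, ] + tissue@pos[j, ]) / 2
    tissue <- insertGhost(tissue, i, j, mid)
    events[[length(events) + 1L]] <-
      data.frame(event = "boundary_add", id1 = tissue@id[nrow(tissue@pos)],
                 id2 = tissue@id[i], id3 = tissue@id[j], id4 = NA_integer_)
    changed <- TRUE
  }
  # --- merges ---------------------------------------------------------------
  repeat {
    e <- boundaryEdges(tissue)
    d <- tissue@pos[e[, 2], , drop = FALSE] - tissue@pos[e[, 1], , drop = FALSE]
    l <- sqrt(rowSums(d^2))
    k <- which(l < bnd@lMin)
    if (!length(k)) break
    done <- FALSE
    for (kk in k) {
      i <- e[kk, 1]; j <- e[kk, 2]
      if (loopSize(tissue, i) <= 3L) next
      mid <- (tissue@pos[i, ] + tissue@pos[j, ]) / 2
      if (mergeWouldIntersect(tissue, i, j, mid)) {
        warning("boundary merge rejected: would self-intersect")
        next
      }
      events[[length(events) + 1L]] <-
        data.frame(event = "boundary_remove", id1 = tissue@id[j],
                   id2 = tissue@id[i], id3 = NA_integer_, id4 = NA_integer_)
      tissue <- mergeGhosts(tissue, i, j, mid)
      changed <- TRUE
      done <- TRUE
      break
    }
    if (!done) break
  }
  if (changed) tissue <- buildTriangulation(tissue)
  list(tissue = tissue,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(event = character(), id1 = integer(),
                                id2 = integer(), id3 = integer(),
                                id4 = integer()))
}

loopSize <- function(tissue, g) {
  cur <- tissue@bnext[g]; m <- 1L
  while (cur != g) { cur <- tissue@bnext[cur]; m <- m + 1L }
  m
}

insertGhost <- function(tissue, i, j, at) {
  n <- nrow(tissue@pos)
  tissue@pos <- rbind(tissue@pos, at)
  rownames(tissue@pos) <- NULL
  tissue@flag <- c(tissue@flag, tissue@flag[i])
  tissue@type <- c(tissue@type, "M")
  tissue@theta <- c(tissue@theta, NA_real_)
  tissue@A0 <- c(tissue@A0, NA_real_)
  tissue@age <- c(tissue@age, NA_real_)
  tissue@id <- c(tissue@id, max(tissue@id) + 1L)
  tissue@bnext <- c(tissue@bnext, j)
  tissue@bprev <- c(tissue@bprev, i)
  tissue@bnext[i] <- n + 1L
  tissue@bprev[j] <- n + 1L
  tissue@stale <- TRUE
  tissue
}

mergeGhosts <- function(tissue, i, j, at) {
  # move i to the midpoint, splice j out, then drop row j
  tissue@pos[i, ] <- at
  nx <- tissue@bnext[j]
  tissue@bnext[i] <- nx
  tissue@bprev[nx] <- i
  keep <- setdiff(seq_len(nrow(tissue@pos)), j)
  remap <- integer(nrow(tissue@pos)); remap[keep] <- seq_along(keep)
  tissue@pos <- tissue@pos[keep, , drop = FALSE]
  tissue@flag <- tissue@flag[keep]; tissue@type <- tissue@type[keep]
  tissue@theta <- tissue@theta[keep]; tissue@A0 <- tissue@A0[keep]
  tissue@age <- tissue@age[keep]; tissue@id <- tissue@id[keep]
  bn <- tissue@bnext[keep]; bp <- tissue@bprev[keep]
  tissue@bnext <- remapLinks(bn, remap)
  tissue@bprev <- remapLinks(bp, remap)
  tissue@stale <- TRUE
  tissue
}

# remap 1-based links through `remap`, keeping 0 (no link) fixed
remapLinks <- function(links, remap) c(0L, remap)[links + 1L]

mergeWouldIntersect <- function(tissue, i, j, at) {
  p <- tissue@pos
  p[i, ] <- at
  e <- boundaryEdges(tissue)
  # edges after the merge: splice j out
  e <- e[e[, 1] != j & e[, 2] != j, , drop = FALSE]
  e <- rbind(e, c(i, tissue@bnext[j]))
  anyCrossing(p, e)
}

# proper-crossing test over all edge pairs (shared endpoints excluded)
anyCrossing <- function(p, e) {
  m <- nrow(e)
  if (m < 2) return(FALSE)
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      if (length(intersect(e[a, ], e[b, ]))) next
      if (segCross(p[e[a, 1], ], p[e[a, 2], ], p[e[b, 1], ], p[e[b, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

segCross <- function(a, b, c, d) {
  o <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

#' Verify the boundary-topology invariants
#'
#' The boundary topology is fixed for a whole run: every ghost has exactly
#' two boundary neighbours, every loop is a simple (non-self-intersecting)
#' polygon, and the number of loops is constant.  Splitting a tissue into
#' two domains or opening a hole is not representable; this guard is the
#' safety net that detects a corrupted boundary.
#'
#' @param tissue a [Tissue-class] object.
#' @param referenceLoopCount optional expected number of loops.
#' @return list(ok = logical, violations = character vector).
#' @export
topologyGuard <- function(tissue, referenceLoopCount = NULL) {
  v <- character()
  ghosts <- which(tissue@flag != "interior")
  ok2 <- tryCatch({
    loops <- boundaryLoops(tissue)
    if (length(unlist(loops)) != length(ghosts))
      v <- c(v, "ghosts outside any loop")
    if (!is.null(referenceLoopCount) && length(loops) != referenceLoopCount)
      v <- c(v, sprintf("loop count changed: %d != %d", length(loops),
                        referenceLoopCount))
    TRUE
  }, error = function(e) {
    v <<- c(v, conditionMessage(e)); FALSE
  })
  if (ok2) {
    bn <- tissue@bnext[ghosts]
    if (anyDuplicated(bn) || any(bn == 0L) ||
        !all(tissue@bprev[bn] == ghosts))
      v <- c(v, "two-neighbour property violated")
    if (anyCrossing(tissue@pos, boundaryEdges(tissue)))
      v <- c(v, "boundary line self-intersects")
  }
  list(ok = length(v) == 0L, violations = v)
}
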