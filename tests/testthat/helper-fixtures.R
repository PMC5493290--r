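# Fixtures and independent oracles shared across the test files.

# random interior sites in a disk, enclosed by a ring of boundary ghosts
makeDiskTissue <- function(nInt = 60, seed = 1, Rint = NULL, types = NULL) {
  set.seed(seed)
  if (is.null(Rint)) Rint <- sqrt(nInt)
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < nInt) {
    cand <- matrix(runif(2 * nInt, -Rint, Rint), ncol = 2)
    cand <- cand[sqrt(rowSums(cand^2)) < Rint, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(nInt), , drop = FALSE]
  Rg <- Rint + 1.2
  m <- max(8L, round(2 * pi * Rg))
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  ghosts <- cbind(Rg * cos(th), Rg * sin(th))
  if (is.null(types)) types <- rep("c", nInt)
  Tissue(rbind(pts, ghosts),
         flag = c(rep("interior", nInt), rep("boundary", m)),
         type = c(types, rep("M", m)),
         theta = c(runif(nInt, -pi, pi), rep(NA_real_, m)),
         boundaryLoops = list(nInt + seq_len(m)))
}

# triangular-lattice patch: rings 0..nr of spacing d, outermost ring = ghosts
makeHexTissue <- function(nr = 4, d = 2) {
  a1 <- c(d, 0); a2 <- c(d / 2, d * sqrt(3) / 2)
  pts <- ring <- NULL
  hexdist <- function(i, j) (abs(i) + abs(j) + abs(i + j)) / 2
  for (i in -nr:nr) for (j in -nr:nr) {
    h <- hexdist(i, j)
    if (h > nr) next
    p <- i * a1 + j * a2
    pts <- rbind(pts, c(p, h))
  }
  interior <- pts[pts[, 3] < nr, 1:2, drop = FALSE]
  ghost <- pts[pts[, 3] == nr, 1:2, drop = FALSE]
  ghost <- ghost[order(atan2(ghost[, 2], ghost[, 1])), , drop = FALSE]
  nInt <- nrow(interior); m <- nrow(ghost)
  Tissue(rbind(interior, ghost),
         flag = c(rep("interior", nInt), rep("boundary", m)),
         boundaryLoops = list(nInt + seq_len(m)))
}

# hexagon-lattice reference values for spacing d
hexCellArea <- function(d) sqrt(3) / 2 * d^2
hexCellPerim <- function(d) 2 * sqrt(3) * d

# R-side incircle determinant: > 0 iff p lies strictly inside the
# circumcircle of CCW triangle (a, b, c)
incircleDet <- function(a, b, c, p) {
  M <- rbind(c(a - p, sum((a - p)^2)),
             c(b - p, sum((b - p)^2)),
             c(c - p, sum((c - p)^2)))
  det(M)
}

# certificate: every interior edge of the mesh satisfies the empty-
# circumcircle property
isDelaunayMesh <- function(pos, tri, tol = 1e-9) {
  key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  adj <- list()
  for (t in seq_len(nrow(tri))) {
    for (e in list(tri[t, 1:2], tri[t, 2:3], tri[t, c(3, 1)])) {
      k <- key(e[1], e[2])
      adj[[k]] <- c(adj[[k]], t)
    }
  }
  scale4 <- max(abs(pos))^4
  for (k in names(adj)) {
    ts <- adj[[k]]
    if (length(ts) != 2) next
    uv <- as.integer(strsplit(k, " ")[[1]])
    opp <- vapply(ts, function(t) setdiff(tri[t, ], uv), 0L)
    a <- pos[uv[1], ]; b <- pos[uv[2], ]
    c1 <- pos[opp[1], ]; d1 <- pos[opp[2], ]
    o <- (b[1] - a[1]) * (c1[2] - a[2]) - (b[2] - a[2]) * (c1[1] - a[1])
    inc <- if (o > 0) incircleDet(a, b, c1, d1) else incircleDet(b, a, c1, d1)
    if (inc > tol * scale4) return(FALSE)
  }
  TRUE
}

# sorted canonical edge set of a triangulation (for oracle comparison)
edgeSet <- function(tri) {
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# central finite-difference gradient of the vertex-model energy
fdForces <- function(tissue, mech, idx, h = 1e-6, bnd = NULL) {
  F <- matrix(NA_real_, length(idx), 2)
  for (r in seq_along(idx)) for (k in 1:2) {
    tp <- tissue; tp@pos[idx[r], k] <- tp@pos[idx[r], k] + h
    tp@stale <- TRUE; tp <- equiangulate(tp)$tissue
    tm <- tissue; tm@pos[idx[r], k] <- tm@pos[idx[r], k] - h
    tm@stale <- TRUE; tm <- equiangulate(tm)$tissue
    ep <- vmEnergy(tp, mech, bnd = bnd)$total
    em <- vmEnergy(tm, mech, bnd = bnd)$total
    F[r, k] <- -(ep - em) / (2 * h)
  }
  F
}

# independent from-scratch Delaunay oracle: scipy.spatial.Delaunay run in a
# single batched python call; returns a list of 1-based edge matrices
scipyDelaunayEdges <- function(posList) {
  stopifnot(requireNamespace("jsonlite", quietly = TRUE))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(posList, function(p) unname(as.matrix(p))),
                       fin, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import numpy as np",
    "from scipy.spatial import Delaunay",
    "data = json.load(open(sys.argv[1]))",
    "out = []",
    "for pts in data:",
    "    tr = Delaunay(np.asarray(pts, dtype=float))",
    "    es = set()",
    "    for s in tr.simplices:",
    "        for a, b in ((0, 1), (1, 2), (2, 0)):",
    "            u, v = sorted((int(s[a]), int(s[b])))",
    "            es.add((u, v))",
    "    es = sorted(es)",
    "    out.append({'u': [e[0] for e in es], 'v': [e[1] for e in es],",
    "                't0': [int(s[0]) for s in tr.simplices],",
    "                't1': [int(s[1]) for s in tr.simplices],",
    "                't2': [int(s[2]) for s in tr.simplices]})",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  st <- system2("python", c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) stop("scipy oracle failed: ", paste(st, collapse = "\n"))
  res <- jsonlite::read_json(fout)
  lapply(res, function(r) {
    e <- cbind(unlist(r$u), unlist(r$v)) + 1L
    storage.mode(e) <- "integer"
    tri <- cbind(unlist(r$t0), unlist(r$t1), unlist(r$t2)) + 1L
    storage.mode(tri) <- "integer"
    list(edges = e[order(e[, 1], e[, 2]), , drop = FALSE], triangles = tri)
  })
}

# equiangulated result vs from-scratch oracle: identical edge sets, or --
# when degenerate ties make the Delaunay triangulation non-unique -- both
# must pass the strict empty-circumcircle certificate
sameDelaunay <- function(pos, tri, oracle) {
  isTRUE(identical(edgeSet(tri), oracle$edges)) ||
    (isDelaunayMesh(pos, tri) && isDelaunayMesh(pos, oracle$triangles))
}

# apply n random legal (orientation-preserving) edge flips to a valid
# triangulation, producing a valid but generally non-Delaunay mesh
randomFlips <- function(pos, tri, n = 10) {
  orient <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  for (rep in seq_len(n)) {
    e <- edgeSet(tri)
    e <- e[sample(nrow(e)), , drop = FALSE]
    for (r in seq_len(nrow(e))) {
      u <- e[r, 1]; v <- e[r, 2]
      ts <- which(apply(tri, 1, function(tr) u %in% tr && v %in% tr))
      if (length(ts) != 2) next
      c1 <- setdiff(tri[ts[1], ], c(u, v))
      d1 <- setdiff(tri[ts[2], ], c(u, v))
      a <- pos[u, ]; b <- pos[v, ]; pc <- pos[c1, ]; pd <- pos[d1, ]
      # flip valid iff quad strictly convex
      if (orient(pc, a, pd) <= 1e-12 || orient(pd, b, pc) <= 1e-12) next
      if (orient(a, pd, pc) == 0 || orient(b, pc, pd) == 0) next
      t1 <- c(c1, u, d1); t2 <- c(c1, d1, v)
      fix <- function(t) if (orient(pos[t[1], ], pos[t[2], ], pos[t[3], ]) > 0)
        t else t[c(1, 3, 2)]
      tri[ts[1], ] <- fix(t1)
      tri[ts[2], ] <- fix(t2)
      break
    }
  }
  tri
}
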