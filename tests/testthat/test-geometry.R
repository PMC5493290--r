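test_that("circumcenter matches symmetry cases and the equidistance oracle", {
  expect_equal(circumcenter(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
               c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  expect_equal(circumcenter(c(0, 0), c(2, 0), c(0, 2)), c(1, 1),
               tolerance = 1e-12)
  # brute-force oracle: solve the two equidistance equations directly
  p1 <- c(0, 0); p2 <- c(3, 0); p3 <- c(1, 2)
  A <- 2 * rbind(p2 - p1, p3 - p1)
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
  oracle <- solve(A, b)
  cc <- circumcenter(p1, p2, p3)
  expect_equal(cc, unname(oracle), tolerance = 1e-12)
  d <- sapply(list(p1, p2, p3), function(p) sqrt(sum((cc - p)^2)))
  expect_lt(diff(range(d)), 1e-12)
  set.seed(7)
  for (k in 1:20) {
    ps <- matrix(rnorm(6), 3, 2)
    cc <- circumcenter(ps[1, ], ps[2, ], ps[3, ])
    d <- sqrt(rowSums((ps - matrix(cc, 3, 2, byrow = TRUE))^2))
    expect_lt(diff(range(d)), 1e-10)
  }
  expect_error(circumcenter(c(0, 0), c(1, 1), c(2, 2), ids = c(4, 5, 6)),
               "sites 4, 5, 6")
})

test_that("triangulation construction is Delaunay and matches scipy", {
  # unit square plus corners as its own boundary
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tis <- Tissue(pos, flag = rep("boundary", 4), boundaryLoops = list(1:4))
  tri <- triangulation(tis)
  expect_true(nrow(tri) %in% c(2L, 4L))
  expect_true(isDelaunayMesh(pos, tri))
  # random disk vs independent from-scratch construction
  tis2 <- makeDiskTissue(nInt = 50, seed = 3)
  expect_true(isDelaunayMesh(positions(tis2), triangulation(tis2)))
  oe <- scipyDelaunayEdges(list(positions(tis2)))[[1]]
  expect_identical(edgeSet(triangulation(tis2)), oe$edges)
  # collinear input has no triangulation
  expect_error(Tissue(cbind(0:2, 0:2)), "collinear|degenerate")
  expect_error(Tissue(rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 0))),
               "duplicate")
})

test_that("equiangulation flips an obtuse quadrilateral and fixes nothing twice", {
  pos <- rbind(c(0, 0), c(2, 0), c(1, 0.5), c(1, -0.5))
  tri <- rbind(c(1L, 2L, 3L), c(1L, 4L, 2L))
  # opposite angles at sites 3 and 4 sum to > 180 degrees
  r <- avm:::cpp_equiangulate(pos, tri)
  expect_equal(r$n_flips, 1L)
  expect_identical(unname(sort(r$flipped[1, 1:2])), c(1L, 2L))  # lost junction
  expect_identical(unname(sort(r$flipped[1, 3:4])), c(3L, 4L))  # gained junction
  expect_true(isDelaunayMesh(pos, r$triangles))
  # incircle predicate confirms the flip was required
  expect_gt(incircleDet(pos[1, ], pos[2, ], pos[3, ], pos[4, ]), 0)
  # idempotence on an already-Delaunay mesh
  r2 <- avm:::cpp_equiangulate(pos, r$triangles)
  expect_equal(r2$n_flips, 0L)
  expect_identical(edgeSet(r2$triangles), edgeSet(r$triangles))
})

test_that("equiangulation of a perturbed mesh equals from-scratch Delaunay", {
  tis <- makeDiskTissue(nInt = 100, seed = 11)
  set.seed(1)
  pos <- positions(tis)
  k <- sample(which(isInterior(tis)), 1)
  pos[k, ] <- pos[k, ] + c(0.05, -0.03)
  positions(tis) <- pos
  eq <- equiangulate(tis)
  expect_true(isDelaunayMesh(pos, triangulation(eq$tissue)))
  oracle <- scipyDelaunayEdges(list(pos))[[1]]
  expect_identical(edgeSet(triangulation(eq$tissue)), oracle$edges)
})

test_that("dual cells reproduce lattice geometry and the shoelace identity", {
  hex <- makeHexTissue(nr = 4, d = 2)
  cells <- dualCells(hex)
  expect_equal(cells$area, rep(hexCellArea(2), length(cells$area)),
               tolerance = 1e-10)
  expect_equal(cells$perimeter, rep(hexCellPerim(2), length(cells$perimeter)),
               tolerance = 1e-10)
  expect_true(all(lengths(cells$neighbours) == 6L))
  # square lattice: bulk cells are unit squares
  g <- expand.grid(x = 0:6, y = 0:6)
  onEdge <- g$x %in% c(0, 6) | g$y %in% c(0, 6)
  ord <- order(atan2(g$y[onEdge] - 3, g$x[onEdge] - 3))
  pos <- rbind(as.matrix(g[!onEdge, ]), as.matrix(g[onEdge, ][ord, ]))
  nInt <- sum(!onEdge)
  sq <- Tissue(pos, flag = c(rep("interior", nInt),
                             rep("boundary", sum(onEdge))),
               boundaryLoops = list(nInt + seq_len(sum(onEdge))))
  cs <- dualCells(sq)
  expect_equal(cs$area, rep(1, length(cs$area)), tolerance = 1e-10)
  # random tissue: stored area equals the shoelace value of the vertex list
  tis <- makeDiskTissue(nInt = 200, seed = 5)
  cells <- dualCells(tis)
  for (c in seq_along(cells$site)) {
    v <- cells$vertices[[c]]
    nxt <- c(2:nrow(v), 1)
    shoelace <- 0.5 * sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])
    expect_equal(cells$area[c], shoelace, tolerance = 1e-12)
  }
  # all-interior tissue: unbounded cells must be refused
  open <- Tissue(matrix(runif(20), 10, 2))
  expect_error(dualCells(open), "unbounded|boundary ghosts")
})

test_that("voronoi vertices are equidistant from their three sites", {
  tis <- makeDiskTissue(nInt = 80, seed = 9)
  cells <- dualCells(tis)
  tri <- triangulation(tis)
  pos <- positions(tis)
  for (t in seq_len(nrow(tri))) {
    d <- sqrt(rowSums((pos[tri[t, ], ] -
                         matrix(cells$circumcenters[t, ], 3, 2,
                                byrow = TRUE))^2))
    expect_lt(diff(range(d)), 1e-10)
  }
})

test_that("vertex Jacobians sum to identity, match FD and rotate covariantly", {
  tis <- makeDiskTissue(nInt = 30, seed = 2)
  tri <- triangulation(tis)
  set.seed(4)
  for (t in sample(nrow(tri), 5)) {
    Js <- lapply(tri[t, ], function(s) vertexJacobian(tis, t, s))
    expect_equal(Reduce(`+`, Js), diag(2), tolerance = 1e-10)
    # finite-difference oracle on the circumcenter map
    p <- positions(tis)[tri[t, ], ]
    h <- 1e-6
    for (corner in 1:3) {
      for (k in 1:2) {
        pp <- p; pp[corner, k] <- pp[corner, k] + h
        pm <- p; pm[corner, k] <- pm[corner, k] - h
        fd <- (circumcenter(pp[1, ], pp[2, ], pp[3, ]) -
                 circumcenter(pm[1, ], pm[2, ], pm[3, ])) / (2 * h)
        expect_equal(Js[[corner]][, k], unname(fd), tolerance = 1e-5)
      }
    }
  }
  # rotation equivariance: J(R p) = R J(p) R^T
  p <- matrix(rnorm(6), 3, 2)
  phi <- 0.7
  R <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  J <- avm:::jacobianCircumcenter(p[1, ], p[2, ], p[3, ], 2)
  pr <- t(R %*% t(p))
  Jr <- avm:::jacobianCircumcenter(pr[1, ], pr[2, ], pr[3, ], 2)
  expect_equal(Jr, R %*% J %*% t(R), tolerance = 1e-10)
  expect_error(vertexJacobian(tis, 1, 10000), "not a corner")
})

test_that("one edge flip only changes the four quadrilateral cells", {
  tis <- makeDiskTissue(nInt = 80, seed = 13)
  pos <- positions(tis)
  triOld <- triangulation(tis)
  # move one interior site just enough to force exactly one flip
  set.seed(3)
  done <- FALSE
  for (trial in 1:200) {
    k <- sample(which(isInterior(tis)), 1)
    p2 <- pos
    p2[k, ] <- p2[k, ] + rnorm(2, 0, 0.08)
    r <- avm:::cpp_equiangulate(p2, triOld)
    if (r$n_flips == 1L) { done <- TRUE; break }
  }
  expect_true(done)
  quad <- as.integer(r$flipped[1, ])
  before <- avm:::cpp_cell_geometry(p2, triOld, isInterior(tis))
  after <- avm:::cpp_cell_geometry(p2, r$triangles, isInterior(tis))
  vlist <- function(g, c) {
    idx <- (g$ptr[c] + 1L):g$ptr[c + 1L]
    v <- g$circumcenters[g$fan_tri[idx], , drop = FALSE]
    v[order(atan2(v[, 2], v[, 1])), , drop = FALSE]  # canonical rotation
  }
  for (c in seq_along(before$site)) {
    if (before$site[c] %in% quad) next
    expect_identical(vlist(before, c), vlist(after, c))
  }
  changed <- vapply(seq_along(before$site), function(c)
    !isTRUE(all.equal(vlist(before, c), vlist(after, c))), FALSE)
  expect_lte(sum(changed), 4L)
})

test_that("a driven junction shrinks smoothly to zero through the T1 point", {
  # four cells around a shrinking junction, enclosed by a ghost ring
  base <- rbind(c(-2, 0), c(2, 0), c(0, 1.4), c(0, -1.4))
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  ghosts <- cbind(6 * cos(th), 6 * sin(th))
  junctionLength <- function(s) {
    pos <- base
    pos[3, 2] <- 1.4 + s  # drive the top site outwards across cocircularity
    tis <- Tissue(rbind(pos, ghosts),
                  flag = c(rep("interior", 4), rep("boundary", 16)),
                  boundaryLoops = list(4 + seq_len(16)))
    cells <- dualCells(tis)
    c3 <- which(cells$site == 3)
    nb <- cells$neighbours[[c3]]
    v <- cells$vertices[[c3]]
    e4 <- which(nb == 4L)
    if (!length(e4)) return(0)  # junction gone: cells 3 and 4 no longer touch
    nxt <- if (e4 == nrow(v)) 1L else e4 + 1L
    sqrt(sum((v[nxt, ] - v[e4, ])^2))
  }
  s <- seq(0, 2, length.out = 401)
  l <- vapply(s, junctionLength, 0)
  expect_gt(l[1], 0.2)            # junction open before the drive
  expect_equal(min(l), 0, tolerance = 0.02)  # shrinks to a point
  expect_equal(l[length(l)], 0)   # and stays closed after the exchange
  expect_lt(max(abs(diff(l))), 0.03)         # no discontinuous jump
})

test_that("equiangulation agrees with the from-scratch oracle on random sets", {
  set.seed(21)
  cases <- lapply(1:50, function(k) {
    n <- sample(10:30, 1)
    matrix(runif(2 * n, 0, 10), ncol = 2)
  })
  oracle <- scipyDelaunayEdges(cases)
  for (k in seq_along(cases)) {
    pos <- cases[[k]]
    tri0 <- avm:::cpp_delaunay(pos)
    scrambled <- randomFlips(pos, tri0, n = 6)
    r <- avm:::cpp_equiangulate(pos, scrambled)
    expect_true(sameDelaunay(pos, r$triangles, oracle[[k]]))
  }
})
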