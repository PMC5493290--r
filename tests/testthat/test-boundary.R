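# ghost-only loop tissue helper
loopTissue <- function(pts) {
  Tissue(pts, flag = rep("boundary", nrow(pts)),
         boundaryLoops = list(seq_len(nrow(pts))), build = nrow(pts) >= 3)
}

test_that("boundary line and bending energies match hand values", {
  # isoceles loop: two edges of length l0 = 2, one stretched to l0 + 1
  l0 <- 2
  apex <- c(1.5, sqrt(l0^2 - 1.5^2))
  tri <- loopTissue(rbind(c(0, 0), c(3, 0), apex))
  bnd <- BoundaryParams(mode = "free", lambda = 2, l0 = l0, zeta = 0)
  E <- boundaryEnergy(tri, bnd)
  expect_equal(E$line_term, 0.5 * 2 * 1^2)
  expect_equal(E$bend_term, 0)
  # square loop: four right angles, each contributing (1/2)(pi/2)^2
  sq <- loopTissue(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  bndb <- BoundaryParams(mode = "free", lambda = 0, l0 = 1, zeta = 1)
  Eb <- boundaryEnergy(sq, bndb)
  expect_equal(Eb$angles, rep(pi / 2, 4))
  expect_equal(Eb$bend_term, 4 * 0.5 * (pi / 2)^2, tolerance = 1e-12)
  expect_equal(Eb$line_term, 0)
  # a straight (locally flat) stretch at native length costs nothing
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  R <- 1 / (2 * sin(pi / 100))  # polygon side exactly l0 = 1
  circ <- loopTissue(cbind(R * cos(th), R * sin(th)))
  Ec <- boundaryEnergy(circ, BoundaryParams(lambda = 3, l0 = 1, zeta = 0))
  expect_equal(Ec$line_term, 0, tolerance = 1e-12)
})

test_that("boundary forces equal the finite-difference gradient", {
  set.seed(8)
  th <- sort(runif(12, 0, 2 * pi))
  r <- 3 + runif(12, -0.5, 0.5)
  tis <- loopTissue(cbind(r * cos(th), r * sin(th)))
  bnd <- BoundaryParams(mode = "free", lambda = 1.3, l0 = 1.2, zeta = 0.7)
  F <- boundaryForces(tis, bnd)
  h <- 1e-6
  for (i in c(1, 5, 9)) for (k in 1:2) {
    tp <- tis; tp@pos[i, k] <- tp@pos[i, k] + h
    tm <- tis; tm@pos[i, k] <- tm@pos[i, k] - h
    ep <- sum(unlist(boundaryEnergy(tp, bnd)[c("line_term", "bend_term")]))
    em <- sum(unlist(boundaryEnergy(tm, bnd)[c("line_term", "bend_term")]))
    expect_equal(F[i, k], -(ep - em) / (2 * h), tolerance = 1e-5)
  }
  # stretched circle: net inward pull, zero total force
  th2 <- seq(0, 2 * pi, length.out = 21)[-21]
  circ <- loopTissue(cbind(5 * cos(th2), 5 * sin(th2)))
  bnd2 <- BoundaryParams(mode = "free", lambda = 1, l0 = 0.5, zeta = 0)
  Fc <- boundaryForces(circ, bnd2)
  radial <- rowSums(Fc * positions(circ)) /
    sqrt(rowSums(positions(circ)^2))
  expect_true(all(radial < 0))
  expect_equal(colSums(Fc), c(0, 0), tolerance = 1e-10)
})

test_that("refinement splits long edges and contracts short ones", {
  bnd <- BoundaryParams(mode = "free", lambda = 0.1, l0 = 1, zeta = 0.1)
  # one edge exactly twice lMax: split into two edges of length lMax
  w <- 2 * bnd@lMax
  pts <- rbind(c(0, 0), c(w, 0), c(w, 1.5), c(2.7, 1.9), c(1.3, 1.9),
               c(0, 1.5))
  tis <- loopTissue(pts)
  r <- refineBoundary(tis, bnd)
  expect_equal(r$events$event, "boundary_add")
  e <- avm:::boundaryEdges(r$tissue)
  l <- sqrt(rowSums((r$tissue@pos[e[, 1], ] - r$tissue@pos[e[, 2], ])^2))
  expect_equal(sort(l)[length(l) - 0:1], c(bnd@lMax, bnd@lMax))
  tg <- topologyGuard(r$tissue, 1)
  expect_true(tg$ok)
  # edges inside the band: untouched
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  R <- 1.2 / (2 * sin(pi / 12))
  ok <- loopTissue(cbind(R * cos(th), R * sin(th)))
  r2 <- refineBoundary(ok, bnd)
  expect_equal(nrow(r2$events), 0L)
  expect_identical(positions(r2$tissue), positions(ok))
  # jagged loop: repeated refinement lands in the resolution band
  set.seed(9)
  th3 <- sort(runif(20, 0, 2 * pi))
  r3v <- 4 + runif(20, -1, 1)
  jag <- loopTissue(cbind(r3v * cos(th3), r3v * sin(th3)))
  cur <- jag
  for (k in 1:6) cur <- suppressWarnings(refineBoundary(cur, bnd)$tissue)
  e3 <- avm:::boundaryEdges(cur)
  l3 <- sqrt(rowSums((cur@pos[e3[, 1], ] - cur@pos[e3[, 2], ])^2))
  expect_true(all(l3 >= bnd@lMin / 2 - 1e-9 & l3 <= bnd@lMax + 1e-9))
  expect_true(topologyGuard(cur, 1)$ok)
})

test_that("merges never shrink a loop below three ghosts", {
  bnd <- BoundaryParams(mode = "free", lambda = 0, l0 = 10, zeta = 0,
                        lMin = 5, lMax = 20)
  tri <- loopTissue(rbind(c(0, 0), c(1, 0), c(0.5, 1)))
  r <- refineBoundary(tri, bnd)   # all edges "short" but nothing may merge
  expect_equal(nrow(r$events), 0L)
  expect_equal(sum(r$tissue@flag != "interior"), 3L)
})

test_that("the topology guard detects corrupted boundaries", {
  tis <- makeDiskTissue(nInt = 20, seed = 5)
  expect_true(topologyGuard(tis, 1)$ok)
  # figure-eight: swap two non-adjacent links to splice the loop
  bad <- tis
  g <- which(bad@flag != "interior")
  a <- g[1]; b <- g[8]
  na <- bad@bnext[a]; nb <- bad@bnext[b]
  bad@bnext[a] <- nb; bad@bprev[nb] <- a
  bad@bnext[b] <- na; bad@bprev[na] <- b
  tg <- topologyGuard(bad, 1)
  expect_false(tg$ok)
  # loop count change is flagged
  tg2 <- topologyGuard(tis, 2)
  expect_false(tg2$ok)
  expect_match(paste(tg2$violations, collapse = " "), "loop count")
})

test_that("fixed ghosts stay put while free ghosts follow the forces", {
  tis <- makeDiskTissue(nInt = 25, seed = 7)
  mech <- MechParams(K = 1, Gamma = 1, Lambda = lambdaForP0(3.5),
                     kCore = 1, aCore = 1)
  act <- ActiveParams(fa = 0, D = 0, dt = 0.01)
  gpos <- positions(tis)[!isInterior(tis), ]
  fx <- stepTissue(tis, mech, act,
                   bnd = BoundaryParams(mode = "fixed", lambda = 0.1))
  expect_identical(positions(fx$tissue)[!isInterior(tis), ], gpos)
  fr <- stepTissue(tis, mech, act,
                   bnd = BoundaryParams(mode = "free", lambda = 0.1, l0 = 1))
  expect_gt(max(abs(positions(fr$tissue)[!isInterior(tis), ] - gpos)), 0)
})

test_that("strong line tension pulls a corrugated boundary towards minimal", {
  tis <- initPacking("disk", N = 30, seed = 11)
  mech <- MechParams(K = 1, Gamma = 1, Lambda = lambdaForP0(3.3),
                     kCore = 1, aCore = 1)
  tis <- relaxTissue(tis, mech, nSteps = 100, dt = 0.01)
  # corrugate the ghost line: alternate radial bumps, far from minimal
  g <- which(tis@flag != "interior")
  rr <- sqrt(rowSums(tis@pos[g, ]^2))
  bump <- 1 + 0.18 * rep_len(c(1, -1), length(g))
  tis@pos[g, ] <- tis@pos[g, ] * bump
  tis@stale <- TRUE
  tis <- buildTriangulation(tis)
  act <- ActiveParams(fa = 0, D = 0, dt = 0.005)
  bnd <- BoundaryParams(mode = "free", lambda = 20, l0 = 0.2, zeta = 0.1)
  L0 <- boundaryLength(tis)
  traj <- runSimulation(tis, mech, act, bnd = bnd, nSteps = 400,
                        snapshotEvery = 400, seed = 3, guardEvery = 0)
  L <- traj@boundaryLength
  expect_lt(L[length(L)], L0)
  # decreasing trend over the window
  expect_lt(mean(tail(L, 100)), mean(head(L, 100)))
})
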