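# tissue whose vertex-model forces are numerically negligible: reference
# areas pinned to the current areas, no perimeter, junction or core terms
freeTissue <- function(nInt = 50, seed = 1, spacing = 8) {
  set.seed(seed)
  m <- ceiling(sqrt(nInt))
  g <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m)))[seq_len(nInt), ]
  pts <- g * spacing + matrix(runif(2 * nInt, -1, 1), ncol = 2)
  ctr <- colMeans(pts)
  Rg <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2))) + 10
  mg <- max(12L, round(2 * pi * Rg / 4))
  th <- seq(0, 2 * pi, length.out = mg + 1)[-(mg + 1)]
  tis <- Tissue(rbind(pts, cbind(ctr[1] + Rg * cos(th),
                                 ctr[2] + Rg * sin(th))),
                flag = c(rep("interior", nInt), rep("boundary", mg)),
                boundaryLoops = list(nInt + seq_len(mg)))
  tis@A0[isInterior(tis)] <- dualCells(tis)$area
  tis
}
freeMech <- MechParams(K = 1e-12, Gamma = 0, Lambda = 0, kCore = 0, aCore = 1)

test_that("alignment torques follow the three coupling rules", {
  # two interior cells side by side inside a ghost ring
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  tis <- Tissue(rbind(c(-1, 0), c(1, 0), cbind(5 * cos(th), 5 * sin(th))),
                flag = c("interior", "interior", rep("boundary", 12)),
                boundaryLoops = list(2 + seq_len(12)))
  tis@theta[1:2] <- c(0, pi / 2)
  act <- ActiveParams(Jp = 1, alignment = "polar", dt = 0.01)
  tau <- alignmentTorque(tis, act)
  expect_equal(tau[1], 1)    # d/dtheta_i of -cos(theta_j - theta_i)
  expect_equal(tau[2], -1)
  # velocity model: zero for parallel, sine of the angle otherwise
  act2 <- ActiveParams(Jv = 2, alignment = "velocity", dt = 0.01)
  v <- matrix(0, nrow(positions(tis)), 2)
  v[1, ] <- c(cos(tis@theta[1]), sin(tis@theta[1]))  # parallel to n
  v[2, ] <- c(0, 1)                                  # at -pi/2 from n_2... aligned
  tau2 <- alignmentTorque(tis, act2, velocities = v)
  expect_equal(tau2[1], 0)
  expect_equal(tau2[2], 0)
  v[2, ] <- c(1, 0)  # 90 degrees clockwise from n_2
  tau3 <- alignmentTorque(tis, act2, velocities = v)
  expect_equal(tau3[2], 2 * sin(0 - pi / 2))
  # at rest: defined zero limit
  expect_equal(alignmentTorque(tis, act2,
                               velocities = 0 * v)[1:2], c(0, 0))
})

test_that("shape alignment pulls the polarity towards the cell long axis", {
  # Voronoi cell of the centre site is a 1 x 2 rectangle (long axis y)
  pos <- rbind(c(0, 0), c(1, 0), c(0, 2), c(-1, 0), c(0, -2))
  tis <- Tissue(pos, flag = c("interior", rep("boundary", 4)),
                boundaryLoops = list(2:5))
  cells <- dualCells(tis)
  st <- shapeTensor(cells$vertices[[1]])
  expect_equal(abs(st$axis), c(0, 1), tolerance = 1e-12)
  tis@theta[1] <- pi / 2 - pi / 6   # 30 degrees off the long axis
  act <- ActiveParams(Js = 1, alignment = "shape", dt = 0.01)
  tau <- alignmentTorque(tis, act)
  expect_equal(tau[1], sin(pi / 6), tolerance = 1e-12)
  # nematic coupling: the reversed polarity feels the same-magnitude torque
  tis@theta[1] <- tis@theta[1] + pi
  expect_equal(abs(alignmentTorque(tis, act)[1]), sin(pi / 6),
               tolerance = 1e-12)
})

test_that("force-free active cells translate at exactly fa over gamma", {
  tis <- freeTissue(nInt = 25, seed = 2)
  set.seed(1)
  tis@theta[isInterior(tis)] <- runif(25, -pi, pi)
  act <- ActiveParams(fa = 0.7, gamma = 2, D = 0, Dr = 0, dt = 0.01)
  p0 <- positions(tis)
  st <- stepTissue(tis, freeMech, act)
  disp <- positions(st$tissue) - p0
  speeds <- sqrt(rowSums(disp^2))[isInterior(tis)] / act@dt
  expect_equal(speeds, rep(0.7 / 2, 25), tolerance = 1e-9)
  # direction along the polarity
  ii <- which(isInterior(tis))[1]
  expect_equal(unname(disp[ii, ]) / sqrt(sum(disp[ii, ]^2)),
               c(cos(tis@theta[ii]), sin(tis@theta[ii])), tolerance = 1e-9)
  # and with everything off, nothing moves
  still <- stepTissue(tis, freeMech, ActiveParams(fa = 0, D = 0, dt = 0.01))
  expect_equal(positions(still$tissue), p0, tolerance = 1e-11)
})

test_that("free diffusion reproduces MSD = 4 D t within 3 standard errors", {
  tis <- freeTissue(nInt = 400, seed = 3)
  act <- ActiveParams(fa = 0, gamma = 1, D = 0.2, Dr = 0, dt = 0.01)
  set.seed(99)
  p0 <- positions(tis)[isInterior(tis), ]
  for (s in 1:150) {
    tis <- stepTissue(tis, freeMech, act)$tissue
    if (s %% 25 == 0) tis <- buildTriangulation(tis)  # gas-like motion
  }
  dr2 <- rowSums((positions(tis)[isInterior(tis), ] - p0)^2)
  t <- 150 * act@dt
  se <- sd(dr2) / sqrt(length(dr2))
  expect_lt(abs(mean(dr2) - 4 * act@D * t), 3 * se + 1e-9)
})

test_that("polarity decorrelates as exp(-Dr t) and drifts under torque", {
  set.seed(5)
  r0 <- polarityAutocorrelation(Dr = 0, nWalkers = 50, tMax = 2, dt = 0.01)
  expect_equal(r0$C, rep(1, length(r0$C)))
  r <- polarityAutocorrelation(Dr = 0.1, gammaR = 1, nWalkers = 2000,
                               tMax = 30, dt = 0.01)
  expect_equal(r$tauFit, 10, tolerance = 0.1)
  expect_equal(r$tauR, 5)  # the gamma_r/(2 Dr) persistence-time convention
  # deterministic limit: C(t) = cos(torque t / gamma_r) exactly
  rt <- polarityAutocorrelation(Dr = 0, gammaR = 2, torque = 0.4,
                                nWalkers = 10, tMax = 5, dt = 0.01)
  expect_equal(rt$C, cos(0.4 / 2 * rt$t), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  tis <- initPacking("disk", N = 30, seed = 4)
  mech <- MechParams(K = 1, Gamma = 1, Lambda = lambdaForP0(3.7),
                     kCore = 1, aCore = 1)
  act <- ActiveParams(fa = 0.05, D = 0.01, Dr = 0.01, dt = 0.01)
  t1 <- runSimulation(tis, mech, act, nSteps = 100, snapshotEvery = 50,
                      seed = 42)
  t2 <- runSimulation(tis, mech, act, nSteps = 100, snapshotEvery = 50,
                      seed = 42)
  expect_identical(positions(t1@finalTissue), positions(t2@finalTissue))
  expect_identical(t1@events, t2@events)
})

test_that("equiangulation keeps the Delaunay certificate during dynamics", {
  tis <- initPacking("disk", N = 40, seed = 6)
  mech <- MechParams(K = 1, Gamma = 1, Lambda = lambdaForP0(3.9),
                     kCore = 1, aCore = 1)
  act <- ActiveParams(fa = 0.1, D = 0.01, Dr = 0.05, dt = 0.01)
  set.seed(31)
  for (s in 1:50) {
    tis <- stepTissue(tis, mech, act)$tissue
    if (s %% 10 == 0)
      expect_true(isDelaunayMesh(positions(tis), triangulation(tis)))
  }
  # a stale mesh is refused
  tis@stale <- TRUE
  expect_error(vmForces(tis, mech), "stale")
})

test_that("velocity alignment in a confined solid drives oscillatory modes", {
  tis <- initPacking("disk", N = 50, seed = 5)
  mech <- MechParams(K = 1, Gamma = 1, Lambda = lambdaForP0(3.385),
                     kCore = 1, aCore = 1)
  act <- ActiveParams(fa = 0.03, D = 0, Dr = taurInverse(0.01), Jv = 1,
                      alignment = "velocity", dt = 0.025)
  tis <- relaxTissue(tis, mech, nSteps = 200, dt = 0.025)
  traj <- runSimulation(tis, mech, act, nSteps = 4000, snapshotEvery = 25,
                        seed = 77)
  fr <- traj@frames
  vx <- vapply(2:length(fr), function(k) {
    ia <- fr[[k - 1]]$flag == "interior"
    mean(fr[[k]]$x[ia] - fr[[k - 1]]$x[ia])
  }, 0)
  ac <- acf(vx, lag.max = 80, plot = FALSE)$acf
  expect_lt(min(ac), 0)  # the mean-velocity autocorrelation changes sign
})
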