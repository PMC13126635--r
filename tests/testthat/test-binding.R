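test_that("Coulomb pair energies follow the screened point formula", {
  atoms <- makeAtoms(2)
  frame <- rbind(c(0, 0, 0), c(3.32, 0, 0))
  # +1 and -1 e at 3.32 A in dielectric 4
  expect_equal(coulombEnergy(frame, c(1, -1), 1, 2, epsilon = 4),
               -332.0637 / (4 * 3.32), tolerance = 1e-9)
  expect_equal(coulombEnergy(frame, c(1, -1), 1, 2, epsilon = 4), -25.00,
               tolerance = 0.005)
  expect_equal(coulombEnergy(frame, c(0, -1), 1, 2), 0)
  # linear in the charge: deprotonating removes exactly the q-delta term
  e1 <- coulombEnergy(frame, c(1, -1), 1, 2)
  e0 <- coulombEnergy(frame, c(0.4, -1), 1, 2)
  expect_equal(e1 - e0, coulombEnergy(frame, c(0.6, -1), 1, 2),
               tolerance = 1e-9)
  expect_error(coulombEnergy(rbind(c(0, 0, 0), c(0, 0, 0)),
                             c(1, 1), 1, 2), "singularity")
  expect_error(coulombEnergy(frame, c(1, 1), 1, 1), "disjoint")
})

test_that("Lennard-Jones pairs hit the 12-6 landmarks", {
  atoms <- makeAtoms(2, ljSigma = c(3, 3.6), ljEpsilon = c(0.2, 0.3))
  sig <- (3 + 3.6) / 2
  eps <- sqrt(0.2 * 0.3)
  at_sigma <- rbind(c(0, 0, 0), c(sig, 0, 0))
  expect_equal(ljEnergy(at_sigma, atoms, 1, 2), 0, tolerance = 1e-12)
  at_min <- rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0))
  expect_equal(ljEnergy(at_min, atoms, 1, 2), -eps, tolerance = 1e-12)
  # brute-force double loop on a random frame
  ens <- boundEnsemble(ph = 7)
  a <- atoms(ens)
  xyz <- getFrame(ens, 4)
  dend <- which(a$partner == "DENDRIMER")
  rna <- which(a$partner != "DENDRIMER")
  brute <- 0
  for (i in dend) for (j in rna) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sg <- (a$ljSigma[i] + a$ljSigma[j]) / 2
    ep <- sqrt(a$ljEpsilon[i] * a$ljEpsilon[j])
    brute <- brute + 4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  expect_equal(ljEnergy(xyz, a, dend, rna), brute, tolerance = 1e-9)
})

test_that("the FD-PB solver reproduces the Born ion and refines toward it", {
  atoms <- makeAtoms(1, radius = 2)
  frame <- matrix(0, 1, 3)
  born <- -(332.0637 / (2 * 2)) * (1 / 4 - 1 / 80)
  e05 <- as.numeric(pbSolvation(frame, atoms, 1, pbGrid(spacing = 0.5)))
  e10 <- as.numeric(pbSolvation(frame, atoms, 1, pbGrid(spacing = 1.0)))
  expect_equal(e05 / born, 1, tolerance = 0.05)
  expect_lt(abs(e05 - born), abs(e10 - born))
  e025 <- as.numeric(pbSolvation(frame, atoms, 1, pbGrid(spacing = 0.25)))
  expect_equal(e025 / born, 1, tolerance = 0.02)
  # no charge, no energy
  expect_equal(as.numeric(pbSolvation(frame, atoms, 0, pbGrid())), 0)
})

test_that("apolar solvation is linear with the documented intercept", {
  atoms <- makeAtoms(1, radius = 1.9)
  frame <- matrix(0, 1, 3)
  expect_equal(apolarSolvation(frame, atoms, integer(0)), 0.92)
  a1 <- apolarSolvation(frame, atoms)
  area <- sasa(frame, atoms)$total
  expect_equal(a1, 0.00542 * area + 0.92, tolerance = 1e-9)
  # complex term minus parts is negative for a buried interface
  ens <- boundEnsemble(ph = 5)
  xyz <- getFrame(ens, 10)
  a <- atoms(ens)
  dend <- which(a$partner == "DENDRIMER")
  rna <- which(a$partner != "DENDRIMER")
  dAp <- apolarSolvation(xyz, a, nPoints = 480) -
    apolarSolvation(xyz, a, dend, nPoints = 480) -
    apolarSolvation(xyz, a, rna, nPoints = 480)
  expect_lt(dAp + 0.92, 0)
})

test_that("non-interacting partners bind with ~zero free energy", {
  atoms <- makeAtoms(2, partner = c("DENDRIMER", "RNA_A"),
                     qProt = c(1, -1), qDeprot = c(1, -1), radius = 2)
  frame <- rbind(c(0, 0, 0), c(100, 0, 0))
  ens <- ComplexEnsemble(atoms, emptySites(), list(frame), NULL, ph = 7)
  bd <- mmpbsaBinding(ens, stride = 1, burnInFraction = 0,
                      grid = pbGrid(spacing = 1.0))
  expect_equal(bd@mean[["dGbind"]], 0, tolerance = 0.5)
  expect_true(is.na(bd@sem))
})

test_that("the decomposition identity holds exactly per frame", {
  ens <- boundEnsemble(ph = 5)
  bd <- memo("bd_identity",
             mmpbsaBinding(ens, stride = 10, grid = pbGrid(spacing = 1.5),
                           nPoints = 240))
  pf <- bd@perFrame
  expect_gt(nrow(pf), 1)
  resid <- pf$dGbind - (pf$eCoul + pf$eVdw + pf$solvPolar + pf$solvApolar)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("the linkage formula is exact and linear", {
  rt310 <- 1.9872e-3 * 310
  expect_equal(wtLinkDdg(0.4, 0.4), 0)
  expect_equal(wtLinkDdg(-1, 0), -log(10) * rt310, tolerance = 1e-12)
  expect_equal(wtLinkDdg(-1, 0), -1.419, tolerance = 0.001)
  expect_equal(wtLinkDdg(2.1, 5.2), wtLinkDdg(-3.1, 0), tolerance = 1e-12)
  expect_equal(wtLinkDdg(-3.1, 0), -4.40, tolerance = 0.005)
  # linear in dq and in temperature
  expect_equal(wtLinkDdg(3, 1, 310), 2 * wtLinkDdg(2, 1, 310),
               tolerance = 1e-12)
  expect_equal(wtLinkDdg(2, 1, 620), 2 * wtLinkDdg(2, 1, 310),
               tolerance = 1e-12)
  # trapezoidal variant agrees with the analytic integral for linear dq
  ph <- c(5, 6, 7)
  dq <- c(3, 2, 1)
  expect_equal(wtLinkDdgIntegral(ph, dq, workPh = 5, refPh = 7),
               log(10) * rt310 * -4, tolerance = 1e-9)
})
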