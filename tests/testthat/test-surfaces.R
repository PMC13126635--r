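test_that("an isolated sphere reproduces the analytic area", {
  atoms <- makeAtoms(1, radius = 1.9)
  s <- sasa(matrix(0, 1, 3), atoms, probe = 1.4)
  expect_equal(s$total, 4 * pi * 3.3^2, tolerance = 0.01)
  expect_equal(s$perAtom, s$total)
})

test_that("well-separated atoms have additive areas", {
  atoms <- makeAtoms(2, radius = c(2, 1.5))
  frame <- rbind(c(0, 0, 0), c(100, 0, 0))
  s <- sasa(frame, atoms)
  iso1 <- sasa(frame, atoms, subset = 1, context = 1)$total
  iso2 <- sasa(frame, atoms, subset = 2, context = 2)$total
  expect_equal(s$total, iso1 + iso2, tolerance = 1e-9)
})

test_that("a fully caged atom has zero exposed area", {
  cage <- .cage(30, 3.4)
  atoms <- makeAtoms(31, radius = 2)
  frame <- rbind(c(0, 0, 0), cage)
  s <- sasa(frame, atoms)
  expect_equal(s$perAtom[1], 0)
})

test_that("sparse point sampling tracks a dense oracle", {
  # one phosphate half-capped by a single bead
  atoms <- makeAtoms(2, radius = c(2.4, 2.1))
  frame <- rbind(c(0, 0, 0), c(3.2, 0, 0))
  coarse <- sasa(frame, atoms, subset = 1, context = 1:2, nPoints = 960)
  dense <- sasa(frame, atoms, subset = 1, context = 1:2, nPoints = 10000)
  expect_equal(coarse$total / dense$total, 1, tolerance = 0.02)
  # and on a generated complex frame
  ens <- boundEnsemble(ph = 7)
  xyz <- getFrame(ens, 3)
  a <- atoms(ens)
  phos <- which(a$isPhosphate)
  coarse <- sasa(xyz, a, subset = phos, context = seq_len(nrow(a)),
                 nPoints = 960)$total
  dense <- sasa(xyz, a, subset = phos, context = seq_len(nrow(a)),
                nPoints = 10000)$total
  expect_equal(coarse / dense, 1, tolerance = 0.02)
})

test_that("shielding spans its exact limits and stays in [0, 100]", {
  # dendrimer 100 A away shields nothing
  atoms <- makeAtoms(2, partner = c("RNA_A", "DENDRIMER"),
                     isPhosphate = c(TRUE, FALSE), radius = 2.4)
  frame <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(shielding(frame, atoms), 0)
  # a phosphate fully caged by dendrimer beads is 100% shielded
  cage <- .cage(30, 3.4)
  atomsC <- makeAtoms(31, partner = c("RNA_A", rep("DENDRIMER", 30)),
                      isPhosphate = c(TRUE, rep(FALSE, 30)),
                      radius = c(2.4, rep(2, 30)))
  expect_equal(shielding(rbind(c(0, 0, 0), cage), atomsC), 100)
  # bound frames stay in range
  ens <- boundEnsemble(ph = 5)
  sh <- vapply(c(1, 12, 30), function(f)
    shielding(getFrame(ens, f), atoms(ens), nPoints = 480), numeric(1))
  expect_true(all(sh >= 0 & sh <= 100))
})

test_that("interface area is symmetric, near zero when apart, stable when bound", {
  atoms <- makeAtoms(2, partner = c("RNA_A", "DENDRIMER"),
                     isPhosphate = c(TRUE, FALSE))
  frame <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(interfaceArea(frame, atoms), 0, tolerance = 1e-9)
  # swapping the partner labels leaves the value unchanged
  ens <- boundEnsemble(ph = 7)
  a <- atoms(ens)
  xyz <- getFrame(ens, 8)
  ia <- interfaceArea(xyz, a, nPoints = 480)
  aSwap <- a
  aSwap$partner <- ifelse(a$partner == "DENDRIMER", "RNA_A", "DENDRIMER")
  expect_equal(interfaceArea(xyz, aSwap, nPoints = 480), ia,
               tolerance = 1e-9)
  # positive and reasonably stable across frames (generator contract)
  st <- surfacesTable(ens, burnInFraction = 1 / 3, nPoints = 240)
  expect_true(all(st$interfaceA2 > 0))
  expect_lt(sd(st$interfaceA2) / mean(st$interfaceA2), 0.3)
})
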