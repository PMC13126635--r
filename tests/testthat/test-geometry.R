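# fixture: two terminal anchors on the z axis plus a dendrimer bead
.axisAtoms <- function(dendXyz) {
  makeAtoms(3,
            partner = c("RNA_A", "RNA_A", "DENDRIMER"),
            residueIndex = c(1L, 21L, 1L),
            isTerminalBp = c(TRUE, TRUE, FALSE))
}

test_that("position along the duplex reproduces the worked projection", {
  atoms <- .axisAtoms()
  frame <- rbind(c(0, 0, 0), c(0, 0, 50), c(10, 0, 40))
  expect_equal(positionAlongDuplex(frame, atoms), 80, tolerance = 1e-9)
  # midpoint -> 50, coincident with anchor -> 0
  frame[3, ] <- c(0, 0, 25)
  expect_equal(positionAlongDuplex(frame, atoms), 50, tolerance = 1e-9)
  frame[3, ] <- c(0, 0, 0)
  expect_equal(positionAlongDuplex(frame, atoms), 0)
  # beyond an end -> outside 0..100
  frame[3, ] <- c(0, 0, 55)
  expect_gt(positionAlongDuplex(frame, atoms), 100)
  expect_error(positionAlongDuplex(rbind(c(0, 0, 0), c(0, 0, 0),
                                         c(1, 1, 1)), atoms),
               "coincident")
})

test_that("position is invariant to atom order and rigid motions", {
  ens <- boundEnsemble(ph = 7)
  a <- atoms(ens)
  xyz <- getFrame(ens, 5)
  p0 <- positionAlongDuplex(xyz, a)
  # permute rows (relabeling of the strands' atom order)
  withr::with_seed(1, perm <- sample(nrow(a)))
  expect_equal(positionAlongDuplex(xyz[perm, ], a[perm, ]), p0,
               tolerance = 1e-9)
  # rigid rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(xyz %*% t(R), 2, c(5, -3, 11), "+")
  expect_equal(positionAlongDuplex(moved, a), p0, tolerance = 1e-9)
  expect_equal(bendingAngle(moved, a), bendingAngle(xyz, a),
               tolerance = 1e-9)
  dend <- a$partner == "DENDRIMER"
  expect_equal(radiusOfGyration(moved, dend), radiusOfGyration(xyz, dend),
               tolerance = 1e-9)
})

test_that("bending angle handles collinear and right-angle cases", {
  atoms <- makeAtoms(3, partner = rep("RNA_A", 3),
                     residueIndex = c(1L, 2L, 3L),
                     isTerminalBp = c(TRUE, FALSE, TRUE),
                     isCentralBp = c(FALSE, TRUE, FALSE))
  expect_equal(bendingAngle(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)),
                            atoms), 180)
  expect_equal(bendingAngle(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)),
                            atoms), 90)
  expect_error(bendingAngle(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            atoms), "degenerate")
})

test_that("groove assignment applies the distance and precedence rules", {
  # markers: minor at x=0, major at x=8; phosphate far / near
  atoms <- makeAtoms(4,
                     partner = c("RNA_A", "RNA_A", "RNA_A", "DENDRIMER"),
                     isMinorGroove = c(TRUE, FALSE, FALSE, FALSE),
                     isMajorGroove = c(FALSE, TRUE, FALSE, FALSE),
                     isPhosphate = c(FALSE, FALSE, TRUE, FALSE),
                     isTitratable = c(FALSE, FALSE, FALSE, TRUE),
                     qProt = c(0, 0, 0, 1))
  sites <- data.frame(siteId = 1L, group = "G3_NTR", atomSerial = 4L,
                      pkaIntrinsic = 7.5)
  # site 3 A from minor, 5 A from major, 7 A from phosphate
  frame <- rbind(c(0, 0, 0), c(8, 0, 0), c(3, 7, 0), c(3, 0, 0))
  ga <- assignGrooves(frame, atoms, sites)
  expect_equal(ga$groove, "MINOR")
  expect_equal(ga$signedDistance, -3)
  expect_equal(ga$context, "GROOVE")
  # phosphate within 4 A takes precedence
  frame[3, ] <- c(3, 3.5, 0)
  expect_equal(assignGrooves(frame, atoms, sites)$context, "PHOS")
  # exact groove tie goes to MAJOR
  frame <- rbind(c(0, 0, 0), c(8, 0, 0), c(4, 50, 0), c(4, 0, 0))
  ga <- assignGrooves(frame, atoms, sites)
  expect_equal(ga$groove, "MAJOR")
  expect_equal(ga$signedDistance, 4)
})

test_that("groove contexts are exhaustive and mutually exclusive", {
  ens <- boundEnsemble(ph = 7)
  a <- atoms(ens)
  s <- sites(ens)
  for (f in c(1, 10, 25)) {
    ga <- assignGrooves(getFrame(ens, f), a, s)
    expect_equal(nrow(ga), nrow(s))
    expect_true(all(ga$context %in% c("PHOS", "GROOVE", "FREE")))
    expect_equal(sum(table(ga$context)), nrow(s))
  }
})

test_that("contact counting matches a brute-force double loop", {
  ens <- boundEnsemble(ph = 7)
  a <- atoms(ens)
  s <- sites(ens)
  brute <- function(frame, cutoff) {
    sXyz <- frame[match(s$atomSerial, a$serial), , drop = FALSE]
    pXyz <- frame[a$isPhosphate, , drop = FALSE]
    n <- 0L
    for (i in seq_len(nrow(sXyz)))
      for (j in seq_len(nrow(pXyz)))
        if (sqrt(sum((sXyz[i, ] - pXyz[j, ])^2)) <= cutoff) n <- n + 1L
    n
  }
  for (f in c(2, 17)) {
    xyz <- getFrame(ens, f)
    expect_identical(countPhosphateContacts(xyz, a, s, 4), brute(xyz, 4))
    expect_identical(countPhosphateContacts(xyz, a, s, 6), brute(xyz, 6))
  }
  # one amine within range of two phosphates counts both pairs
  atoms2 <- makeAtoms(3, partner = c("RNA_A", "RNA_B", "DENDRIMER"),
                      isPhosphate = c(TRUE, TRUE, FALSE),
                      isTitratable = c(FALSE, FALSE, TRUE),
                      qProt = c(0, 0, 1))
  s2 <- data.frame(siteId = 1L, group = "G3_NTR", atomSerial = 3L,
                   pkaIntrinsic = 7.5)
  frame2 <- rbind(c(0, 0, 0), c(7.8, 0, 0), c(3.9, 0, 0))
  expect_equal(countPhosphateContacts(frame2, atoms2, s2, 4), 2L)
})

test_that("Rg, RMSD and charge follow their standard definitions", {
  atoms <- makeAtoms(2)
  frame <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radiusOfGyration(frame, 1:2), 1)
  expect_equal(radiusOfGyration(frame, 1), 0)
  expect_equal(superposedRmsd(frame, frame, 1:2), 0, tolerance = 1e-6)
  # rmsd is superposition-invariant
  th <- 1.2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(frame %*% t(R), 2, c(1, 2, 3), "+")
  expect_equal(superposedRmsd(moved, frame, 1:2), 0, tolerance = 1e-6)
  expect_error(radiusOfGyration(frame, integer(0)), "empty")
  # fully protonated MH18 with neutral backbone carries +20 e
  den <- buildDendrimer(DendrimerSpec("MH18"))
  expect_equal(totalCharge(rep(1, 20), den$atoms, den$sites), 20)
  expect_equal(totalCharge(rep(0, 20), den$atoms, den$sites), 0)
})
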