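test_that("duplex construction obeys the counting and length rules", {
  dup <- buildDuplex(DuplexSpec())
  expect_equal(sum(dup$atoms$isPhosphate), 2 * 21 - 2)
  # end-to-end axis length
  ends <- dup$coords[dup$atoms$isTerminalBp, 3]
  expect_equal(max(ends) - min(ends), (21 - 1) * 2.81, tolerance = 1e-9)
  # phosphates carry -1 e
  expect_true(all(dup$atoms$qDeprot[dup$atoms$isPhosphate] == -1))
  # small duplex: finite coordinates, both groove sets non-empty
  d5 <- buildDuplex(DuplexSpec(nBp = 5))
  expect_true(all(is.finite(d5$coords)))
  expect_gt(sum(d5$atoms$isMajorGroove), 0)
  expect_gt(sum(d5$atoms$isMinorGroove), 0)
  expect_error(DuplexSpec(nBp = 4), "nBp")
})

test_that("dendrimer topology yields the variant-dependent site counts", {
  mh18 <- buildDendrimer(DendrimerSpec("MH18"))
  expect_equal(nrow(mh18$sites), 20L)
  expect_equal(as.vector(table(mh18$sites$group)[c("G2", "G3_NTR", "G3_SIDE")]),
               c(4L, 8L, 8L))
  mh47 <- buildDendrimer(DendrimerSpec("MH47"))
  expect_equal(nrow(mh47$sites), 16L)
  expect_equal(sum(mh47$sites$group == "G2"), 0L)
  expect_gt(sum(mh47$atoms$isHydrophobic), sum(mh18$atoms$isHydrophobic))
  # every bonded pair exactly bondLength apart
  d <- sqrt(rowSums((mh18$coords[mh18$bonds[, 1], ] -
                       mh18$coords[mh18$bonds[, 2], ])^2))
  expect_equal(max(abs(d - 3.8)), 0, tolerance = 1e-9)
  expect_error(DendrimerSpec("XX"), "variant")
})

test_that("apo lysine sites stay protonated near physiological pH", {
  apo <- apoEnsemble(ph = 7)
  lys <- sites(apo)$group != "G3_NTR"
  expect_gte(mean(occupancy(apo)[, lys]), 0.99)
})

test_that("ensembles are bitwise reproducible under a fixed seed", {
  e1 <- sampleEnsemble(nFrames = 8, ph = 7, bound = TRUE, seed = 9)
  e2 <- sampleEnsemble(nFrames = 8, ph = 7, bound = TRUE, seed = 9)
  expect_identical(frames(e1), frames(e2))
  expect_identical(occupancy(e1), occupancy(e2))
  e3 <- sampleEnsemble(nFrames = 8, ph = 7, bound = TRUE, seed = 10)
  expect_false(identical(frames(e1), frames(e3)))
})

test_that("binding raises N-termini protonation and total charge", {
  bnd <- boundEnsemble(ph = 7)
  apo <- apoEnsemble(ph = 7)
  ntrB <- mean(occupancy(bnd)[, sites(bnd)$group == "G3_NTR"])
  ntrA <- mean(occupancy(apo)[, sites(apo)$group == "G3_NTR"])
  expect_gt(ntrB, ntrA)
  chg <- function(e) {
    a <- atoms(e)
    dend <- a$partner == "DENDRIMER"
    mean(vapply(seq_len(nFrames(e)), function(f)
      totalCharge(occupancy(e)[f, ], a, sites(e), dend), numeric(1)))
  }
  expect_gte(chg(bnd), chg(apo))
})

test_that("dendrimer charge grows with acidity in bound and apo states", {
  chg <- function(e) {
    a <- atoms(e)
    dend <- a$partner == "DENDRIMER"
    mean(vapply(seq_len(nFrames(e)), function(f)
      totalCharge(occupancy(e)[f, ], a, sites(e), dend), numeric(1)))
  }
  expect_gte(chg(boundEnsemble(ph = 5)), chg(boundEnsemble(ph = 7)))
  expect_gte(chg(apoEnsemble(ph = 5)), chg(apoEnsemble(ph = 7)))
})

test_that("the rigid scaffold stays straight and in contact", {
  ens <- boundEnsemble(ph = 7)
  a <- atoms(ens)
  s <- sites(ens)
  bends <- vapply(seq_len(nFrames(ens)), function(f)
    bendingAngle(getFrame(ens, f), a), numeric(1))
  expect_true(all(bends >= 175))
  contact <- vapply(seq_len(nFrames(ens)), function(f)
    countPhosphateContacts(getFrame(ens, f), a, s, 4) > 0, logical(1))
  expect_gte(mean(contact), 0.8)
})
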