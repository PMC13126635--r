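test_that("a point cloud at one location peaks there and integrates to 1", {
  x <- rep(2, 50)
  y <- rep(-1, 50)
  expect_warning(d <- kdeDensity(x, y, gridSpacing = 0.05),
                 "bandwidth floor")
  peak <- arrayInd(which.max(d$z), dim(d$z))
  expect_equal(d$x[peak[1]], 2, tolerance = 0.06)
  expect_equal(d$y[peak[2]], -1, tolerance = 0.06)
  dx <- diff(d$x[1:2]); dy <- diff(d$y[1:2])
  expect_equal(sum(d$z) * dx * dy, 1, tolerance = 0.01)
})

test_that("a mirror-symmetric cloud gives a symmetric density", {
  x0 <- c(seq(0.5, 3, by = 0.25), seq(0.7, 2.2, by = 0.3))
  x <- c(x0, -x0)
  y0 <- rep(seq_len(2), length.out = length(x0))
  y <- c(y0, y0)
  d <- kdeDensity(x, y, bandwidth = c(0.5, 0.5), gridSpacing = 0.25)
  # grid is symmetric because range(x) is; flip rows and compare
  expect_equal(d$z, d$z[rev(seq_along(d$x)), ], tolerance = 1e-10)
})

test_that("a standard-normal cloud reproduces the closed-form peak", {
  withr::with_seed(12, {
    x <- rnorm(1000)
    y <- rnorm(1000)
  })
  d <- kdeDensity(x, y, bandwidth = c(0.25, 0.25), gridSpacing = 0.1)
  i <- which.min(abs(d$x)); j <- which.min(abs(d$y))
  expect_lt(abs(d$z[i, j] - 1 / (2 * pi)), 0.1 / (2 * pi))
  dx <- diff(d$x[1:2]); dy <- diff(d$y[1:2])
  expect_equal(sum(d$z) * dx * dy, 1, tolerance = 0.01)
})

test_that("the energy surface is anchored at zero and scale invariant", {
  z <- matrix(c(4, 2, 1, 0), 2, 2)
  d <- list(x = 1:2, y = 1:2, z = z, bandwidth = c(1, 1))
  e <- energySurface(d, temperature = 310)
  expect_equal(e@energy[1, 1], 0)
  rt310 <- 1.9872e-3 * 310
  expect_equal(e@energy[2, 1], rt310 * log(2), tolerance = 1e-9)
  expect_equal(e@energy[2, 1], 0.427, tolerance = 0.001)
  expect_true(is.na(e@energy[2, 2]))
  # doubling all densities leaves E unchanged
  d2 <- d; d2$z <- 2 * z
  expect_equal(energySurface(d2, 310)@energy, e@energy)
  expect_error(energySurface(list(x = 1, y = 1, z = matrix(0, 1, 1))),
               "all-zero")
})

test_that("landscape minimum is unique-zero and halves agree", {
  bnd <- phGridEnsembles(TRUE)
  bnd7 <- Filter(function(e) pH(e) == 7, bnd)
  sc <- protonationScatter(bnd7, "G3_NTR")
  mk <- function(idx) energySurface(
    kdeDensity(sc$signedGroove[idx], sc$phosphateDistance[idx],
               gridSpacing = 0.25))
  full <- mk(seq_len(nrow(sc)))
  expect_equal(min(full@energy, na.rm = TRUE), 0)
  expect_equal(full@energy[which.max(full@density)], 0)
  # odd/even frame halves: low-energy cells move by < 0.3 kcal/mol
  odd <- mk(which(sc$frame %% 2 == 1))
  even <- mk(which(sc$frame %% 2 == 0))
  # compare on the shared grid region via interpolation-free alignment:
  # both halves share x/y ranges up to padding; sample at common points
  common <- expand.grid(x = seq(-4, 4, by = 1), y = seq(2, 8, by = 1))
  lookup <- function(l, x, y) {
    i <- vapply(x, function(v) which.min(abs(l@x - v)), integer(1))
    j <- vapply(y, function(v) which.min(abs(l@y - v)), integer(1))
    l@energy[cbind(i, j)]
  }
  eO <- lookup(odd, common$x, common$y)
  eE <- lookup(even, common$x, common$y)
  sel <- !is.na(eO) & !is.na(eE) & eO < 2 & eE < 2
  expect_gt(sum(sel), 5)
  expect_lt(max(abs(eO[sel] - eE[sel])), 0.3)
})

test_that("protonation scatter reflects the field geography", {
  bnd <- phGridEnsembles(TRUE)
  bnd7 <- Filter(function(e) pH(e) %in% c(7, 7.5, 8), bnd)
  sc <- protonationScatter(bnd7, "G3_NTR")
  phosClose <- sc$occupancy[sc$phosphateDistance < 3]
  grooveOnly <- sc$occupancy[abs(sc$signedGroove) < 4 &
                               sc$phosphateDistance > 4]
  expect_gt(length(phosClose), 10)
  expect_gt(length(grooveOnly), 10)
  expect_gt(mean(phosClose), mean(grooveOnly))
  # fully protonated input gives occupancy identically 1
  ens <- bnd7[[1]]
  occ1 <- matrix(1, nFrames(ens), nSites(ens))
  ensFull <- ComplexEnsemble(atoms(ens), sites(ens), frames(ens), occ1,
                             ph = pH(ens), bound = TRUE)
  scF <- protonationScatter(list(ensFull), "G3_NTR")
  expect_true(all(scF$occupancy == 1))
})

test_that("landscape TSV serializes masked cells as empty fields", {
  z <- matrix(c(4, 2, 1, 0), 2, 2)
  e <- energySurface(list(x = 1:2, y = 1:2, z = z, bandwidth = c(1, 1)))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLandscapeTsv(e, p)
  lines <- readLines(p)
  expect_equal(length(lines), 5L)
  expect_true(any(grepl("\t$", lines)))
  back <- read.table(p, sep = "\t", header = TRUE)
  expect_equal(sum(is.na(back$E)), 1L)
})
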