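test_that("exact enumeration reproduces closed forms", {
  # single site, pH one unit below pKa: 1/(1 + 10^-1) = 10/11
  expect_equal(exactOccupancies(TitrationModel(7), ph = 6), 10 / 11,
               tolerance = 1e-12)
  # uncoupled sites factorize into independent Henderson-Hasselbalch terms
  pkas <- c(5.5, 7.0, 9.2, 10.4)
  m <- TitrationModel(pkas)
  expect_equal(exactOccupancies(m, 7), hendersonHasselbalch(7, pkas),
               tolerance = 1e-12)
  expect_error(exactOccupancies(TitrationModel(rep(7, 21)), 7), "size")
})

test_that("a symmetric single site sits at half occupancy", {
  mc <- sampleStates(TitrationModel(7), ph = 7, nCycles = 20000, seed = 1)
  expect_equal(mc$meanOccupancy, 0.5, tolerance = 0.02)
})

test_that("two uncoupled sites sample the product of single-site values", {
  m <- TitrationModel(c(6.5, 8.0))
  mc <- sampleStates(m, ph = 7, nCycles = 30000, seed = 2)
  expect_equal(mc$meanOccupancy, hendersonHasselbalch(7, c(6.5, 8.0)),
               tolerance = 0.02)
})

test_that("coupled-site sampling matches Boltzmann enumeration", {
  # three equal sites with 1 kcal/mol couplings at pH = pKa
  W <- matrix(1, 3, 3) - diag(3)
  m <- TitrationModel(c(7, 7, 7), coupling = W)
  ex <- exactOccupancies(m, 7)
  mc <- sampleStates(m, 7, nCycles = 30000, seed = 3)
  expect_true(all(abs(mc$meanOccupancy - ex) <= 3 * mc$seOccupancy))
  # a 12-site random model
  withr::with_seed(4, {
    n <- 12
    pk <- runif(n, 6, 9)
    W <- matrix(runif(n * n, 0, 0.8), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    phi <- runif(n, -1, 0.3)
  })
  m12 <- TitrationModel(pk, coupling = W, field = phi)
  ex12 <- exactOccupancies(m12, 7.5)
  mc12 <- sampleStates(m12, 7.5, nCycles = 40000, seed = 5)
  expect_true(all(abs(mc12$meanOccupancy - ex12) <=
                    pmax(3 * mc12$seOccupancy, 0.01)))
})

test_that("occupancy falls with pH and rises with a stabilizing field", {
  withr::with_seed(6, {
    for (k in 1:5) {
      n <- sample(2:6, 1)
      pk <- runif(n, 5, 10)
      W <- matrix(runif(n * n, 0, 0.5), n, n)
      W <- (W + t(W)) / 2
      diag(W) <- 0
      m <- TitrationModel(pk, coupling = W)
      occs <- vapply(c(5, 6.5, 8, 9.5), function(p)
        exactOccupancies(m, p), numeric(n))
      expect_true(all(diff(t(occs)) <= 1e-12))
      # negative phi strictly increases occupancy at fixed pH
      mNeg <- TitrationModel(pk, coupling = W, field = rep(-1, n))
      expect_true(all(exactOccupancies(mNeg, 7) >
                        exactOccupancies(m, 7)))
    }
  })
})

test_that("positive coupling among equal sites flattens the Hill slope", {
  ph <- seq(4, 9.5, by = 0.5)
  n <- 8
  m0 <- TitrationModel(rep(6.4, n))
  W <- 0.8 * (matrix(1, n, n) - diag(n))
  m1 <- TitrationModel(rep(6.4, n), coupling = W)
  occ0 <- vapply(ph, function(p) mean(exactOccupancies(m0, p)), numeric(1))
  occ1 <- vapply(ph, function(p) mean(exactOccupancies(m1, p)), numeric(1))
  f0 <- hillFit(ph, occ0)
  f1 <- hillFit(ph, occ1)
  expect_true(f0@converged && f1@converged)
  expect_equal(f0@n, 1, tolerance = 0.01)
  expect_lt(f1@n, 1)
})
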