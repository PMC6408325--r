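# 1:1 sequestration equilibrium, ITC simulation and one-site fitting.

test_that("the closed-form equilibrium matches limits and the numeric oracle", {
  none <- freeSpecies1to1(20e-6, 0, 0.27e-6)
  expect_equal(none$free_macromolecule, 20e-6)
  expect_equal(none$complex, 0)
  tight <- freeSpecies1to1(20e-6, 5e-6, 1e-15)
  expect_equal(tight$free_macromolecule, 15e-6, tolerance = 1e-6)
  mid <- freeSpecies1to1(20e-6, 5e-6, 0.27e-6)
  expect_equal(mid$free_macromolecule,
               freeMacromoleculeNumeric(20e-6, 5e-6, 0.27e-6),
               tolerance = 1e-10)
  expect_equal(mid$free_macromolecule, 15.09e-6, tolerance = 1e-3)
  expect_error(freeSpecies1to1(-1, 0, 1e-6), "non-negative")
  expect_error(freeSpecies1to1(1e-6, 1e-6, 0), "positive")
})

test_that("mass conservation is exact and monotonicities hold", {
  grid <- expand.grid(total = c(1, 5, 20, 50) * 1e-6,
                      ligand = c(0, 1, 5, 10, 40) * 1e-6,
                      kd = c(1e-9, 95e-9, 270e-9, 1e-6))
  sp <- freeSpecies1to1(grid$total, grid$ligand, grid$kd)
  expect_equal(sp$free_macromolecule + sp$complex, grid$total)
  expect_equal(sp$free_ligand + sp$complex, grid$ligand)
  expect_true(all(sp$complex >= 0 &
                    sp$complex <= pmin(grid$total, grid$ligand) + 1e-18))
  # decreasing in ligand at fixed kd, increasing in kd at fixed ligand
  lig <- seq(0, 40e-6, length.out = 30)
  free <- effectiveFreeTubulin(20e-6, lig, 95e-9)
  expect_true(all(diff(free) < 0))
  kds <- 10^seq(-9, -5, length.out = 30)
  free2 <- effectiveFreeTubulin(20e-6, 10e-6, kds)
  expect_true(all(diff(free2) > 0))
})

test_that("sequestration arithmetic reproduces the turbidity-control equivalences", {
  expect_identical(round(effectiveFreeTubulin(20e-6, 5e-6, 270e-9) * 1e6),
                   15)
  expect_identical(round(effectiveFreeTubulin(20e-6, 10e-6, 270e-9) * 1e6),
                   10)
  expect_equal(effectiveFreeTubulin(20e-6, 20e-6, 95e-9) * 1e6, 1.3,
               tolerance = 0.05)
})

test_that("simulated heats follow the independent mass-balance oracle", {
  g <- itcGeometry()
  params <- list(n = 1, kd = 95e-9, dh = -16)
  ser <- simulateItc(params, g)
  expect_equal(injectionHeats(ser), itcHeatsOracle(1, 95e-9, -16, g),
               tolerance = 1e-9)
  # dh = 0 gives all-zero heats regardless of kd
  expect_identical(injectionHeats(simulateItc(list(n = 1, kd = 1e-9, dh = 0),
                                              g)), rep(0, 19))
  # saturation: once the cell is titrated past the equivalence point,
  # later heats fall to the dilution baseline
  sat <- injectionHeats(simulateItc(list(n = 1, kd = 1e-12, dh = -16), g))
  expect_lt(abs(sat[19]) / abs(sat[1]), 0.01)
  # inflection of the sigmoid sits near molar ratio 1
  q <- injectionHeats(ser)
  tot <- cumsum(g$injectionVolumes) * g$syringeConcentration /
    (g$cellVolume * g$cellConcentration)  # crude cumulative molar ratio
  steep <- which.max(abs(diff(q)))
  expect_gt(tot[steep + 1], 0.8)
  expect_lt(tot[steep + 1], 1.25)
  expect_error(simulateItc(params, itcGeometry(injectionVolumes = numeric(0))),
               "at least one injection")
})

test_that("noise is seed-reproducible and leaves the caller's RNG alone", {
  params <- list(n = 1, kd = 95e-9, dh = -16)
  s1 <- makeItcDataset(params, noiseSd = 0.05, seed = 7)
  s2 <- makeItcDataset(params, noiseSd = 0.05, seed = 7)
  expect_identical(injectionHeats(s1), injectionHeats(s2))
  expect_identical(injectionHeats(makeItcDataset(params, noiseSd = 0)),
                   injectionHeats(simulateItc(params)))
  clean <- injectionHeats(simulateItc(params))
  devs <- vapply(1:50, function(s)
    sd(injectionHeats(makeItcDataset(params, noiseSd = 0.05, seed = s)) -
         clean), numeric(1))
  expect_equal(median(devs), 0.05, tolerance = 0.25)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(makeItcDataset(params, noiseSd = 0.05, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("noise-free fits recover the generating parameters", {
  for (kd in c(50e-9, 95e-9, 270e-9, 1e-6)) {
    params <- list(n = if (kd > 1e-7) 0.8 else 1, kd = kd, dh = -12)
    fit <- fitOneSite(simulateItc(params))
    expect_equal(fit@n, params$n, tolerance = 1e-6)
    expect_equal(fit@kd, params$kd, tolerance = 1e-6)
    expect_equal(fit@dh, params$dh, tolerance = 1e-6)
    expect_equal(fit@dg, thermoDerive(fit@kd, fit@dh)$dg)
    expect_equal(fit@tds, fit@dh - fit@dg)
  }
})

test_that("degenerate series are rejected with diagnostics", {
  g <- itcGeometry()
  flat <- simulateItc(list(n = 1, kd = 1e-9, dh = 0), g)
  expect_error(fitOneSite(flat), "zero")
  short <- simulateItc(list(n = 1, kd = 95e-9, dh = -16),
                       itcGeometry(injectionVolumes = rep(2e-6, 5)))
  expect_error(fitOneSite(short), "at least 8")
  # c-value far out of range carries a warning note
  weak <- simulateItc(list(n = 1, kd = 5e-3, dh = -16))
  fitW <- tryCatch(fitOneSite(weak), error = function(e) NULL)
  if (!is.null(fitW)) expect_match(fitW@notes, "c-value", all = FALSE)
})

test_that("fit bias vanishes as noise vanishes", {
  params <- list(n = 1, kd = 95e-9, dh = -16)
  peak <- max(abs(injectionHeats(simulateItc(params))))
  bias <- vapply(c(0.04, 0.01, 0.0025) * peak, function(ns) {
    kds <- vapply(1:10, function(s)
      fitOneSite(makeItcDataset(params, noiseSd = ns, seed = s))@kd,
      numeric(1))
    abs(median(kds) - params$kd)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3] / params$kd, 0.02)
})

test_that("derived thermodynamics follow dG = RT ln Kd and TdS = dH - dG", {
  expect_equal(thermoDerive(1, -5)$dg, 0)
  expect_equal(thermoDerive(1e-6, thermoDerive(1e-6, 0)$dg)$tds, 0)
  iE5 <- thermoDerive(270e-9, -8, 293.15)
  expect_equal(iE5$dg, -8.81, tolerance = 0.01)
  expect_equal(iE5$tds, 0.81, tolerance = 0.01)
  # agreement with the reported ITC table within rounding conventions
  expect_lt(abs(iE5$dg - (-8.4)), 0.5)
  expect_error(thermoDerive(-1, 0), "positive")
})
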