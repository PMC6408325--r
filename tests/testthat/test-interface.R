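# SASA quadrature, buried surface area, contacts and graft clashes.

test_that("single-sphere SASA matches the analytic area within quadrature error", {
  s <- shrakeRupleySasa(makeSphereSystem(matrix(0, 1, 3), 1.9))
  expect_equal(s@total, sphereArea(1.9), tolerance = 0.005)
  expect_equal(s@total, sum(s@perAtomArea))
})

test_that("well-separated atoms are additive; overlapping ones match the cap formula", {
  far <- makeSphereSystem(rbind(c(0, 0, 0), c(20, 0, 0)), c(1.9, 1.9))
  expect_equal(shrakeRupleySasa(far)@total, 2 * sphereArea(1.9),
               tolerance = 1e-9)
  near <- makeSphereSystem(rbind(c(0, 0, 0), c(3, 0, 0)), c(1.9, 1.9))
  oracle <- twoSphereExposed(1.9, 1.9, 3)
  got <- shrakeRupleySasa(near)
  expect_equal(got@total, unname(oracle["total"]), tolerance = 0.01)
  expect_equal(got@perAtomArea, unname(oracle[c("a1", "a2")]),
               tolerance = 0.01)
  # asymmetric radii too
  mix <- makeSphereSystem(rbind(c(0, 0, 0), c(2.5, 0, 0)), c(1.9, 1.4))
  expect_equal(shrakeRupleySasa(mix)@total,
               unname(twoSphereExposed(1.9, 1.4, 2.5)["total"]),
               tolerance = 0.01)
})

test_that("quadrature converges and unknown elements are rejected", {
  m <- makeBentDimer(12, withBinder = TRUE)
  sub <- structureFromAtoms("frag",
    atomTable(m)[atomTable(m)$resno <= 120, ])
  s1 <- shrakeRupleySasa(sub, nSpherePoints = 960)
  s2 <- shrakeRupleySasa(sub, nSpherePoints = 4000)
  expect_lt(abs(s1@total - s2@total) / s2@total, 0.005)
  at <- atomTable(makeSphereSystem(matrix(0, 1, 3), 1.9))
  at$vdw <- NA_real_
  at$elesym <- "Qq"
  expect_error(shrakeRupleySasa(structureFromAtoms("bad", at)),
               "van der Waals")
})

test_that("buried surface area behaves like an interface measure", {
  set.seed(30)
  apart <- mergeModels(list(makeSphereSystem(randomCloud(30, 4), rep(1.7, 30), "A"),
                            makeSphereSystem(randomCloud(30, 4) + 100,
                                             rep(1.7, 30), "B")))
  expect_equal(buriedSurfaceArea(apart, "A", "B")@bsaTotal, 0,
               tolerance = 1e-6)
  m <- makeBentDimer(12, withBinder = TRUE)
  ab <- buriedSurfaceArea(m, c("A", "B"), "C")
  ba <- buriedSurfaceArea(m, "C", c("A", "B"))
  expect_gt(ab@bsaTotal, 0)
  expect_lt(abs(ab@bsaTotal - ba@bsaTotal), 1e-6)  # symmetry
  expect_error(buriedSurfaceArea(m, c("A", "B"), "B"), "overlap")
  expect_error(buriedSurfaceArea(m, character(0), "B"), "non-empty")
})

test_that("pulling partners apart never increases the buried area", {
  set.seed(31)
  base <- makeSphereSystem(randomCloud(25, 3), rep(1.7, 25), "A")
  other <- makeSphereSystem(randomCloud(25, 3), rep(1.7, 25), "B")
  seps <- c(0, 2, 5, 10, 30)
  bsa <- vapply(seps, function(s) {
    m <- mergeModels(list(base, translateModel(other, c(8 + s, 0, 0))))
    buriedSurfaceArea(m, "A", "B")@bsaTotal
  }, numeric(1))
  expect_true(all(diff(bsa) <= 1e-6))
})

test_that("contacts use a strict heavy-atom distance cutoff", {
  two <- function(d) mergeModels(list(
    makeSphereSystem(matrix(0, 1, 3), 1.7, "A"),
    makeSphereSystem(matrix(c(d, 0, 0), 1, 3), 1.7, "B")))
  expect_identical(nrow(contactResidues(two(4.9), "A", "B")), 1L)
  expect_identical(nrow(contactResidues(two(5.1), "A", "B")), 0L)
  expect_equal(contactResidues(two(4.9), "A", "B")$min_dist, 4.9)
})

test_that("binder contacts are attributed to named tubulin elements", {
  m <- makeBentDimer(12, withBinder = TRUE)
  ann <- annotateModel(m)
  contacts <- contactResidues(m, "C", "A", mapB = ann$maps[["A"]])
  expect_gt(nrow(contacts), 0)
  # binder residue i sits 4 A from alpha residue i by construction
  self <- contacts[contacts$resno_a == contacts$resno_b, ]
  expect_equal(self$min_dist, rep(4, nrow(self)), tolerance = 1e-9)
  # residues in H7 (224-243) are outside the 100-residue binder reach here;
  # check attribution on the covered N-terminal elements instead
  h1 <- contacts[!is.na(contacts$canonical_b) &
                   contacts$canonical_b %in% 10:28, ]
  expect_true(all(h1$sse_b == "H1"))
})

test_that("graft clash counting is positive on overlap and zero when remote", {
  complexM <- makeBentDimer(12, withBinder = TRUE)
  lattice <- makeToyLattice(2)
  # binder moved far away: grafting cannot clash anywhere
  remote <- translateModel(complexM, shift = c(0, 0, -300), chains = "C")
  r0 <- latticeGraftClash(remote, lattice, "A", binderChain = "C")
  expect_identical(r0@clashCount, 0L)
  # binder atom placed 1.0 A from a known lattice atom
  latAt <- atomTable(lattice)
  target <- unlist(latAt[latAt$chain == "B", c("x", "y", "z")][1, ])
  at <- atomTable(complexM)
  probe <- at[at$chain == "C", ][1, ]
  probe[, c("x", "y", "z")] <- target + c(1, 0, 0)
  probe$resno <- 999L
  withProbe <- structureFromAtoms("probe", rbind(at, probe))
  r1 <- latticeGraftClash(withProbe, lattice, "A", binderChain = "C")
  expect_gte(r1@clashCount, 1L)
  expect_true(any(abs(r1@contacts$dist - 1) < 1e-6))
  expect_error(latticeGraftClash(complexM, lattice, "Q", binderChain = "C"),
               "argument error")
})
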