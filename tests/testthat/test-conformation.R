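# Heterodimer pairing, bend angles, helix shift, complex RMSD matrix.

test_that("pairing finds the constructed heterodimer and attaches binders", {
  m0 <- makeBentDimer(12)
  ann <- annotateModel(m0)
  expect_length(ann$pairs, 1L)
  expect_identical(ann$pairs[[1]]$alpha, "A")
  expect_identical(ann$pairs[[1]]$beta, "B")
  expect_length(ann$pairs[[1]]$binders, 0L)
  mB <- makeBentDimer(12, withBinder = TRUE)
  annB <- annotateModel(mB)
  expect_identical(annB$pairs[[1]]$binders, "C")
  # alpha alone: no pair, warning recorded
  at <- atomTable(m0)
  alphaOnly <- structureFromAtoms("alpha_only", at[at$chain == "A", ])
  roles <- classifyChains(alphaOnly)
  pairs <- pairHeterodimers(alphaOnly, roles)
  expect_length(pairs, 0L)
  expect_match(attr(pairs, "warnings"), "unpaired", all = FALSE)
})

test_that("constructed bend angles are recovered and survive rigid motions", {
  m <- makeBentDimer(12)
  ann <- annotateModel(m)
  r <- interSubunitBendAngle(m, ann$pairs[[1]], ann$maps)
  expect_equal(r$angle_deg, 12, tolerance = 0.01)
  expect_gte(r$n_positions_used, 50)
  set.seed(21)
  for (i in 1:10) {
    R <- quatMatrix(randomUnitQuaternion())
    moved <- translateModel(m, shift = rnorm(3, sd = 30), rotation = R)
    annM <- annotateModel(moved)
    rM <- interSubunitBendAngle(moved, annM$pairs[[1]], annM$maps)
    expect_equal(rM$angle_deg, r$angle_deg, tolerance = 1e-6)
  }
})

test_that("too few resolvable correspondence positions is a geometry error", {
  m <- makeBentDimer(12)
  at <- atomTable(m)
  # keep only 20 N-terminal-domain residues on the alpha chain
  keep <- !(at$chain == "A" & at$resno <= 205 & at$resno > 20)
  trimmed <- structureFromAtoms("sparse", at[keep, ])
  ann <- annotateModel(trimmed)
  expect_error(interSubunitBendAngle(trimmed, ann$pairs[[1]], ann$maps),
               "correspondence")
})

test_that("the survey reports per-dimer rows, entry means and skipped entries", {
  models <- list(MT_LIKE = makeBentDimer(1.1),
                 CURVED = makeBentDimer(11.9),
                 MOST_CURVED = makeBentDimer(18.2),
                 NO_TUBULIN = makeIdealHelix(30))
  survey <- bendAngleSurvey(models)
  expect_identical(nrow(survey$perDimer), 3L)
  expect_identical(survey$perEntry$entry_id,
                   c("MT_LIKE", "CURVED", "MOST_CURVED"))
  expect_equal(survey$perEntry$mean_angle_deg, c(1.1, 11.9, 18.2),
               tolerance = 0.01)
  expect_false(is.unsorted(survey$perEntry$mean_angle_deg))
  expect_identical(survey$skipped$entry_id, "NO_TUBULIN")
})

test_that("helix shift is zero against itself and recovers a 1 A translation", {
  m <- makeBentDimer(10.7)
  ann <- annotateModel(m)
  same <- helixShift(m, ann$pairs[[1]], ann$maps,
                     m, ann$pairs[[1]], ann$maps)
  expect_equal(same$shift_A, 0, tolerance = 1e-9)
  at <- atomTable(m)
  idx <- at$chain == "A" & at$resno %in% 224:243
  at[idx, "x"] <- at[idx, "x"] + 1.0
  q <- structureFromAtoms("h7_shifted", at)
  annQ <- annotateModel(q)
  shifted <- helixShift(m, ann$pairs[[1]], ann$maps,
                        q, annQ$pairs[[1]], annQ$maps, element = "H7")
  expect_equal(shifted$shift_A, 1.0, tolerance = 0.01)
  expect_equal(shifted$alignment_rmsd, 0, tolerance = 1e-9)
  # unresolved element is a geometry error
  noH7 <- structureFromAtoms("noH7", atomTable(m)[!idx, ])
  annN <- annotateModel(noH7)
  expect_error(helixShift(m, ann$pairs[[1]], ann$maps, noH7,
                          annN$pairs[[1]], annN$maps, element = "H7"),
               "geometry error")
})

twoComplexModel <- function(jitterSd = 0) {
  c1 <- makeBentDimer(11, withBinder = TRUE, chains = c("A", "B", "C"))
  c2 <- makeBentDimer(11, withBinder = TRUE, chains = c("D", "E", "F"))
  c2 <- translateModel(c2, shift = c(120, 0, 0))
  if (jitterSd > 0) {
    at <- atomTable(c2)
    at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
      matrix(rnorm(3 * nrow(at), sd = jitterSd), ncol = 3)
    c2 <- structureFromAtoms("jittered", at)
  }
  mergeModels(list(c1, c2), id = "two_complexes")
}

test_that("duplicated complexes have zero pairwise RMSD", {
  m <- twoComplexModel()
  ann <- annotateModel(m)
  expect_length(ann$pairs, 2L)
  rm <- pairwiseComplexRmsd(m, ann$pairs, ann$maps)
  expect_equal(rm[1, 2], 0, tolerance = 1e-9)
  expect_identical(rm[1, 2], rm[2, 1])
  expect_identical(diag(rm), c(0, 0))
  # tubulin + binder Calphas all enter the common set
  expect_identical(attr(rm, "nPoints"), 451L + 444L + 100L)
  expect_error(pairwiseComplexRmsd(m, ann$pairs[1], ann$maps),
               "at least 2")
})

test_that("a jittered copy lands at the expected RMSD", {
  # per-coordinate sd 0.4/sqrt(3) gives E[rmsd] ~ 0.4 A
  set.seed(22)
  m <- twoComplexModel(jitterSd = 0.4 / sqrt(3))
  ann <- annotateModel(m)
  rm <- pairwiseComplexRmsd(m, ann$pairs, ann$maps)
  expect_gt(rm[1, 2], 0.3)
  expect_lt(rm[1, 2], 0.5)
})
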