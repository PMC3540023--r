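# Atom typing, pair accumulation, smoothing, the reference state and
# interaction energies.

test_that("atom types are residue specific and reject nonstandard residues", {
  expect_equal(assignAtomType("ALA", "CB"), "ALA CB")
  expect_false(assignAtomType("GUA", "N2") == assignAtomType("ADE", "N6"))
  expect_equal(assignAtomType("DA", "N6"), assignAtomType("A", "N6"))
  expect_error(assignAtomType("HOH", "O"), "HOH")
})

test_that("pair accumulation bins cross pairs and respects the cutoff", {
  cfg <- potentialConfig(useSmoothing = FALSE, useDipolar = FALSE,
                         useReweight = FALSE, useVolumeFraction = FALSE)
  s <- pointStructure(dnaAtomRow("N6", "DA", c(5.1, 0, 0)))
  h <- accumulatePairs(list(s), cfg)
  expect_equal(length(h@counts), 1L)
  v <- h@counts[[1L]]
  expect_equal(sum(v), 1)
  expect_equal(which(v > 0), 11L)  # [5.0, 5.5) with 0.5 A bins
  # beyond the cutoff: nothing counted at all
  far <- pointStructure(dnaAtomRow("N6", "DA", c(12, 0, 0)))
  expect_error(accumulatePairs(list(far), cfg), "within the cutoff")
  expect_error(accumulatePairs(list(), cfg), "at least one")
})

test_that("reweighting makes training invariant to duplicated structures", {
  cfg <- potentialConfig(useDipolar = FALSE)
  cx <- fixtureToy()
  h1 <- accumulatePairs(list(cx), cfg)
  h2 <- accumulatePairs(list(cx, cx), cfg)
  # identical histograms after normalization by the structure count
  expect_equal(lapply(h2@counts, function(v) v / h2@nStructures)[names(h1@counts)],
               lapply(h1@counts, function(v) v / h1@nStructures))
  p1 <- buildPotential(smoothHistogram(h1), list(cx), cfg)
  p2 <- buildPotential(smoothHistogram(h2), list(cx, cx), cfg)
  expect_equal(p2@energies[names(p1@energies)], p1@energies)
  # trainTfire is the composition of the three steps
  t1 <- trainTfire(cx, cfg)
  expect_equal(t1@energies, p1@energies)
  expect_equal(t1@trainingIds, sourceId(cx))
})

test_that("smoothing applies the conserved [1,2,4,2,1]/10 kernel", {
  cfg <- potentialConfig(useSmoothing = TRUE)
  nb <- as.integer(cfg@rCut / cfg@deltaR)
  v <- numeric(nb); v[20] <- 10
  h <- methods::new("PairHistogram", counts = list(`GLY CA||ADE N6` = v),
                    nStructures = 1L,
                    binEdges = seq(0, cfg@rCut, cfg@deltaR), config = cfg)
  sm <- smoothHistogram(h)
  expect_equal(sm@counts[[1L]][18:22], c(1, 2, 4, 2, 1))
  expect_equal(sum(sm@counts[[1L]]), 10, tolerance = 1e-9)
  # edge truncation conserves weight
  v2 <- numeric(nb); v2[1] <- 5
  h@counts <- list(k = v2)
  expect_equal(sum(smoothHistogram(h)@counts[[1L]]), 5, tolerance = 1e-9)
  # identity when disabled
  cfgOff <- potentialConfig(useSmoothing = FALSE)
  hOff <- methods::new("PairHistogram", counts = list(k = v2),
                       nStructures = 1L,
                       binEdges = seq(0, cfgOff@rCut, cfgOff@deltaR),
                       config = cfgOff)
  expect_identical(smoothHistogram(hOff)@counts, hOff@counts)
})

test_that("volume fractions are atom-count fractions, scale invariant", {
  s1 <- pointStructure(dnaAtomRow("N6", "DA", c(5, 0, 0)))
  v <- volumeFractionFactor(list(s1))
  expect_equal(unname(v), c(0.5, 0.5))
  expect_equal(sum(v), 1)
  expect_equal(volumeFractionFactor(list(s1, s1)), v)
})

test_that("the reference state yields zero energy on reference-shaped counts", {
  cfg <- potentialConfig(useSmoothing = FALSE, useDipolar = FALSE,
                         useReweight = FALSE, useVolumeFraction = FALSE,
                         pseudoCount = 0)
  nb <- as.integer(cfg@rCut / cfg@deltaR)
  centers <- (seq_len(nb) - 0.5) * cfg@deltaR
  shaped <- 7 * centers^cfg@alpha / sum(centers^cfg@alpha)
  h <- methods::new("PairHistogram", counts = list(`GLY CA||ADE N6` = shaped),
                    nStructures = 1L, binEdges = seq(0, cfg@rCut, cfg@deltaR),
                    config = cfg)
  s <- pointStructure(dnaAtomRow("N6", "DA", c(5, 0, 0)))
  pot <- buildPotential(h, list(s), cfg)
  expect_lt(max(abs(pot@energies[[1L]])), 1e-9)
  # reference self-normalization: sum Nref == sum Nobs for every type pair
  refShape <- centers^cfg@alpha / sum(centers^cfg@alpha)
  nobs <- shaped + cfg@pseudoCount
  expect_equal(sum(sum(nobs) * refShape), sum(nobs), tolerance = 1e-9)
  # doubling one bin strictly lowers its energy
  bumped <- shaped; bumped[10] <- bumped[10] * 2
  h2 <- methods::new("PairHistogram", counts = list(`GLY CA||ADE N6` = bumped),
                     nStructures = 1L, binEdges = h@binEdges, config = cfg)
  pot2 <- buildPotential(h2, list(s), cfg)
  expect_lt(pot2@energies[[1L]][10], pot@energies[[1L]][10])
  # finite everywhere once a pseudo-count is present
  cfgP <- potentialConfig(useSmoothing = FALSE, useDipolar = FALSE,
                          useReweight = FALSE, useVolumeFraction = FALSE)
  hz <- methods::new("PairHistogram",
                     counts = list(`GLY CA||ADE N6` = numeric(nb)),
                     nStructures = 1L, binEdges = h@binEdges, config = cfgP)
  potz <- buildPotential(hz, list(s), cfgP)
  expect_true(all(is.finite(potz@energies[[1L]])))
})

test_that("dipolar weights follow the orientation rule and stay in [0,1]", {
  # carbon pairs are apolar: always 1
  expect_equal(dipolarWeight(c(0, 0, 0), c(4, 0, 0),
                             matrix(c(-1, 0, 0), 1), matrix(c(5, 0, 0), 1),
                             "C", "C"), 1)
  # both dipoles facing each other: full weight
  expect_equal(dipolarWeight(c(0, 0, 0), c(4, 0, 0),
                             matrix(c(-1, 0, 0), 1), matrix(c(5, 0, 0), 1),
                             "N", "O"), 1)
  # both pointing away: zero
  expect_equal(dipolarWeight(c(0, 0, 0), c(4, 0, 0),
                             matrix(c(1, 0, 0), 1), matrix(c(3, 0, 0), 1),
                             "N", "O"), 0)
  # missing neighbor: weight 1 with a warning
  expect_warning(
    w <- dipolarWeight(c(0, 0, 0), c(4, 0, 0),
                       matrix(numeric(0), 0, 3), matrix(c(5, 0, 0), 1),
                       "N", "O"),
    "without bonded neighbor")
  expect_equal(w, 1)
  # bounded on random geometries
  set.seed(9)
  for (k in 1:50) {
    w <- dipolarWeight(c(0, 0, 0), runif(3, 1, 4),
                       matrix(rnorm(3), 1), matrix(rnorm(3) + 2, 1),
                       "O", "N")
    expect_gte(w, 0); expect_lte(w, 1)
  }
})

test_that("interaction energy is additive, oracle-exact and rigid-invariant", {
  pot <- fixturePotential()
  cx <- fixtureToy()
  expect_identical(interactionEnergy(pot, cx, positions = integer(0)), 0)
  eAll <- interactionEnergy(pot, cx)
  perPos <- vapply(tfbsPositions(cx),
                   function(p) interactionEnergy(pot, cx, positions = p), 0)
  expect_equal(sum(perPos), eAll, tolerance = 1e-9)
  # brute-force double-loop oracle on a subset
  expect_equal(interactionEnergy(pot, cx, positions = c(2L, 5L)),
               bruteForceEnergy(pot, cx, c(2L, 5L)), tolerance = 1e-9)
  # rigid motion of the whole complex leaves the energy unchanged
  rot <- cx
  a <- atoms(rot)
  R <- tfire:::rotationMatrix(c(1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3)), 0.83)
  m <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- m[, 1] + 5; a$y <- m[, 2] - 2; a$z <- m[, 3] + 1
  rot@atoms <- a
  expect_equal(interactionEnergy(pot, rot), eAll, tolerance = 1e-9)
})

test_that("potential TSV serialization round-trips energies and config", {
  pot <- fixturePotential()
  f <- tempfile(fileext = ".tsv")
  writePotential(pot, f)
  pot2 <- readPotential(f)
  expect_equal(sort(names(pot2@energies)), sort(names(pot@energies)))
  for (k in names(pot@energies))
    expect_equal(pot2@energies[[k]], pot@energies[[k]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  expect_equal(pot2@nullEnergy, pot@nullEnergy, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(pot2@config, pot@config)
  expect_equal(pot2@trainingIds, pot@trainingIds)
  # energies evaluated through the round-tripped table agree
  cx <- fixtureToy()
  expect_equal(interactionEnergy(pot2, cx), interactionEnergy(pot, cx),
               tolerance = 1e-4)
})

test_that("training requires a nonempty interface", {
  cx <- fixtureToy()
  a <- atoms(cx)
  a$x[a$class == "protein"] <- a$x[a$class == "protein"] + 500
  far <- methods::new("ComplexStructure", atoms = a,
                      basePairs = basePairs(cx),
                      tfbsPositions = tfbsPositions(cx), sourceId = "far")
  expect_error(trainTfire(far), "within the cutoff")
})
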