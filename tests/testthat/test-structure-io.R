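# Structure reading/writing, base-pair detection, the interface window,
# fixed-backbone substitution and rigid perturbation.

test_that("PDB round trip preserves atoms, chains and coordinates", {
  cx <- fixtureToy()
  f <- tempfile(fileext = ".pdb")
  writeComplex(cx, f)
  cx2 <- readComplex(f, proteinChains = "A", dnaChains = c("C", "D"))
  a0 <- atoms(cx); a2 <- atoms(cx2)
  expect_equal(nrow(a0), nrow(a2))
  k0 <- paste(a0$chain, a0$resid, a0$name)
  k2 <- paste(a2$chain, a2$resid, a2$name)
  expect_true(setequal(k0, k2))
  mm <- match(k0, k2)
  expect_lt(max(abs(as.matrix(a0[, c("x", "y", "z")]) -
                    as.matrix(a2[mm, c("x", "y", "z")]))), 1e-3)
  expect_equal(nrow(basePairs(cx2)), nrow(basePairs(cx)))
  expect_equal(tfbsLength(cx2), tfbsLength(cx))
})

test_that("readComplex partitions chains and rejects bad chain specs", {
  cx <- makeToyComplex(toySpec(sequence = "GCGTACGTACGCAT"))
  expect_equal(nrow(basePairs(cx)), 14L)
  f <- tempfile(fileext = ".pdb")
  writeComplex(cx, f)
  cx2 <- readComplex(f, proteinChains = "A", dnaChains = c("C", "D"))
  expect_true(all(atoms(cx2)$chain[atoms(cx2)$class == "protein"] == "A"))
  expect_error(readComplex(f, proteinChains = "Q", dnaChains = c("C", "D")),
               "Q")
  expect_error(readComplex(f, proteinChains = "A", dnaChains = character(0)),
               "DNA chain")
  expect_error(readComplex(f, proteinChains = "C", dnaChains = "A"),
               "amino-acid")
})

test_that("base pairs are detected in order; unpairable residues drop out", {
  dna <- dnaOnlyComplex("GCCGGTACCGGC")
  bp <- detectBasePairs(dna)
  expect_equal(bp$position, 1:12)
  expect_equal(paste(bp$base1, collapse = ""), "GCCGGTACCGGC")
  expect_true(all(bp$base2 == chartr("ACGT", "TGCA", bp$base1)))
  # remove the partner of position 1 -> an unpaired overhang
  a <- atoms(dna)
  drop <- a$chain == "D" & a$resid == 12L
  ov <- methods::new("ComplexStructure", atoms = a[!drop, , drop = FALSE],
                     basePairs = data.frame(), sourceId = "overhang")
  expect_warning(bp2 <- detectBasePairs(ov), "could not be paired")
  expect_equal(nrow(bp2), 11L)
  # single-stranded input fails
  ss <- methods::new("ComplexStructure",
                     atoms = a[a$chain == "C", , drop = FALSE],
                     basePairs = data.frame(), sourceId = "ss")
  expect_error(detectBasePairs(ss), "two DNA strands")
})

test_that("effective TFBS follows the 10 A rule and is monotone in cutoff", {
  cx <- fixtureToy()
  expect_equal(tfbsPositions(cx), 1:12)   # every pair has a nearby probe
  expect_equal(tfbsLength(cx), 12L)
  # push three terminal pairs far away
  moved <- cx
  a <- atoms(moved)
  bp <- basePairs(moved)
  sel <- (a$chain == "C" & a$resid %in% 1:3) |
         (a$chain == "D" & a$resid %in% bp$resid2[bp$position %in% 1:3])
  a$z[sel] <- a$z[sel] - 25   # below the helix start, away from every probe
  moved@atoms <- a
  pos <- effectiveTfbs(moved)
  expect_false(any(1:3 %in% pos))
  expect_true(all(4:12 %in% pos))
  # monotonicity
  p6 <- effectiveTfbs(cx, cutoff = 6)
  p10 <- effectiveTfbs(cx, cutoff = 10)
  p14 <- effectiveTfbs(cx, cutoff = 14)
  expect_true(all(p6 %in% p10))
  expect_true(all(p10 %in% p14))
  expect_error(effectiveTfbs(cx, cutoff = 0), "no interface")
})

test_that("substitution keeps the backbone fixed and is local", {
  cx <- fixtureToy()
  a0 <- atoms(cx)
  bp <- basePairs(cx)
  # self-substitution: position 3 is native G
  expect_equal(bp$pairType[3], "G-C")
  s <- substituteBasePair(cx, 3, "G-C")
  a1 <- atoms(s)
  k0 <- paste(a0$chain, a0$resid, a0$name)
  k1 <- paste(a1$chain, a1$resid, a1$name)
  expect_true(setequal(k0, k1))
  mm <- match(k0, k1)
  expect_lt(max(abs(as.matrix(a0[, c("x", "y", "z")]) -
                    as.matrix(a1[mm, c("x", "y", "z")]))), 0.8)
  # cross substitution: A-T at position 5 -> G-C; only that pair moves
  s2 <- substituteBasePair(cx, 5, "G-C")
  a2 <- atoms(s2)
  expect_equal(basePairs(s2)$pairType[5], "G-C")
  k2 <- paste(a2$chain, a2$resid, a2$name)
  common <- intersect(k0, k2)
  d <- rowSums(abs(as.matrix(a0[match(common, k0), c("x", "y", "z")]) -
                   as.matrix(a2[match(common, k2), c("x", "y", "z")])))
  touched <- unique(paste(a0$chain[match(common, k0)],
                          a0$resid[match(common, k0)])[d > 0])
  expect_true(all(touched %in% c(paste("C", bp$resid1[5]),
                                 paste("D", bp$resid2[5]))))
  # backbone of the substituted residues is bit-identical
  backboneNames <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "C1'")
  bbKeys <- k0[a0$name %in% backboneNames]
  expect_true(all(d[match(bbKeys, common)] == 0, na.rm = TRUE))
  # guanine gains N2/O6, loses N6 relative to adenine: standard composition
  r5 <- a2[a2$chain == "C" & a2$resid == bp$resid1[5], ]
  expect_true(all(c("N2", "O6") %in% r5$name))
  expect_false("N6" %in% r5$name)
  expect_error(substituteBasePair(cx, 99, "A-T"), "not within")
})

test_that("rigid DNA perturbation lands in its RMSD group deterministically", {
  cx <- fixtureToy()
  d0 <- as.matrix(atoms(cx)[atoms(cx)$class == "dna", c("x", "y", "z")])
  p0 <- as.matrix(proteinAtoms(cx)[, c("x", "y", "z")])
  for (g in c(1L, 4L)) {
    pert <- perturbDna(cx, g, seed = 7L)
    d1 <- as.matrix(atoms(pert)[atoms(pert)$class == "dna", c("x", "y", "z")])
    r <- computeRmsd(d0, d1)
    expect_gt(r, g - 1)
    expect_lte(r, g)
    # protein untouched
    expect_identical(as.matrix(proteinAtoms(pert)[, c("x", "y", "z")]), p0)
    # rigidity: intra-DNA distances preserved
    i <- seq(1, nrow(d0), by = 37)
    expect_equal(as.vector(dist(d0[i, ])), as.vector(dist(d1[i, ])),
                 tolerance = 1e-9)
    # determinism
    pert2 <- perturbDna(cx, g, seed = 7L)
    expect_identical(atoms(pert2), atoms(pert))
  }
})

test_that("computeRmsd matches the closed form and a brute-force oracle", {
  a <- matrix(rnorm(30), 10, 3)
  expect_identical(computeRmsd(a, a), 0)
  b <- sweep(a, 2, c(3, 0, 0), "+")
  expect_equal(computeRmsd(a, b), 3)
  set.seed(42)
  c2 <- matrix(rnorm(30), 10, 3)
  brute <- sqrt(sum((a - c2)^2) / 10)
  expect_equal(computeRmsd(a, c2), brute, tolerance = 1e-12)
  expect_equal(computeRmsd(a, c2), computeRmsd(c2, a))
  # triangle-like bound on random fixtures
  for (k in 1:5) {
    x <- matrix(rnorm(30), 10, 3); y <- matrix(rnorm(30), 10, 3)
    z <- matrix(rnorm(30), 10, 3)
    expect_lte(computeRmsd(x, z), computeRmsd(x, y) + computeRmsd(y, z) + 1e-12)
  }
  expect_error(computeRmsd(a, a[1:5, ]), "differ in size")
})
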