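# Promoter threading, site merging, the >50% overlap rule and threshold
# selection.

mkPem <- function(m) {
  rownames(m) <- c("A", "C", "G", "T")
  methods::new("PEM", energies = m, tfId = "t")
}

test_that("window counting, tie ranks and the brute-force energy oracle", {
  # 500 bp promoter, motif length 14: 487 windows
  set.seed(21)
  seq500 <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                  collapse = "")
  pem14 <- mkPem(matrix(rnorm(56), 4, 14))
  w <- scoreWindows(pem14, seq500)
  expect_equal(nrow(w), 487L)
  # all-zero PEM: all energies zero, ranks follow offsets
  z <- scoreWindows(mkPem(matrix(0, 4, 14)), seq500)
  expect_true(all(z$energy == 0))
  expect_equal(z$rank, seq_len(487L))
  # brute-force per-position sums on a short random sequence
  set.seed(22)
  seq60 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  pem8 <- mkPem(matrix(rnorm(32), 4, 8))
  w8 <- scoreWindows(pem8, seq60)
  chars <- strsplit(seq60, "")[[1L]]
  brute <- vapply(0:(60 - 8), function(off)
    sum(vapply(1:8, function(j) pemEnergies(pem8)[chars[off + j], j], 0)), 0)
  expect_equal(w8$energy, brute, tolerance = 1e-9)
  # windows containing N are kept in the count but never predictable
  seqN <- paste0(substr(seq60, 1, 20), "N", substr(seq60, 22, 60))
  wN <- scoreWindows(pem8, seqN)
  expect_equal(nrow(wN), 53L)
  expect_true(all(is.infinite(wN$energy[14:21])))
  # shorter than the motif: empty with a warning
  expect_warning(w0 <- scoreWindows(pem8, "ACGT"), "shorter")
  expect_equal(nrow(w0), 0L)
})

test_that("per-position energy shifts change window energies by a constant", {
  set.seed(3)
  seq60 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  m <- matrix(rnorm(24), 4, 6)
  w1 <- scoreWindows(mkPem(m), seq60)
  w2 <- scoreWindows(mkPem(sweep(m, 2, c(1, -2, 0.5, 3, 3, -1), "+")), seq60)
  expect_equal(w2$energy - w1$energy, rep(4.5, nrow(w1)), tolerance = 1e-9)
  expect_equal(w2$rank, w1$rank)
})

test_that("overlapping and bookended site annotations merge to their union", {
  # curated-style 1-based inclusive intervals 1984-2007 and 1988-2012
  f <- tempfile(fileext = ".tsv")
  writeLines("orf\tstart\tend\nchr1\t1984\t2007\nchr1\t1988\t2012", f)
  sites <- readSites(f, oneBased = TRUE)
  m <- mergeSites(sites)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start + 1L, 1984L)  # back to 1-based
  expect_equal(m$end, 2012L)
  # disjoint unchanged; nested collapse to the outer interval
  s2 <- data.frame(orf = "p", start = c(0L, 50L), end = c(10L, 60L))
  expect_equal(mergeSites(s2)[, c("start", "end")], s2[, c("start", "end")],
               ignore_attr = TRUE)
  s3 <- data.frame(orf = "p", start = c(10L, 12L), end = c(40L, 20L))
  expect_equal(mergeSites(s3)$start, 10L)
  expect_equal(mergeSites(s3)$end, 40L)
  # disjoint output covering exactly the union
  set.seed(7)
  s4 <- data.frame(orf = "p", start = st <- sample(0:80, 12))
  s4$end <- s4$start + sample(3:15, 12, replace = TRUE)
  m4 <- mergeSites(s4)
  expect_true(all(m4$start[-1] > m4$end[-nrow(m4)]))
  cover <- function(df) sort(unique(unlist(Map(seq, df$start, df$end - 1L))))
  expect_equal(cover(m4), cover(s4))
})

test_that("classification follows the >50% rule, including long sites", {
  cfg <- scanConfig()
  site14 <- data.frame(orf = "p", start = 100L, end = 114L)  # Ld = 14
  predHit <- data.frame(orf = "p", offset = 106L, length = 14L)  # Lo = 8
  c1 <- classifyPredictions(predHit, site14, Ln = 14L, cfg)
  expect_equal(c(c1$tp, c1$fn, c1$fp), c(1L, 0L, 0L))
  # database site longer than the template: Lo/Ln rescues the call
  site30 <- data.frame(orf = "p", start = 100L, end = 130L)  # Ld = 30
  c2 <- classifyPredictions(predHit, site30, Ln = 14L, cfg)
  expect_equal(c2$tp, 1L)  # 8/14 > 0.5 even though 8/30 < 0.5
  # exactly 50% overlap is not enough
  pred7 <- data.frame(orf = "p", offset = 107L, length = 14L)  # Lo = 7
  c3 <- classifyPredictions(pred7, site14, Ln = 14L, cfg)
  expect_equal(c(c3$tp, c3$fp), c(0L, 1L))
  # several windows on one site: one TP, no FP
  multi <- data.frame(orf = "p", offset = c(98L, 100L, 102L), length = 14L)
  c4 <- classifyPredictions(multi, site14, Ln = 14L, cfg)
  expect_equal(c(c4$tp, c4$fp), c(1L, 0L))
  expect_error(classifyPredictions(predHit, site14, Ln = 0L), "positive")
})

test_that("classification is monotone as the threshold relaxes", {
  set.seed(13)
  wins <- data.frame(orf = "p", offset = sample(0:90, 40, replace = TRUE),
                     length = 10L, energy = rnorm(40))
  sites <- mergeSites(data.frame(orf = "p", start = c(5L, 40L, 70L),
                                 end = c(15L, 50L, 80L)))
  prev <- NULL
  for (cut in sort(unique(wins$energy))) {
    cc <- classifyPredictions(wins[wins$energy <= cut, ], sites, Ln = 10L)
    if (!is.null(prev)) {
      expect_gte(cc$tp, prev$tp)
      expect_gte(cc$fp, prev$fp)
    }
    prev <- cc
  }
})

test_that("threshold choice maximizes SE+SP, ties toward stringency", {
  cfg <- scanConfig(keepK = 50L)
  # separable toy: planted windows at -10, everything else >= 0
  wins <- data.frame(orf = "p",
                     offset = c(10L, 40L, 0L, 20L, 30L, 55L, 70L, 80L),
                     length = 10L,
                     energy = c(-10, -10, 0, 0.5, 1, 2, 3, 4),
                     kept = TRUE)
  sites <- data.frame(orf = "p", start = c(10L, 40L), end = c(20L, 50L))
  th <- chooseThreshold(wins, sites, Ln = 10L, cfg)
  expect_equal(th$cutoff, -10)
  expect_equal(th$seSp, 2)
  # degenerate: all windows at the same energy
  winsEq <- transform(wins, energy = 1)
  thEq <- chooseThreshold(winsEq, sites, Ln = 10L, cfg)
  expect_equal(thEq$se, 1)
  expect_equal(thEq$sp, thEq$counts$tp / nrow(wins))
  expect_error(chooseThreshold(wins, sites[0, ], Ln = 10L, cfg), "no annotated")
})

test_that("threshold choice matches exhaustive enumeration", {
  cfg <- scanConfig(keepK = 20L)
  set.seed(31)
  for (rep in 1:5) {
    wins <- data.frame(orf = "p", offset = sample(seq(0, 180, by = 3), 20),
                       length = 12L, energy = round(rnorm(20), 2), kept = TRUE)
    sites <- mergeSites(data.frame(orf = "p",
                                   start = st <- sample(0:170, 4),
                                   end = st + 12L))
    th <- chooseThreshold(wins, sites, Ln = 12L, cfg)
    seSp <- function(cut) {
      cc <- classifyPredictions(wins[wins$energy <= cut, ], sites, Ln = 12L, cfg)
      sensitivity(cc) + specificity(cc)
    }
    best <- max(vapply(sort(unique(wins$energy)), seSp, 0))
    expect_equal(th$seSp, best, tolerance = 1e-12)
    expect_equal(seSp(th$cutoff), best, tolerance = 1e-12)
    # SE+SP at the returned threshold dominates every candidate
    expect_true(all(vapply(sort(unique(wins$energy)), seSp, 0) <= th$seSp + 1e-12))
  }
})

test_that("promoter scanning keeps the lowest-energy windows per promoter", {
  pem <- fixturePem()
  pr <- fixturePromoters()
  sc <- scanPromoters(pem, pr$promoters, scanConfig(keepK = 25L))
  expect_equal(unname(table(sc$orf)[1]), 500L - pemLength(pem) + 1L)
  for (id in unique(sc$orf)) {
    sub <- sc[sc$orf == id, ]
    expect_equal(sum(sub$kept), 25L)
    expect_lte(max(sub$energy[sub$kept]), min(sub$energy[!sub$kept]))
  }
})
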