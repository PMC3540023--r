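# Synthetic fixtures: idealized B-form DNA, sequence-specific toy complexes,
# planted-motif promoters with annotations, and random decoy sequences.
# Every generator is a pure function of its arguments plus a seed.

#' Idealized B-form DNA duplex
#'
#' Builds a duplex from the given first-strand sequence with helical rise
#' 3.38 A and twist 36 degrees per step, idealized heavy-atom base
#' geometries and a schematic sugar/phosphate backbone. Strand 1 is chain C
#' (residues 1..n, 5' to 3'), strand 2 chain D (complementary, antiparallel).
#'
#' @param sequence DNA string (A/C/G/T), length at least 2
#' @return atom data.frame (DNA only) suitable for [newComplexStructure()]
#' @export
makeBDna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) < 2L) stop("sequence must have at least 2 bases")
  if (!all(chars %in% DNA_BASES))
    stop("sequence contains non-ACGT characters")
  n <- length(chars)
  rise <- 3.38
  twist <- 36 * pi / 180
  resRows <- function(mat, base, resid, chain) {
    data.frame(name = rownames(mat), resname = paste0("D", base),
               resid = resid, chain = chain,
               x = mat[, 1L], y = mat[, 2L], z = mat[, 3L],
               class = "dna", stringsAsFactors = FALSE)
  }
  addBackbone <- function(mat) {
    fr <- glycosidicFrame(mat)
    bb <- sweep(BACKBONE_LOCAL %*% t(fr$R), 2, fr$origin, "+")
    colnames(bb) <- c("x", "y", "z")
    rbind(bb, mat)
  }
  s1 <- vector("list", n)
  s2 <- vector("list", n)
  for (k in seq_len(n)) {
    tmpl <- pairTemplate(chars[k])
    R <- rotationMatrix(c(0, 0, 1), -twist * (k - 1L))
    tz <- c(0, 0, rise * (k - 1L))
    place <- function(m) sweep(m %*% t(R), 2, tz, "+")
    b1 <- addBackbone(place(tmpl$b1))
    b2 <- addBackbone(place(tmpl$b2))
    s1[[k]] <- resRows(b1, chars[k], k, "C")
    s2[[k]] <- resRows(b2, complementBase(chars[k]), n + 1L - k, "D")
  }
  atoms <- rbind(do.call(rbind, s1), do.call(rbind, rev(s2)))
  rownames(atoms) <- NULL
  atoms
}

#' Toy complex specification
#'
#' @param sequence first-strand DNA sequence of the duplex (8-20 bases)
#' @param nProbeAtoms number of pseudo-protein probe atoms (>= 4); probes
#'   are assigned cyclically to duplex positions
#' @param specificityStrength 1 anchors each probe 3.5 A outside the
#'   major-groove atom unique to the native base at its position; 0 removes
#'   the anchoring (seeded random placement near the pair); intermediate
#'   values interpolate
#' @param seed RNG seed
#' @return a list with class `ToySpec`
#' @export
toySpec <- function(sequence = "GCGTACGTACGC", nProbeAtoms = nchar(sequence),
                    specificityStrength = 1, seed = 1L) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) < 8L || length(chars) > 20L)
    stop("sequence must have 8-20 bases")
  if (!all(chars %in% DNA_BASES)) stop("sequence must be A/C/G/T only")
  if (nProbeAtoms < 4L) stop("nProbeAtoms must be at least 4")
  structure(list(sequence = paste(chars, collapse = ""),
                 nProbeAtoms = as.integer(nProbeAtoms),
                 specificityStrength = specificityStrength,
                 seed = as.integer(seed)),
            class = "ToySpec")
}

# major-groove heavy atom unique to each base
UNIQUE_BASE_ATOM <- c(A = "N6", C = "N4", G = "O6", T = "C7")

#' Sequence-specific toy protein/DNA complex
#'
#' Builds idealized B-DNA from the spec sequence and adds pseudo-protein
#' probe atoms (single-atom GLY CA residues, chain A) in the major groove.
#' At full specificity strength each probe sits about 3.5 A outside the
#' major-groove atom unique to the native first-strand base at its position,
#' so the contact geometry is tied to the native sequence; at strength 0 the
#' probes are placed at seeded random offsets near the pair instead.
#'
#' @param spec a [toySpec()]
#' @return a [ComplexStructure-class]
#' @export
makeToyComplex <- function(spec = toySpec()) {
  atoms <- makeBDna(spec$sequence)
  chars <- strsplit(spec$sequence, "")[[1L]]
  n <- length(chars)
  probes <- withSeed(spec$seed, {
    lapply(seq_len(spec$nProbeAtoms), function(i) {
      pos <- ((i - 1L) %% n) + 1L
      base <- chars[pos]
      sel <- atoms$chain == "C" & atoms$resid == pos
      m <- atomCoords(atoms[sel, , drop = FALSE])
      rownames(m) <- atoms$name[sel]
      ctr <- colMeans(m[intersect(ringAtomNames(base), rownames(m)), ,
                        drop = FALSE])
      anchor <- m[UNIQUE_BASE_ATOM[[base]], ]
      dir <- anchor - ctr
      dir <- dir / sqrt(sum(dir^2))
      anchored <- anchor + 3.5 * dir
      jitter <- randomUnitVector() * (1 - spec$specificityStrength) * 4 +
        randomUnitVector() * 0.05
      p <- anchored + jitter
      data.frame(name = "CA", resname = "GLY", resid = i, chain = "A",
                 x = p[1L], y = p[2L], z = p[3L], class = "protein",
                 stringsAsFactors = FALSE)
    })
  })
  atoms <- rbind(do.call(rbind, probes), atoms)
  newComplexStructure(atoms,
                      sourceId = sprintf("toy_%s_s%d", spec$sequence,
                                         spec$seed))
}

#' Promoter set specification
#'
#' @param nPromoters number of promoters
#' @param length promoter length in bp (default 500, the upstream window of
#'   an ORF start codon)
#' @param nSites total number of planted sites (ignored when `plantedSites`
#'   is given); every promoter receives at least one site
#' @param plantedSites optional data.frame (`promoter` index, `offset`) of
#'   explicit plant positions
#' @param backgroundGc background GC content
#' @param seed RNG seed
#' @return a list with class `PromoterSpec`
#' @export
promoterSpec <- function(nPromoters = 10L, length = 500L, nSites = 15L,
                         plantedSites = NULL, backgroundGc = 0.38,
                         seed = 1L) {
  structure(list(nPromoters = as.integer(nPromoters),
                 length = as.integer(length), nSites = as.integer(nSites),
                 plantedSites = plantedSites, backgroundGc = backgroundGc,
                 seed = as.integer(seed)),
            class = "PromoterSpec")
}

.sampleMotif <- function(motif) {
  if (is(motif, "PWM")) {
    p <- pwmProbs(motif)
    paste(vapply(seq_len(ncol(p)), function(j)
      sample(DNA_BASES, 1L, prob = p[, j]), ""), collapse = "")
  } else {
    toupper(motif)
  }
}

#' Promoters with planted binding sites
#'
#' Generates i.i.d. background sequence at the requested GC content, plants
#' motif instances (an exact motif string, or draws from a PWM) at
#' seeded-random non-overlapping offsets (or at the spec's explicit
#' positions), and rewrites any background window that matches the planted
#' consensus exactly so that separability claims are constructive.
#' Overlapping planted sites are merged in the returned annotations.
#'
#' @param spec a [promoterSpec()]
#' @param motif exact motif string or a [PWM-class]
#' @return list with `promoters` (named character vector) and `sites`
#'   (data.frame `orf`, `start`, `end`, 0-based half-open)
#' @export
makePromoters <- function(spec, motif) {
  consensus <- if (is(motif, "PWM")) pwmConsensus(motif)$consensus
               else toupper(motif)
  L <- nchar(consensus)
  if (L > spec$length) stop("motif longer than the promoter")
  withSeed(spec$seed, {
    bg <- c((1 - spec$backgroundGc) / 2, spec$backgroundGc / 2,
            spec$backgroundGc / 2, (1 - spec$backgroundGc) / 2)
    proms <- vapply(seq_len(spec$nPromoters), function(i)
      paste(sample(DNA_BASES, spec$length, replace = TRUE, prob = bg),
            collapse = ""), "")
    names(proms) <- sprintf("ORF%03d", seq_len(spec$nPromoters))
    plan <- spec$plantedSites
    if (is.null(plan)) {
      if (spec$nSites < spec$nPromoters)
        stop("need at least one site per promoter")
      promOf <- c(seq_len(spec$nPromoters),
                  sample(spec$nPromoters, spec$nSites - spec$nPromoters,
                         replace = TRUE))
      plan <- data.frame(promoter = promOf, offset = NA_integer_)
      for (i in seq_len(nrow(plan))) {
        repeat {
          off <- sample.int(spec$length - L + 1L, 1L) - 1L
          others <- plan$offset[plan$promoter == plan$promoter[i] &
                                  !is.na(plan$offset)]
          if (!length(others) || all(abs(others - off) >= L)) break
        }
        plan$offset[i] <- off
      }
    }
    if (any(plan$offset < 0L | plan$offset + L > spec$length))
      stop("planted sites must fit within promoter bounds")
    for (i in seq_len(nrow(plan))) {
      inst <- .sampleMotif(motif)
      p <- plan$promoter[i]
      substr(proms[p], plan$offset[i] + 1L, plan$offset[i] + L) <- inst
    }
    # background scrub: resample any non-planted exact consensus match
    for (p in seq_along(proms)) {
      planted <- plan$offset[plan$promoter == p]
      repeat {
        hits <- as.integer(
          Biostrings::start(Biostrings::matchPattern(consensus,
                                                     proms[[p]]))) - 1L
        hits <- setdiff(hits, planted)
        if (!length(hits)) break
        for (h in hits) {
          repl <- paste(sample(DNA_BASES, L, replace = TRUE, prob = bg),
                        collapse = "")
          substr(proms[p], h + 1L, h + L) <- repl
        }
      }
    }
    sites <- mergeSites(data.frame(orf = names(proms)[plan$promoter],
                                   start = plan$offset,
                                   end = plan$offset + L,
                                   stringsAsFactors = FALSE))
    list(promoters = proms, sites = sites)
  })
}

#' Random threading-decoy sequences
#'
#' @param L sequence length
#' @param n number of decoys
#' @param seed RNG seed
#' @return character vector of `n` uniform random sequences of length `L`
#' @export
makeThreadingDecoys <- function(L, n, seed = 1L) {
  if (n < 1L) stop("n must be at least 1")
  withSeed(seed, vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), ""))
}
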