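# Derivation of the distance-dependent knowledge-based potential and
# evaluation of protein-DNA interaction energies.
#
# Energies follow the distance-scaled ideal-gas reference construction:
#   u(i,j,r) = -etaRT * ln( Nobs~(i,j,r) / Nref(i,j,r) )
# with Nobs~ = (possibly reweighted and smoothed) counts + pseudo-count and
# Nref proportional to r^alpha, normalized per atom-type pair so that the
# reference carries the same total weight as the observations (times a
# 2*v_protein*v_dna factor when the volume-fraction correction is on).

#' Potential configuration constructor
#'
#' @param rCut interaction cutoff in Angstrom
#' @param deltaR bin width in Angstrom; defaults to 0.25 when `useSmoothing`
#'   is on and 0.5 otherwise
#' @param alpha exponent of the distance-scaled reference
#' @param etaRT overall energy scale (arbitrary units)
#' @param pseudoCount additive count per bin
#' @param useReweight equal per-structure contribution to the counts
#' @param useSmoothing fine bins plus kernel smoothing of the counts
#' @param useDipolar orientation weight for polar-polar atom pairs
#' @param useVolumeFraction protein/DNA volume-fraction correction
#' @param seed RNG seed recorded with the configuration
#' @return a [PotentialConfig-class]
#' @export
potentialConfig <- function(rCut = 10, deltaR = NULL, alpha = 1.61,
                            etaRT = 1, pseudoCount = 0.5,
                            useReweight = TRUE, useSmoothing = TRUE,
                            useDipolar = TRUE, useVolumeFraction = TRUE,
                            seed = 1L) {
  if (is.null(deltaR)) deltaR <- if (useSmoothing) 0.25 else 0.5
  new("PotentialConfig", rCut = rCut, deltaR = deltaR, alpha = alpha,
      etaRT = etaRT, pseudoCount = pseudoCount, useReweight = useReweight,
      useSmoothing = useSmoothing, useDipolar = useDipolar,
      useVolumeFraction = useVolumeFraction, seed = as.integer(seed))
}

nBins <- function(config) as.integer(round(config@rCut / config@deltaR))

#' Residue-specific atom type
#'
#' The potential distinguishes atoms by residue and atom label, e.g.
#' `(GUA, N2)` and `(ADE, N6)` are different types even though both are
#' exocyclic amino nitrogens.
#'
#' @param residueName standard amino-acid code or nucleotide code
#'   (A/C/G/T, DA/DC/DG/DT or ADE/CYT/GUA/THY)
#' @param atomName heavy-atom label
#' @return canonical type string `"RES ATOM"`
#' @export
assignAtomType <- function(residueName, atomName) {
  up <- toupper(residueName)
  base <- normalizeBase(up)
  res <- ifelse(!is.na(base), BASE_RESNAME[base],
                ifelse(up %in% AMINO3, up, NA_character_))
  if (anyNA(res)) {
    bad <- unique(up[is.na(res)])
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  }
  paste(res, toupper(atomName))
}

.pairKey <- function(ptype, dtype) paste(ptype, dtype, sep = "||")

# per-atom dipole axes: mean direction from bonded heavy neighbors (same
# molecule, distance < 1.8 A) to the atom; NA rows where no neighbor exists
.dipoleAxes <- function(coords) {
  n <- nrow(coords)
  axes <- matrix(NA_real_, n, 3L)
  if (n < 2L) return(axes)
  dm <- crossDist(coords, coords)
  diag(dm) <- Inf
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < 1.8)
    if (!length(nb)) next
    dirs <- sweep(-coords[nb, , drop = FALSE], 2, coords[i, ], "+")
    dirs <- dirs / sqrt(rowSums(dirs^2))
    v <- colSums(dirs)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) axes[i, ] <- v / nv
  }
  axes
}

#' Dipolar orientation weight of an atom pair
#'
#' Apolar atoms (C, S, P) always get weight 1. For a polar-polar pair (N or
#' O on both sides) the weight is `(1 + cos ti)(1 + cos tj)/4`, where `tx`
#' is the angle between atom x's dipole axis (mean direction from its bonded
#' heavy neighbors to the atom) and the interatomic vector toward the
#' partner; the result is clipped to [0, 1]. An atom without a bonded
#' neighbor contributes weight 1 with a warning.
#'
#' @param coordI,coordJ length-3 coordinates of the two atoms
#' @param neighborsI,neighborsJ matrices of bonded-neighbor coordinates
#'   (possibly 0 rows)
#' @param elementI,elementJ chemical elements, e.g. `"N"`, `"C"`
#' @return weight in `[0, 1]`
#' @export
dipolarWeight <- function(coordI, coordJ, neighborsI, neighborsJ,
                          elementI, elementJ) {
  polar <- function(e) e %in% c("N", "O")
  if (!polar(elementI) || !polar(elementJ)) return(1)
  axis <- function(coord, nb) {
    if (is.null(nb) || nrow(nb) == 0L) {
      warning("polar atom without bonded neighbor: dipolar weight 1")
      return(NULL)
    }
    dirs <- sweep(-nb, 2, coord, "+")
    dirs <- dirs / sqrt(rowSums(dirs^2))
    v <- colSums(dirs)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) return(NULL)
    v / nv
  }
  ai <- axis(coordI, neighborsI)
  aj <- axis(coordJ, neighborsJ)
  if (is.null(ai) || is.null(aj)) return(1)
  rij <- coordJ - coordI
  rij <- rij / sqrt(sum(rij^2))
  w <- (1 + sum(ai * rij)) * (1 + sum(aj * (-rij))) / 4
  min(max(w, 0), 1)
}

# all typed cross pairs of one structure within the cutoff:
# returns data.frame(key, bin, w)
.structurePairs <- function(structure, config) {
  atoms <- structure@atoms
  prot <- atoms[atoms$class == "protein", , drop = FALSE]
  dna <- atoms[atoms$class == "dna", , drop = FALSE]
  if (!nrow(prot) || !nrow(dna)) stop("structure lacks protein or DNA atoms")
  ptype <- assignAtomType(prot$resname, prot$name)
  dtype <- assignAtomType(dna$resname, dna$name)
  pm <- atomCoords(prot); dm <- atomCoords(dna)
  D <- crossDist(pm, dm)
  sel <- which(D < config@rCut, arr.ind = TRUE)
  if (!nrow(sel)) stop("no protein-DNA atom pair within the cutoff")
  d <- D[sel]
  w <- rep(1, length(d))
  if (config@useDipolar) {
    pax <- .dipoleAxes(pm)
    dax <- .dipoleAxes(dm)
    pe <- atomElement(prot$name); de <- atomElement(dna$name)
    pol <- (pe[sel[, 1L]] %in% c("N", "O")) & (de[sel[, 2L]] %in% c("N", "O"))
    ok <- pol & !is.na(pax[sel[, 1L], 1L]) & !is.na(dax[sel[, 2L], 1L])
    if (any(ok)) {
      i <- sel[ok, 1L]; j <- sel[ok, 2L]
      rij <- dm[j, , drop = FALSE] - pm[i, , drop = FALSE]
      rij <- rij / sqrt(rowSums(rij^2))
      ci <- rowSums(pax[i, , drop = FALSE] * rij)
      cj <- rowSums(dax[j, , drop = FALSE] * (-rij))
      wk <- (1 + ci) * (1 + cj) / 4
      w[ok] <- pmin(pmax(wk, 0), 1)
    }
  }
  data.frame(key = .pairKey(ptype[sel[, 1L]], dtype[sel[, 2L]]),
             bin = pmin(floor(d / config@deltaR) + 1L, nBins(config)),
             w = w, stringsAsFactors = FALSE)
}

#' Accumulate protein-DNA atom-pair counts
#'
#' Counts every cross protein-DNA heavy-atom pair with distance below the
#' cutoff into distance bins, per residue-specific atom-type pair. With
#' `useReweight`, every training structure contributes equal total weight
#' (counts are used per-structure-averaged downstream, so training on one
#' structure and on k copies of it yields identical results). With
#' `useDipolar`, each pair's weight is multiplied by its orientation weight.
#'
#' @param structures list of [ComplexStructure-class]
#' @param config a [PotentialConfig-class]
#' @return a [PairHistogram-class]
#' @export
accumulatePairs <- function(structures, config = potentialConfig()) {
  if (is(structures, "ComplexStructure")) structures <- list(structures)
  if (!length(structures)) stop("at least one training structure is required")
  nb <- nBins(config)
  perStructure <- lapply(structures, .structurePairs, config = config)
  totals <- vapply(perStructure, function(df) sum(df$w), 0)
  scale <- if (config@useReweight) mean(totals) / totals else rep(1, length(totals))
  acc <- new.env(parent = emptyenv())
  for (s in seq_along(perStructure)) {
    df <- perStructure[[s]]
    grp <- split(seq_len(nrow(df)), df$key)
    for (k in names(grp)) {
      v <- if (is.null(acc[[k]])) numeric(nb) else acc[[k]]
      idx <- grp[[k]]
      t2 <- tapply(df$w[idx] * scale[s], df$bin[idx], sum)
      v[as.integer(names(t2))] <- v[as.integer(names(t2))] + t2
      acc[[k]] <- v
    }
  }
  counts <- as.list(acc)
  new("PairHistogram", counts = counts,
      nStructures = length(structures),
      binEdges = seq(0, config@rCut, by = config@deltaR),
      config = config)
}

# scatter form of the truncated [1,2,4,2,1]/10 kernel: each source bin's
# weight is redistributed with edge-renormalized kernel weights, so the
# per-type total is conserved exactly
.smoothVector <- function(v) {
  kern <- c(1, 2, 4, 2, 1) / 10
  n <- length(v)
  out <- numeric(n)
  for (b in which(v > 0)) {
    tgt <- (b - 2L):(b + 2L)
    ok <- tgt >= 1L & tgt <= n
    kw <- kern[ok]
    out[tgt[ok]] <- out[tgt[ok]] + v[b] * kw / sum(kw)
  }
  out
}

#' Smooth a pair histogram
#'
#' Convolves each atom-type pair's per-bin counts with the symmetric kernel
#' `[1,2,4,2,1]/10` (edge-truncated and renormalized, so the total weight
#' per type pair is conserved). Identity when `useSmoothing` is off.
#'
#' @param histogram a [PairHistogram-class]
#' @param config the matching [PotentialConfig-class]
#' @return a smoothed [PairHistogram-class]
#' @export
smoothHistogram <- function(histogram, config = histogram@config) {
  if (!config@useSmoothing) return(histogram)
  out <- histogram
  out@counts <- lapply(histogram@counts, .smoothVector)
  out
}

#' Protein/DNA volume fractions of a training set
#'
#' Fractions of the total heavy-atom count contributed by protein and by DNA
#' over all training structures.
#'
#' @param structures list of [ComplexStructure-class]
#' @return named numeric vector `c(protein = , dna = )` summing to 1
#' @export
volumeFractionFactor <- function(structures) {
  if (is(structures, "ComplexStructure")) structures <- list(structures)
  np <- sum(vapply(structures, function(s) sum(s@atoms$class == "protein"), 0))
  nd <- sum(vapply(structures, function(s) sum(s@atoms$class == "dna"), 0))
  tot <- np + nd
  if (tot == 0) stop("no atoms in training structures")
  c(protein = np / tot, dna = nd / tot)
}

.binCenters <- function(config) {
  (seq_len(nBins(config)) - 0.5) * config@deltaR
}

.referenceShape <- function(config) {
  r <- .binCenters(config)^config@alpha
  r / sum(r)
}

.energyFromCounts <- function(v, config, fvc) {
  nobs <- v + config@pseudoCount
  tot <- sum(nobs)
  if (tot <= 0) return(numeric(length(v)))
  ref <- tot * .referenceShape(config) * fvc
  -config@etaRT * log(nobs / ref)
}

#' Build the potential from a histogram
#'
#' Converts per-bin counts into energies against the distance-scaled
#' ideal-gas reference. The reference for each atom-type pair is
#' self-normalizing (it integrates to the same total as the pseudo-counted
#' observations); with the volume-fraction correction it is additionally
#' scaled by `2 * v_protein * v_dna`. Energies are zero at and beyond the
#' cutoff. Type pairs never observed fall back to a pseudo-count-only curve.
#'
#' @param histogram a [PairHistogram-class] built with the same config
#' @param structures the training structures (needed for volume fractions)
#' @param config a [PotentialConfig-class]
#' @return a [Potential-class]
#' @export
buildPotential <- function(histogram, structures, config = histogram@config) {
  if (!identical(config, histogram@config))
    stop("config does not match the histogram")
  if (is(structures, "ComplexStructure")) structures <- list(structures)
  fvc <- 1
  if (config@useVolumeFraction) {
    v <- volumeFractionFactor(structures)
    if (v["dna"] == 0 || v["protein"] == 0)
      stop("volume-fraction correction undefined: one molecule class is empty")
    fvc <- 2 * v[["protein"]] * v[["dna"]]
  }
  nS <- max(histogram@nStructures, 1L)
  div <- if (config@useReweight) nS else 1L
  energies <- lapply(histogram@counts, function(v)
    .energyFromCounts(v / div, config, fvc))
  nullE <- .energyFromCounts(numeric(nBins(config)), config, fvc)
  ids <- vapply(structures, sourceId, "")
  new("Potential", energies = energies, nullEnergy = nullE,
      config = config, trainingIds = ids)
}

#' Train a template-specific potential
#'
#' The single-template training strategy: the potential is derived from the
#' very complex structure it will be used to analyse (accumulate counts,
#' smooth, build). This memorizes the template's residue-specific contact
#' statistics and is the basis of the structure-trained prediction pipeline.
#'
#' @param template a [ComplexStructure-class] with a nonempty interface
#' @param config a [PotentialConfig-class]
#' @return a [Potential-class]
#' @export
trainTfire <- function(template, config = potentialConfig()) {
  h <- accumulatePairs(list(template), config)
  h <- smoothHistogram(h, config)
  buildPotential(h, list(template), config)
}

# energy lookup matrix: one row per known type pair plus the null row
.energyMatrix <- function(potential) {
  if (length(potential@energies))
    rbind(do.call(rbind, potential@energies), potential@nullEnergy)
  else
    matrix(potential@nullEnergy, 1L)
}

#' Protein-DNA interaction energy
#'
#' Sum of tabulated pair energies over all (protein atom, DNA base atom)
#' pairs within the cutoff, with the DNA atoms restricted to the base atoms
#' of the requested base-pair positions. Backbone/sugar atoms are excluded:
#' the backbone is identical across base-pair substitutions, so its
#' contribution is a per-position constant that cancels in the Boltzmann
#' conversion.
#'
#' @param potential a [Potential-class]
#' @param structure a [ComplexStructure-class]
#' @param positions base-pair positions to include, or `NULL` for the whole
#'   effective TFBS
#' @return energy in arbitrary units (0 for an empty selection)
#' @export
interactionEnergy <- function(potential, structure, positions = NULL) {
  config <- potential@config
  if (is.null(positions)) positions <- structure@tfbsPositions
  if (!length(positions)) return(0)
  atoms <- structure@atoms
  bp <- structure@basePairs
  i <- match(positions, bp$position)
  if (anyNA(i)) stop("unknown base-pair position(s): ",
                     paste(positions[is.na(i)], collapse = ", "))
  resSel <- paste(atoms$chain, atoms$resid) %in%
    c(paste(bp$chain1[i], bp$resid1[i]), paste(bp$chain2[i], bp$resid2[i]))
  dna <- atoms[atoms$class == "dna" & resSel & isBaseAtom(atoms$name), , drop = FALSE]
  prot <- atoms[atoms$class == "protein", , drop = FALSE]
  if (!nrow(dna) || !nrow(prot)) return(0)
  ptype <- assignAtomType(prot$resname, prot$name)
  dtype <- assignAtomType(dna$resname, dna$name)
  D <- crossDist(atomCoords(prot), atomCoords(dna))
  sel <- which(D < config@rCut, arr.ind = TRUE)
  if (!nrow(sel)) return(0)
  bin <- pmin(floor(D[sel] / config@deltaR) + 1L, nBins(config))
  key <- .pairKey(ptype[sel[, 1L]], dtype[sel[, 2L]])
  row <- match(key, names(potential@energies))
  em <- .energyMatrix(potential)
  row[is.na(row)] <- nrow(em)
  sum(em[cbind(row, bin)])
}
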