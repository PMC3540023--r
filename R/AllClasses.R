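#' @import methods
NULL

#' Protein/DNA complex structure
#'
#' Container for one protein/DNA complex: typed heavy atoms, the detected
#' Watson-Crick base pairs of the DNA duplex, and the effective binding-site
#' window (the base-pair positions with at least one atom within 10 A of the
#' protein).
#'
#' @slot atoms data.frame with columns `name`, `resname`, `resid`, `chain`,
#'   `x`, `y`, `z`, `class` (`"protein"` or `"dna"`).
#' @slot basePairs data.frame with one row per detected pair: `position`
#'   (1-based, 5' to 3' along the first DNA chain), `chain1`, `resid1`,
#'   `base1`, `chain2`, `resid2`, `base2`, `pairType` (e.g. `"A-T"`).
#' @slot tfbsPositions integer vector, subset of `basePairs$position` within
#'   the interface distance cutoff of the protein.
#' @slot sourceId free-text identifier of the complex.
#'
#' @seealso [readComplex()], [makeToyComplex()]
#' @export
setClass("ComplexStructure",
  representation(atoms = "data.frame", basePairs = "data.frame",
                 tfbsPositions = "integer", sourceId = "character"),
  prototype(tfbsPositions = integer(0), sourceId = "complex"))

setValidity("ComplexStructure", function(object) {
  a <- object@atoms
  need <- c("name", "resname", "resid", "chain", "x", "y", "z", "class")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
    return("atom coordinates must be finite")
  if (nrow(a) && !all(a$class %in% c("protein", "dna")))
    return("atom class must be 'protein' or 'dna'")
  bp <- object@basePairs
  if (nrow(bp)) {
    want <- vapply(strsplit(bp$pairType, "-", fixed = TRUE), `[`, "", 1L)
    if (!all(want == bp$base1))
      return("pairType must match the first-strand base")
    if (!all(complementBase(bp$base1) == bp$base2))
      return("pairType must pair complementary bases")
  }
  if (length(object@tfbsPositions) &&
      !all(object@tfbsPositions %in% bp$position))
    return("tfbsPositions must be detected base-pair positions")
  TRUE
})

#' Configuration of the knowledge-based potential
#'
#' Holds the distance grid and the correction toggles of the pair potential.
#' `rCut` (A) is the interaction cutoff; `deltaR` (A) the bin width (0.5 by
#' default, 0.25 when bin smoothing is enabled); `alpha` the exponent of the
#' distance-scaled ideal-gas reference (r^alpha); `etaRT` the overall energy
#' scale in arbitrary units; `pseudoCount` the additive count per bin.
#' Toggles: `useReweight` (equal per-structure weight), `useSmoothing`
#' (fine bins + kernel smoothing), `useDipolar` (orientation weight for
#' polar-polar contacts), `useVolumeFraction` (protein/DNA unmixability
#' correction to the reference).
#'
#' @export
setClass("PotentialConfig",
  representation(rCut = "numeric", deltaR = "numeric", alpha = "numeric",
                 etaRT = "numeric", pseudoCount = "numeric",
                 useReweight = "logical", useSmoothing = "logical",
                 useDipolar = "logical", useVolumeFraction = "logical",
                 seed = "integer"),
  prototype(rCut = 10, deltaR = 0.5, alpha = 1.61, etaRT = 1,
            pseudoCount = 0.5, useReweight = TRUE, useSmoothing = TRUE,
            useDipolar = TRUE, useVolumeFraction = TRUE, seed = 1L))

setValidity("PotentialConfig", function(object) {
  if (object@rCut <= 0) return("rCut must be positive")
  if (object@deltaR <= 0) return("deltaR must be positive")
  nb <- object@rCut / object@deltaR
  if (abs(nb - round(nb)) > 1e-8)
    return("rCut must be an integer multiple of deltaR")
  if (object@pseudoCount < 0) return("pseudoCount must be non-negative")
  TRUE
})

#' Atom-pair distance histogram
#'
#' Observed (possibly reweighted/smoothed) protein-DNA atom-pair counts per
#' residue-specific atom-type pair and distance bin.
#'
#' @slot counts named list; element `"RES ATOM||RES ATOM"` (protein type,
#'   DNA type) is a numeric vector of per-bin weights.
#' @slot nStructures number of training structures accumulated.
#' @slot binEdges distance grid (length nbins + 1).
#' @slot config the [PotentialConfig-class] used.
#' @export
setClass("PairHistogram",
  representation(counts = "list", nStructures = "integer",
                 binEdges = "numeric", config = "PotentialConfig"))

setValidity("PairHistogram", function(object) {
  if (length(object@counts) &&
      any(vapply(object@counts, function(v) any(v < 0), NA)))
    return("histogram weights must be non-negative")
  TRUE
})

#' Distance-dependent knowledge-based potential
#'
#' Tabulated pair energies u(i, j, r) in arbitrary units per residue-specific
#' atom-type pair and distance bin; zero at and beyond the cutoff.  Atom-type
#' pairs never observed in training fall back to the pseudo-count-only energy
#' curve stored in `nullEnergy`.
#'
#' @slot energies named list of per-bin energy vectors keyed like the
#'   histogram counts.
#' @slot nullEnergy per-bin energy vector for unobserved type pairs.
#' @slot config the [PotentialConfig-class] used in training.
#' @slot trainingIds source identifiers of the training structures.
#' @export
setClass("Potential",
  representation(energies = "list", nullEnergy = "numeric",
                 config = "PotentialConfig", trainingIds = "character"))

setValidity("Potential", function(object) {
  if (length(object@energies) &&
      any(!vapply(object@energies, function(v) all(is.finite(v)), NA)))
    return("potential energies must be finite")
  if (!all(is.finite(object@nullEnergy)))
    return("null energy curve must be finite")
  TRUE
})

#' Position energy matrix (PEM)
#'
#' 4 x L matrix of substitution binding energies: entry (b, p) is the
#' interaction energy between the protein and the base atoms of the pair
#' obtained by substituting position p with the pair whose first-strand base
#' is b.  Rows are ordered A, C, G, T, i.e. pairs A-T, C-G, G-C, T-A.
#'
#' @slot energies numeric matrix, rownames A,C,G,T, one column per interface
#'   position.
#' @slot tfId identifier of the factor/template.
#' @slot nativeBases first-strand bases of the template at each column.
#' @export
setClass("PEM",
  representation(energies = "matrix", tfId = "character",
                 nativeBases = "character"),
  prototype(tfId = "pem", nativeBases = character(0)))

setValidity("PEM", function(object) {
  m <- object@energies
  if (nrow(m) != 4L || !identical(rownames(m), DNA_BASES))
    return("PEM must have 4 rows named A,C,G,T")
  if (!all(is.finite(m))) return("PEM entries must be finite")
  if (length(object@nativeBases) &&
      length(object@nativeBases) != ncol(m))
    return("nativeBases length must equal the number of positions")
  TRUE
})

#' Position weight matrix (PWM)
#'
#' 4 x L column-stochastic base-probability matrix, rows A, C, G, T.
#'
#' @slot probs numeric matrix of probabilities.
#' @export
setClass("PWM", representation(probs = "matrix"))

setValidity("PWM", function(object) {
  m <- object@probs
  if (nrow(m) != 4L || !identical(rownames(m), DNA_BASES))
    return("PWM must have 4 rows named A,C,G,T")
  if (any(m < -1e-9) || any(m > 1 + 1e-9))
    return("PWM entries must lie in [0,1]")
  if (ncol(m) && any(abs(colSums(m) - 1) > 1e-9))
    return("PWM columns must sum to 1")
  TRUE
})

# ---- accessors ----

#' @describeIn ComplexStructure-class all atoms as a data.frame
#' @param object,x a `ComplexStructure`
#' @export
atoms <- function(object) object@atoms

#' @describeIn ComplexStructure-class protein atoms only
#' @export
proteinAtoms <- function(object) object@atoms[object@atoms$class == "protein", , drop = FALSE]

#' @describeIn ComplexStructure-class DNA atoms only
#' @export
dnaAtoms <- function(object) object@atoms[object@atoms$class == "dna", , drop = FALSE]

#' @describeIn ComplexStructure-class detected base pairs
#' @export
basePairs <- function(object) object@basePairs

#' @describeIn ComplexStructure-class interface base-pair positions
#' @export
tfbsPositions <- function(object) object@tfbsPositions

#' @describeIn ComplexStructure-class number of interface positions (Ln)
#' @export
tfbsLength <- function(object) length(object@tfbsPositions)

#' @describeIn ComplexStructure-class identifier of the complex
#' @export
sourceId <- function(object) object@sourceId

#' First-strand base sequence of the effective binding site
#'
#' @param object a [ComplexStructure-class]
#' @return character vector of first-strand bases, one per interface position
#' @export
tfbsSequence <- function(object) {
  bp <- object@basePairs
  bp$base1[match(object@tfbsPositions, bp$position)]
}

#' @describeIn PEM-class the 4 x L energy matrix
#' @param object a `PEM` or `PWM`
#' @export
pemEnergies <- function(object) object@energies

#' @describeIn PWM-class the 4 x L probability matrix
#' @export
pwmProbs <- function(object) object@probs

#' @describeIn PEM-class motif length
#' @export
pemLength <- function(object) ncol(object@energies)

setMethod("show", "ComplexStructure", function(object) {
  cat("ComplexStructure:", object@sourceId, "\n")
  cat("  atoms:", sum(object@atoms$class == "protein"), "protein /",
      sum(object@atoms$class == "dna"), "DNA\n")
  cat("  base pairs:", nrow(object@basePairs),
      " effective TFBS positions:", length(object@tfbsPositions), "\n")
  if (length(object@tfbsPositions))
    cat("  TFBS (strand 1):", paste(tfbsSequence(object), collapse = ""), "\n")
})

setMethod("show", "Potential", function(object) {
  cfg <- object@config
  cat("Knowledge-based potential:", length(object@energies), "atom-type pairs,",
      round(cfg@rCut / cfg@deltaR), "bins of", cfg@deltaR, "A up to", cfg@rCut, "A\n")
  corr <- c(if (cfg@useReweight) "R", if (cfg@useSmoothing) "a",
            if (cfg@useDipolar) "P", if (cfg@useVolumeFraction) "vc")
  cat("  corrections:", if (length(corr)) paste(corr, collapse = "") else "none",
      " trained on:", paste(object@trainingIds, collapse = ", "), "\n")
})

setMethod("show", "PEM", function(object) {
  cat("PEM", object@tfId, ":", ncol(object@energies), "positions\n")
  print(round(object@energies, 3))
})

setMethod("show", "PWM", function(object) {
  cat("PWM:", ncol(object@probs), "positions, consensus",
      pwmConsensus(object)$consensus, "\n")
  print(round(object@probs, 3))
})
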