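# Position energy matrices by base-pair substitution, Boltzmann conversion
# to position weight matrices, reference/mutant variants and PWM comparison.

#' Build the position energy matrix of a template
#'
#' For every effective TFBS position the base pair is substituted, on the
#' fixed backbone, by each of the four pair types (A-T, C-G, G-C, T-A,
#' keyed by the first-strand base A, C, G, T) and the interaction energy
#' contributed by the substituted pair's base atoms is tabulated. The input
#' structure is not modified.
#'
#' @param potential a [Potential-class]
#' @param structure a [ComplexStructure-class]
#' @param tfId identifier stored with the matrix
#' @return a [PEM-class] with one column per interface position
#' @export
buildPem <- function(potential, structure, tfId = sourceId(structure)) {
  pos <- structure@tfbsPositions
  if (!length(pos)) stop("structure has no effective TFBS")
  m <- matrix(NA_real_, 4L, length(pos),
              dimnames = list(DNA_BASES, as.character(pos)))
  for (j in seq_along(pos)) {
    for (b in DNA_BASES) {
      sub <- substituteBasePair(structure, pos[j], PAIR_TYPES[[b]])
      m[b, j] <- interactionEnergy(potential, sub, positions = pos[j])
    }
  }
  new("PEM", energies = m, tfId = tfId, nativeBases = tfbsSequence(structure))
}

#' Convert a PEM to a PWM by the Boltzmann formula
#'
#' Per position j, `p(i, j) = exp(-beta e_ij) / sum_k exp(-beta e_kj)`,
#' computed with max-subtraction for numerical stability. `beta` trades off
#' how sharply energy differences are converted into base preferences;
#' `beta = 0` yields the uniform matrix.
#'
#' @param pem a [PEM-class]
#' @param beta inverse-energy scale (default 0.05, per arbitrary energy unit)
#' @return a [PWM-class]
#' @export
pemToPwm <- function(pem, beta = 0.05) {
  if (beta < 0) stop("beta must be non-negative")
  e <- -beta * pem@energies
  e <- sweep(e, 2, apply(e, 2, max), "-")
  w <- exp(e)
  p <- sweep(w, 2, colSums(w), "/")
  new("PWM", probs = p)
}

#' Uniform reference PWM
#'
#' The flat reference with expected frequency 0.25 for each base at every
#' position.
#'
#' @param L motif length
#' @return a [PWM-class]
#' @export
evenPwm <- function(L) {
  if (!is.numeric(L) || L < 1) stop("L must be at least 1")
  new("PWM", probs = matrix(0.25, 4L, as.integer(L),
                            dimnames = list(DNA_BASES, NULL)))
}

#' Zero out non-lowest PEM energies
#'
#' Keeps, per position, only the minimum-energy entries (ties keep all tied
#' minima) and sets the rest to zero. Used to probe how much of the
#' prediction rests on the lowest-energy base pair alone versus the full
#' energy profile.
#'
#' @param pem a [PEM-class]
#' @return a [PEM-class]
#' @export
zeroReference <- function(pem) {
  m <- pem@energies
  for (j in seq_len(ncol(m))) {
    keep <- m[, j] <= min(m[, j]) + 1e-12
    m[!keep, j] <- 0
  }
  new("PEM", energies = m, tfId = paste0(pem@tfId, "_reference"),
      nativeBases = pem@nativeBases)
}

#' Randomize the template's binding-site sequence
#'
#' Substitutes every effective TFBS position by a base pair drawn uniformly
#' from the four types (fixed backbone). Used as the mutant-template
#' control: the resulting template memorizes a random sequence.
#'
#' @param structure a [ComplexStructure-class]
#' @param seed RNG seed
#' @return a [ComplexStructure-class]
#' @export
mutateTemplateSequence <- function(structure, seed = 1L) {
  pos <- structure@tfbsPositions
  if (!length(pos)) stop("structure has no effective TFBS")
  draws <- withSeed(seed, sample(DNA_BASES, length(pos), replace = TRUE))
  out <- structure
  for (j in seq_along(pos))
    out <- substituteBasePair(out, pos[j], PAIR_TYPES[[draws[j]]])
  out
}

#' Deterministic PWM of an exact motif
#'
#' The degenerate PWM assigning probability 1 to the motif base at every
#' position; useful as the planted-motif reference in benchmarks.
#'
#' @param sequence motif string (A/C/G/T)
#' @return a [PWM-class]
#' @export
pwmFromSequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(chars %in% DNA_BASES)) stop("motif must be A/C/G/T only")
  p <- matrix(0, 4L, length(chars), dimnames = list(DNA_BASES, NULL))
  p[cbind(match(chars, DNA_BASES), seq_along(chars))] <- 1
  new("PWM", probs = p)
}

#' PWM dissimilarity (psi test)
#'
#' Mean per-position total-variation distance between two equal-length PWMs:
#' `(1/L) * sum_j 0.5 * sum_i |a_ij - b_ij|`. Zero iff the matrices are
#' equal; symmetric; bounded by 1; smaller means more similar.
#'
#' @param pwmA,pwmB [PWM-class] objects of equal length
#' @return list with `value` and the `perPosition` contributions
#' @export
psiTest <- function(pwmA, pwmB) {
  a <- pwmA@probs; b <- pwmB@probs
  if (ncol(a) != ncol(b)) stop("PWMs differ in length (align/trim first)")
  per <- colSums(abs(a - b)) / 2
  list(value = mean(per), perPosition = unname(per))
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax base; ties are broken alphabetically and flagged.
#'
#' @param pwm a [PWM-class]
#' @return list with `consensus` (string) and logical `tie` per position
#' @export
pwmConsensus <- function(pwm) {
  p <- pwm@probs
  idx <- apply(p, 2, which.max)
  tie <- vapply(seq_len(ncol(p)),
                function(j) sum(p[, j] >= max(p[, j]) - 1e-12) > 1L, NA)
  list(consensus = paste(DNA_BASES[idx], collapse = ""), tie = tie)
}
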