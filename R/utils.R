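# internal helpers shared across modules

#' @importFrom methods new validObject is
#' @importFrom stats setNames
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# printed pair order keyed by the first-strand base A,C,G,T
PAIR_TYPES <- c(A = "A-T", C = "C-G", G = "G-C", T = "T-A")

complementBase <- function(b) chartr("ACGT", "TGCA", b)

# nucleotide naming dialects: DA/DC/DG/DT and bare A/C/G/T
normalizeBase <- function(resname) {
  up <- toupper(resname)
  out <- ifelse(up %in% c("DA", "A", "ADE"), "A",
         ifelse(up %in% c("DC", "C", "CYT"), "C",
         ifelse(up %in% c("DG", "G", "GUA"), "G",
         ifelse(up %in% c("DT", "T", "THY"), "T", NA_character_))))
  out
}

# canonical residue names used by the atom-typing scheme
BASE_RESNAME <- c(A = "ADE", C = "CYT", G = "GUA", T = "THY")

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

# heavy-atom element from a PDB atom label (C5', OP1, N9, CA, SD, ...)
atomElement <- function(name) {
  substr(gsub("[^A-Za-z]", "", toupper(name)), 1L, 1L)
}

isHydrogen <- function(name) atomElement(name) %in% c("H", "D")

BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                    "C3'", "O3'", "C2'", "C1'")

isBaseAtom <- function(name) !(name %in% BACKBONE_ATOMS)

# squared-distance free cross-distance matrix (n x m)
crossDist <- function(a, b) {
  # a, b: numeric matrices with columns x,y,z
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

atomCoords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
rotationMatrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

randomUnitVector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}
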