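# Reading/writing complexes, base-pair detection, the effective TFBS window,
# fixed-backbone base-pair substitution and rigid-body DNA perturbation.

# residue key used internally
.resKey <- function(chain, resid) paste(chain, resid, sep = ":")

#' Assemble a complex from an atom table
#'
#' Internal constructor shared by [readComplex()] and the synthetic
#' generators: validates the atom table, detects base pairs and the
#' effective TFBS window.
#'
#' @param atoms atom data.frame (see [ComplexStructure-class])
#' @param sourceId identifier
#' @param cutoff interface distance cutoff in Angstrom
#' @return a [ComplexStructure-class]
#' @keywords internal
newComplexStructure <- function(atoms, sourceId = "complex", cutoff = 10) {
  rownames(atoms) <- NULL
  obj <- new("ComplexStructure", atoms = atoms,
             basePairs = data.frame(), sourceId = sourceId)
  obj@basePairs <- detectBasePairs(obj)
  obj@tfbsPositions <- effectiveTfbs(obj, cutoff = cutoff)
  validObject(obj)
  obj
}

#' Read a protein/DNA complex from a PDB file
#'
#' Parses ATOM records (via bio3d), keeps heavy atoms of the first model
#' with alternate-location indicator blank or 'A', partitions chains into
#' protein and DNA, detects Watson-Crick base pairs, and determines the
#' effective binding-site window (base pairs with at least one atom within
#' `cutoff` of the protein).
#'
#' @param file path to a PDB file
#' @param proteinChains character vector of protein chain identifiers
#' @param dnaChains character vector of DNA chain identifiers
#' @param cutoff interface distance cutoff in Angstrom (default 10)
#' @param sourceId identifier; defaults to file name plus chain spec
#' @return a [ComplexStructure-class]
#' @examples
#' cx <- makeToyComplex(toySpec(sequence = "GCGTACGC"))
#' f <- tempfile(fileext = ".pdb")
#' writeComplex(cx, f)
#' cx2 <- readComplex(f, proteinChains = "A", dnaChains = c("C", "D"))
#' tfbsLength(cx2)
#' @export
readComplex <- function(file, proteinChains, dnaChains, cutoff = 10,
                        sourceId = NULL) {
  if (length(dnaChains) == 0L) stop("at least one DNA chain is required")
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  a <- a[!isHydrogen(a$elety), , drop = FALSE]
  have <- unique(a$chain)
  missing <- setdiff(c(proteinChains, dnaChains), have)
  if (length(missing))
    stop("chain(s) not present in file: ", paste(missing, collapse = ", "))
  a <- a[a$chain %in% c(proteinChains, dnaChains), , drop = FALSE]
  cls <- ifelse(a$chain %in% proteinChains, "protein", "dna")
  resname <- toupper(a$resid)
  # validate chain composition
  dnaRows <- cls == "dna"
  if (!any(dnaRows)) stop("no DNA atoms found in chains ",
                          paste(dnaChains, collapse = ","))
  badDna <- dnaRows & resname %in% AMINO3
  if (any(badDna))
    stop("DNA chain(s) contain amino-acid residues: ",
         paste(unique(a$chain[badDna]), collapse = ", "))
  isNuc <- !is.na(normalizeBase(resname))
  drop <- dnaRows & !isNuc
  keep <- !(drop)
  atoms <- data.frame(
    name = a$elety[keep], resname = resname[keep],
    resid = as.integer(a$resno[keep]), chain = a$chain[keep],
    x = a$x[keep], y = a$y[keep], z = a$z[keep],
    class = cls[keep], stringsAsFactors = FALSE)
  if (is.null(sourceId))
    sourceId <- paste0(basename(file), "_",
                       paste(proteinChains, collapse = ","))
  newComplexStructure(atoms, sourceId = sourceId, cutoff = cutoff)
}

#' Write a complex to a PDB file
#'
#' Emits fixed-width ATOM records (via bio3d). Round-tripping through
#' [readComplex()] preserves atom names, chains and coordinates to the PDB
#' precision of 1e-3 A.
#'
#' @param object a [ComplexStructure-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeComplex <- function(object, file) {
  a <- object@atoms
  xyz <- as.vector(t(atomCoords(a)))
  bio3d::write.pdb(file = file, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resid, resid = a$resname, chain = a$chain,
                   elety = a$name, o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(file)
}

# coordinates of one residue as a named matrix
.residueCoords <- function(atoms, chain, resid) {
  sel <- atoms$chain == chain & atoms$resid == resid
  m <- atomCoords(atoms[sel, , drop = FALSE])
  rownames(m) <- atoms$name[sel]
  m
}

#' Detect Watson-Crick base pairs in a duplex
#'
#' Pairs residues of the first DNA chain (5' to 3' in residue order) with
#' complementary residues of the other DNA chain(s) using identity plus
#' geometry: C1'-C1' distance within 10.4 +/- 1.5 A and the central
#' N1(purine)-N3(pyrimidine) hydrogen-bond distance below 3.5 A.
#' Unpairable residues are excluded with a warning.
#'
#' @param object a [ComplexStructure-class] (or an object under construction
#'   whose atoms are populated)
#' @return data.frame of pairs ordered along the first strand with columns
#'   `position`, `chain1`, `resid1`, `base1`, `chain2`, `resid2`, `base2`,
#'   `pairType`
#' @export
detectBasePairs <- function(object) {
  atoms <- object@atoms
  dna <- atoms[atoms$class == "dna", , drop = FALSE]
  chains <- unique(dna$chain)
  if (length(chains) < 2L)
    stop("base-pair detection requires two DNA strands")
  ch1 <- chains[1L]
  s1 <- dna[dna$chain == ch1, , drop = FALSE]
  s2 <- dna[dna$chain != ch1, , drop = FALSE]
  res1 <- unique(s1$resid)
  key2 <- unique(.resKey(s2$chain, s2$resid))
  # cache per-residue C1' and central N coordinates
  resInfo <- function(df) {
    keys <- .resKey(df$chain, df$resid)
    uk <- unique(keys)
    info <- lapply(uk, function(k) {
      sub <- df[keys == k, , drop = FALSE]
      base <- normalizeBase(sub$resname[1L])
      c1 <- sub[sub$name == "C1'", c("x", "y", "z")]
      cn <- if (!is.na(base) && base %in% c("A", "G")) "N1" else "N3"
      nn <- sub[sub$name == cn, c("x", "y", "z")]
      list(base = base, chain = sub$chain[1L], resid = sub$resid[1L],
           c1 = if (nrow(c1)) as.numeric(c1[1L, ]) else NULL,
           n = if (nrow(nn)) as.numeric(nn[1L, ]) else NULL)
    })
    names(info) <- uk
    info
  }
  i1 <- resInfo(s1)
  i2 <- resInfo(s2)
  used2 <- character(0)
  rows <- list()
  unpaired <- 0L
  for (k in .resKey(ch1, res1)) {
    a <- i1[[k]]
    if (is.na(a$base) || is.null(a$c1) || is.null(a$n)) { unpaired <- unpaired + 1L; next }
    best <- NULL; bestd <- Inf
    for (k2 in setdiff(key2, used2)) {
      b <- i2[[k2]]
      if (is.na(b$base) || is.null(b$c1) || is.null(b$n)) next
      if (b$base != complementBase(a$base)) next
      dc1 <- sqrt(sum((a$c1 - b$c1)^2))
      if (dc1 < 10.4 - 1.5 || dc1 > 10.4 + 1.5) next
      dn <- sqrt(sum((a$n - b$n)^2))
      if (dn >= 3.5) next
      if (dn < bestd) { bestd <- dn; best <- k2 }
    }
    if (is.null(best)) { unpaired <- unpaired + 1L; next }
    used2 <- c(used2, best)
    b <- i2[[best]]
    rows[[length(rows) + 1L]] <- data.frame(
      chain1 = a$chain, resid1 = a$resid, base1 = a$base,
      chain2 = b$chain, resid2 = b$resid, base2 = b$base,
      stringsAsFactors = FALSE)
  }
  unpaired <- unpaired + (length(key2) - length(used2))
  if (unpaired > 0L)
    warning(unpaired, " DNA residue(s) could not be paired and were excluded")
  if (length(rows) < 2L) stop("fewer than 2 base pairs detected")
  bp <- do.call(rbind, rows)
  bp$position <- seq_len(nrow(bp))
  bp$pairType <- paste(bp$base1, bp$base2, sep = "-")
  bp[, c("position", "chain1", "resid1", "base1",
         "chain2", "resid2", "base2", "pairType")]
}

#' Effective binding-site positions
#'
#' Base-pair positions whose minimal atom-to-protein distance is at most
#' `cutoff` (default 10 A); pairs farther away are excluded from the
#' effective TFBS and from the energy matrix.
#'
#' @param object a [ComplexStructure-class]
#' @param cutoff distance cutoff in Angstrom
#' @return sorted integer vector of positions
#' @export
effectiveTfbs <- function(object, cutoff = 10) {
  atoms <- object@atoms
  prot <- atoms[atoms$class == "protein", , drop = FALSE]
  bp <- object@basePairs
  if (!nrow(prot) || !nrow(bp)) stop("no interface: need protein atoms and base pairs")
  pm <- atomCoords(prot)
  keep <- integer(0)
  for (i in seq_len(nrow(bp))) {
    sel <- (atoms$chain == bp$chain1[i] & atoms$resid == bp$resid1[i]) |
           (atoms$chain == bp$chain2[i] & atoms$resid == bp$resid2[i])
    dm <- crossDist(atomCoords(atoms[sel, , drop = FALSE]), pm)
    if (min(dm) <= cutoff) keep <- c(keep, bp$position[i])
  }
  if (!length(keep)) stop("no interface: no base pair within ", cutoff, " A of the protein")
  sort(keep)
}

# replace the base atoms of one residue with the ideal base `newBase`,
# keeping all backbone/sugar atoms bit-identical
.substituteResidue <- function(atoms, chain, resid, newBase) {
  sel <- atoms$chain == chain & atoms$resid == resid
  res <- atoms[sel, , drop = FALSE]
  m <- atomCoords(res)
  rownames(m) <- res$name
  if (!("C1'" %in% res$name)) stop("residue lacks C1'; cannot substitute")
  if (!any(c("N9", "N1") %in% res$name))
    stop("residue lacks a glycosidic nitrogen; cannot substitute")
  fr <- glycosidicFrame(m)
  placed <- placeIdealBase(newBase, fr)
  keepIdx <- which(sel)[res$name %in% BACKBONE_ATOMS]
  newRows <- data.frame(
    name = rownames(placed),
    resname = paste0("D", newBase),
    resid = resid, chain = chain,
    x = placed[, 1L], y = placed[, 2L], z = placed[, 3L],
    class = "dna", stringsAsFactors = FALSE)
  # rebuild the table: everything before the residue, its backbone, the new
  # base atoms, everything after - other residues untouched
  first <- min(which(sel))
  before <- atoms[seq_len(nrow(atoms)) < first & !sel, , drop = FALSE]
  after <- atoms[seq_len(nrow(atoms)) > first & !sel, , drop = FALSE]
  backbone <- atoms[keepIdx, , drop = FALSE]
  backbone$resname <- paste0("D", newBase)
  out <- rbind(before, backbone, newRows, after)
  rownames(out) <- NULL
  out
}

#' Substitute one base pair on a fixed backbone
#'
#' Replaces the base atoms of both strands at one interface position with
#' idealized base geometries placed via the residue's base reference frame
#' (origin at C1', x toward the glycosidic nitrogen, z along the base-plane
#' normal). Backbone and sugar atoms are bit-identical to the input; no atom
#' outside the substituted pair moves.
#'
#' @param object a [ComplexStructure-class]
#' @param position an interface (TFBS) base-pair position
#' @param pairType one of `"A-T"`, `"C-G"`, `"G-C"`, `"T-A"`
#' @return a new [ComplexStructure-class] with the pair replaced
#' @export
substituteBasePair <- function(object, position, pairType) {
  pairType <- match.arg(pairType, unname(PAIR_TYPES))
  if (!(position %in% object@tfbsPositions))
    stop("position ", position, " is not within the effective TFBS")
  bp <- object@basePairs
  i <- match(position, bp$position)
  b1 <- substr(pairType, 1L, 1L)
  b2 <- substr(pairType, 3L, 3L)
  atoms <- .substituteResidue(object@atoms, bp$chain1[i], bp$resid1[i], b1)
  atoms <- .substituteResidue(atoms, bp$chain2[i], bp$resid2[i], b2)
  bp$base1[i] <- b1
  bp$base2[i] <- b2
  bp$pairType[i] <- pairType
  out <- object
  out@atoms <- atoms
  out@basePairs <- bp
  validObject(out)
  out
}

#' Root mean square deviation between matched coordinate sets
#'
#' Plain RMSD over matched atoms, with no re-superposition (perturbations
#' are absolute displacements).
#'
#' @param a,b numeric matrices of matched coordinates (n x 3)
#' @return RMSD in Angstrom
#' @export
computeRmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Rigid-body DNA perturbation into an RMSD group
#'
#' Applies one random rigid rotation plus translation to all DNA atoms
#' (protein untouched) such that the RMSD of the DNA to its original
#' coordinates falls in the half-open interval (n-1, n] for group `n`.
#' The perturbation direction is drawn once from the seeded generator and
#' its magnitude is scaled by bisection until the interval is hit.
#'
#' @param object a [ComplexStructure-class]
#' @param groupN RMSD group, integer 1..4
#' @param seed RNG seed controlling the perturbation direction
#' @param maxAttempts maximum bisection steps before giving up
#' @param cutoff interface cutoff used to refresh the effective TFBS
#' @return perturbed [ComplexStructure-class]
#' @export
perturbDna <- function(object, groupN, seed = 1L, maxAttempts = 60L,
                       cutoff = 10) {
  if (!(groupN %in% 1:4)) stop("groupN must be in 1..4")
  atoms <- object@atoms
  isD <- atoms$class == "dna"
  dm <- atomCoords(atoms[isD, , drop = FALSE])
  ctr <- colMeans(dm)
  dir <- withSeed(seed, list(axis = randomUnitVector(),
                             trans = randomUnitVector()))
  apply_m <- function(m) {
    R <- rotationMatrix(dir$axis, m * 0.08)       # radians per unit magnitude
    tv <- dir$trans * (m * 0.35)                  # Angstrom per unit magnitude
    sweep(sweep(dm, 2, ctr, "-") %*% t(R), 2, ctr + tv, "+")
  }
  target <- c(groupN - 1, groupN)
  lo <- 0; hi <- 1
  r <- computeRmsd(dm, apply_m(hi))
  att <- 0L
  while (r <= target[1] && att < maxAttempts) { hi <- hi * 2; r <- computeRmsd(dm, apply_m(hi)); att <- att + 1L }
  if (r <= target[1]) stop("perturbation magnitude search exhausted maxAttempts")
  best <- NULL
  while (att < maxAttempts) {
    mid <- (lo + hi) / 2
    r <- computeRmsd(dm, apply_m(mid))
    if (r > target[1] && r <= target[2]) { best <- mid; break }
    if (r > target[2]) hi <- mid else lo <- mid
    att <- att + 1L
  }
  if (is.null(best)) stop("perturbation magnitude search exhausted maxAttempts")
  newd <- apply_m(best)
  atoms$x[isD] <- newd[, 1L]
  atoms$y[isD] <- newd[, 2L]
  atoms$z[isD] <- newd[, 3L]
  out <- object
  out@atoms <- atoms
  # pairing is rigid-invariant, but the interface window can change
  out@tfbsPositions <- effectiveTfbs(out, cutoff = cutoff)
  validObject(out)
  out
}
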