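# Shared fixtures, computed once per test run.

.fx <- new.env(parent = emptyenv())

fixtureToy <- function() {
  if (is.null(.fx$toy)) .fx$toy <- makeToyComplex(toySpec())
  .fx$toy
}

fixturePotential <- function() {
  if (is.null(.fx$pot)) .fx$pot <- trainTfire(fixtureToy())
  .fx$pot
}

fixturePem <- function() {
  if (is.null(.fx$pem)) .fx$pem <- buildPem(fixturePotential(), fixtureToy())
  .fx$pem
}

fixturePromoters <- function() {
  if (is.null(.fx$prom))
    .fx$prom <- makePromoters(promoterSpec(seed = 11L),
                              paste(tfbsSequence(fixtureToy()), collapse = ""))
  .fx$prom
}

# a bare DNA-only ComplexStructure (no interface bookkeeping)
dnaOnlyComplex <- function(sequence) {
  methods::new("ComplexStructure", atoms = makeBDna(sequence),
               basePairs = data.frame(), sourceId = sequence)
}

# minimal hand-built structure for histogram tests: one GLY CA probe plus
# explicit DNA atoms (no base-pair detection involved)
pointStructure <- function(dnaAtoms, probe = c(0, 0, 0)) {
  atoms <- rbind(
    data.frame(name = "CA", resname = "GLY", resid = 1L, chain = "A",
               x = probe[1], y = probe[2], z = probe[3], class = "protein",
               stringsAsFactors = FALSE),
    dnaAtoms)
  methods::new("ComplexStructure", atoms = atoms, basePairs = data.frame(),
               sourceId = "point")
}

dnaAtomRow <- function(name, resname, xyz, resid = 1L, chain = "C") {
  data.frame(name = name, resname = resname, resid = resid, chain = chain,
             x = xyz[1], y = xyz[2], z = xyz[3], class = "dna",
             stringsAsFactors = FALSE)
}

# independent brute-force interaction energy: double loop with direct table
# lookup (kept deliberately naive; the implementation is vectorized)
bruteForceEnergy <- function(potential, structure, positions) {
  cfg <- potential@config
  bp <- basePairs(structure)
  a <- atoms(structure)
  i <- match(positions, bp$position)
  resKeys <- c(paste(bp$chain1[i], bp$resid1[i]),
               paste(bp$chain2[i], bp$resid2[i]))
  dna <- a[a$class == "dna" & paste(a$chain, a$resid) %in% resKeys &
             !(a$name %in% c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                             "C3'", "O3'", "C2'", "C1'")), , drop = FALSE]
  prot <- a[a$class == "protein", , drop = FALSE]
  nb <- as.integer(round(cfg@rCut / cfg@deltaR))
  total <- 0
  for (p in seq_len(nrow(prot))) {
    for (d in seq_len(nrow(dna))) {
      r <- sqrt((prot$x[p] - dna$x[d])^2 + (prot$y[p] - dna$y[d])^2 +
                  (prot$z[p] - dna$z[d])^2)
      if (r >= cfg@rCut) next
      bin <- min(floor(r / cfg@deltaR) + 1, nb)
      key <- paste(assignAtomType(prot$resname[p], prot$name[p]),
                   assignAtomType(dna$resname[d], dna$name[d]), sep = "||")
      vec <- potential@energies[[key]]
      if (is.null(vec)) vec <- potential@nullEnergy
      total <- total + vec[bin]
    }
  }
  total
}

randomPwm <- function(L) {
  m <- matrix(stats::runif(4 * L), 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  methods::new("PWM", probs = sweep(m, 2, colSums(m), "/"))
}
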