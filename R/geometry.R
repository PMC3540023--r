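# Idealized heavy-atom base geometries and Watson-Crick pair templates.
#
# Bases are built as planar rings (regular hexagon, side 1.39 A; fused
# regular pentagon for purines) with exocyclic substituents on the radial
# directions (C=O 1.23 A, C-N 1.34 A, C-CH3 1.50 A, N-C1' 1.47 A).  Pairs
# are assembled so that the central N1(purine)...N3(pyrimidine) hydrogen
# bond is 2.9 A and the C6/C4-substituent hydrogen-bond rails run parallel
# to it, which reproduces the canonical pair metrics (C1'-C1' ~ 10.4-11.2 A,
# both glycosidic bonds on the minor-groove side).  The table is internal
# and self-consistent: the synthetic B-DNA generator and the base-pair
# substitution operator draw from the same coordinates.

HEX_SIDE <- 1.39

.ring6 <- function() {
  ang <- c(90, 30, -30, -90, -150, 150) * pi / 180
  m <- cbind(HEX_SIDE * cos(ang), HEX_SIDE * sin(ang))
  rownames(m) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  m
}

.addExo <- function(m, at, name, len) {
  v <- m[at, ]
  u <- v / sqrt(sum(v^2))  # radial: ring is centered at the origin
  rbind(m, matrix(v + u * len, 1, 2, dimnames = list(name, NULL)))
}

.pyrimidine2d <- function(base) {
  m <- .ring6()
  m <- .addExo(m, "C2", "O2", 1.23)
  if (base == "T") {
    m <- .addExo(m, "C4", "O4", 1.23)
    m <- .addExo(m, "C5", "C7", 1.50)
  } else {
    m <- .addExo(m, "C4", "N4", 1.34)
  }
  .addExo(m, "N1", "C1'", 1.47)
}

.purine2d <- function(base) {
  m <- .ring6()
  C4 <- m["C4", ]; C5 <- m["C5", ]
  mid <- (C4 + C5) / 2
  outd <- mid / sqrt(sum(mid^2))
  apo <- HEX_SIDE / (2 * tan(36 * pi / 180))
  P <- mid + outd * apo  # pentagon center, outside the hexagon
  rotP <- function(p, th) {
    d <- p - P
    P + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
  }
  # step direction chosen so the pentagon lies away from the hexagon center
  sgn <- if (sum(rotP(C4, 72 * pi / 180)^2) > sum(rotP(C4, -72 * pi / 180)^2)) 1 else -1
  m <- rbind(m,
             N7 = rotP(C5, -sgn * 72 * pi / 180),
             C8 = rotP(C4, sgn * 144 * pi / 180),
             N9 = rotP(C4, sgn * 72 * pi / 180))
  if (base == "A") {
    m <- .addExo(m, "C6", "N6", 1.34)
  } else {
    m <- .addExo(m, "C6", "O6", 1.23)
    m <- .addExo(m, "C2", "N2", 1.34)
  }
  v <- m["N9", ] - P
  u <- v / sqrt(sum(v^2))
  rbind(m, matrix(m["N9", ] + u * 1.47, 1, 2, dimnames = list("C1'", NULL)))
}

.rot2 <- function(m, th) {
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t(R %*% t(m))
}

.angTo <- function(v, target) atan2(target[2], target[1]) - atan2(v[2], v[1])

# purine-first Watson-Crick pair in 2D: purine glycosidic anchor N1 at the
# origin, pyrimidine N3 at (2.9, 0), hydrogen-bond rails parallel to x.
.assemblePair2d <- function(puBase, pyBase) {
  hb <- 2.9
  pu <- .purine2d(puBase)
  py <- .pyrimidine2d(pyBase)
  # one shared spin per ring system (computed from A and T) keeps the ring
  # cores, C1' anchors and backbone sequence-independent
  pa <- .purine2d("A")
  th1 <- .angTo(pa["N6", ] - pa["N1", ], c(0, 1))
  pt <- .pyrimidine2d("T")
  th2 <- .angTo(pt["O4", ] - pt["N3", ], c(0, 1))
  m1 <- .rot2(pu, th1); m1 <- sweep(m1, 2, m1["N1", ], "-")
  m2 <- .rot2(py, th2); m2 <- sweep(m2, 2, m2["N3", ] - c(hb, 0), "-")
  list(pu = m1, py = m2)
}

.to3d <- function(m) {
  out <- cbind(m, 0)
  colnames(out) <- c("x", "y", "z")
  out
}

# 180-degree rotation about the in-plane axis perpendicular to the C1'-C1'
# segment through its midpoint: swaps the two strand slots exactly.
.dyadFlip <- function(template) {
  c1a <- template$b1["C1'", ]
  c1b <- template$b2["C1'", ]
  m <- (c1a + c1b) / 2
  u <- (c1b - c1a); u <- u / sqrt(sum(u^2))
  # in-plane perpendicular to u (z = 0 plane)
  d <- c(-u[2], u[1], 0); d <- d / sqrt(sum(d^2))
  R <- 2 * tcrossprod(d) - diag(3)
  f <- function(p) sweep(t(R %*% t(sweep(p, 2, m, "-"))), 2, m, "+")
  list(b1 = f(template$b2), b2 = f(template$b1))
}

.geomCache <- new.env(parent = emptyenv())

# pair template for a first-strand base: list(b1, b2) of 3D atom matrices
# (base atoms + C1'), b1 on strand 1.  Strand-1 C1' is identical across the
# four templates so a helix built from them has a sequence-independent
# backbone.
pairTemplate <- function(base1) {
  key <- paste0("tmpl_", base1)
  if (!is.null(.geomCache[[key]])) return(.geomCache[[key]])
  if (base1 %in% c("A", "G")) {
    p <- .assemblePair2d(base1, complementBase(base1))
    tmpl <- list(b1 = .to3d(p$pu), b2 = .to3d(p$py))
  } else {
    pu <- complementBase(base1)
    p <- .assemblePair2d(pu, base1)
    tmpl <- .dyadFlip(list(b1 = .to3d(p$pu), b2 = .to3d(p$py)))
  }
  .geomCache[[key]] <- tmpl
  tmpl
}

glycosidicNitrogen <- function(base) if (base %in% c("A", "G")) "N9" else "N1"

ringAtomNames <- function(base) {
  if (base %in% c("A", "G"))
    c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  else
    c("N1", "C2", "N3", "C4", "C5", "C6")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Base reference frame of a residue: origin at C1', x from C1' toward the
# glycosidic nitrogen, z the base-plane normal with a fixed sign convention
# (cross product of the two ring bonds at the glycosidic nitrogen in a fixed
# order), y = z cross x.  The ideal base tables are extracted with the same
# convention, so a base expressed in this frame always extends toward the
# partner strand regardless of which ring system occupied the slot before.
glycosidicFrame <- function(coords) {
  # coords: named matrix of atom coordinates for one residue
  nms <- rownames(coords)
  if (!("C1'" %in% nms)) stop("residue lacks a C1' atom")
  purine <- "N9" %in% nms
  gn <- if (purine) "N9" else "N1"
  if (!(gn %in% nms)) stop("residue lacks a glycosidic nitrogen (N9/N1)")
  nb <- if (purine) c("C4", "C8") else c("C2", "C6")
  if (!all(nb %in% nms)) stop("residue lacks ring atoms for frame computation")
  o <- coords["C1'", ]
  x <- coords[gn, ] - o
  x <- x / sqrt(sum(x^2))
  v1 <- coords[nb[1L], ] - coords[gn, ]
  v2 <- coords[nb[2L], ] - coords[gn, ]
  z0 <- .cross3(v1, v2)
  z0 <- z0 - sum(z0 * x) * x
  nz <- sqrt(sum(z0^2))
  if (nz < 1e-6) stop("degenerate base geometry: cannot orient frame")
  z <- z0 / nz
  y <- .cross3(z, x)
  list(origin = o, R = cbind(x, y, z))
}

# Ideal base-atom coordinates (glycosidic N, ring, exocyclic; no C1') of a
# base expressed in its own glycosidic frame.
idealBaseLocal <- function(base) {
  key <- paste0("local_", base)
  if (!is.null(.geomCache[[key]])) return(.geomCache[[key]])
  tmpl <- pairTemplate(base)
  m <- tmpl$b1
  fr <- glycosidicFrame(m)
  keep <- setdiff(rownames(m), "C1'")
  loc <- sweep(m[keep, , drop = FALSE], 2, fr$origin, "-") %*% fr$R
  colnames(loc) <- c("x", "y", "z")
  .geomCache[[key]] <- loc
  loc
}

# place the ideal base atoms of `base` into a residue frame
placeIdealBase <- function(base, frame) {
  loc <- idealBaseLocal(base)
  out <- sweep(loc %*% t(frame$R), 2, frame$origin, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

# Schematic sugar/phosphate offsets in the glycosidic frame.  These are not
# chemically refined; they provide a fixed, distinct, PDB-serializable
# backbone that substitution never touches.
BACKBONE_LOCAL <- local({
  m <- rbind(
    "O4'" = c(-0.70,  1.10,  0.75),
    "C2'" = c(-0.85, -0.95,  0.60),
    "C3'" = c(-2.15, -0.80,  1.15),
    "O3'" = c(-2.85, -1.95,  1.55),
    "C4'" = c(-2.60,  0.55,  1.30),
    "C5'" = c(-3.85,  0.75,  0.50),
    "O5'" = c(-4.60, -0.45,  0.25),
    "P"   = c(-5.90, -0.35, -0.55),
    "OP1" = c(-6.75,  0.75, -0.20),
    "OP2" = c(-6.40, -1.65, -0.10)
  )
  colnames(m) <- c("x", "y", "z")
  m
})
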