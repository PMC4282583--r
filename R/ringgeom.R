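# Endocyclic torsion extraction, Westhof-Sundaralingam pseudorotation analysis,
# endo/exo classification, ideal-ring generation, rigid superposition and
# jump-angle determination for five-membered (pyrrolidine) rings.
#
# Ring atoms are kept in the fixed order N, CA, CB, CG, CD.  The five
# endocyclic torsions are labelled chi1..chi5 with chi2 spanning
# CA-CB-CG-CD (the torsion about the CB-CG bond); chi_j is the torsion about
# the bond between ring atoms j+1 and j+2 (cyclic).  All angles are degrees,
# wrapped to (-180, 180].

RING_LABELS <- c("N", "CA", "CB", "CG", "CD")

#' Wrap angles to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360)   # [0, 360)
  ifelse(w > 180, w - 360, w)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Construct a ring-atom set
#'
#' Bundles the five ring atoms of a pyrrolidine (proline/hydroxyproline) ring
#' in the fixed order N, CA, CB, CG, CD, plus any extra named atoms (protons,
#' carbonyl carbons) needed for jump-angle or coupling geometry.
#'
#' @param coords 5 x 3 numeric matrix of ring-atom positions (Angstrom), rows
#'   in the order N, CA, CB, CG, CD.
#' @param extra optional named list of additional 3-vectors keyed by atom name
#'   (e.g. `HG2`, `HG3`, `C`).
#' @param check if `TRUE`, consecutive ring-atom distances are required to lie
#'   in (1.2, 1.8) Angstrom, the plausible range for real covalent ring bonds.
#' @return object of class `ring_atoms`.
#' @export
ring_atoms <- function(coords, extra = list(), check = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(is.numeric(coords), nrow(coords) == 5, ncol(coords) == 3,
            all(is.finite(coords)))
  rownames(coords) <- RING_LABELS
  if (check) {
    d <- sqrt(rowSums((coords - coords[c(2:5, 1), , drop = FALSE])^2))
    if (any(d <= 1.2 | d >= 1.8))
      stop("consecutive ring-atom distances outside (1.2, 1.8) Angstrom; ",
           "use check = FALSE for idealised fixtures")
  }
  structure(list(coords = coords, extra = extra), class = "ring_atoms")
}

#' Dihedral angle of four points
#'
#' IUPAC-signed dihedral (degrees) for points p1-p2-p3-p4: the angle between
#' the p1-p2-p3 and p2-p3-p4 planes, positive for a clockwise rotation of
#' p4 relative to p1 when viewed down the p2->p3 bond.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return dihedral in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("collinear atom triple: dihedral undefined (degenerate geometry)")
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  wrap_angle(rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

#' Endocyclic torsions of a five-membered ring
#'
#' Returns the five ring torsions chi1..chi5 in the proline labelling where
#' chi2 spans CA-CB-CG-CD.  chi_j is the dihedral about the bond between
#' ring atoms (j+1, j+2) counted cyclically from N.
#'
#' @param ring a `ring_atoms` object (or bare 5 x 3 coordinate matrix in ring
#'   order N, CA, CB, CG, CD).
#' @return named numeric vector `chi1..chi5` (degrees), class `ring_torsions`.
#' @export
endocyclic_torsions <- function(ring) {
  xyz <- if (inherits(ring, "ring_atoms")) ring$coords else as.matrix(ring)
  stopifnot(nrow(xyz) == 5, ncol(xyz) == 3, all(is.finite(xyz)))
  # chi_j = dihedral(j, j+1, j+2, j+3) with atom indices 1..5 cyclic;
  # chi2 = CA-CB-CG-CD corresponds to starting index 2.
  chi <- vapply(1:5, function(j) {
    i <- ((j - 1 + 0:3) %% 5) + 1
    dihedral(xyz[i[1], ], xyz[i[2], ], xyz[i[3], ], xyz[i[4], ])
  }, numeric(1))
  ring_torsions(chi)
}

#' Ring-torsion container
#'
#' @param chi numeric length-5 vector of torsions chi1..chi5 in degrees.
#' @return classed named vector, angles wrapped to (-180, 180].
#' @export
ring_torsions <- function(chi) {
  stopifnot(length(chi) == 5, all(is.finite(chi)))
  structure(stats::setNames(wrap_angle(as.numeric(chi)),
                            paste0("chi", 1:5)),
            class = "ring_torsions")
}

#' @export
print.ring_torsions <- function(x, ...) {
  cat("Endocyclic torsions (deg):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Ideal ring torsions from pseudorotation coordinates
#'
#' Inverse of [pseudorotation()]: the cosine model
#' chi_j = chi_m * cos(P + 144 (j - 2) degrees).
#'
#' @param P pseudorotation phase, degrees.
#' @param chi_m pseudorotation amplitude, degrees (>= 0).
#' @return `ring_torsions` object.
#' @export
ideal_ring_torsions <- function(P, chi_m) {
  stopifnot(chi_m >= 0)
  j <- 1:5
  ring_torsions(chi_m * cos(deg2rad(P + 144 * (j - 2))))
}

#' Pseudorotation phase and amplitude (Westhof-Sundaralingam)
#'
#' Computes the pseudorotation phase P and amplitude chi_m of a five-membered
#' ring from its endocyclic torsions using the Westhof-Sundaralingam relation
#' `tan P = ((chi4 + chi1) - (chi3 + chi5)) / (2 chi2 (sin 36 + sin 72))`
#' with chi2 as the zero-phase torsion, adding 180 degrees when chi2 < 0.
#' The amplitude is the maximum torsion attained by the cosine model
#' chi_j = chi_m cos(P + 144 (j - 2)).
#'
#' @param t a `ring_torsions` object (or length-5 numeric vector chi1..chi5).
#' @return object of class `pucker_state`: list with `P` (degrees in
#'   \[0, 360)), `chi_m` (degrees, >= 0) and `label` ("endo" or "exo").
#' @export
pseudorotation <- function(t) {
  chi <- as.numeric(t)
  stopifnot(length(chi) == 5)
  if (all(abs(chi) < 1e-12))
    stop("planar ring (all torsions zero): pseudorotation phase undefined")
  s36 <- sin(deg2rad(36)); s72 <- sin(deg2rad(72))
  a <- chi[2]                                      # chi_m cos P
  b <- ((chi[4] + chi[1]) - (chi[3] + chi[5])) / (2 * (s36 + s72))  # chi_m sin P
  # atan2 realises the printed rule "add 180 deg if chi2 < 0" while staying
  # defined at chi2 = 0; chi_m = chi2 / cos P evaluated in the stable form.
  P <- rad2deg(atan2(b, a)) %% 360
  chi_m <- sqrt(a^2 + b^2)
  structure(list(P = P, chi_m = chi_m, label = classify_pucker(P)),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  cat(sprintf("Pucker: P = %.3f deg, chi_m = %.3f deg (%s)\n",
              x$P, x$chi_m, x$label))
  invisible(x)
}

#' Classify a pucker phase as endo or exo
#'
#' Cgamma-exo conformers have P in (-90, 90) mod 360 (P_exo ~ 11-14 deg),
#' Cgamma-endo conformers have P around 180 (P_endo ~ 178-185 deg).  The
#' boundary is half-open: P = +90 classifies as endo, P = 270 (= -90) as exo.
#'
#' @param p a `pucker_state` object or numeric phase in degrees.
#' @return `"endo"` or `"exo"`.
#' @export
classify_pucker <- function(p) {
  P <- if (inherits(p, "pucker_state")) p$P else as.numeric(p)
  P <- P %% 360
  ifelse(P >= 90 & P < 270, "endo", "exo")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `mobile` onto `reference`
#' in the least-squares sense, with the determinant of the rotation
#' constrained to +1 (chirality is never inverted).
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows.
#' @param indices optional row indices (e.g. the four C-N-CA-C frame atoms)
#'   over which the fit is performed; the returned transform still applies to
#'   any coordinates.  Default: all rows.
#' @return object of class `rigid_transform`: list with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom, over the fitted atoms).
#'   Apply with [apply_transform()].
#' @export
superpose_fragment <- function(mobile, reference, indices = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(indices)) indices <- seq_len(nrow(mobile))
  A <- mobile[indices, , drop = FALSE]
  B <- reference[indices, , drop = FALSE]
  if (nrow(A) < 3) stop("need at least 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2)
    stop("degenerate (collinear) point set: superposition undefined")
  H <- crossprod(A0, B0)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)      # proper rotation: B0 ~ A0 %*% t(R)
  tr <- cb - as.numeric(R %*% ca)
  fitted <- sweep(A %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform` from [superpose_fragment()].
#' @param coords n x 3 matrix (or 3-vector).
#' @return transformed coordinates, same shape as input.
#' @export
apply_transform <- function(transform, coords) {
  v <- is.null(dim(coords))
  m <- if (v) matrix(coords, 1, 3) else as.matrix(coords)
  out <- sweep(m %*% t(transform$rotation), 2, transform$translation, "+")
  if (v) as.numeric(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: rmsd = %.4g Angstrom\n", x$rmsd))
  invisible(x)
}

#' Jump angle between C-H bond directions of two conformers
#'
#' Superposes conformer B onto conformer A on a rigid fragment (by default the
#' C-N-CA-C backbone fragment, the most rigid part of a proline ring in a
#' peptide) and returns the angle swept by the C-H bond direction between the
#' two conformations, in \[0, 180\] degrees.  For the two-site jump model this
#' is the jump angle Delta-theta entering the order parameter
#' S^2 = 1 - 3 x (1 - x) sin^2(Delta-theta).
#'
#' @param conf_a,conf_b n x 3 coordinate matrices with paired rows (identical
#'   atom ordering).
#' @param bond integer length-2: row indices of the C and H atoms of the bond.
#' @param frame integer indices of the (>= 3) frame atoms used for the
#'   superposition.
#' @return jump angle in degrees.
#' @export
jump_angle <- function(conf_a, conf_b, bond, frame) {
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  stopifnot(length(bond) == 2)
  tf <- superpose_fragment(conf_b, conf_a, indices = frame)
  b_in_a <- apply_transform(tf, conf_b)
  va <- conf_a[bond[2], ] - conf_a[bond[1], ]
  vb <- b_in_a[bond[2], ] - b_in_a[bond[1], ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length bond vector")
  cosang <- sum(va * vb) / (na * nb)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Cartesian builder for an idealised puckered ring
#'
#' Builds five ring-atom positions whose endocyclic torsions approximate the
#' cosine pseudorotation model at (P, chi_m), with all ring bonds near 1.53
#' Angstrom.  Ring closure is enforced by penalised quasi-Newton refinement of
#' the coordinates; the builder is a geometric fixture (for round-trip tests
#' and proton-placement oracles), not a molecular-mechanics minimiser.
#'
#' @param P pseudorotation phase, degrees.
#' @param chi_m pseudorotation amplitude, degrees.
#' @param bond target ring bond length, Angstrom.
#' @return `ring_atoms` object (check disabled if refinement leaves residual
#'   bond strain; in practice bonds close to < 0.01 Angstrom).
#' @export
ideal_ring_coords <- function(P, chi_m, bond = 1.53) {
  target <- as.numeric(ideal_ring_torsions(P, chi_m))
  # start: planar regular pentagon + out-of-plane displacement following the
  # pucker wave, which has the right sign pattern for small amplitudes
  r0 <- bond / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  z0 <- 0.012 * chi_m * cos(deg2rad(P) + 4 * pi * ((1:5) - 1) / 5)
  x0 <- cbind(r0 * cos(ang), r0 * sin(ang), z0)
  obj <- function(par) {
    xyz <- matrix(par, 5, 3)
    d <- sqrt(rowSums((xyz - xyz[c(2:5, 1), , drop = FALSE])^2))
    chi <- tryCatch(as.numeric(endocyclic_torsions(xyz)),
                    error = function(e) rep(1e3, 5))
    dchi <- wrap_angle(chi - target)
    sum(dchi^2) + 4e4 * sum((d - bond)^2)
  }
  fit <- stats::optim(as.numeric(x0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  ring_atoms(matrix(fit$par, 5, 3), check = FALSE)
}

#' Add idealised protons to ring carbons
#'
#' Places one or two protons on a ring atom using tetrahedral geometry: proton
#' directions lie in the plane bisecting the two ring-bond directions,
#' perpendicular to the ring-neighbour plane.
#'
#' @param ring a `ring_atoms` object.
#' @param r_ch C-H bond length, Angstrom.
#' @return `ring_atoms` with `extra` populated with `HA`, `HB2`, `HB3`,
#'   `HG2`, `HG3`, `HD2`, `HD3` positions.  The "2"-proton is on the +normal
#'   side of the local neighbour plane (cross product of the bonds to the
#'   previous and next ring atom), the "3"-proton on the -normal side.
#' @export
add_ring_protons <- function(ring, r_ch = 1.09) {
  xyz <- ring$coords
  half <- deg2rad(109.47 / 2)
  place <- function(i) {
    ip <- ((i - 2) %% 5) + 1; im <- (i %% 5) + 1
    a <- xyz[ip, ] - xyz[i, ]; b <- xyz[im, ] - xyz[i, ]
    a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
    e1 <- -(a + b); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    e2 <- e2 / sqrt(sum(e2^2))
    list(plus  = xyz[i, ] + r_ch * (cos(half) * e1 + sin(half) * e2),
         minus = xyz[i, ] + r_ch * (cos(half) * e1 - sin(half) * e2))
  }
  ex <- ring$extra
  ha <- place(2); ex$HA <- ha$plus        # CA carries a single proton
  hb <- place(3); ex$HB2 <- hb$plus; ex$HB3 <- hb$minus
  hg <- place(4); ex$HG2 <- hg$plus; ex$HG3 <- hg$minus
  hd <- place(5); ex$HD2 <- hd$plus; ex$HD3 <- hd$minus
  ring_atoms(xyz, extra = ex, check = FALSE)
}

#' Read proline ring atoms from a PDB file
#'
#' Extracts the five ring atoms (N, CA, CB, CG, CD) of one residue from a PDB
#' file by atom name.  Only the first model is used and alternate locations
#' are ignored (first kept).  Requires the `bio3d` package.
#'
#' @param file path to a PDB file.
#' @param resno residue number to extract.
#' @param chain optional chain identifier.
#' @param extra extra atom names to carry along (e.g. `c("HG2","HG3","C")`).
#' @return `ring_atoms` object.
#' @export
read_ring_atoms <- function(file, resno, chain = NULL,
                            extra = c("HG2", "HG3", "C")) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_ring_atoms() requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(file, multi = FALSE)
  at <- pdb$atom
  sel <- at$resno == resno
  if (!is.null(chain)) sel <- sel & at$chain == chain
  at <- at[sel, , drop = FALSE]
  at <- at[!duplicated(at$elety), , drop = FALSE]   # drop altlocs
  get1 <- function(name) {
    row <- at[at$elety == name, , drop = FALSE]
    if (nrow(row) == 0) stop("atom ", name, " not found in residue ", resno)
    as.numeric(row[1, c("x", "y", "z")])
  }
  coords <- t(vapply(RING_LABELS, get1, numeric(3)))
  ex <- list()
  for (nm in extra)
    ex[[nm]] <- tryCatch(get1(nm), error = function(e) NULL)
  ex <- ex[!vapply(ex, is.null, logical(1))]
  ring_atoms(coords, extra = ex)
}
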