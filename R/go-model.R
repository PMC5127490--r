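# Structure-based C-alpha Go model builder.
#
# Reduced units: the native-contact well depth epsilon sets the energy scale
# (epsilon = 1), lengths are nm, masses 1, k_B = 1.  SMOG-style bonded
# constants: k_bond = 2e4 eps/nm^2, k_angle = 40 eps/rad^2, dihedral
# K [(1 - cos(phi - phi0)) + 1/2 (1 - cos 3(phi - phi0))] with K = 1 eps.

#' Build a C-alpha Go model from a native structure
#'
#' Bond lengths, angles and dihedrals are taken from the native geometry so
#' the model is built at its minimum.  Native pairs attract through a 10-12
#' potential with minimum at the native C-alpha separation:
#' \deqn{U(r) = \epsilon_{ij} [5 (r_0/r)^{12} - 6 (r_0/r)^{10}]}
#' Pair strengths are uniform unless a heavy-atom reference structure is
#' given, in which case \eqn{\epsilon_{ij}} is proportional to the number of
#' heavy-atom contacts the residue pair forms (heterogeneous interactions,
#' normalized to mean 1).  All other bead pairs repel with
#' \eqn{\epsilon_{nc} (\sigma_{NC}/r)^{12}}, \eqn{\sigma_{NC} = 0.4} nm.
#'
#' @param structure a C-alpha [Structure-class].
#' @param heavyReference optional heavy-atom [Structure-class] for
#'   heterogeneous pair strengths.
#' @param contactMap optional [NativeContactMap-class]; built from
#'   `structure` with `cdef` when missing.
#' @param heavyCdef contact definition applied to `heavyReference` for the
#'   heavy-atom-count weighting.
#' @param cdef contact definition for the model's pair list.  The default
#'   uses sequence separation >= 3 (the force-field convention, as opposed
#'   to the >= 4 analysis convention) and a 0.8 nm C-alpha cutoff, the
#'   usual C-alpha-distance proxy for residue pairs with heavy atoms within
#'   0.6 nm; the wider 1.2 nm cutoff of the analysis contact definition
#'   would give an unphysically dense pair network.
#' @param kBond,kAngle,kDihedral bonded force constants (reduced units).
#' @param sigmaNC,epsNC excluded-volume diameter (nm) and strength.
#' @return A [GoModel-class].
#' @export
buildCaGoModel <- function(structure, heavyReference = NULL, contactMap = NULL,
                           cdef = contactDefinition("ca", rCut = 0.8, minSeparation = 3L),
                           heavyCdef = contactDefinition("heavy"),
                           kBond = 2e4, kAngle = 40, kDihedral = 1,
                           sigmaNC = 0.4, epsNC = 1) {
  if (structure@resolution != "Ca")
    stop("buildCaGoModel requires a Ca-resolution structure")
  xyz <- coords(structure)
  n <- nrow(xyz)
  if (is.null(contactMap)) {
    contactMap <- buildNativeContactMap(
      structure, cdef,
      weighting = if (is.null(heavyReference)) "none" else "heavy-atom-count",
      heavyReference = heavyReference, heavyCdef = heavyCdef)
  }
  p <- contactMap@pairs
  eps <- p$weight
  if (length(eps)) eps <- eps / mean(eps)  # epsilon_c = 1 sets the scale

  seg <- function(i) xyz[i, , drop = FALSE]
  dist1 <- function(i, j) sqrt(rowSums((seg(i) - seg(j))^2))

  bonds <- cbind(seq_len(n - 1L), seq(2L, n))
  bondParams <- cbind(r0 = dist1(bonds[, 1], bonds[, 2]), k = kBond)

  if (n >= 3) {
    angles <- cbind(seq_len(n - 2L), seq(2L, n - 1L), seq(3L, n))
    th0 <- vapply(seq_len(nrow(angles)), function(t) {
      u <- xyz[angles[t, 1], ] - xyz[angles[t, 2], ]
      w <- xyz[angles[t, 3], ] - xyz[angles[t, 2], ]
      acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
    }, numeric(1))
    angleParams <- cbind(theta0 = th0, k = kAngle)
  } else {
    angles <- matrix(integer(), 0, 3); angleParams <- matrix(numeric(), 0, 2)
  }

  if (n >= 4) {
    dihedrals <- cbind(seq_len(n - 3L), seq(2L, n - 2L), seq(3L, n - 1L), seq(4L, n))
    phi0 <- vapply(seq_len(nrow(dihedrals)), function(t)
      .dihedral(xyz[dihedrals[t, 1], ], xyz[dihedrals[t, 2], ],
                xyz[dihedrals[t, 3], ], xyz[dihedrals[t, 4], ]), numeric(1))
    dihedralParams <- cbind(phi0 = phi0, k = kDihedral)
  } else {
    dihedrals <- matrix(integer(), 0, 4); dihedralParams <- matrix(numeric(), 0, 2)
  }

  new("GoModel", structure = structure,
      bonds = bonds, bondParams = bondParams,
      angles = angles, angleParams = angleParams,
      dihedrals = dihedrals, dihedralParams = dihedralParams,
      pairs = cbind(i = p$i, j = p$j),
      pairParams = cbind(r0 = p$r0, eps = eps),
      sigmaNC = sigmaNC, epsNC = epsNC, exclSep = 3L, map = contactMap)
}

.dihedral <- function(ri, rj, rk, rl) {
  b1 <- rj - ri; b2 <- rk - rj; b3 <- rl - rk
  m <- .cross3(b1, b2); nv <- .cross3(b2, b3)
  atan2(sum(.cross3(m, nv) * b2) / sqrt(sum(b2^2)), sum(m * nv))
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])

.model_cpp <- function(model) {
  list(n = nrow(model@structure@atoms),
       bonds = .int_mat(model@bonds, 2), bond_params = .num_mat(model@bondParams, 2),
       angles = .int_mat(model@angles, 3), angle_params = .num_mat(model@angleParams, 2),
       dihedrals = .int_mat(model@dihedrals, 4),
       dihedral_params = .num_mat(model@dihedralParams, 2),
       pairs = .int_mat(model@pairs, 2), pair_params = .num_mat(model@pairParams, 2),
       sigma_nc = model@sigmaNC, eps_nc = model@epsNC,
       rc_nc = 2.5 * model@sigmaNC, excl_sep = model@exclSep)
}

.int_mat <- function(m, k) {
  m <- matrix(as.integer(m), ncol = k)
  m
}
.num_mat <- function(m, k) matrix(as.numeric(m), ncol = k)

#' Potential energy and forces of a Go model
#'
#' @param model a [GoModel-class].
#' @param x `[n, 3]` coordinate matrix (nm); defaults to the native
#'   coordinates.
#' @return List with `potential` (reduced units) and `forces` (`[n, 3]`).
#' @export
goEnergy <- function(model, x = coords(model@structure)) {
  .go_energy(.model_cpp(model), .num_mat(x, 3))
}
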