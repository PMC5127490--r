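# S4 containers for the pipeline.  Coordinates are always in nm; energies in
# reduced units (native-contact epsilon = 1) unless a method says otherwise.

#' Molecular structure at heavy-atom or C-alpha resolution
#'
#' An ordered list of moieties (heavy atoms or backbone beads).  The `atoms`
#' data frame has one row per moiety with columns `moiety_id` (character),
#' `resno` (1-based residue index, non-decreasing), `role` (one of
#' `"heavy-atom"`, `"Ca"`, `"backbone-bead"`), and coordinates `x`, `y`, `z`
#' in nm.
#'
#' @slot atoms data.frame of moieties, see description.
#' @slot resolution character, `"heavy-atom"` or `"Ca"`.
#' @export
setClass("Structure",
  representation(atoms = "data.frame", resolution = "character"),
  validity = function(object) {
    a <- object@atoms
    msg <- character()
    need <- c("moiety_id", "resno", "role", "x", "y", "z")
    if (!all(need %in% names(a)))
      return(paste("atoms must have columns", paste(need, collapse = ", ")))
    if (nrow(a) == 0) msg <- c(msg, "structure has no moieties")
    if (is.unsorted(a$resno)) msg <- c(msg, "residue indices must be non-decreasing")
    if (!all(is.finite(c(a$x, a$y, a$z)))) msg <- c(msg, "coordinates must be finite")
    if (!object@resolution %in% c("heavy-atom", "Ca"))
      msg <- c(msg, "resolution must be 'heavy-atom' or 'Ca'")
    if (length(msg)) msg else TRUE
  })

#' Smoothed contact definition
#'
#' Parameters of the smoothed contact counting functions: the logistic
#' smoothing parameter `beta0` (1/nm), the fluctuation factor `lambda`
#' (dimensionless, >= 1), the native cutoff `rCut` (nm), the minimum sequence
#' separation in residues, and the non-native length scale `R0` (nm, the mean
#' native pair distance; may be `NA` until a map is built).
#'
#' @export
setClass("ContactDefinition",
  representation(beta0 = "numeric", lambda = "numeric", rCut = "numeric",
                 minSeparation = "integer", R0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@beta0 <= 0) msg <- c(msg, "beta0 must be > 0")
    if (object@lambda < 1) msg <- c(msg, "lambda must be >= 1")
    if (object@rCut <= 0) msg <- c(msg, "rCut must be > 0")
    if (object@minSeparation < 1L) msg <- c(msg, "minSeparation must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Native contact map
#'
#' The reference pair set of the native structure.  `pairs` has one row per
#' native moiety pair: `i`, `j` (row indices into the structure's moiety
#' list), `resi`, `resj` (residue indices), `r0` (native distance, nm) and
#' `weight` (contact multiplicity, >= 1).  `moietyResidues` records the
#' residue index of every moiety so that frames carrying only coordinates can
#' be scored against the map.
#'
#' @export
setClass("NativeContactMap",
  representation(pairs = "data.frame", totalWeight = "numeric",
                 resolution = "character", moietyResidues = "integer",
                 cdef = "ContactDefinition"),
  validity = function(object) {
    p <- object@pairs
    msg <- character()
    need <- c("i", "j", "resi", "resj", "r0", "weight")
    if (!all(need %in% names(p)))
      return(paste("pairs must have columns", paste(need, collapse = ", ")))
    if (nrow(p)) {
      if (any(p$weight < 1)) msg <- c(msg, "weights must be >= 1")
      if (any(abs(p$resi - p$resj) < object@cdef@minSeparation))
        msg <- c(msg, "pairs must respect the minimum sequence separation")
      if (any(p$r0 >= object@cdef@rCut))
        msg <- c(msg, "native distances must be below the cutoff")
    }
    if (abs(object@totalWeight - sum(p$weight)) > 1e-9)
      msg <- c(msg, "totalWeight must equal the sum of weights")
    if (length(msg)) msg else TRUE
  })

#' Trajectory of frames
#'
#' Ordered coordinate frames with per-frame time (LJ time units for the
#' bundled engine), tether extension `extension` (nm, `NA` when no pulling),
#' applied spring force (reduced units), and optional potential/kinetic
#' energies.  `coords` is an array `[n_moieties, 3, n_frames]`.
#'
#' @export
setClass("Trajectory",
  representation(coords = "array", time = "numeric", extension = "numeric",
                 force = "numeric", potential = "numeric", kinetic = "numeric",
                 runId = "character", metadata = "list"),
  validity = function(object) {
    d <- dim(object@coords)
    msg <- character()
    if (length(d) != 3 || d[2] != 3)
      return("coords must be an [n_moieties, 3, n_frames] array")
    nf <- d[3]
    if (length(object@time) != nf) msg <- c(msg, "time must have one value per frame")
    if (nf > 1 && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' C-alpha Go model
#'
#' Bonded terms (harmonic bonds and angles, cosine dihedrals), attractive
#' 10-12 native pairs, and a uniform excluded-volume repulsion for all other
#' pairs.  Built at the native minimum, in reduced units (epsilon = 1).
#'
#' @export
setClass("GoModel",
  representation(structure = "Structure", bonds = "matrix", bondParams = "matrix",
                 angles = "matrix", angleParams = "matrix",
                 dihedrals = "matrix", dihedralParams = "matrix",
                 pairs = "matrix", pairParams = "matrix",
                 sigmaNC = "numeric", epsNC = "numeric", exclSep = "integer",
                 map = "NativeContactMap"))

#' Thermal melting curve
#' @export
setClass("MeltingCurve",
  representation(temperatures = "numeric", meanQ = "numeric", semQ = "numeric",
                 series = "list"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@temperatures, strictly = TRUE))
      msg <- c(msg, "temperatures must be strictly increasing")
    if (length(object@meanQ) != length(object@temperatures))
      msg <- c(msg, "meanQ must match temperatures")
    if (any(object@meanQ < -1e-9 | object@meanQ > 1 + 1e-9))
      msg <- c(msg, "meanQ must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Two-state melting fit
#'
#' Baselines `qf` (folded) and `qu` (unfolded), unfolding enthalpy `dH`
#' (kJ/mol) and entropy `dS` (kJ/(mol K)), with the folding temperature
#' `Tf = dH/dS` (K) where the two states are equally stable.
#'
#' @export
setClass("TwoStateFit",
  representation(qf = "numeric", qu = "numeric", dH = "numeric", dS = "numeric",
                 Tf = "numeric", cov = "matrix", window = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@qf <= object@qu) msg <- c(msg, "qf must exceed qu")
    if (object@dH <= 0 || object@dS <= 0) msg <- c(msg, "dH and dS must be positive")
    if (length(msg)) msg else TRUE
  })

#' Double-exponential relaxation fit
#' @export
setClass("RelaxationFit",
  representation(A1 = "numeric", A2 = "numeric", kappa1 = "numeric",
                 kappa2 = "numeric", single = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@A1 < 0 || object@A2 < 0) msg <- c(msg, "amplitudes must be >= 0")
    if (object@kappa1 <= 0 || object@kappa2 <= 0) msg <- c(msg, "rates must be > 0")
    if (object@kappa1 > object@kappa2 + 1e-12)
      msg <- c(msg, "kappa1 must not exceed kappa2")
    if (length(msg)) msg else TRUE
  })

#' Ensemble of pulling work values
#'
#' One work integral per trajectory (same units as 1/beta), the inverse
#' temperature `beta`, and the integration limit `L` (nm).
#'
#' @export
setClass("WorkEnsemble",
  representation(works = "numeric", beta = "numeric", L = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@works))) msg <- c(msg, "works must be finite")
    if (object@beta <= 0) msg <- c(msg, "beta must be positive")
    if (length(msg)) msg else TRUE
  })

#' Force-scale solution
#' @export
setClass("ForceScaleResult",
  representation(alpha = "numeric", dGRef = "numeric", trace = "data.frame"),
  validity = function(object) {
    if (object@alpha <= 0) "alpha must be positive" else TRUE
  })

#' Clusters of conformations at one Q level
#' @export
setClass("ClusterSet",
  representation(Q = "numeric", assignments = "integer", centroids = "integer",
                 members = "list"),
  validity = function(object) {
    msg <- character()
    k <- length(object@centroids)
    if (length(object@members) != k) msg <- c(msg, "one member set per centroid")
    for (cl in seq_len(k)) {
      if (!object@centroids[cl] %in% object@members[[cl]])
        msg <- c(msg, "each centroid must be a member of its cluster")
    }
    if (length(msg)) msg else TRUE
  })

#' Unfolding pathway graph
#'
#' Nodes are clusters of conformations at discrete Q levels; directed edges
#' connect clusters at consecutive levels (from higher to lower Q) with
#' weight equal to the fraction of trajectories taking that step.
#'
#' @export
setClass("PathwayGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 nTrajectories = "integer"))
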