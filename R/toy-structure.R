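# Deterministic toy folded structures.  These stand in for an experimental
# PDB structure so the whole pipeline can run without downloads: a compact
# C-alpha chain with a heterogeneous native contact map and at least two
# topologically distinct strand pairings.

#' Generate a compact toy folded structure
#'
#' Builds a self-avoiding C-alpha chain with exact 0.38 nm virtual bonds.
#' The `"hairpin-barrel"` motif is a two-layer antiparallel beta-sandwich
#' (serpentine strands within each layer, layers stacked); `"helix-bundle"`
#' packs alpha-helical segments side by side.  A small seeded jitter breaks
#' exact symmetry, after which bond lengths are restored to 0.38 nm by
#' constraint projection, so coordinates are deterministic given the seed.
#'
#' @param nResidues chain length (>= 20).
#' @param motif `"hairpin-barrel"` or `"helix-bundle"`.
#' @param seed integer seed for the jitter.
#' @param jitter jitter amplitude in nm (default 0.015).
#' @return A C-alpha [Structure-class].
#' @examples
#' s <- generateToyStructure(40, seed = 1)
#' nResidues(s)
#' @export
generateToyStructure <- function(nResidues, motif = c("hairpin-barrel", "helix-bundle"),
                                 seed = 1L, jitter = 0.015) {
  motif <- match.arg(motif)
  stopifnot(nResidues >= 20)
  xyz <- switch(motif,
    "hairpin-barrel" = .toy_sandwich(nResidues),
    "helix-bundle"   = .toy_bundle(nResidues))
  set.seed(seed)
  xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter), ncol = 3)
  xyz <- .fix_bonds(xyz, b = 0.38)
  Structure(data.frame(moiety_id = paste0(seq_len(nResidues), ":CA"),
                       resno = seq_len(nResidues), role = "Ca",
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
            resolution = "Ca")
}

# two-layer antiparallel beta sandwich: strands along x (zigzag in z),
# strand spacing 0.5 nm in y, layer spacing 0.55 nm in z
.toy_sandwich <- function(n) {
  strand_len <- max(5L, round(sqrt(n)))
  per_layer <- 2L
  xyz <- matrix(0, n, 3)
  dxs <- sqrt(0.38^2 - 0.19^2)   # along-strand step with +/-0.095 z zigzag
  i <- 1L; strand <- 0L
  while (i <= n) {
    layer <- (strand %/% per_layer) %% 2L
    row <- strand %% per_layer + (strand %/% (2L * per_layer)) * per_layer
    y0 <- 0.5 * row
    z0 <- 0.55 * layer
    rev_dir <- strand %% 2L == 1L
    for (k in seq_len(strand_len)) {
      if (i > n) break
      xpos <- if (rev_dir) (strand_len - k) * dxs else (k - 1L) * dxs
      xyz[i, ] <- c(xpos, y0, z0 + 0.095 * (-1)^k)
      i <- i + 1L
    }
    strand <- strand + 1L
  }
  xyz
}

# alpha-helical segments packed in a row; helix geometry tuned for 0.38 nm
# consecutive C-alpha distance (rise 0.15 nm, 100 degrees per residue)
.toy_bundle <- function(n) {
  rise <- 0.15; ang <- 100 * pi / 180
  radius <- sqrt(0.38^2 - rise^2) / (2 * sin(ang / 2))
  helix_len <- max(8L, ceiling(n / 3))
  xyz <- matrix(0, n, 3)
  i <- 1L; h <- 0L
  while (i <= n) {
    x0 <- 0.55 * h
    up <- h %% 2L == 0L
    for (k in seq_len(helix_len)) {
      if (i > n) break
      zk <- rise * (k - 1L)
      if (!up) zk <- rise * (helix_len - k)
      xyz[i, ] <- c(x0 + radius * cos(ang * k), radius * sin(ang * k), zk)
      i <- i + 1L
    }
    h <- h + 1L
  }
  xyz
}

# iterative bond-length projection (SHAKE-like) to |r_{i,i+1}| = b
.fix_bonds <- function(xyz, b = 0.38, tol = 1e-10, maxit = 20000L) {
  n <- nrow(xyz)
  for (it in seq_len(maxit)) {
    d <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    err <- max(abs(len - b))
    if (err < tol) break
    for (i in seq_len(n - 1L)) {
      v <- xyz[i + 1L, ] - xyz[i, ]
      l <- sqrt(sum(v^2))
      corr <- 0.5 * (l - b) / l * v
      xyz[i, ] <- xyz[i, ] + corr
      xyz[i + 1L, ] <- xyz[i + 1L, ] - corr
    }
  }
  xyz
}

#' Scripted unfolding ensembles
#'
#' Generates geometric (non-dynamical) unfolding trajectories with a
#' prescribed residue unfolding order: at unfolding fraction f, the first
#' `round(f * n)` residues of `order` are displaced onto an extended tail
#' far from the folded core, the rest stay at their native positions plus
#' Gaussian noise.  Used to exercise the pathway-taxonomy machinery with a
#' known number of pathways.
#'
#' @param structure native C-alpha [Structure-class].
#' @param order integer vector: residue indices in the order they unfold.
#' @param nFrames frames per trajectory (unfolding fractions 0..1).
#' @param noise Gaussian positional noise (nm) on folded residues
#'   (default 0.01 nm, small against the TM-score d0 so that a shared
#'   unfolding order reads as a shared pathway).
#' @param seed integer seed.
#' @param runId trajectory identifier.
#' @return A [Trajectory-class] whose frames progress from folded to
#'   unfolded.
#' @export
scriptedUnfoldingTrajectory <- function(structure, order, nFrames = 41,
                                        noise = 0.01, seed = 1L,
                                        runId = "scripted") {
  xyz0 <- coords(structure)
  n <- nrow(xyz0)
  stopifnot(length(order) == n)
  set.seed(seed)
  far <- max(xyz0) + 3
  arr <- array(NA_real_, c(n, 3, nFrames))
  for (k in seq_len(nFrames)) {
    f <- (k - 1) / (nFrames - 1)
    x <- xyz0 + matrix(rnorm(3 * n, sd = noise), ncol = 3)
    gone <- order[seq_len(round(f * n))]
    if (length(gone))
      x[gone, ] <- cbind(far + 0.5 * seq_along(gone), 5, 5)
    arr[, , k] <- x
  }
  new("Trajectory", coords = arr, time = as.numeric(seq_len(nFrames)),
      extension = rep(NA_real_, nFrames), force = rep(NA_real_, nFrames),
      potential = numeric(nFrames), kinetic = numeric(nFrames),
      runId = runId, metadata = list(order = order, seed = seed))
}
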