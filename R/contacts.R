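# Native/non-native contact observables: the smoothed order parameter Q,
# non-native counts, per-residue profiles and contact maps along Q.

#' Contact definition presets
#'
#' Smoothed-contact parameters per model resolution: beta0 = 50/nm for all
#' models; lambda = 1.8 and rCut = 0.48 nm for heavy-atom structures,
#' lambda = 1.2 with rCut = 0.6 nm (three-bead backbone models) or 1.2 nm
#' (C-alpha models).  The non-native length scale R0 defaults to the printed
#' per-model constants (0.24, 0.46, 0.91 nm); pass `R0 = NA` to have
#' [buildNativeContactMap()] recompute it as the mean native pair distance.
#'
#' @param model preset name: `"heavy"` (all-atom / heavy-atom Go),
#'   `"awsem"` (three-bead backbone), or `"ca"` (C-alpha).
#' @param beta0,lambda,rCut,minSeparation,R0 override individual parameters.
#' @return A [ContactDefinition-class].
#' @examples
#' contactDefinition("ca")
#' @export
contactDefinition <- function(model = c("ca", "heavy", "awsem"),
                              beta0 = NULL, lambda = NULL, rCut = NULL,
                              minSeparation = 4L, R0 = NULL) {
  model <- match.arg(model)
  preset <- switch(model,
    heavy = list(beta0 = 50, lambda = 1.8, rCut = 0.48, R0 = 0.24),
    awsem = list(beta0 = 50, lambda = 1.2, rCut = 0.60, R0 = 0.46),
    ca    = list(beta0 = 50, lambda = 1.2, rCut = 1.20, R0 = 0.91))
  new("ContactDefinition",
      beta0 = if (is.null(beta0)) preset$beta0 else beta0,
      lambda = if (is.null(lambda)) preset$lambda else lambda,
      rCut = if (is.null(rCut)) preset$rCut else rCut,
      minSeparation = as.integer(minSeparation),
      R0 = if (is.null(R0)) preset$R0 else as.numeric(R0))
}

#' Build the native contact map of a structure
#'
#' Enumerates all moiety pairs separated by at least `minSeparation` residues
#' whose native distance is below `rCut`.  With
#' `weighting = "heavy-atom-count"` (C-alpha maps only) each residue pair's
#' weight is the number of heavy-atom contacts the same residue pair forms in
#' `heavyReference`, so that residue pairs with large interfaces count more,
#' as in the native state of a higher-resolution model.
#'
#' @param structure a [Structure-class].
#' @param cdef a [ContactDefinition-class]; defaults to the preset matching
#'   the structure resolution.
#' @param weighting `"none"` or `"heavy-atom-count"`.
#' @param heavyReference heavy-atom [Structure-class] used for weighting.
#' @param heavyCdef contact definition used on `heavyReference`
#'   (default: the `"heavy"` preset).
#' @return A [NativeContactMap-class].  If `cdef@R0` is `NA`, R0 is recorded
#'   as the mean native pair distance.
#' @export
buildNativeContactMap <- function(structure, cdef = NULL,
                                  weighting = c("none", "heavy-atom-count"),
                                  heavyReference = NULL,
                                  heavyCdef = contactDefinition("heavy")) {
  weighting <- match.arg(weighting)
  if (is.null(cdef))
    cdef <- contactDefinition(if (structure@resolution == "Ca") "ca" else "heavy")
  a <- structure@atoms
  xyz <- coords(structure)
  n <- nrow(a)
  pr <- .eligible_pairs(a$resno, cdef@minSeparation)
  if (nrow(pr)) {
    d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                       xyz[pr[, 2], , drop = FALSE])^2))
    sel <- d < cdef@rCut
    pr <- pr[sel, , drop = FALSE]
    d <- d[sel]
  } else d <- numeric()
  pairs <- data.frame(i = as.integer(pr[, 1]), j = as.integer(pr[, 2]),
                      resi = a$resno[pr[, 1]], resj = a$resno[pr[, 2]],
                      r0 = d, weight = rep(1, nrow(pr)))
  if (weighting == "heavy-atom-count") {
    if (is.null(heavyReference))
      stop("heavy-atom-count weighting requires a heavyReference structure")
    hmap <- buildNativeContactMap(heavyReference, heavyCdef)
    hp <- hmap@pairs
    hkey <- paste(pmin(hp$resi, hp$resj), pmax(hp$resi, hp$resj))
    counts <- table(hkey)
    key <- paste(pmin(pairs$resi, pairs$resj), pmax(pairs$resi, pairs$resj))
    w <- as.integer(counts[key])
    w[is.na(w)] <- 0L
    keep <- w >= 1L
    pairs <- pairs[keep, , drop = FALSE]
    pairs$weight <- w[keep]
  }
  if (nrow(pairs) == 0)
    warning("empty native contact map: no pairs satisfy the contact criteria")
  if (is.na(cdef@R0))
    cdef@R0 <- if (nrow(pairs)) mean(pairs$r0) else NA_real_
  rownames(pairs) <- NULL
  new("NativeContactMap", pairs = pairs, totalWeight = sum(pairs$weight),
      resolution = structure@resolution, moietyResidues = as.integer(a$resno),
      cdef = cdef)
}

# all i<j moiety pairs with residue separation >= minSep
.eligible_pairs <- function(resno, minSep) {
  n <- length(resno)
  idx <- which(outer(resno, resno, function(a, b) b - a) >= minSep, arr.ind = TRUE)
  cbind(i = idx[, 1], j = idx[, 2])
}

.frame_coords <- function(frame) {
  if (is(frame, "Structure")) return(coords(frame))
  if (is.matrix(frame)) return(frame)
  stop("frame must be a Structure or an [n, 3] coordinate matrix")
}

.contact_smooth <- function(r, r_ref, beta0, lambda)
  1 / (1 + exp(pmin(700, beta0 * (r - lambda * r_ref))))

#' Fraction of native contacts Q
#'
#' The smoothed native fraction of a conformation X:
#' \deqn{Q(X) = \frac{1}{|S|} \sum_{(i,j) \in S}
#'   \frac{w_{ij}}{1 + \exp[\beta_0 (r_{ij}(X) - \lambda r^0_{ij})]}}
#' where S is the native pair set, \eqn{|S|} the total weight, and
#' \eqn{r^0_{ij}} the native distance of the pair.
#'
#' @param frame an `[n, 3]` coordinate matrix (nm) or a [Structure-class]
#'   congruent with the map's moiety list.
#' @param map a [NativeContactMap-class].
#' @param cdef optional [ContactDefinition-class] override (defaults to the
#'   definition stored in the map).
#' @return Q in `[0, 1]`.
#' @export
nativeFraction <- function(frame, map, cdef = map@cdef) {
  x <- .frame_coords(frame)
  if (nrow(x) != length(map@moietyResidues))
    stop("frame has ", nrow(x), " moieties but the map expects ",
         length(map@moietyResidues))
  p <- map@pairs
  if (nrow(p) == 0) return(NA_real_)
  r <- sqrt(rowSums((x[p$i, , drop = FALSE] - x[p$j, , drop = FALSE])^2))
  sum(p$weight * .contact_smooth(r, p$r0, cdef@beta0, cdef@lambda)) /
    map@totalWeight
}

#' Q for every frame of a trajectory
#' @param trajectory a [Trajectory-class].
#' @inheritParams nativeFraction
#' @return Numeric vector of Q values, one per frame.
#' @export
trajectoryQ <- function(trajectory, map, cdef = map@cdef) {
  vapply(seq_len(nFrames(trajectory)),
         function(k) nativeFraction(trajectory@coords[, , k], map, cdef),
         numeric(1))
}

# candidate non-native moiety pairs for a map: eligible separation, not native
.nonnative_pairs <- function(map) {
  pr <- .eligible_pairs(map@moietyResidues, map@cdef@minSeparation)
  if (nrow(map@pairs)) {
    n <- length(map@moietyResidues)
    nat <- map@pairs$i * (n + 1) + map@pairs$j
    key <- pr[, 1] * (n + 1) + pr[, 2]
    pr <- pr[!key %in% nat, , drop = FALSE]
  }
  pr
}

#' Number of non-native contacts
#'
#' Smoothed count over all moiety pairs meeting the sequence-separation rule
#' that are not native, each scored against the common length scale R0 (the
#' mean native pair distance):
#' \deqn{N_{nn}(X) = \sum_{(i,j)'} \frac{1}{1 + \exp[\beta_0 (r_{ij}(X) -
#'   \lambda R_0)]}}
#'
#' @inheritParams nativeFraction
#' @return Non-negative smoothed count.
#' @export
nonnativeCount <- function(frame, map, cdef = map@cdef) {
  x <- .frame_coords(frame)
  if (nrow(x) != length(map@moietyResidues))
    stop("frame has ", nrow(x), " moieties but the map expects ",
         length(map@moietyResidues))
  pr <- .nonnative_pairs(map)
  if (nrow(pr) == 0) return(0)
  r <- sqrt(rowSums((x[pr[, 1], , drop = FALSE] - x[pr[, 2], , drop = FALSE])^2))
  sum(.contact_smooth(r, cdef@R0, cdef@beta0, cdef@lambda))
}

# nearest-center Q bin assignment on a grid of spacing dQ
.q_bin <- function(q, dQ) round(q / dQ) * dQ

#' Per-residue native-contact profiles along Q
#'
#' For each residue k, the fraction of k's native contact weight present,
#' averaged over all frames falling in each Q bin (nearest bin center on a
#' grid of spacing `dQ`).  Residues with no native contacts are `NA`
#' throughout; empty bins are dropped.
#'
#' @param trajectories a [Trajectory-class] or list of them.
#' @param map a [NativeContactMap-class].
#' @param cdef optional contact definition override.
#' @param dQ bin width (default 0.01).
#' @return A matrix `[n_residues, n_bins]` with Q bin centers as column
#'   names, plus attribute `"counts"` (frames per bin).
#' @export
residueProfile <- function(trajectories, map, cdef = map@cdef, dQ = 0.01) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  p <- map@pairs
  resnos <- sort(unique(map@moietyResidues))
  nres <- length(resnos)
  res_of <- match(map@moietyResidues, resnos)
  wres <- numeric(nres)  # native weight per residue
  for (t in seq_len(nrow(p))) {
    wres[res_of[p$i[t]]] <- wres[res_of[p$i[t]]] + p$weight[t]
    wres[res_of[p$j[t]]] <- wres[res_of[p$j[t]]] + p$weight[t]
  }
  acc <- list(); cnt <- list()
  for (traj in trajectories) {
    for (k in seq_len(nFrames(traj))) {
      x <- traj@coords[, , k]
      r <- sqrt(rowSums((x[p$i, , drop = FALSE] - x[p$j, , drop = FALSE])^2))
      s <- p$weight * .contact_smooth(r, p$r0, cdef@beta0, cdef@lambda)
      q <- sum(s) / map@totalWeight
      qk <- numeric(nres)
      for (t in seq_len(nrow(p))) {
        qk[res_of[p$i[t]]] <- qk[res_of[p$i[t]]] + s[t]
        qk[res_of[p$j[t]]] <- qk[res_of[p$j[t]]] + s[t]
      }
      qk <- ifelse(wres > 0, qk / wres, NA_real_)
      b <- sprintf("%.6g", .q_bin(q, dQ))
      if (is.null(acc[[b]])) { acc[[b]] <- qk; cnt[[b]] <- 1L }
      else { acc[[b]] <- acc[[b]] + qk; cnt[[b]] <- cnt[[b]] + 1L }
    }
  }
  bins <- names(acc)[order(as.numeric(names(acc)))]
  out <- vapply(bins, function(b) acc[[b]] / cnt[[b]], numeric(nres))
  out <- matrix(out, nrow = nres, dimnames = list(resnos, bins))
  attr(out, "counts") <- vapply(bins, function(b) cnt[[b]], integer(1))
  out
}

#' Off-native residue pairs relative to native pairs
#'
#' An "off-native" pair is a residue pair engaged in a non-native contact
#' that is a +/-1 primary-sequence shift of some native residue pair (and is
#' not itself native) - the signature of beta-strand register slippage.  A
#' smoothed contact term above 0.5 counts as a contact.  Counts are averaged
#' over the ensemble.
#'
#' @param frames list of coordinate matrices (or a [Trajectory-class]).
#' @param map a [NativeContactMap-class].
#' @param cdef optional contact definition override.
#' @return Named vector `c(n_off = , n_native_pairs = )` of thermal averages.
#' @export
offNativeRatio <- function(frames, map, cdef = map@cdef) {
  if (is(frames, "Trajectory"))
    frames <- lapply(seq_len(nFrames(frames)), function(k) frames@coords[, , k])
  p <- map@pairs
  natkey <- unique(paste(pmin(p$resi, p$resj), pmax(p$resi, p$resj)))
  shift <- unique(unlist(lapply(strsplit(natkey, " "), function(mn) {
    m <- as.integer(mn[1]); n <- as.integer(mn[2])
    c(paste(pmin(m + 1, n), pmax(m + 1, n)), paste(pmin(m - 1, n), pmax(m - 1, n)),
      paste(pmin(m, n + 1), pmax(m, n + 1)), paste(pmin(m, n - 1), pmax(m, n - 1)))
  })))
  shift <- setdiff(shift, natkey)
  nn <- .nonnative_pairs(map)
  nn_key <- paste(pmin(map@moietyResidues[nn[, 1]], map@moietyResidues[nn[, 2]]),
                  pmax(map@moietyResidues[nn[, 1]], map@moietyResidues[nn[, 2]]))
  n_off <- n_nat <- numeric(length(frames))
  for (f in seq_along(frames)) {
    x <- .frame_coords(frames[[f]])
    r <- sqrt(rowSums((x[p$i, , drop = FALSE] - x[p$j, , drop = FALSE])^2))
    s <- .contact_smooth(r, p$r0, cdef@beta0, cdef@lambda)
    alive <- unique(paste(pmin(p$resi, p$resj), pmax(p$resi, p$resj))[s > 0.5])
    n_nat[f] <- length(alive)
    if (nrow(nn)) {
      rn <- sqrt(rowSums((x[nn[, 1], , drop = FALSE] - x[nn[, 2], , drop = FALSE])^2))
      sn <- .contact_smooth(rn, cdef@R0, cdef@beta0, cdef@lambda)
      inref <- unique(nn_key[sn > 0.5])
      n_off[f] <- sum(inref %in% shift)
    }
  }
  c(n_off = mean(n_off), n_native_pairs = mean(n_nat))
}

#' Residue-residue contact maps at target Q values
#'
#' For each target Q, frames within `dQ` of the target are pooled.  The
#' native map entry for residues (k, l) is the mean surviving fraction of
#' their native contact weight; the non-native entry is the fraction of
#' frames with at least one non-native contact between k and l (smoothed
#' term above 0.5).
#'
#' @param trajectories a [Trajectory-class] or list of them.
#' @param map a [NativeContactMap-class].
#' @param cdef optional contact definition override.
#' @param qTargets numeric vector of target Q values.
#' @param dQ bin half-width (default 0.01).
#' @return Named list per target with elements `native` and `nonnative`
#'   (`[n_res, n_res]` matrices, `NA` where undefined) and `nFrames`.
#'   Targets with no frames are returned as `NULL` with a warning.
#' @export
contactMapAtQ <- function(trajectories, map, cdef = map@cdef,
                          qTargets = c(0.8, 0.5, 0.1), dQ = 0.01) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  p <- map@pairs
  resnos <- sort(unique(map@moietyResidues))
  nres <- length(resnos)
  pk <- match(p$resi, resnos); pl <- match(p$resj, resnos)
  natw <- matrix(0, nres, nres)
  for (t in seq_len(nrow(p)))
    natw[pk[t], pl[t]] <- natw[pk[t], pl[t]] + p$weight[t]
  nn <- .nonnative_pairs(map)
  nk <- match(map@moietyResidues[nn[, 1]], resnos)
  nl <- match(map@moietyResidues[nn[, 2]], resnos)

  frames <- list(); qs <- numeric()
  for (traj in trajectories) {
    for (k in seq_len(nFrames(traj))) {
      x <- traj@coords[, , k]
      frames[[length(frames) + 1L]] <- x
      qs <- c(qs, nativeFraction(x, map, cdef))
    }
  }
  out <- list()
  for (qt in qTargets) {
    sel <- which(abs(qs - qt) <= dQ + 1e-12)
    if (!length(sel)) {
      warning("no frames within ", dQ, " of Q = ", qt)
      out[[sprintf("%.6g", qt)]] <- NULL
      next
    }
    natacc <- matrix(0, nres, nres)
    nnacc <- matrix(0, nres, nres)
    for (f in sel) {
      x <- frames[[f]]
      r <- sqrt(rowSums((x[p$i, , drop = FALSE] - x[p$j, , drop = FALSE])^2))
      s <- p$weight * .contact_smooth(r, p$r0, cdef@beta0, cdef@lambda)
      m <- matrix(0, nres, nres)
      for (t in seq_len(nrow(p))) m[pk[t], pl[t]] <- m[pk[t], pl[t]] + s[t]
      natacc <- natacc + ifelse(natw > 0, m / pmax(natw, 1e-300), 0)
      if (nrow(nn)) {
        rn <- sqrt(rowSums((x[nn[, 1], , drop = FALSE] -
                            x[nn[, 2], , drop = FALSE])^2))
        sn <- .contact_smooth(rn, cdef@R0, cdef@beta0, cdef@lambda)
        hit <- matrix(FALSE, nres, nres)
        on <- which(sn > 0.5)
        for (t in on) hit[nk[t], nl[t]] <- TRUE
        nnacc <- nnacc + hit
      }
    }
    natmap <- natacc / length(sel)
    natmap[natw == 0] <- NA_real_
    out[[sprintf("%.6g", qt)]] <- list(native = natmap,
                                       nonnative = nnacc / length(sel),
                                       nFrames = length(sel))
  }
  out
}
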