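# Unfolding pathway taxonomy: folded-segment extraction, all-against-all
# TM matrices, clustering, pathway-flow graphs, reference curves and
# cross-model comparisons.

#' Extract the folded segment from a per-residue profile
#'
#' The folded region at a given Q is the largest contiguous run of residues
#' with mean per-residue nativeness above 0.5.  Sub-threshold gaps of up to
#' `maxGap` residues inside a run are tolerated; a longer unfolded stretch
#' splits the region, and the largest resulting segment wins.
#'
#' @param profile numeric vector of per-residue `<Q_i>` values (one per
#'   residue, in residue order).
#' @param threshold nativeness threshold (default 0.5).
#' @param maxGap largest tolerated internal sub-threshold gap (default 10).
#' @return List with `start`, `end` (1-based, inclusive; `NA` if no residue
#'   is above threshold) and `meanQ` over the segment.
#' @export
foldedSegment <- function(profile, threshold = 0.5, maxGap = 10L) {
  above <- which(!is.na(profile) & profile > threshold)
  if (!length(above))
    return(list(start = NA_integer_, end = NA_integer_, meanQ = NA_real_))
  # runs of consecutive above-threshold residues
  brk <- c(0L, which(diff(above) > 1L), length(above))
  runs <- lapply(seq_len(length(brk) - 1L), function(k)
    c(above[brk[k] + 1L], above[brk[k + 1L]]))
  # merge runs separated by gaps <= maxGap
  groups <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- groups[[length(groups)]]
    if (r[1] - last[2] - 1L <= maxGap)
      groups[[length(groups)]] <- c(last[1], r[2])
    else groups[[length(groups) + 1L]] <- r
  }
  span <- vapply(groups, function(g) g[2] - g[1] + 1L, integer(1))
  g <- groups[[which.max(span)]]
  list(start = g[1], end = g[2],
       meanQ = mean(profile[g[1]:g[2]], na.rm = TRUE))
}

#' Representative frame of each trajectory at a Q bin
#'
#' Selects, per trajectory, the frame whose Q is closest to the bin center;
#' trajectories with no frame within `tol` are excluded.
#'
#' @param trajectories list of [Trajectory-class].
#' @param map a [NativeContactMap-class].
#' @param q bin center.
#' @param tol largest accepted |Q - q| (default 0.05).
#' @return Named list of coordinate matrices (names = trajectory runIds);
#'   attribute `"Q"` carries the selected frames' Q values.
#' @export
framesAtQ <- function(trajectories, map, q, tol = 0.05) {
  out <- list(); qs <- numeric()
  for (traj in trajectories) {
    qv <- trajectoryQ(traj, map)
    k <- which.min(abs(qv - q))
    if (abs(qv[k] - q) > tol) next
    out[[traj@runId]] <- traj@coords[, , k]
    qs <- c(qs, qv[k])
  }
  attr(out, "Q") <- qs
  out
}

#' All-against-all TM-score matrix
#'
#' Pairwise TM-scores between ensemble members over the folded segment's
#' C-alpha atoms; unit diagonal, symmetric for equal-length inputs
#' (the pairwise score is computed once per pair).
#'
#' @param frames named list of `[n, 3]` coordinate matrices (one per
#'   trajectory).
#' @param segment a [foldedSegment()] result (or `NULL` for the full chain).
#' @return Symmetric score matrix with unit diagonal.
#' @export
allVsAllTM <- function(frames, segment = NULL) {
  m <- length(frames)
  if (m < 2) stop("need at least 2 ensemble members")
  sel <- if (!is.null(segment) && !is.na(segment$start))
    segment$start:segment$end else seq_len(nrow(frames[[1]]))
  M <- diag(1, m)
  dimnames(M) <- list(names(frames), names(frames))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      s <- tmScore(frames[[i]][sel, , drop = FALSE],
                   frames[[j]][sel, , drop = FALSE])$score
      M[i, j] <- M[j, i] <- s
    }
  }
  M
}

#' Mean pairwise TM-score as a function of Q
#'
#' For each Q bin: the folded segment is taken from the pooled per-residue
#' profile, one frame per trajectory is selected, and the mean and standard
#' error of the upper-triangle pairwise TM-scores are reported.  Bins where
#' fewer than 2 trajectories contribute are skipped.
#'
#' @param trajectories list of [Trajectory-class].
#' @param map a [NativeContactMap-class].
#' @param qGrid Q bin centers.
#' @param tol frame-selection tolerance (see [framesAtQ()]).
#' @return data.frame with columns `Q`, `meanTM`, `semTM`, `n`,
#'   `segStart`, `segEnd`.
#' @export
meanTMvsQ <- function(trajectories, map, qGrid = seq(0.1, 0.9, by = 0.1),
                      tol = 0.05) {
  prof <- residueProfile(trajectories, map, dQ = 0.05)
  bins <- as.numeric(colnames(prof))
  rows <- list()
  nres <- nrow(prof)
  for (q in qGrid) {
    fr <- framesAtQ(trajectories, map, q, tol)
    if (length(fr) < 2) next
    seg <- foldedSegment(prof[, which.min(abs(bins - q))])
    if (is.na(seg$start) || seg$end - seg$start + 1 < 3) {
      # no coherent folded region in the pooled profile (incoherent
      # ensembles): compare over the full chain instead
      seg <- list(start = 1L, end = nres, meanQ = NA_real_)
    }
    M <- allVsAllTM(fr, seg)
    ut <- M[upper.tri(M)]
    rows[[length(rows) + 1L]] <- data.frame(
      Q = q, meanTM = mean(ut), semTM = sd(ut) / sqrt(length(ut)),
      n = length(fr), segStart = seg$start, segEnd = seg$end)
  }
  do.call(rbind, rows)
}

#' Sliding-window reference overlap curve
#'
#' Generates partial native structures by sliding windows of every length
#' along the sequence (only window residues keep coordinates), computes
#' each window's Q against the full native map, bins the windows by Q, and
#' reports the mean all-against-all TM-score per bin.  This is the
#' randomized "partially unfolded but undistorted" baseline against which
#' pathway coherence is judged.
#'
#' @param native native [Structure-class].
#' @param map the native [NativeContactMap-class].
#' @param dQ bin width (default 0.1).
#' @param minLen smallest window (default 5 residues).
#' @param maxPerBin windows subsampled per bin for the TM average
#'   (default 12; seeded).
#' @param seed integer seed for the subsampling.
#' @return data.frame with columns `Q`, `meanTM`, `n`.
#' @export
windowReferenceCurve <- function(native, map, dQ = 0.1, minLen = 5L,
                                 maxPerBin = 12L, seed = 1L) {
  xyz <- coords(native)
  n <- nrow(xyz)
  wins <- list(); qs <- numeric()
  p <- map@pairs
  for (len in seq(minLen, n)) {
    for (o in seq_len(n - len + 1L)) {
      res <- o:(o + len - 1L)
      inw <- p$i %in% res & p$j %in% res
      qs[length(wins) + 1L] <- sum(p$weight[inw]) / map@totalWeight
      wins[[length(wins) + 1L]] <- res
    }
  }
  bins <- .q_bin(qs, dQ)
  out <- list()
  set.seed(seed)
  for (b in sort(unique(bins))) {
    idx <- which(bins == b)
    if (length(idx) > maxPerBin) idx <- sample(idx, maxPerBin)
    if (length(idx) < 2) {
      if (length(idx) == 1 && abs(b - 1) < 1e-9)
        out[[length(out) + 1L]] <- data.frame(Q = b, meanTM = 1, n = 1L)
      next
    }
    frames <- lapply(idx, function(k) {
      x <- matrix(NA_real_, n, 3)
      x[wins[[k]], ] <- xyz[wins[[k]], ]
      x
    })
    scores <- c()
    for (i in seq_len(length(frames) - 1)) {
      for (j in seq(i + 1, length(frames))) {
        common <- sum(complete.cases(frames[[i]]) & complete.cases(frames[[j]]))
        LRef <- max(length(wins[[idx[i]]]), length(wins[[idx[j]]]))
        s <- if (common < 3) 0 else
          tmScore(frames[[i]], frames[[j]], LRef = LRef)$score
        scores <- c(scores, s)
      }
    }
    out[[length(out) + 1L]] <- data.frame(Q = b, meanTM = mean(scores),
                                          n = length(idx))
  }
  do.call(rbind, out)
}

#' Cluster conformations by TM-score
#'
#' Hierarchical agglomerative clustering on distance 1 - TM, cut at
#' distance 1 - cutoff.  The centroid of each cluster is the member with
#' the highest mean TM-score to its cluster (ties: lowest index).
#'
#' @param tm symmetric TM-score matrix.
#' @param cutoff TM-score cutoff (default 0.6).
#' @param Q the Q level of the ensemble (bookkeeping; default `NA`).
#' @param linkage `"average"` (default) or `"single"` (nearest-neighbour
#'   variant).
#' @return A [ClusterSet-class].
#' @export
clusterByTM <- function(tm, cutoff = 0.6, Q = NA_real_,
                        linkage = c("average", "single")) {
  linkage <- match.arg(linkage)
  m <- nrow(tm)
  if (m == 1) {
    assign <- stats::setNames(1L, rownames(tm))
  } else {
    hc <- hclust(as.dist(1 - tm), method = linkage)
    assign <- cutree(hc, h = 1 - cutoff)
    # renumber clusters by order of first appearance for determinism
    assign <- stats::setNames(match(assign, unique(assign)), rownames(tm))
  }
  k <- max(assign)
  members <- lapply(seq_len(k), function(cl) which(assign == cl))
  centroids <- vapply(members, function(mem) {
    if (length(mem) == 1) return(mem[[1]])
    meanTM <- vapply(mem, function(i) mean(tm[i, setdiff(mem, i)]), numeric(1))
    mem[which.max(meanTM)]
  }, integer(1))
  new("ClusterSet", Q = Q,
      assignments = setNames(as.integer(assign), names(assign)),
      centroids = centroids,
      members = lapply(members, as.integer))
}

#' Build the unfolding pathway graph
#'
#' Nodes are clusters at successive Q levels (ordered from high to low Q);
#' a directed edge connects cluster a at level l to cluster b at level l+1
#' with weight equal to the fraction of all trajectories whose frames move
#' from a to b.  Trajectories absent from a level pass through a `0`
#' ("missing") placeholder cluster.
#'
#' @param clusterSets list of [ClusterSet-class], ordered by decreasing Q;
#'   each `assignments` vector must be named by trajectory id.
#' @param trajectoryIds ids of all trajectories (default: union of names).
#' @return A [PathwayGraph-class].
#' @export
pathwayGraph <- function(clusterSets, trajectoryIds = NULL) {
  if (length(clusterSets) < 2) stop("need cluster sets at >= 2 Q levels")
  if (is.null(trajectoryIds))
    trajectoryIds <- unique(unlist(lapply(clusterSets, function(cs)
      names(cs@assignments))))
  nT <- length(trajectoryIds)
  L <- length(clusterSets)
  memb <- vapply(clusterSets, function(cs) {
    a <- cs@assignments[trajectoryIds]
    a[is.na(a)] <- 0L
    a
  }, integer(nT))
  memb <- matrix(memb, nrow = nT)
  nodes <- list(); edges <- list()
  for (l in seq_len(L)) {
    cs <- clusterSets[[l]]
    for (cl in sort(unique(memb[, l]))) {
      size <- sum(memb[, l] == cl)
      nodes[[length(nodes) + 1L]] <- data.frame(
        level = l, Q = cs@Q, cluster = cl,
        centroid = if (cl >= 1 && cl <= length(cs@centroids))
          cs@centroids[cl] else NA_integer_,
        size = size, fraction = size / nT)
    }
    if (l == L) next
    tab <- table(memb[, l], memb[, l + 1L])
    for (a in rownames(tab)) for (b in colnames(tab)) {
      w <- tab[a, b] / nT
      if (w > 0)
        edges[[length(edges) + 1L]] <- data.frame(
          fromLevel = l, fromCluster = as.integer(a),
          toLevel = l + 1L, toCluster = as.integer(b), weight = w)
    }
  }
  new("PathwayGraph", nodes = do.call(rbind, nodes),
      edges = do.call(rbind, edges), nTrajectories = as.integer(nT))
}

#' Dominant unfolding pathway
#'
#' The path from the highest to the lowest Q level maximizing the smallest
#' edge weight along the path (the fraction of trajectories the path
#' carries end to end).  Ties are broken by larger cluster size, then lower
#' cluster id.
#'
#' @param graph a [PathwayGraph-class].
#' @return List with `clusters` (cluster id per level) and `flow` (the
#'   bottleneck fraction of trajectories).
#' @export
dominantPathway <- function(graph) {
  nodes <- graph@nodes; edges <- graph@edges
  L <- max(nodes$level)
  # DP over levels: best bottleneck reaching each node
  best <- list()
  for (cl in nodes$cluster[nodes$level == 1])
    best[[paste(1, cl)]] <- list(flow = Inf, path = cl)
  for (l in seq_len(L - 1)) {
    e <- edges[edges$fromLevel == l, , drop = FALSE]
    nxt <- list()
    for (r in seq_len(nrow(e))) {
      from <- best[[paste(l, e$fromCluster[r])]]
      if (is.null(from)) next
      fl <- min(from$flow, e$weight[r])
      keynext <- paste(l + 1, e$toCluster[r])
      better <- is.null(nxt[[keynext]]) || fl > nxt[[keynext]]$flow
      if (better)
        nxt[[keynext]] <- list(flow = fl, path = c(from$path, e$toCluster[r]))
    }
    best <- nxt
  }
  if (!length(best)) stop("no complete path through the graph")
  flows <- vapply(best, function(b) b$flow, numeric(1))
  cand <- which(flows == max(flows))
  if (length(cand) > 1) {
    # ties: larger terminal cluster size, then lower cluster id
    endcl <- vapply(best[cand], function(b) tail(b$path, 1), numeric(1))
    sizes <- vapply(endcl, function(cl) {
      s <- nodes$size[nodes$level == L & nodes$cluster == cl]
      if (length(s)) s[1] else 0L
    }, numeric(1))
    cand <- cand[order(-sizes, endcl)][1]
  }
  sel <- best[[cand[1]]]
  list(clusters = sel$path, flow = sel$flow)
}

#' Cross-model TM and RMSD curves with bootstrap bands
#'
#' Per Q bin, the mean pairwise TM-score and C-alpha RMSD between the
#' dominant-cluster members of a reference model ensemble and another
#' model's ensemble, over the reference model's folded segment.  Bootstrap
#' resampling of frame pairs yields the error bands.
#'
#' @param trajsA,trajsB trajectory lists of the reference model A and the
#'   compared model B (same residue count).
#' @param map contact map of the reference model (used for Q and segments).
#' @param qGrid Q bin centers.
#' @param tol frame-selection tolerance.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `Q`, `meanTM`, `semTM`, `rmsd`,
#'   `semRMSD`, `nPairs`, `segStart`, `segEnd`.
#' @export
crossModelAlignment <- function(trajsA, trajsB, map,
                                qGrid = seq(0.2, 0.8, by = 0.2), tol = 0.05,
                                nBoot = 1000L, seed = 1L) {
  profA <- residueProfile(trajsA, map, dQ = 0.05)
  binsA <- as.numeric(colnames(profA))
  set.seed(seed)
  rows <- list()
  for (q in qGrid) {
    frA <- framesAtQ(trajsA, map, q, tol)
    frB <- framesAtQ(trajsB, map, q, tol)
    if (!length(frA) || !length(frB)) next
    seg <- foldedSegment(profA[, which.min(abs(binsA - q))])
    if (is.na(seg$start) || seg$end - seg$start + 1 < 3) next
    sel <- seg$start:seg$end
    pairs <- expand.grid(a = seq_along(frA), b = seq_along(frB))
    tms <- rmsds <- numeric(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      xa <- frA[[pairs$a[r]]][sel, , drop = FALSE]
      xb <- frB[[pairs$b[r]]][sel, , drop = FALSE]
      tms[r] <- tmScore(xa, xb)$score
      rmsds[r] <- kabschRMSD(xa, xb)
    }
    bootTM <- bootRMSD <- numeric(nBoot)
    for (bb in seq_len(nBoot)) {
      idx <- sample.int(nrow(pairs), replace = TRUE)
      bootTM[bb] <- mean(tms[idx]); bootRMSD[bb] <- mean(rmsds[idx])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      Q = q, meanTM = mean(tms), semTM = sd(bootTM),
      rmsd = mean(rmsds), semRMSD = sd(bootRMSD),
      nPairs = nrow(pairs), segStart = seg$start, segEnd = seg$end)
  }
  do.call(rbind, rows)
}

#' Persistence scores and cross-model unfolding-order correlation
#'
#' Each residue's persistence score is the Q value at which its profile
#' first drops below 0.5, scanning from Q = 1 downward (residues that never
#' drop score 0, the most persistent end of the scale).  Strand scores are
#' means over the supplied strand residue ranges, and the Pearson
#' correlation of strand scores between two models quantifies how similar
#' their unfolding orders are.
#'
#' @param profileA,profileB per-residue profile matrices from
#'   [residueProfile()] (same residue count).
#' @param strandRanges list of integer vectors (residue indices per strand).
#' @return List with `r` (Pearson correlation), `scoresA`, `scoresB`
#'   (strand score vectors) and `persistenceA`, `persistenceB` (per
#'   residue).
#' @export
unfoldingOrderCorrelation <- function(profileA, profileB, strandRanges) {
  pA <- .persistence_scores(profileA)
  pB <- .persistence_scores(profileB)
  sA <- vapply(strandRanges, function(rg) mean(pA[rg], na.rm = TRUE), numeric(1))
  sB <- vapply(strandRanges, function(rg) mean(pB[rg], na.rm = TRUE), numeric(1))
  list(r = cor(sA, sB), scoresA = sA, scoresB = sB,
       persistenceA = pA, persistenceB = pB)
}

# per-residue Q at which the profile first drops below 0.5, scanning from
# high Q down; 0 when it never drops
.persistence_scores <- function(prof) {
  bins <- as.numeric(colnames(prof))
  o <- order(bins, decreasing = TRUE)
  bins_desc <- bins[o]
  apply(prof[, o, drop = FALSE], 1, function(row) {
    ok <- !is.na(row)
    hit <- which(ok & row < 0.5)[1]
    if (is.na(hit)) 0 else bins_desc[hit]
  })
}
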