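# TM-score, clustering and pathway-graph machinery.

test_that("TM-score is 1 for identical fragments and ~0.5 at the d0 shell", {
  set.seed(1)
  A <- matrix(rnorm(25 * 3, sd = 0.8), ncol = 3)
  r <- tmScore(A, A)
  expect_equal(r$score, 1, tolerance = 1e-9)
  expect_true(all(r$d < 1e-6))
  # displace every residue by d0 in a direction pattern that neither
  # translation nor rotation can undo: the identity superposition then
  # leaves every d_i = d0 and the score sits at the midpoint
  d0 <- tmD0(25)
  delta0 <- matrix(rnorm(75), ncol = 3)
  Am <- sweep(A, 2, colMeans(A))
  for (it in 1:200) {
    delta0 <- delta0 - Am %*% solve(t(Am) %*% Am, t(Am) %*% delta0)
    delta0 <- sweep(delta0, 2, colMeans(delta0))
    delta0 <- delta0 / sqrt(rowSums(delta0^2)) * (d0 / 10)  # nm
  }
  B <- A + delta0
  rB <- tmScore(A, B)
  expect_gte(rB$score, 0.5 - 1e-6)
  expect_lt(abs(rB$score - 0.5), 0.05)
})

test_that("TM-score matches the exhaustive-superposition oracle", {
  set.seed(2)
  for (rep in 1:4) {
    n <- sample(5:8, 1)
    A <- matrix(rnorm(n * 3, sd = 0.5), ncol = 3)
    # decoys: partial distortion plus a random rigid motion
    B <- A + matrix(rnorm(n * 3, sd = 0.15 * rep), ncol = 3)
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3)
    B <- B %*% Rz + matrix(runif(3), n, 3, byrow = TRUE)
    got <- tmScore(A, B, LRef = n)$score
    want <- bruteTM(A, B, LRef = n)
    expect_lt(abs(got - want), 0.01)
  }
})

test_that("TM-score rejects degenerate fragments and mismatched lengths", {
  A <- matrix(rnorm(9), 3)
  expect_error(tmScore(A, matrix(rnorm(12), 4)), "equal residue counts")
  expect_error(tmScore(A[1:2, ], A[1:2, ]), "3")
})

test_that("folded segments honor the 10-residue gap rule", {
  prof <- rep(0.9, 50)
  seg <- foldedSegment(prof)
  expect_equal(c(seg$start, seg$end), c(1, 50))
  # 15-residue sub-threshold gap splits; the larger strict run wins
  prof2 <- c(rep(0.9, 30), rep(0.1, 15), rep(0.9, 15))
  seg2 <- foldedSegment(prof2)
  expect_equal(c(seg2$start, seg2$end), c(1, 30))
  # an 8-residue internal dip is spanned
  prof3 <- c(rep(0.9, 20), rep(0.3, 8), rep(0.9, 22))
  seg3 <- foldedSegment(prof3)
  expect_equal(c(seg3$start, seg3$end), c(1, 50))
  # nothing above threshold: flagged empty
  seg4 <- foldedSegment(rep(0.2, 10))
  expect_true(is.na(seg4$start))
})

test_that("all-against-all matrices are symmetric with unit diagonal", {
  set.seed(3)
  base <- matrix(rnorm(30 * 3, sd = 0.6), ncol = 3)
  frames <- list(a = base, b = base + rnorm(90, sd = 0.02),
                 c = base[, c(1, 2, 3)] + rnorm(90, sd = 0.3),
                 d = matrix(rnorm(90, sd = 0.6), ncol = 3))
  M <- allVsAllTM(frames)
  expect_equal(diag(M), c(a = 1, b = 1, c = 1, d = 1))
  expect_lt(max(abs(M - t(M))), 1e-12)
  # identical frames give a matrix of ones
  M1 <- allVsAllTM(list(x = base, y = base, z = base))
  expect_true(all(abs(M1 - 1) < 1e-9))
  # block structure matches pairwise calls
  expect_equal(M["a", "d"], tmScore(frames$a, frames$d)$score,
               tolerance = 1e-12)
})

test_that("clustering by TM respects the cutoff and is permutation-invariant", {
  M1 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  cs1 <- clusterByTM(M1)
  expect_equal(max(cs1@assignments), 1)
  # two blocks: within 0.9, between 0.1 -> exactly two clusters at 0.6
  tm <- matrix(0.1, 6, 6)
  tm[1:3, 1:3] <- 0.9; tm[4:6, 4:6] <- 0.9
  diag(tm) <- 1
  dimnames(tm) <- list(letters[1:6], letters[1:6])
  cs <- clusterByTM(tm, cutoff = 0.6)
  expect_equal(max(cs@assignments), 2)
  expect_equal(unname(cs@assignments[1:3]), rep(1L, 3))
  expect_equal(unname(cs@assignments[4:6]), rep(2L, 3))
  # centroids are members of their clusters
  for (cl in 1:2)
    expect_true(cs@centroids[cl] %in% cs@members[[cl]])
  # permutation invariance of the induced partition
  perm <- c(4, 1, 6, 2, 5, 3)
  tmP <- tm[perm, perm]
  csP <- clusterByTM(tmP, cutoff = 0.6)
  same <- outer(cs@assignments[rownames(tmP)], cs@assignments[rownames(tmP)],
                "==")
  sameP <- outer(csP@assignments, csP@assignments, "==")
  expect_true(all(same == sameP))
})

test_that("pathway graphs conserve trajectory flow", {
  mkset <- function(assign, Q) {
    k <- max(assign)
    members <- lapply(seq_len(k), function(cl) which(assign == cl))
    new("ClusterSet", Q = Q, assignments = assign,
        centroids = vapply(members, function(m) m[[1]], integer(1)),
        members = members)
  }
  ids <- sprintf("t%02d", 1:20)
  # all 20 together, then a 15/5 split, then three groups
  a1 <- setNames(rep(1L, 20), ids)
  a2 <- setNames(c(rep(1L, 15), rep(2L, 5)), ids)
  a3 <- setNames(c(rep(1L, 10), rep(2L, 5), rep(3L, 5)), ids)
  g <- pathwayGraph(list(mkset(a1, 0.8), mkset(a2, 0.5), mkset(a3, 0.2)))
  e12 <- g@edges[g@edges$fromLevel == 1, ]
  expect_equal(sort(e12$weight), c(0.25, 0.75))
  # conservation: outgoing weight at each node equals its share
  for (l in 1:2) {
    for (cl in unique(g@nodes$cluster[g@nodes$level == l])) {
      out <- sum(g@edges$weight[g@edges$fromLevel == l &
                                g@edges$fromCluster == cl])
      share <- g@nodes$fraction[g@nodes$level == l & g@nodes$cluster == cl]
      expect_equal(out, share)
    }
  }
  dom <- dominantPathway(g)
  expect_equal(dom$clusters, c(1, 1, 1))
  expect_equal(dom$flow, 0.5)
  # a single shared sequence carries full flow
  g1 <- pathwayGraph(list(mkset(a1, 0.8), mkset(a1, 0.5)))
  expect_equal(dominantPathway(g1)$flow, 1)
})

test_that("scripted single-order ensembles yield one dominant pathway", {
  sys <- toy_system()
  ord <- c(31:40, 1:10, 30:11)
  trajs <- lapply(1:8, function(s)
    scriptedUnfoldingTrajectory(sys$structure, ord, nFrames = 21, seed = s,
                                runId = sprintf("tr%02d", s)))
  prof <- residueProfile(trajs, sys$map, dQ = 0.1)
  bins <- as.numeric(colnames(prof))
  sets <- list()
  for (q in c(0.7, 0.5, 0.3)) {
    fr <- framesAtQ(trajs, sys$map, q, tol = 0.08)
    seg <- foldedSegment(prof[, which.min(abs(bins - q))])
    sets[[length(sets) + 1L]] <- clusterByTM(allVsAllTM(fr, seg), Q = q)
  }
  dom <- dominantPathway(pathwayGraph(sets))
  expect_gte(dom$flow, 0.9)
})

test_that("mean TM vs Q separates coherent from shuffled unfolding", {
  sys <- toy_system()
  ord <- c(31:40, 1:10, 30:11)
  coh <- lapply(1:6, function(s)
    scriptedUnfoldingTrajectory(sys$structure, ord, nFrames = 21, seed = s,
                                runId = sprintf("c%02d", s)))
  shuf <- lapply(1:6, function(s) {
    set.seed(100 + s)
    scriptedUnfoldingTrajectory(sys$structure, sample(40), nFrames = 21,
                                seed = 200 + s,
                                runId = sprintf("s%02d", s))
  })
  grid <- c(0.3, 0.5, 0.7)
  mc <- meanTMvsQ(coh, sys$map, qGrid = grid, tol = 0.08)
  ms <- meanTMvsQ(shuf, sys$map, qGrid = grid, tol = 0.08)
  common <- intersect(mc$Q, ms$Q)
  expect_gt(length(common), 0)
  for (q in common)
    expect_gt(mc$meanTM[mc$Q == q], ms$meanTM[ms$Q == q])
})

test_that("the sliding-window reference curve starts at (1, 1)", {
  s <- generateToyStructure(30, seed = 1)
  m <- buildNativeContactMap(s)
  wrc <- windowReferenceCurve(s, m, dQ = 0.2, minLen = 6, maxPerBin = 6,
                              seed = 1)
  expect_gte(wrc$meanTM[which.max(wrc$Q)], 0.9)
  expect_true(all(wrc$meanTM >= 0 & wrc$meanTM <= 1))
  # two disjoint windows share no residues: TM defined as 0
  x1 <- matrix(NA_real_, 30, 3); x1[1:10, ] <- coords(s)[1:10, ]
  x2 <- matrix(NA_real_, 30, 3); x2[15:24, ] <- coords(s)[15:24, ]
  common <- sum(complete.cases(x1) & complete.cases(x2))
  expect_equal(common, 0)
})

test_that("cross-model curves are exact for identical/rotated ensembles", {
  sys <- toy_system()
  ord <- c(31:40, 1:10, 30:11)
  # identical trajectories (same seed) so every cross pair coincides
  ens <- lapply(1:4, function(s)
    scriptedUnfoldingTrajectory(sys$structure, ord, nFrames = 21, seed = 1,
                                runId = sprintf("a%02d", s)))
  cm <- crossModelAlignment(ens, ens, sys$map, qGrid = c(0.4, 0.7),
                            nBoot = 50, seed = 1)
  expect_true(all(cm$rmsd < 1e-6))
  expect_equal(cm$meanTM, rep(1, nrow(cm)), tolerance = 1e-9)
  # rigidly rotated ensemble B is indistinguishable after superposition
  th <- pi / 5
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  ensR <- lapply(ens, function(tr) {
    tr2 <- tr
    for (k in seq_len(nFrames(tr))) tr2@coords[, , k] <- tr@coords[, , k] %*% Rz
    tr2
  })
  cmR <- crossModelAlignment(ens, ensR, sys$map, qGrid = c(0.4, 0.7),
                             nBoot = 50, seed = 1)
  expect_equal(cmR$rmsd, cm$rmsd, tolerance = 1e-6)
  expect_equal(cmR$meanTM, cm$meanTM, tolerance = 1e-6)
})

test_that("per-atom Gaussian noise shows up as ~sigma*sqrt(3) RMSD", {
  set.seed(9)
  A <- matrix(rnorm(200 * 3, sd = 1), ncol = 3)
  sigma <- 0.05
  B <- A + matrix(rnorm(600, sd = sigma), ncol = 3)
  expect_equal(kabschRMSD(A, B), sigma * sqrt(3), tolerance = 0.1)
})

test_that("unfolding-order correlations behave at the extremes", {
  # two synthetic profiles over a 0..1 Q grid
  bins <- seq(0, 1, by = 0.05)
  mkprof <- function(persist) {
    # residue k keeps Q_k = 1 until Q < persist[k], then 0
    m <- t(vapply(persist, function(p) as.numeric(bins >= p), numeric(length(bins))))
    colnames(m) <- bins
    m
  }
  pers <- bins[4:15]   # grid-aligned values: quantization-free
  pA <- mkprof(pers)
  strands <- list(1:4, 5:8, 9:12)
  same <- unfoldingOrderCorrelation(pA, pA, strands)
  expect_equal(same$r, 1)
  pB <- mkprof(rev(pers))
  opp <- unfoldingOrderCorrelation(pA, pB, strands)
  expect_equal(opp$r, -1)
  # partially permuted orders match a hand-computed Pearson correlation
  persC <- pers[c(2, 1, 3, 4, 6, 5, 7, 8, 10, 9, 12, 11)]
  pC <- mkprof(persC)
  res <- unfoldingOrderCorrelation(pA, pC, strands)
  sA <- vapply(strands, function(rg) mean(res$persistenceA[rg]), numeric(1))
  sC <- vapply(strands, function(rg) mean(res$persistenceC <- res$persistenceB[rg]),
               numeric(1))
  expect_equal(res$r, cor(sA, sC), tolerance = 1e-12)
})
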