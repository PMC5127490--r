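# Independent reference implementations used as oracles, plus small fixture
# builders.  These deliberately avoid the package's vectorized code paths.

# brute-force double-loop Q: enumerate every native pair explicitly
bruteQ <- function(x, map, cdef = map@cdef) {
  p <- map@pairs
  tot <- 0
  for (t in seq_len(nrow(p))) {
    r <- sqrt(sum((x[p$i[t], ] - x[p$j[t], ])^2))
    tot <- tot + p$weight[t] / (1 + exp(cdef@beta0 * (r - cdef@lambda * p$r0[t])))
  }
  tot / map@totalWeight
}

# brute-force double-loop non-native count over all moiety pairs
bruteNnn <- function(x, map, cdef = map@cdef) {
  res <- map@moietyResidues
  n <- length(res)
  natkey <- paste(map@pairs$i, map@pairs$j)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (res[j] - res[i] < cdef@minSeparation) next
      if (paste(i, j) %in% natkey) next
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      tot <- tot + 1 / (1 + exp(cdef@beta0 * (r - cdef@lambda * cdef@R0)))
    }
  }
  tot
}

# exhaustive TM-score oracle: SO(3) Euler grid, centroid translation,
# then the same d < d0 Kabsch refinement loop as the main algorithm
bruteTM <- function(a, b, LRef = nrow(a), step = 20) {
  A <- a * 10; B <- b * 10
  d0 <- pullscope::tmD0(LRef)
  kabsch <- function(X, Y) {
    cx <- colMeans(X); cy <- colMeans(Y)
    C <- t(sweep(Y, 2, cy)) %*% sweep(X, 2, cx)
    s <- svd(C)
    R <- s$u %*% diag(c(1, 1, sign(det(s$u) * det(s$v)))) %*% t(s$v)
    list(R = R, cx = cx, cy = cy)
  }
  score_for <- function(Bt) {
    di <- sqrt(rowSums((Bt - A)^2))
    sum(1 / (1 + (di / d0)^2)) / LRef
  }
  rotmat <- function(a1, a2, a3) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
    Rz(a1) %*% Ry(a2) %*% Rz(a3)
  }
  best <- -Inf
  angs <- seq(0, 2 * pi - 1e-9, by = step * pi / 180)
  tilts <- seq(0, pi, by = step * pi / 180)
  cb <- colMeans(B); ca <- colMeans(A)
  Bm <- sweep(B, 2, cb)
  for (a1 in angs) for (a2 in tilts) for (a3 in angs) {
    Bt <- sweep(Bm %*% rotmat(a1, a2, a3), 2, -ca)
    sc <- score_for(Bt)
    if (sc > best) best <- sc
    # refinement from this start
    for (it in 1:15) {
      di <- sqrt(rowSums((Bt - A)^2))
      dcut <- d0
      sel <- which(di < dcut)
      while (length(sel) < 3 && dcut < 100) { dcut <- dcut + 0.5; sel <- which(di < dcut) }
      if (length(sel) < 3) break
      sup <- kabsch(A[sel, , drop = FALSE], B[sel, , drop = FALSE])
      Bt2 <- sweep(sweep(B, 2, sup$cy) %*% sup$R, 2, -sup$cx)
      sc2 <- score_for(Bt2)
      if (sc2 > best) best <- sc2
      if (max(abs(Bt2 - Bt)) < 1e-9) break
      Bt <- Bt2
    }
  }
  best
}

# AR(1) series with marginal variance 1
ar1_series <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  x
}

# C-alpha structure from explicit coordinates
caStructure <- function(xyz, resno = seq_len(nrow(xyz))) {
  Structure(data.frame(moiety_id = paste0(resno, ":CA"), resno = resno,
                       role = "Ca", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE), resolution = "Ca")
}

# shared toy system, built once per test run
toy_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- generateToyStructure(40, seed = 1)
      cache <<- list(structure = s,
                     model = buildCaGoModel(s),
                     map = buildNativeContactMap(s),
                     Tf = 1.36)  # from the bundled melting calibration
    }
    cache
  }
})

# write a small PDB text fixture, returns the path
write_pdb_fixture <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, elem = substr(name, 1, 1), alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0, elem)
}
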