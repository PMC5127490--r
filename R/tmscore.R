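# TM-score structural similarity for same-sequence conformations.
#
# Residue correspondence is fixed (identical sequences); only the rigid
# superposition is optimized, by the standard iterative seed-fragment
# search.  Scores use the length-dependent normalization
# d0 = 1.24 (N - 15)^(1/3) - 1.8 Angstrom, floored at 0.5 A.

#' TM-score normalization length
#' @param LRef number of residues in the reference structure.
#' @return d0 in Angstrom (floor 0.5).
#' @export
tmD0 <- function(LRef) {
  if (LRef <= 15) return(0.5)  # formula turns negative/complex below N = 21
  max(0.5, 1.24 * (LRef - 15)^(1/3) - 1.8)
}

# Kabsch: rotation R and translation such that (Y - cy) R + cx ~ X
.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xm <- sweep(X, 2, cx); Ym <- sweep(Y, 2, cy)
  C <- t(Ym) %*% Xm
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, cx = cx, cy = cy)
}

.apply_sup <- function(Y, sup) sweep(sweep(Y, 2, sup$cy) %*% sup$R, 2, -sup$cx)

#' Root-mean-square deviation after optimal superposition
#'
#' @param a,b `[n, 3]` coordinate matrices (nm); rows with any `NA` in
#'   either structure are dropped from the superposition.
#' @return RMSD in nm.
#' @export
kabschRMSD <- function(a, b) {
  ok <- complete.cases(a) & complete.cases(b)
  if (sum(ok) < 3) stop("need at least 3 common residues")
  X <- a[ok, , drop = FALSE]; Y <- b[ok, , drop = FALSE]
  sup <- .kabsch(X, Y)
  sqrt(mean(rowSums((.apply_sup(Y, sup) - X)^2)))
}

#' TM-score between two same-sequence conformations
#'
#' \deqn{TM = \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0)^2}}
#' with \eqn{d_i} the distance between identical residues under the best
#' rigid superposition and L the reference length.  The superposition is
#' found by seeding from sliding fragments of several lengths, each refined
#' by iteratively re-selecting residues with \eqn{d_i < d_0} (growing the
#' selection cutoff when fewer than 3 residues qualify) until the selected
#' set is stable; the reported score is the maximum over all seeds.
#'
#' Rows of `a`/`b` may contain `NA` (missing residues of a partial
#' structure); they contribute distance infinity to the sum but still count
#' in L.
#'
#' @param a,b `[n, 3]` C-alpha coordinate matrices in nm, or
#'   [Structure-class] objects.
#' @param LRef reference length for the normalization (default: number of
#'   residues of `a` with coordinates).
#' @return List with `score`, `d0` (Angstrom), `rotation`, `translation`
#'   (applied to `b`), and `d` (per-residue distances, Angstrom).
#' @export
tmScore <- function(a, b, LRef = NULL) {
  if (is(a, "Structure")) a <- coords(a)
  if (is(b, "Structure")) b <- coords(b)
  if (nrow(a) != nrow(b))
    stop("same-sequence comparison requires equal residue counts")
  A <- a * 10; B <- b * 10  # nm -> Angstrom
  oka <- complete.cases(A); okb <- complete.cases(B)
  common <- which(oka & okb)
  if (is.null(LRef)) LRef <- sum(oka)
  if (length(common) < 3) stop("fewer than 3 common residues to superpose")
  if (LRef < 3) stop("fragment shorter than 3 residues")
  d0 <- tmD0(LRef)

  score_of <- function(sup) {
    Bt <- .apply_sup(B[common, , drop = FALSE], sup)
    di <- sqrt(rowSums((Bt - A[common, , drop = FALSE])^2))
    list(score = sum(1 / (1 + (di / d0)^2)) / LRef, d = di)
  }
  refine <- function(sup) {
    cur <- score_of(sup)
    best <- cur
    best_sup <- sup
    prev_sel <- integer()
    for (it in 1:30) {
      di <- cur$d
      dcut <- d0
      sel <- which(di < dcut)
      while (length(sel) < 3 && dcut < 100) {
        dcut <- dcut + 0.5
        sel <- which(di < dcut)
      }
      if (length(sel) < 3 || identical(sel, prev_sel)) break
      prev_sel <- sel
      sup <- .kabsch(A[common[sel], , drop = FALSE],
                     B[common[sel], , drop = FALSE])
      cur <- score_of(sup)
      if (cur$score > best$score) { best <- cur; best_sup <- sup }
    }
    list(score = best$score, d = best$d, sup = best_sup)
  }

  nC <- length(common)
  frag_lens <- if (nC <= 12) seq(3L, nC) else
    unique(pmax(4, c(nC, ceiling(nC / 2), ceiling(nC / 4))))
  frag_lens <- frag_lens[frag_lens <= nC]
  best <- NULL
  for (fl in frag_lens) {
    stride <- if (nC <= 12) 1L else max(1L, fl %/% 2L)
    offs <- unique(c(seq(1L, nC - fl + 1L, by = stride), nC - fl + 1L))
    for (o in offs) {
      idx <- common[o:(o + fl - 1L)]
      sup <- .kabsch(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
      r <- refine(sup)
      if (is.null(best) || r$score > best$score) best <- r
    }
  }
  # short fragments: also seed from every residue triple, since the best
  # superposition of dissimilar structures may align a non-contiguous set
  if (nC <= 10) {
    triples <- utils::combn(nC, 3)
    for (t in seq_len(ncol(triples))) {
      idx <- common[triples[, t]]
      sup <- .kabsch(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
      r <- refine(sup)
      if (r$score > best$score) best <- r
    }
  }
  dfull <- rep(Inf, nrow(A))
  dfull[common] <- best$d
  list(score = best$score, d0 = d0, rotation = best$sup$R,
       translation = c(best$sup$cx - best$sup$cy %*% best$sup$R),
       d = dfull)
}
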