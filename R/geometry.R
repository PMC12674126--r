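# Small-matrix geometry primitives: centers of mass, torsion angles, Kabsch
# least-squares superposition, residue matching and RMSD.

#' Center of mass of an atom set
#'
#' @param x N x 3 coordinate matrix (Angstrom), or a
#'   [chain_model][new_chain_model] (hydrogens are excluded for chains).
#' @param masses per-atom masses; taken from the chain when `x` is a
#'   `chain_model`, required otherwise when `weighting = "mass"`.
#' @param weighting `"mass"` (default) or `"geometric"` (unweighted mean).
#' @return length-3 numeric vector (Angstrom).
#' @export
#' @examples
#' center_of_mass(rbind(c(0, 0, 0), c(2, 0, 0)), weighting = "geometric")
center_of_mass <- function(x, masses = NULL, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (inherits(x, "chain_model")) {
    keep <- x$elesy != "H"
    if (is.null(masses)) masses <- x$mass[keep]
    x <- coords(x)[keep, , drop = FALSE]
  }
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("center of mass of an empty atom set", call. = FALSE)
  w <- if (weighting == "geometric") rep(1, nrow(x)) else {
    if (is.null(masses)) stop("masses required for mass weighting", call. = FALSE)
    as.numeric(masses)
  }
  if (length(w) != nrow(x)) stop("length(masses) != nrow(x)", call. = FALSE)
  as.numeric(colSums(x * w) / sum(w))
}

#' Signed torsion (dihedral) angle of four points
#'
#' Right-handed IUPAC convention: looking down the p2 -> p3 bond, a positive
#' angle is a clockwise rotation carrying the p1 branch onto the p4 branch.
#' Computed with the numerically stable atan2 formulation.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Angstrom).
#' @return angle in degrees, in (-180, 180].
#' @details Degenerate quadruples (collinear p1,p2,p3 or p2,p3,p4, or a
#'   zero-length central bond) have no defined torsion and raise an error.
#' @export
#' @examples
#' torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))  # 180 (anti)
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  nb2 <- vnorm(b2)
  if (nb2 < 1e-10) stop("undefined torsion: zero-length central bond", call. = FALSE)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 * max(1, vnorm(b1)) * nb2 ||
      vnorm(n2) < 1e-10 * max(1, vnorm(b3)) * nb2) {
    stop("undefined torsion: collinear points", call. = FALSE)
  }
  ang <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation mapping point set `P` onto `Q`
#' with minimum (weighted) RMSD. Reflections are suppressed by flipping the
#' sign of the smallest singular vector, so the returned rotation always has
#' determinant +1.
#'
#' @param P,Q N x 3 coordinate matrices of paired points (N >= 3).
#' @param weights optional non-negative per-pair weights.
#' @return an object of class `superposition`: list with `rotation` (3x3),
#'   `translation` (length 3, applied as `x' = R x + t`), `rmsd` (Angstrom)
#'   and `n_matched` (number of pairs).
#' @export
#' @examples
#' P <- matrix(rnorm(15), 5)
#' fit <- kabsch_fit(P, P)
#' fit$rmsd  # 0
kabsch_fit <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  if (n < 3L) stop("at least 3 point pairs required for superposition", call. = FALSE)
  if (nrow(Q) != n) stop("P and Q must pair the same number of points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights", call. = FALSE)
  pbar <- colSums(P * w) / sum(w)
  qbar <- colSums(Q * w) / sum(w)
  Pc <- sweep(P, 2L, pbar)
  Qc <- sweep(Q, 2L, qbar)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-12)) {
    stop("degenerate (rank-deficient) point set: superposition undetermined",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(qbar - R %*% pbar)
  Pfit <- sweep(Pc %*% t(R), 2L, qbar, "+")
  rmsd <- sqrt(sum(w * rowSums((Pfit - Q)^2)) / sum(w))
  structure(list(rotation = R, translation = t, rmsd = rmsd,
                 n_matched = n), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d matched atoms, rotation %.2f deg\n",
              x$rmsd, x$n_matched, rotation_angle(x$rotation)))
  invisible(x)
}

#' Pair equivalent atoms of two chains by author residue number
#'
#' Matches one named atom (default Calpha) per residue between two chains by
#' identical (author number, insertion code); altlocs are collapsed first with
#' the default policy. `trim = "iterative"` additionally removes, for up to 5
#' cycles, pairs deviating by more than twice the current fitted RMSD.
#'
#' @param a,b `chain_model` objects.
#' @param atom atom name to pair (default `"CA"`).
#' @param trim `"none"` (default) or `"iterative"`.
#' @param selection optional integer vector of author residue numbers to
#'   restrict the match to.
#' @return list with `P`, `Q` (paired coordinate matrices), `resno` (matched
#'   author numbers) and `n_matched`.
#' @export
match_residues <- function(a, b, atom = "CA", trim = c("none", "iterative"),
                           selection = NULL) {
  trim <- match.arg(trim)
  pick <- function(ch) {
    ch <- resolve_altlocs(ch)
    rows <- ch[trimws(ch$elety) == atom, , drop = FALSE]
    key <- paste(rows$resno, ifelse(is.na(rows$insert), "", rows$insert))
    rows <- rows[!duplicated(key), , drop = FALSE]
    list(rows = rows,
         key = paste(rows$resno, ifelse(is.na(rows$insert), "", rows$insert)))
  }
  A <- pick(a); B <- pick(b)
  common <- intersect(A$key, B$key)
  if (!is.null(selection)) {
    common <- common[A$rows$resno[match(common, A$key)] %in% selection]
  }
  if (length(common) < 3L) {
    stop("fewer than 3 common '", atom, "' residues between chains (",
         length(common), " found)", call. = FALSE)
  }
  ia <- match(common, A$key); ib <- match(common, B$key)
  P <- as.matrix(A$rows[ia, c("x", "y", "z")])
  Q <- as.matrix(B$rows[ib, c("x", "y", "z")])
  resno <- A$rows$resno[ia]
  ord <- order(resno)
  P <- P[ord, , drop = FALSE]; Q <- Q[ord, , drop = FALSE]
  resno <- resno[ord]
  if (trim == "iterative") {
    for (cycle in seq_len(5L)) {
      fit <- kabsch_fit(P, Q)
      Pf <- sweep(P %*% t(fit$rotation), 2L, fit$translation, "+")
      dev <- sqrt(rowSums((Pf - Q)^2))
      keep <- dev <= 2 * fit$rmsd
      if (all(keep) || sum(keep) < 3L) break
      P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
      resno <- resno[keep]
    }
  }
  dimnames(P) <- NULL; dimnames(Q) <- NULL
  list(P = P, Q = Q, resno = resno, n_matched = length(resno))
}

#' Superpose two chains and report RMSD over a selection
#'
#' Kabsch-fits chain `a` onto chain `b` using Calpha pairs from
#' `fit_selection`, then reports the RMSD over `report_selection` pairs
#' (which may differ: e.g. fit on SD3/SD4 and report the whole chain, the
#' standard way of exposing relative SD1/SD2 motion between actin
#' conformers).
#'
#' @param a,b `chain_model` objects.
#' @param fit_selection integer author residue numbers used for the fit
#'   (`NULL` = all common residues).
#' @param report_selection residue numbers the RMSD is reported over
#'   (`NULL` = same as `fit_selection`).
#' @param atom atom name to pair (default `"CA"`).
#' @param trim trimming policy for the fit pairs, see [match_residues()].
#' @return a `superposition` whose `rmsd`/`n_matched` refer to the report
#'   selection; the rotation/translation map `a` coordinates onto `b`'s
#'   frame.
#' @export
superpose_chains <- function(a, b, fit_selection = NULL,
                             report_selection = NULL, atom = "CA",
                             trim = c("none", "iterative")) {
  trim <- match.arg(trim)
  fitm <- match_residues(a, b, atom = atom, trim = trim,
                         selection = fit_selection)
  fit <- kabsch_fit(fitm$P, fitm$Q)
  rep_sel <- report_selection %||% fit_selection
  repm <- if (is.null(rep_sel) && trim == "none") fitm else {
    match_residues(a, b, atom = atom, trim = "none", selection = rep_sel)
  }
  Pf <- sweep(repm$P %*% t(fit$rotation), 2L, fit$translation, "+")
  rmsd <- sqrt(mean(rowSums((Pf - repm$Q)^2)))
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = rmsd, n_matched = repm$n_matched,
                 n_fit = fitm$n_matched), class = "superposition")
}
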