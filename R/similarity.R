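#' Kabsch superposition of two coordinate sets
#'
#' Least-squares optimal proper rotation (no reflection) and translation
#' superposing `coords_a` onto `coords_b`, computed via the SVD of the
#' cross-covariance of the centred point sets. The transform maps a point
#' row-vector `p` to `p %*% rotation + translation`.
#'
#' @param coords_a,coords_b n x 3 matrices of paired points (n >= 3,
#'   non-collinear).
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom).
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have equal dimensions")
  if (nrow(a) < 3) stop("at least 3 points are required")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  h <- crossprod(ac, bc)  # t(ac) %*% bc
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- ac %*% rot
  rmsd <- sqrt(mean(rowSums((moved - bc)^2)))
  trans <- cb - as.numeric(ca %*% rot)
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param coords n x 3 matrix.
#' @param sup A `superposition` from [kabsch()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

#' Length-dependent TM-score distance scale
#' @param L Protein length.
#' @return d0 in Angstrom, floored at 0.5.
#' @export
tm_d0 <- function(L) {
  x <- L - 15
  max(0.5, 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8)
}

#' Fixed-correspondence TM-score of a model against a native structure
#'
#' Length-normalized structural similarity in (0, 1] over C-alpha atoms
#' with positional residue correspondence (model and native must share the
#' sequence length; no alignment is attempted, which is exact for decoys
#' that model the full target sequence). The score is
#' `max (1/L) * sum 1 / (1 + (d_i/d0)^2)` over superpositions found by the
#' standard fragment-seeded search: seed windows of lengths L, L/2 and L/4
#' (at least 4 residues) at every start position, each refined by
#' iterating a Kabsch fit on the residues currently within d0 until the
#' inclusion set is stable (capped at `max_iter`).
#'
#' @param model,native [structure_model()]s of equal length (or n x 3
#'   C-alpha matrices).
#' @param max_iter Cap on inclusion-set refinement iterations per seed.
#' @return List of class `tm_result`: `tm`, `d0`, `aligned_length`.
#' @export
tm_score <- function(model, native, max_iter = 50L) {
  xa <- if (inherits(model, "structure_model")) model$ca else as.matrix(model)
  xb <- if (inherits(native, "structure_model")) native$ca else as.matrix(native)
  if (!all(dim(xa) == dim(xb))) {
    stop("model and native must have the same number of residues")
  }
  L <- nrow(xa)
  if (L < 3) stop("need at least 3 residues")
  d0 <- tm_d0(L)
  score_of <- function(idx) {
    # superpose on idx, score all residues, refine inclusion set
    best <- -Inf
    for (iter in seq_len(max_iter)) {
      if (length(idx) < 3) break
      sup <- kabsch(xa[idx, , drop = FALSE], xb[idx, , drop = FALSE])
      moved <- apply_superposition(xa, sup)
      di <- sqrt(rowSums((moved - xb)^2))
      s <- mean(1 / (1 + (di / d0)^2))
      if (s > best) best <- s
      newidx <- which(di < d0)
      if (length(newidx) < 3 || identical(newidx, idx)) break
      idx <- newidx
    }
    best
  }
  lens <- sort(unique(pmax(4L, as.integer(floor(L / c(1, 2, 4))))), decreasing = TRUE)
  lens <- lens[lens <= L]
  best <- -Inf
  for (len in lens) {
    for (start in seq_len(L - len + 1L)) {
      s <- score_of(start:(start + len - 1L))
      if (s > best) best <- s
    }
  }
  structure(list(tm = best, d0 = d0, aligned_length = L), class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("TM-score = %.4f (L = %d, d0 = %.2f A)\n",
              x$tm, x$aligned_length, x$d0))
  invisible(x)
}

#' Is a decoy a correct model of the native structure?
#'
#' A decoy is correct when its TM-score against the native is strictly
#' greater than the cutoff (0.5 by convention: above it the model has the
#' native fold).
#'
#' @param model,native [structure_model()]s of equal length.
#' @param cutoff TM-score cutoff (strict `>`).
#' @return Logical.
#' @export
is_correct_decoy <- function(model, native, cutoff = 0.5) {
  tm_score(model, native)$tm > cutoff
}
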