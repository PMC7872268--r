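# Kabsch least-squares superposition and RMSD utilities.

#' Optimal rigid superposition of two coordinate sets
#'
#' Kabsch algorithm via SVD; the returned rotation/translation minimise the
#' RMSD of `mobile` onto `ref` over all proper rigid transforms.
#'
#' @param mobile,ref m x 3 coordinate matrices (paired rows).
#' @return list with 3x3 `rotation`, length-3 `translation` (apply as
#'   `x %*% t(rotation) + translation`), and `rmsd`.
#' @export
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref))
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Superpose one BackboneList onto another
#'
#' @param mobile,ref `backbone_list`s of equal length.
#' @param atoms which atom sets to use (subset of `"n"`, `"ca"`, `"c"`,
#'   `"o"`).
#' @return list with `rotation`, `translation`, `rmsd` and `transformed`
#'   (the mobile backbone after applying the transform).
#' @export
superpose <- function(mobile, ref, atoms = c("n", "ca", "c", "o")) {
  if (length(mobile$seq) != length(ref$seq)) {
    stop("backbone lengths differ: ", length(mobile$seq), " vs ",
         length(ref$seq))
  }
  fit <- kabsch(bb_atom_matrix(mobile, atoms), bb_atom_matrix(ref, atoms))
  out <- transform_backbone(mobile, fit$rotation, fit$translation)
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, transformed = out)
}

#' Apply a rigid transform to a BackboneList
#' @param bb a `backbone_list`.
#' @param rotation 3x3 matrix.
#' @param translation length-3 vector.
#' @return transformed `backbone_list`.
#' @export
transform_backbone <- function(bb, rotation, translation) {
  tr <- function(m) {
    ok <- !is.na(m[, 1])
    m[ok, ] <- m[ok, , drop = FALSE] %*% t(rotation) +
      matrix(translation, sum(ok), 3, byrow = TRUE)
    m
  }
  bb$n <- tr(bb$n)
  bb$ca <- tr(bb$ca)
  bb$c <- tr(bb$c)
  bb$o <- tr(bb$o)
  bb$cb <- tr(bb$cb)
  bb
}

#' CA RMSD between two backbones
#' @param a,b `backbone_list`s of equal length.
#' @param superposed if `TRUE`, minimise over rigid transforms first;
#'   otherwise measure in the current frames.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b, superposed = FALSE) {
  if (length(a$seq) != length(b$seq)) {
    stop("backbone lengths differ: ", length(a$seq), " vs ", length(b$seq))
  }
  if (superposed) {
    kabsch(a$ca, b$ca)$rmsd
  } else {
    sqrt(mean(rowSums((a$ca - b$ca)^2)))
  }
}
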