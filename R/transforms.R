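#' Rigid-body transforms
#'
#' A rigid transform is a 6-degree-of-freedom map of world coordinates
#' (rotation plus translation), stored both as Euler parameters and as a 4x4
#' homogeneous matrix.  The Euler convention is intrinsic Z-Y-X: the rotation
#' block is `Rz(a) %*% Ry(b) %*% Rx(c)` for angles `rotation = c(a, b, c)` in
#' radians.  Translations are millimetres.
#'
#' @param rotation numeric(3), Euler angles (radians), intrinsic Z-Y-X.
#' @param translation numeric(3), offsets in mm.
#' @return An object of class `rigid_transform` with fields `rotation`,
#'   `translation` and `matrix` (4x4 homogeneous).
#' @examples
#' t1 <- rigid_transform(rotation = c(0.1, 0, 0), translation = c(1, 2, 3))
#' t2 <- rigid_invert(t1)
#' max(abs(rigid_compose(t1, t2)$matrix - diag(4)))  # ~ 1e-16
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)))
  m <- diag(4)
  m[1:3, 1:3] <- euler_zyx_to_rotation(rotation)
  m[1:3, 4] <- translation
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 matrix = m),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param m a 4x4 homogeneous rigid matrix (orthonormal rotation block,
#'   determinant +1).
#' @export
rigid_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)), all(is.finite(m)))
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("matrix is not a rigid transform (rotation block not orthonormal)")
  structure(list(rotation = rotation_to_euler_zyx(R),
                 translation = as.numeric(m[1:3, 4]),
                 matrix = m),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' @rdname rigid_transform
#' @param a,b `rigid_transform` objects; the composition applies `b` first.
#' @export
rigid_compose <- function(a, b) {
  rigid_from_matrix(a$matrix %*% b$matrix)
}

#' @rdname rigid_transform
#' @param x a `rigid_transform`.
#' @export
rigid_invert <- function(x) {
  R <- t(x$matrix[1:3, 1:3])
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- -R %*% x$matrix[1:3, 4]
  rigid_from_matrix(m)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rotation (rad):",
      paste(signif(x$rotation, 4), collapse = " "),
      "| translation (mm):",
      paste(signif(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

# Rz(a) Ry(b) Rx(c), intrinsic Z-Y-X
euler_zyx_to_rotation <- function(ang) {
  ca <- cos(ang[1]); sa <- sin(ang[1])
  cb <- cos(ang[2]); sb <- sin(ang[2])
  cc <- cos(ang[3]); sc <- sin(ang[3])
  Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cc, sc, 0, -sc, cc), 3, 3)
  Rz %*% Ry %*% Rx
}

# inverse of euler_zyx_to_rotation for pitch in (-pi/2, pi/2)
rotation_to_euler_zyx <- function(R) {
  b <- asin(-max(-1, min(1, R[3, 1])))
  a <- atan2(R[2, 1], R[1, 1])
  c <- atan2(R[3, 2], R[3, 3])
  c(a, b, c)
}

#' Read and write 4x4 transforms as plain text
#'
#' Transforms are serialized row-major as four whitespace-separated rows.
#'
#' @param x a `rigid_transform` (or 4x4 matrix) to write.
#' @param path file path.
#' @return `read_transform` returns a `rigid_transform`.
#' @export
write_transform <- function(x, path) {
  m <- if (inherits(x, "rigid_transform")) x$matrix else x
  write.table(format(m, digits = 17), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  rigid_from_matrix(m)
}
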