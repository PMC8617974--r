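#' Estimate a planar homography from point correspondences
#'
#' Computes the 3x3 projective transformation mapping image-plane points to
#' world-plane points by the normalized direct linear transform: both point
#' sets are translated to their centroid and scaled to mean distance
#' `sqrt(2)` (Hartley normalization), the 2n x 9 DLT system is solved by
#' SVD (exact for 4 correspondences, least squares for more), and the
#' result is denormalized and scaled so `H[3, 3] = 1`. World units are
#' whatever the correspondences are expressed in — meters by convention for
#' fence ground planes.
#'
#' @param image n x 2 matrix of image points (pixels), n >= 4, no three
#'   collinear.
#' @param world n x 2 matrix of corresponding world-plane points.
#' @return A 3x3 matrix of class `"homography"`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' H <- estimate_homography(sq, 2 * sq)  # pure scale: diag(2, 2, 1)
#' transform_points(H, cbind(3, 4))      # (6, 8)
#' @export
estimate_homography <- function(image, world) {
  image <- as.matrix(image); world <- as.matrix(world)
  if (nrow(image) != nrow(world))
    stop("image and world must have the same number of points")
  n <- nrow(image)
  if (n < 4L) stop("at least 4 correspondences are required")
  if (ncol(image) != 2L || ncol(world) != 2L)
    stop("points must be n x 2 matrices")
  if (!all(is.finite(image)) || !all(is.finite(world)))
    stop("correspondences must be finite")
  if (any_collinear_triple(image) || any_collinear_triple(world))
    stop("degenerate configuration: three correspondences are collinear")

  Ti <- hartley_norm(image)
  Tw <- hartley_norm(world)
  xi <- normalize_apply(Ti, image)
  xw <- normalize_apply(Tw, world)

  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- xi[i, 1]; y <- xi[i, 2]
    u <- xw[i, 1]; v <- xw[i, 2]
    A[2 * i - 1L, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]      <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9L)
  h <- sv$v[, 9L]
  Hn <- matrix(h, 3L, 3L, byrow = TRUE)
  H <- solve(Tw) %*% Hn %*% Ti
  if (abs(H[3L, 3L]) < 1e-12)
    stop("degenerate configuration: homography has vanishing scale")
  H <- H / H[3L, 3L]
  if (abs(det(H)) < 1e-12)
    stop("degenerate configuration: singular homography")
  structure(H, class = "homography")
}

any_collinear_triple <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n > 12L) return(FALSE)  # for larger sets, rank issues surface in the solve
  scale <- max(1, max(abs(pts)))
  for (i in seq_len(n - 2L)) for (j in seq.int(i + 1L, n - 1L))
    for (k in seq.int(j + 1L, n)) {
      a <- pts[j, ] - pts[i, ]; b <- pts[k, ] - pts[i, ]
      if (abs(a[1] * b[2] - a[2] * b[1]) < tol * scale^2) return(TRUE)
    }
  FALSE
}

hartley_norm <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  rbind(c(s, 0, -s * ctr[1]),
        c(0, s, -s * ctr[2]),
        c(0, 0, 1))
}

normalize_apply <- function(Tm, pts) {
  ph <- cbind(pts, 1) %*% t(Tm)
  ph[, 1:2, drop = FALSE] / ph[, 3]
}

#' Apply a homography to image points
#'
#' Projective application with perspective division: each point `(x, y)` is
#' lifted to homogeneous coordinates, multiplied by `H`, and divided by the
#' resulting third coordinate.
#'
#' @param h A `"homography"` (or any 3x3 matrix).
#' @param pts n x 2 matrix of points.
#' @return n x 2 matrix of mapped points.
#' @export
transform_points <- function(h, pts) {
  H <- unclass(h)
  stopifnot(is.matrix(H), all(dim(H) == c(3L, 3L)))
  pts <- matrix(as.numeric(pts), ncol = 2L)
  if (!all(is.finite(pts))) stop("points must be finite")
  ph <- cbind(pts, 1) %*% t(H)
  bad <- which(abs(ph[, 3]) < 1e-12)
  if (length(bad))
    stop(sprintf("point %d (%g, %g) maps to infinity (w = 0)",
                 bad[1], pts[bad[1], 1], pts[bad[1], 2]))
  ph[, 1:2, drop = FALSE] / ph[, 3]
}

#' Invert a homography
#'
#' @param a A `"homography"`.
#' @param b Unused.
#' @param ... Unused.
#' @return The inverse mapping, normalized so `H[3, 3] = 1`, as a
#'   `"homography"`.
#' @export
solve.homography <- function(a, b, ...) {
  Hi <- solve(unclass(a))
  structure(Hi / Hi[3L, 3L], class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> image -> world\n")
  print(unclass(x))
  invisible(x)
}

#' Root-mean-square reprojection error of a homography
#'
#' @param h A `"homography"`.
#' @param image,world Correspondences as in [estimate_homography()].
#' @return RMS of `|H(image) - world|` over the points.
#' @export
reprojection_rms <- function(h, image, world) {
  mapped <- transform_points(h, image)
  sqrt(mean(rowSums((mapped - as.matrix(world))^2)))
}
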