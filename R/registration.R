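#' Similarity (rotation + isotropic scale + translation) transform
#'
#' Maps a point `p = (x, y)` (x = column, y = row, pixel units) to
#' `s R p + t`.
#'
#' @param angle_rad Rotation angle (radians, counter-clockwise in x/y).
#' @param scale Isotropic scale, > 0.
#' @param translation Length-2 numeric `(tx, ty)`.
#' @param residual_rms Optional fit residual to carry along.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(angle_rad = 0, scale = 1, translation = c(0, 0),
                            residual_rms = NA_real_) {
  if (scale <= 0) stop("scale must be > 0")
  structure(list(angle_rad = angle_rad, scale = scale,
                 translation = as.numeric(translation),
                 residual_rms = residual_rms),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.4f rad, scale %.6g, t = (%.4g, %.4g), residual %.3g\n",
              x$angle_rad, x$scale, x$translation[1], x$translation[2],
              x$residual_rms))
  invisible(x)
}

transform_matrix <- function(tr) {
  R <- matrix(c(cos(tr$angle_rad), sin(tr$angle_rad),
                -sin(tr$angle_rad), cos(tr$angle_rad)), 2, 2)
  tr$scale * R
}

#' Apply a transform to points
#' @param tr A [rigid_transform()].
#' @param pts n x 2 matrix of `(x, y)` points.
#' @return n x 2 matrix of transformed points.
#' @export
transform_points <- function(tr, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(transform_matrix(tr)), 2, tr$translation, `+`)
}

#' Invert a similarity transform
#' @param tr A [rigid_transform()].
#' @export
invert_transform <- function(tr) {
  Ai <- solve(transform_matrix(tr))
  th <- atan2(Ai[2, 1], Ai[1, 1])
  s <- sqrt(Ai[1, 1]^2 + Ai[2, 1]^2)
  rigid_transform(th, s, as.numeric(-Ai %*% tr$translation))
}

#' Fit a similarity transform to fiducial landmark pairs
#'
#' Closed-form least-squares estimate (Procrustes/Umeyama) of rotation,
#' isotropic scale, and translation mapping source landmarks onto target
#' landmarks; exact (zero residual) whenever the pairs are truly related by a
#' similarity transform.
#'
#' @param src,dst n x 2 matrices of `(x, y)` landmark coordinates (n >= 2,
#'   source points not all coincident).
#' @return A [rigid_transform()] with `residual_rms` the root-mean-square
#'   landmark misfit after alignment.
#' @export
fit_landmark_transform <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) != nrow(dst)) stop("landmark lists must pair up")
  if (nrow(src) < 2) stop("need at least 2 landmark pairs")
  if (any(!is.finite(src)) || any(!is.finite(dst))) stop("landmarks must be finite")
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  X <- sweep(src, 2, mu_s); Y <- sweep(dst, 2, mu_d)
  var_s <- sum(X^2) / nrow(X)
  if (var_s < .Machine$double.eps) stop("coincident source landmarks")
  S <- crossprod(Y, X) / nrow(X)   # covariance dst' src
  sv <- svd(S)
  D <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% D %*% t(sv$v)
  s <- sum(diag(D) * sv$d) / var_s
  t <- mu_d - s * as.numeric(R %*% mu_s)
  th <- atan2(R[2, 1], R[1, 1])
  tr <- rigid_transform(th, s, t)
  res <- transform_points(tr, src) - dst
  tr$residual_rms <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Resample an image or mask through a similarity transform
#'
#' For each target pixel the inverse transform locates the source position;
#' masks are resampled nearest-neighbour, intensity images bilinearly.
#' Out-of-bounds samples take the background value.
#'
#' @param img Matrix (intensity), `rows x cols x k` array, or
#'   [lesion_mask()].
#' @param tr A [rigid_transform()] mapping source coordinates to target
#'   coordinates.
#' @param target_dim `(rows, cols)` of the output grid; defaults to the input
#'   shape.
#' @param interpolation `"auto"` (nearest for masks/logical, bilinear
#'   otherwise), `"nearest"`, or `"bilinear"`.
#' @param background Fill value outside the source support.
#' @return Resampled object of the same kind as the input.
#' @export
apply_transform <- function(img, tr, target_dim = NULL,
                            interpolation = c("auto", "nearest", "bilinear"),
                            background = 0) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(img, "lesion_mask")
  prov <- if (is_mask) img$provenance else NULL
  m <- if (is_mask) img$mask + 0 else img
  logical_in <- is.logical(m)
  if (logical_in) m <- m + 0
  if (interpolation == "auto")
    interpolation <- if (is_mask || logical_in) "nearest" else "bilinear"
  if (length(dim(m)) == 3) {
    out <- array(background, c(if (is.null(target_dim)) dim(m)[1:2] else target_dim,
                               dim(m)[3]))
    for (ch in seq_len(dim(m)[3]))
      out[, , ch] <- apply_transform(m[, , ch], tr, target_dim,
                                     interpolation, background)
    return(out)
  }
  if (is.null(target_dim)) target_dim <- dim(m)
  if (any(target_dim < 1)) stop("empty target grid")
  inv <- invert_transform(tr)
  tx <- matrix(seq_len(target_dim[2]) - 1, target_dim[1], target_dim[2],
               byrow = TRUE)
  ty <- matrix(seq_len(target_dim[1]) - 1, target_dim[1], target_dim[2])
  src <- transform_points(inv, cbind(as.vector(tx), as.vector(ty)))
  sx <- src[, 1]; sy <- src[, 2]
  out <- rep(background, length(sx))
  if (interpolation == "nearest") {
    ix <- round(sx) + 1; iy <- round(sy) + 1
    ok <- ix >= 1 & ix <= ncol(m) & iy >= 1 & iy <= nrow(m)
    out[ok] <- m[cbind(iy[ok], ix[ok])]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    # the upper neighbour is clamped at the far edge, where its weight is 0
    ok <- x0 >= 0 & x0 <= ncol(m) - 1 & y0 >= 0 & y0 <= nrow(m) - 1 &
      (x0 <= ncol(m) - 2 | fx < 1e-9) & (y0 <= nrow(m) - 2 | fy < 1e-9)
    i <- which(ok)
    if (length(i)) {
      y1 <- y0[i] + 1; x1 <- x0[i] + 1
      y2i <- pmin(y1 + 1, nrow(m)); x2i <- pmin(x1 + 1, ncol(m))
      v00 <- m[cbind(y1, x1)]
      v01 <- m[cbind(y1, x2i)]
      v10 <- m[cbind(y2i, x1)]
      v11 <- m[cbind(y2i, x2i)]
      out[i] <- v00 * (1 - fx[i]) * (1 - fy[i]) + v01 * fx[i] * (1 - fy[i]) +
        v10 * (1 - fx[i]) * fy[i] + v11 * fx[i] * fy[i]
    }
  }
  res <- matrix(out, target_dim[1], target_dim[2])
  if (is_mask) lesion_mask(res > 0.5, provenance = prov)
  else if (logical_in) res > 0.5
  else res
}
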