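#' Collapse vertex time courses to a single signed label time course
#'
#' The "PCA flip" reduction for source-localized data: an SVD of the
#' vertex-by-time matrix gives the dominant temporal mode (first right
#' singular vector), whose sign per vertex is carried by the first left
#' singular vector. Because dipole orientations flip sign across a sulcus,
#' a plain vertex average can cancel a coherent signal; the SVD route
#' recovers it regardless of per-vertex polarity. The output is rescaled
#' so its mean power equals the mean per-vertex power, and its global sign
#' is fixed deterministically: the largest-magnitude element of the first
#' left singular vector is made positive.
#'
#' @param vertices numeric matrix, vertices x time (at least 1 vertex and
#'   2 time samples).
#' @return numeric vector: the label time course.
#' @examples
#' tc <- sin(seq(0, 4 * pi, length.out = 200))
#' b <- rbind(tc, -tc)        # anti-phase pair: plain mean cancels
#' y <- pca_flip(b)
#' c(mean(y^2), mean(b^2))    # power preserved
#' @export
pca_flip <- function(vertices) {
  vertices <- as.matrix(vertices)
  nv <- nrow(vertices); nt <- ncol(vertices)
  if (nv < 1 || nt < 2) stop("need >= 1 vertex and >= 2 time samples")
  if (!all(is.finite(vertices))) stop("vertex data must be finite")
  if (all(vertices == 0)) {
    warning("all-zero vertex bundle; returning a zero time course")
    return(numeric(nt))
  }
  sv <- svd(vertices)
  u1 <- sv$u[, 1]
  v1 <- sv$v[, 1]
  if (u1[which.max(abs(u1))] < 0) {
    u1 <- -u1; v1 <- -v1
  }
  # mean power over vertices and time = sum(singular values^2) / (nv * nt)
  scale <- sqrt(sum(sv$d^2) / nv)
  scale * v1
}
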