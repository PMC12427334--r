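# Direct least-squares ellipse fitting (Fitzgibbon, Pilu & Fisher):
# minimise ||D a||^2 over conics a'x^2 + b'xy + c'y^2 + d'x + e'y + f' = 0
# subject to the ellipse-specific constraint 4ac - b^2 = 1, solved as a
# generalized eigenproblem on the scatter matrix. Points are centred and
# scaled first for numerical conditioning.

#' Fit an ellipse to 2D points by direct least squares
#'
#' @param pts n x 2 matrix of point coordinates, n >= 5.
#' @return List with semi-axes `a >= b`, `center` (length 2) and
#'   `angle_deg` (major-axis orientation). Errors if the best-fit conic is
#'   not an ellipse.
#' @export
fit_ellipse_lsq <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  abort_if(nrow(pts) < 5, "need at least 5 points to fit an ellipse")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  sc <- max(stats::sd(pts[, 1]), stats::sd(pts[, 2]))
  abort_if(!is.finite(sc) || sc == 0, "degenerate point set for ellipse fit")
  x <- (pts[, 1] - mx) / sc
  y <- (pts[, 2] - my) / sc

  D1 <- cbind(x^2, x * y, y^2)       # quadratic part
  D2 <- cbind(x, y, rep(1, length(x)))  # linear part
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C) for constraint matrix C = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # admissible eigenvector: 4ac - b^2 > 0
  ok <- which(apply(ev$vectors, 2, function(v) {
    v <- Re(v); 4 * v[1] * v[3] - v[2]^2 > 0
  }))
  abort_if(length(ok) == 0, "least-squares conic fit did not yield an ellipse")
  a1 <- Re(ev$vectors[, ok[1]])
  coef <- c(a1, Tm %*% a1)  # (A, B, C, D, E, F) in scaled frame

  A <- coef[1]; B <- coef[2] / 2; C <- coef[3]
  D <- coef[4] / 2; E <- coef[5] / 2; Fc <- coef[6]
  den <- A * C - B^2
  abort_if(den <= 0, "fitted conic is not an ellipse")
  cx <- (B * E - C * D) / den
  cy <- (B * D - A * E) / den
  num <- A * cx^2 + 2 * B * cx * cy + C * cy^2 +
    2 * D * cx + 2 * E * cy + Fc
  # eigen-decomposition of the quadratic form gives axes
  eq <- eigen(matrix(c(A, B, B, C), 2))
  lam <- eq$values
  abort_if(any(lam * (-num) <= 0), "fitted conic is degenerate")
  axes <- sqrt(-num / lam)  # semi-axes in scaled frame
  ord <- order(axes, decreasing = TRUE)
  major_vec <- eq$vectors[, ord[1]]
  list(a = axes[ord[1]] * sc,
       b = axes[ord[2]] * sc,
       center = c(cx * sc + mx, cy * sc + my),
       angle_deg = atan2(major_vec[2], major_vec[1]) * 180 / pi)
}
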