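#' Minimum-area enclosing ellipse (ellipsoid hull) of planar points
#'
#' Computes the minimum-area ellipse containing all points, the 2-D
#' "spanning ellipsoid" used to summarise a day's GPS coordinates, by
#' solving the dual D-optimal-design problem: maximise `log det X(u)`
#' over point weights `u` on the simplex (Khachiyan's formulation). The
#' solver is an active-set Newton iteration with column exchange, which
#' is robust where plain first-order ascent crawls (near-duplicate
#' boundary points, as produced by GPS noise at a revisited place).
#' Input is first reduced to its convex hull and whitened (the ellipse
#' is affine-covariant), and the final ellipse is rescaled so every
#' input point satisfies the containment inequality exactly.
#'
#' Degenerate inputs are handled explicitly: a single (possibly repeated)
#' point yields a zero-axis ellipse; collinear points yield a segment
#' (semi-minor axis 0, semi-major half the extent, area 0).
#'
#' @param points Two-column numeric matrix of planar coordinates (km).
#' @param tol Convergence tolerance on the relative optimality gap
#'   `max_i M_i / (d+1) - 1`.
#' @param max_iter Iteration cap; non-convergence raises an error naming
#'   the iteration count rather than returning a possibly-bad ellipse.
#' @return An object of class `lifespace_ellipse`: a list with `center`
#'   (length-2), `semi_major`, `semi_minor` (km), `orientation` (radians,
#'   direction of the major axis), `area` (km^2, equal to
#'   `pi * semi_major * semi_minor`), `iterations`, and `degenerate`.
#' @export
#' @examples
#' pts <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
#' e <- min_enclosing_ellipse(pts)
#' e$area # ~pi: the unit circle is the minimal ellipse through a unit diamond
min_enclosing_ellipse <- function(points, tol = 1e-7, max_iter = 10000L) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 1 || !all(is.finite(points))) {
    abort("`points` must be a finite n x 2 matrix with n >= 1")
  }
  pts <- points[!duplicated(points), , drop = FALSE]
  if (nrow(pts) > 3) {
    hull <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]),
                     error = function(e) seq_len(nrow(pts)))
    if (length(hull) >= 2) pts <- pts[hull, , drop = FALSE]
  }
  n <- nrow(pts)

  if (n == 1) {
    return(new_ellipse(pts[1, ], 0, 0, 0, 0L, degenerate = TRUE))
  }

  ctr0 <- colMeans(pts)
  x0 <- sweep(pts, 2, ctr0)
  sv <- svd(x0, nu = 0)
  if (n == 2 || sv$d[2] < 1e-8 * max(1, sv$d[1])) {
    # collinear: a segment along the principal direction
    dir <- sv$v[, 1]
    t <- drop(x0 %*% dir)
    center <- ctr0 + dir * (max(t) + min(t)) / 2
    return(new_ellipse(center, (max(t) - min(t)) / 2, 0,
                       atan2(dir[2], dir[1]), 0L, degenerate = TRUE))
  }

  # Whiten: highly eccentric sets (a day's travel is nearly a line) are
  # ill-conditioned in raw km; the MVEE maps back affinely.
  w_rot <- sv$v
  w_scl <- sv$d / sqrt(n)
  z <- x0 %*% w_rot %*% diag(1 / w_scl)

  sol <- mvee_weights(z, tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    abort(sprintf(
      "minimum enclosing ellipse did not converge after %d iterations (gap %.3g > tol %.3g)",
      sol$iterations, sol$gap, tol))
  }
  u <- sol$u

  center_z <- drop(crossprod(z, u))
  a_z <- solve(crossprod(z * u, z) - tcrossprod(center_z)) / 2
  # map ellipse back: z = (x - ctr0) %*% w_rot %*% diag(1/w_scl)
  t_mat <- w_rot %*% diag(1 / w_scl)
  a_mat <- t_mat %*% a_z %*% t(t_mat)
  a_mat <- (a_mat + t(a_mat)) / 2
  center <- ctr0 + drop(w_rot %*% diag(w_scl) %*% center_z)

  # rescale so containment holds exactly for every original point
  xc <- sweep(points, 2, center)
  mq <- max(rowSums((xc %*% a_mat) * xc))
  if (mq > 1) a_mat <- a_mat / mq

  e <- eigen(a_mat, symmetric = TRUE)
  semi <- 1 / sqrt(pmax(e$values, .Machine$double.xmin))
  # eigenvalues descending => semi ascending: semi[1] minor, semi[2] major
  major_dir <- e$vectors[, 2]
  new_ellipse(center, semi[2], semi[1], atan2(major_dir[2], major_dir[1]),
              sol$iterations)
}

# Dual D-optimal-design weights for the MVEE of whitened points `z`.
# Active-set strategy: Newton-equalise the leverages M_i = q_i' X^-1 q_i
# (q_i the lifted point) on the current support, then add the worst
# outside violator, until max M <= (d+1)(1+tol). In 2D the optimal
# support has at most 5 atoms, so the Newton systems are tiny.
mvee_weights <- function(z, tol = 1e-7, max_iter = 10000L) {
  n <- nrow(z)
  d <- 2
  q <- cbind(z, 1)
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1))
  s <- unique(apply(z %*% t(dirs), 2, which.max))
  if (length(s) < 3) s <- unique(c(s, seq_len(min(n, 3L))))
  u <- numeric(n)
  u[s] <- 1 / length(s)
  iters <- 0L
  gap <- Inf

  while (iters < max_iter) {
    # Newton iterations restricted to the support simplex
    for (inner in 1:60) {
      iters <- iters + 1L
      x <- crossprod(q * u, q)
      xin <- tryCatch(solve(x), error = function(e) NULL)
      if (is.null(xin)) break
      qs <- q[s, , drop = FALSE]
      g <- qs %*% xin %*% t(qs)
      m_s <- diag(g)
      if (max(abs(m_s - (d + 1))) <= tol * (d + 1) / 2) break
      k <- length(s)
      kkt <- rbind(cbind(-(g^2), 1), c(rep(1, k), 0))
      sol <- tryCatch(solve(kkt, c(-(m_s - (d + 1)), 0)),
                      error = function(e) NULL)
      if (is.null(sol)) break
      delta <- sol[seq_len(k)]
      step <- 1
      neg <- delta < 0
      if (any(neg)) step <- min(1, 0.95 * min(-u[s][neg] / delta[neg]))
      f0 <- determinant(x)$modulus
      repeat {
        u_new <- u
        u_new[s] <- u[s] + step * delta
        u_new[u_new < 0] <- 0
        u_new <- u_new / sum(u_new)
        ok <- tryCatch(
          determinant(crossprod(q * u_new, q))$modulus >= f0 - 1e-12,
          error = function(e) FALSE)
        if (ok || step < 1e-8) break
        step <- step / 2
      }
      u <- u_new
      s <- which(u > 1e-12)
      if (iters >= max_iter) break
    }
    x <- crossprod(q * u, q)
    xin <- tryCatch(solve(x), error = function(e) NULL)
    if (is.null(xin)) break
    m <- rowSums((q %*% xin) * q)
    gap <- max(m) / (d + 1) - 1
    if (gap <= tol) {
      return(list(u = u, gap = gap, iterations = iters, converged = TRUE))
    }
    j <- which.max(m)
    s <- sort(unique(c(s, j)))
    u[j] <- max(u[j], 1e-6)
    u <- u / sum(u)
  }
  list(u = u, gap = gap, iterations = iters, converged = FALSE)
}

new_ellipse <- function(center, semi_major, semi_minor, orientation,
                        iterations, degenerate = FALSE) {
  structure(
    list(center = unname(center),
         semi_major = semi_major,
         semi_minor = semi_minor,
         orientation = orientation,
         area = pi * semi_major * semi_minor,
         iterations = iterations,
         degenerate = degenerate),
    class = "lifespace_ellipse")
}

#' @export
print.lifespace_ellipse <- function(x, ...) {
  cat(sprintf(
    "<minimum enclosing ellipse> center (%.3f, %.3f) km, semi-axes %.3f x %.3f km, area %.3f km^2%s\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor, x$area,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
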