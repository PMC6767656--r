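# Structured triangular mesh of a disk with linear (P1) elements.
#
# The problem domain Omega is a disk of radius `radius` (cm). A regular
# square grid on [-R, R]^2 is mapped radially so that concentric L-infinity
# squares morph smoothly into circles: the identity inside t <= R/2 (so the
# imaging domain D keeps an undistorted regular grid) blending to an exact
# circle at the rim, where a curvature-corrected first-order absorbing
# boundary condition is applied. The map is monotone along each ray, so no
# triangle inverts; a validity check is still run at construction.

blend_alpha <- function(t, t0, R) {
  s <- pmin(pmax((t - t0) / (R - t0), 0), 1)
  3 * s^2 - 2 * s^3
}

#' Build a triangulated disk mesh
#'
#' @param radius disk radius (cm); the absorbing boundary sits here.
#' @param h target maximum edge length (cm).
#' @return an object of class `csinet_mesh` with node coordinates (cm),
#'   triangle connectivity, boundary node indices, and cached element
#'   geometry used for finite-element assembly.
#' @export
disk_mesh <- function(radius, h) {
  if (h <= 0 || radius <= 0) stop_csinet("radius and h must be positive")
  n <- as.integer(ceiling(2 * radius / h))
  if (n < 8L) stop_csinet("mesh too coarse: edge bound %g cm cannot resolve a disk of radius %g cm", h, radius)
  if (n %% 2L == 1L) n <- n + 1L
  hs <- 2 * radius / n
  g <- seq(-radius, radius, length.out = n + 1L)
  qx <- rep(g, times = n + 1L)
  qy <- rep(g, each = n + 1L)
  t <- pmax(abs(qx), abs(qy))
  r2 <- sqrt(qx^2 + qy^2)
  a <- blend_alpha(t, radius / 2, radius)
  scl <- ifelse(r2 > 0, (1 - a) + a * t / r2, 1)
  nodes <- cbind(x = qx * scl, y = qy * scl)

  # two triangles per cell, counter-clockwise; the split diagonal follows the
  # quadrant so no triangle degenerates under the tangential compression of
  # the square-to-disk map
  ij <- function(i, j) (j - 1L) * (n + 1L) + i
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  v00 <- ij(i, j); v10 <- ij(i + 1L, j); v01 <- ij(i, j + 1L); v11 <- ij(i + 1L, j + 1L)
  cx <- g[i] + hs / 2; cy <- g[j] + hs / 2
  main_diag <- cx * cy >= 0
  tri <- rbind(
    cbind(ifelse(main_diag, v00, v10), ifelse(main_diag, v10, v11), ifelse(main_diag, v11, v01)),
    cbind(ifelse(main_diag, v00, v10), ifelse(main_diag, v11, v01), ifelse(main_diag, v01, v00)))

  bnd <- which(t >= radius - 1e-12)
  # perimeter edges in order (for the boundary mass matrix)
  side_b <- cbind(ij(seq_len(n), 1L), ij(seq_len(n) + 1L, 1L))
  side_r <- cbind(ij(n + 1L, seq_len(n)), ij(n + 1L, seq_len(n) + 1L))
  side_t <- cbind(ij(seq(n + 1L, 2L), n + 1L), ij(seq(n, 1L), n + 1L))
  side_l <- cbind(ij(1L, seq(n + 1L, 2L)), ij(1L, seq(n, 1L)))
  bedges <- rbind(side_b, side_r, side_t, side_l)

  m <- structure(list(
    nodes = nodes, tri = tri, radius = radius, h = hs, n = n, grid = g,
    boundary_nodes = bnd, boundary_edges = bedges,
    n_nodes = nrow(nodes), n_tri = nrow(tri)
  ), class = "csinet_mesh")
  m$elem <- element_geometry(m)
  if (any(m$elem$area <= 0))
    stop_csinet("mesh construction produced %d inverted triangles", sum(m$elem$area <= 0))
  m
}

#' @export
print.csinet_mesh <- function(x, ...) {
  cat(sprintf("<csinet_mesh> disk radius %.3g cm, %d nodes, %d triangles, h = %.3g cm\n",
              x$radius, x$n_nodes, x$n_tri, x$h))
  invisible(x)
}

# per-element P1 geometry: gradients of basis functions and areas
element_geometry <- function(mesh) {
  tr <- mesh$tri
  x1 <- mesh$nodes[tr[, 1], 1]; y1 <- mesh$nodes[tr[, 1], 2]
  x2 <- mesh$nodes[tr[, 2], 1]; y2 <- mesh$nodes[tr[, 2], 2]
  x3 <- mesh$nodes[tr[, 3], 1]; y3 <- mesh$nodes[tr[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  c_ <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  list(area = area, b = b, c = c_)
}

tri_triplets <- function(mesh) {
  tr <- mesh$tri
  list(i = as.vector(tr[, rep(1:3, each = 3)]),
       j = as.vector(tr[, rep(1:3, times = 3)]))
}

#' Stiffness matrix for P1 elements
#' @keywords internal
assemble_stiffness <- function(mesh) {
  e <- mesh$elem
  nt <- mesh$n_tri
  vals <- matrix(0, nt, 9)
  idx <- 1
  for (a in 1:3) for (b in 1:3) {
    vals[, idx] <- e$area * (e$b[, a] * e$b[, b] + e$c[, a] * e$c[, b])
    idx <- idx + 1
  }
  tp <- tri_triplets(mesh)
  Matrix::sparseMatrix(i = tp$i, j = tp$j, x = as.vector(vals),
                       dims = c(mesh$n_nodes, mesh$n_nodes))
}

#' Mass matrix weighted by a per-node coefficient (element-mean lumping of
#' the coefficient, consistent P1 mass within each element)
#' @keywords internal
assemble_mass <- function(mesh, w_nodes = NULL) {
  e <- mesh$elem
  w <- if (is.null(w_nodes)) rep(1, mesh$n_tri) else
    (w_nodes[mesh$tri[, 1]] + w_nodes[mesh$tri[, 2]] + w_nodes[mesh$tri[, 3]]) / 3
  base <- c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12
  vals <- outer(e$area * w, base)
  tp <- tri_triplets(mesh)
  M <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = as.vector(vals),
                            dims = c(mesh$n_nodes, mesh$n_nodes))
  if (is.complex(w)) {
    Mi <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = as.vector(outer(e$area * Im(w), base)),
                               dims = c(mesh$n_nodes, mesh$n_nodes))
    Mr <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = as.vector(outer(e$area * Re(w), base)),
                               dims = c(mesh$n_nodes, mesh$n_nodes))
    return(list(re = Mr, im = Mi))
  }
  M
}

#' Boundary (rim) mass matrix for the absorbing condition
#' @keywords internal
assemble_boundary_mass <- function(mesh) {
  be <- mesh$boundary_edges
  p1 <- mesh$nodes[be[, 1], , drop = FALSE]
  p2 <- mesh$nodes[be[, 2], , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  i <- c(be[, 1], be[, 2], be[, 1], be[, 2])
  j <- c(be[, 1], be[, 2], be[, 2], be[, 1])
  x <- c(len / 3, len / 3, len / 6, len / 6)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(mesh$n_nodes, mesh$n_nodes))
}

# --- point location -------------------------------------------------------

# invert the disk map: physical points -> square reference coordinates
inverse_disk_map <- function(mesh, pts) {
  R <- mesh$radius
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  if (any(r > R + 1e-9)) stop_csinet("points outside the mesh disk")
  ux <- ifelse(r > 0, pts[, 1] / r, 0)
  uy <- ifelse(r > 0, pts[, 2] / r, 0)
  m <- pmax(abs(ux), abs(uy))
  m[m == 0] <- 1
  # solve g(t) = t * ((1 - alpha(t))/m + alpha(t)) = r by bisection
  lo <- rep(0, length(r)); hi <- rep(R, length(r))
  direct <- m * r <= R / 2   # identity zone
  t <- m * r
  it <- which(!direct)
  if (length(it)) {
    lo <- rep(R / 2, length(it)); hi <- rep(R, length(it))
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      a <- blend_alpha(mid, R / 2, R)
      g <- mid * ((1 - a) / m[it] + a)
      too_low <- g < r[it]
      lo[too_low] <- mid[too_low]
      hi[!too_low] <- mid[!too_low]
    }
    t[it] <- (lo + hi) / 2
  }
  cbind(t * ux / m, t * uy / m)
}

#' Sparse interpolation matrix from mesh nodes to arbitrary points
#'
#' Rows are barycentric (linear basis) weights of the triangle containing
#' each point.
#'
#' @param mesh a `csinet_mesh`.
#' @param pts matrix of points (cm), one row per point, inside the disk.
#' @return sparse `nrow(pts) x n_nodes` matrix.
#' @export
interp_matrix <- function(mesh, pts) {
  pts <- as.matrix(pts)
  q <- inverse_disk_map(mesh, pts)
  n <- mesh$n; R <- mesh$radius; hs <- mesh$h
  ci <- pmin(pmax(floor((q[, 1] + R) / hs) + 1, 1), n)
  cj <- pmin(pmax(floor((q[, 2] + R) / hs) + 1, 1), n)
  np <- nrow(pts)
  best_tri <- integer(np); best_bar <- matrix(0, np, 3)
  best_q <- rep(-Inf, np)
  nx <- c(0L, -1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  ny <- c(0L, 0L, 0L, -1L, 1L, -1L, -1L, 1L, 1L)
  for (s in seq_along(nx)) {
    i <- pmin(pmax(ci + nx[s], 1L), n)
    j <- pmin(pmax(cj + ny[s], 1L), n)
    cell <- (j - 1L) * n + i
    for (half in 0:1) {
      tid <- cell + half * mesh$n_tri / 2
      bar <- barycentric(mesh, tid, pts)
      qual <- pmin(bar[, 1], pmin(bar[, 2], bar[, 3]))
      upd <- qual > best_q
      if (any(upd)) {
        best_q[upd] <- qual[upd]
        best_tri[upd] <- tid[upd]
        best_bar[upd, ] <- bar[upd, , drop = FALSE]
      }
    }
    if (all(best_q > -1e-9)) break
  }
  if (any(best_q < -1e-6))
    stop_csinet("point location failed for %d points (worst barycentric %.3g)",
                sum(best_q < -1e-6), min(best_q))
  best_bar[best_bar < 0] <- 0
  best_bar <- best_bar / rowSums(best_bar)
  Matrix::sparseMatrix(i = rep(seq_len(np), 3),
                       j = as.vector(mesh$tri[best_tri, ]),
                       x = as.vector(best_bar),
                       dims = c(np, mesh$n_nodes))
}

barycentric <- function(mesh, tid, pts) {
  tr <- mesh$tri[tid, , drop = FALSE]
  x1 <- mesh$nodes[tr[, 1], 1]; y1 <- mesh$nodes[tr[, 1], 2]
  x2 <- mesh$nodes[tr[, 2], 1]; y2 <- mesh$nodes[tr[, 2], 2]
  x3 <- mesh$nodes[tr[, 3], 1]; y3 <- mesh$nodes[tr[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  l1 <- ((x2 - pts[, 1]) * (y3 - pts[, 2]) - (x3 - pts[, 1]) * (y2 - pts[, 2])) / det
  l2 <- ((x3 - pts[, 1]) * (y1 - pts[, 2]) - (x1 - pts[, 1]) * (y3 - pts[, 2])) / det
  cbind(l1, l2, 1 - l1 - l2)
}

# --- complex sparse solver (real block embedding) -------------------------

#' Factorise a complex sparse system via its real 2n x 2n block embedding
#' @keywords internal
cfactor <- function(A_re, A_im) {
  B <- rbind(cbind(A_re, -A_im), cbind(A_im, A_re))
  list(lu = Matrix::lu(B), n = nrow(A_re))
}

#' Solve a factorised complex system for (possibly many) complex right-hand sides
#' @keywords internal
csolve <- function(fac, b) {
  b <- as.matrix(b)
  rhs <- rbind(Re(b), Im(b))
  x <- as.matrix(Matrix::solve(fac$lu, rhs))
  n <- fac$n
  out <- x[seq_len(n), , drop = FALSE] + 1i * x[n + seq_len(n), , drop = FALSE]
  out
}
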