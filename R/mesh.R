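# Triangulation of the study domain and linear finite-element assembly for
# the SPDE-GMRF construction.

#' Construct a triangle mesh from explicit vertices and triangles
#'
#' Validates indices, reorients triangles to positive signed area, and
#' rejects degenerate (zero-area) triangles.
#'
#' @param vertices n_v x 2 numeric matrix of (x, y) in km.
#' @param triangles n_t x 3 integer matrix of vertex indices.
#' @param inner logical flag per vertex: TRUE for inner-domain vertices,
#'   FALSE for the outer extension (defaults to all TRUE).
#' @return an object of class \code{wm_mesh}.
#' @export
mesh_create <- function(vertices, triangles, inner = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (ncol(vertices) != 2) stop("vertices must be an n x 2 matrix")
  if (nrow(vertices) < 3) stop("need at least 3 vertices")
  if (min(triangles) < 1 || max(triangles) > nrow(vertices)) {
    stop("triangle indices out of range")
  }
  areas <- triangle_signed_areas(vertices, triangles)
  flip <- areas < 0
  if (any(flip)) {
    triangles[flip, c(2, 3)] <- triangles[flip, c(3, 2)]
    areas[flip] <- -areas[flip]
  }
  if (any(areas <= 1e-14)) {
    stop("degenerate (zero-area) triangle(s): ",
         paste(which(areas <= 1e-14), collapse = ", "))
  }
  if (is.null(inner)) inner <- rep(TRUE, nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles,
                 areas = areas, inner = as.logical(inner)),
            class = "wm_mesh")
}

triangle_signed_areas <- function(v, tr) {
  x1 <- v[tr[, 1], 1]; y1 <- v[tr[, 1], 2]
  x2 <- v[tr[, 2], 1]; y2 <- v[tr[, 2], 2]
  x3 <- v[tr[, 3], 1]; y3 <- v[tr[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' @export
print.wm_mesh <- function(x, ...) {
  cat(sprintf("<wm_mesh> %d vertices (%d inner), %d triangles, area %.4g km^2\n",
              nrow(x$vertices), sum(x$inner), nrow(x$triangles), sum(x$areas)))
  invisible(x)
}

#' Triangulate a study region (or point set) on a regular lattice
#'
#' Builds a structured triangulated lattice over the inner domain plus an
#' outer buffer: a regular grid of vertices with each cell split into two
#' triangles. The lattice spacing is chosen so no inner edge (including
#' diagonals) exceeds \code{max_edge_km}; the buffer mitigates the Neumann
#' boundary inflation of the SPDE approximation and its vertices are flagged
#' as outer.
#'
#' @param x a [make_study_region()] object, or an n x 2 matrix / data.frame
#'   of points whose bounding box defines the inner domain.
#' @param max_edge_km maximum inner edge length, km (> 0).
#' @param buffer_km outer extension width, km (>= 0).
#' @return a \code{wm_mesh} with lattice metadata for O(1) point location.
#' @export
build_mesh <- function(x, max_edge_km, buffer_km = 0) {
  if (max_edge_km <= 0) stop("max_edge_km must be positive")
  if (buffer_km < 0) stop("buffer_km must be nonnegative")
  if (inherits(x, "wm_region")) {
    xlim <- x$xlim; ylim <- x$ylim
  } else {
    pts <- as.matrix(as.data.frame(x))
    if (nrow(pts) < 3) stop("need at least 3 points to define a domain")
    ctr <- scale(pts, scale = FALSE)
    if (qr(ctr)$rank < 2) stop("points are collinear; cannot triangulate")
    xlim <- range(pts[, 1]); ylim <- range(pts[, 2])
  }
  width <- max(diff(xlim), 1e-9); height <- max(diff(ylim), 1e-9)
  h_target <- max_edge_km / sqrt(2)  # diagonal edge = h * sqrt(2)
  nx_in <- max(1L, as.integer(ceiling(width / h_target - 1e-9)))
  ny_in <- max(1L, as.integer(ceiling(height / h_target - 1e-9)))
  hx <- width / nx_in; hy <- height / ny_in
  nbx <- if (buffer_km > 0) as.integer(ceiling(buffer_km / hx - 1e-9)) else 0L
  nby <- if (buffer_km > 0) as.integer(ceiling(buffer_km / hy - 1e-9)) else 0L
  gx <- xlim[1] + hx * seq(-nbx, nx_in + nbx)
  gy <- ylim[1] + hy * seq(-nby, ny_in + nby)
  nvx <- length(gx); nvy <- length(gy)
  vertices <- cbind(rep(gx, times = nvy), rep(gy, each = nvx))
  idx <- function(i, j) (j - 1L) * nvx + i
  tri <- vector("list", 2L * (nvx - 1L) * (nvy - 1L))
  k <- 0L
  for (j in seq_len(nvy - 1L)) {
    for (i in seq_len(nvx - 1L)) {
      v00 <- idx(i, j); v10 <- idx(i + 1L, j)
      v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
      tri[[k + 1L]] <- c(v00, v10, v11)
      tri[[k + 2L]] <- c(v00, v11, v01)
      k <- k + 2L
    }
  }
  tol <- 1e-9 * max(width, height)
  inner <- vertices[, 1] >= xlim[1] - tol & vertices[, 1] <= xlim[2] + tol &
    vertices[, 2] >= ylim[1] - tol & vertices[, 2] <= ylim[2] + tol
  m <- mesh_create(vertices, do.call(rbind, tri), inner = inner)
  m$lattice <- list(x0 = gx[1], y0 = gy[1], hx = hx, hy = hy,
                    nvx = nvx, nvy = nvy)
  m
}

#' Linear finite-element matrices of a mesh
#'
#' Standard linear-element assembly: lumped mass matrix \code{C} (diagonal
#' entry = one third of the area of the triangles incident to the vertex),
#' stiffness matrix \code{G1} from per-triangle gradient inner products, and
#' \code{G2 = G1 C^{-1} G1}, the ingredients of the SPDE precision.
#'
#' @param mesh a \code{wm_mesh}.
#' @return list with sparse \code{C} (diagonal), \code{G1}, \code{G2}.
#' @export
fem_matrices <- function(mesh) {
  stopifnot(inherits(mesh, "wm_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  nv <- nrow(v); nt <- nrow(tr)
  areas <- mesh$areas
  if (any(areas <= 1e-14)) {
    stop("degenerate (zero-area) triangle(s): ",
         paste(which(areas <= 1e-14), collapse = ", "))
  }
  cdiag <- numeric(nv)
  ii <- integer(9L * nt); jj <- integer(9L * nt); gg <- numeric(9L * nt)
  pos <- 0L
  for (t in seq_len(nt)) {
    id <- tr[t, ]
    p <- v[id, , drop = FALSE]
    # edge vectors opposite each vertex
    e <- rbind(p[3, ] - p[2, ], p[1, ] - p[3, ], p[2, ] - p[1, ])
    a <- areas[t]
    kloc <- (e %*% t(e)) / (4 * a)
    cdiag[id] <- cdiag[id] + a / 3
    rng <- pos + 1:9
    ii[rng] <- rep(id, times = 3)
    jj[rng] <- rep(id, each = 3)
    gg[rng] <- as.vector(kloc)
    pos <- pos + 9L
  }
  G1 <- Matrix::sparseMatrix(i = ii, j = jj, x = gg, dims = c(nv, nv))
  G1 <- Matrix::forceSymmetric((G1 + Matrix::t(G1)) / 2)
  C <- Matrix::Diagonal(x = cdiag)
  Cinv <- Matrix::Diagonal(x = 1 / cdiag)
  G2 <- Matrix::forceSymmetric(G1 %*% Cinv %*% G1)
  list(C = C, G1 = G1, G2 = G2)
}

# Barycentric coordinates of point p in triangle with rows of P; may be
# negative if outside.
barycentric <- function(p, P) {
  detT <- (P[2, 2] - P[3, 2]) * (P[1, 1] - P[3, 1]) +
    (P[3, 1] - P[2, 1]) * (P[1, 2] - P[3, 2])
  l1 <- ((P[2, 2] - P[3, 2]) * (p[1] - P[3, 1]) +
           (P[3, 1] - P[2, 1]) * (p[2] - P[3, 2])) / detT
  l2 <- ((P[3, 2] - P[1, 2]) * (p[1] - P[3, 1]) +
           (P[1, 1] - P[3, 1]) * (p[2] - P[3, 2])) / detT
  c(l1, l2, 1 - l1 - l2)
}

#' Projection (observation) matrix from mesh nodes to locations
#'
#' Row i holds the barycentric coordinates of location i in its containing
#' triangle, so \code{A \%*\% w} evaluates the piecewise-linear field with
#' nodal values \code{w} at the locations. Rows sum to 1 with at most three
#' nonzeros.
#'
#' @param mesh a \code{wm_mesh}.
#' @param locations n x 2 matrix or data.frame of (x, y) km.
#' @return sparse \code{n x n_v} matrix.
#' @export
projection_matrix <- function(mesh, locations) {
  stopifnot(inherits(mesh, "wm_mesh"))
  loc <- as.matrix(as.data.frame(locations))
  n <- nrow(loc)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  outside <- integer(0)
  tolb <- -1e-9
  for (i in seq_len(n)) {
    tri_id <- locate_triangle(mesh, loc[i, ])
    found <- FALSE
    for (t in tri_id) {
      id <- mesh$triangles[t, ]
      b <- barycentric(loc[i, ], mesh$vertices[id, , drop = FALSE])
      if (all(b >= tolb)) {
        b <- pmax(b, 0); b <- b / sum(b)
        ii <- c(ii, rep(i, 3)); jj <- c(jj, id); xx <- c(xx, b)
        found <- TRUE
        break
      }
    }
    if (!found) outside <- c(outside, i)
  }
  if (length(outside) > 0) {
    stop("location(s) outside the mesh at row(s): ",
         paste(utils::head(outside, 10L), collapse = ", "))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, nrow(mesh$vertices)))
}

# Candidate triangles containing a point: O(1) on lattice meshes, otherwise a
# bounding-box prefiltered scan.
locate_triangle <- function(mesh, p) {
  if (!is.null(mesh$lattice)) {
    lt <- mesh$lattice
    ci <- floor((p[1] - lt$x0) / lt$hx) + 1
    cj <- floor((p[2] - lt$y0) / lt$hy) + 1
    cand <- integer(0)
    for (j in max(1, cj - 1):min(lt$nvy - 1, cj + 1)) {
      for (i in max(1, ci - 1):min(lt$nvx - 1, ci + 1)) {
        base <- 2L * ((j - 1L) * (lt$nvx - 1L) + (i - 1L))
        cand <- c(cand, base + 1L, base + 2L)
      }
    }
    cand[cand >= 1 & cand <= nrow(mesh$triangles)]
  } else {
    v <- mesh$vertices; tr <- mesh$triangles
    xs <- matrix(v[tr, 1], ncol = 3); ys <- matrix(v[tr, 2], ncol = 3)
    tol <- 1e-9 * (max(v[, 1]) - min(v[, 1]) + max(v[, 2]) - min(v[, 2]) + 1)
    which(p[1] >= apply(xs, 1, min) - tol & p[1] <= apply(xs, 1, max) + tol &
            p[2] >= apply(ys, 1, min) - tol & p[2] <= apply(ys, 1, max) + tol)
  }
}

#' Which locations fall inside the mesh
#'
#' @param mesh a \code{wm_mesh}.
#' @param locations n x 2 matrix or data.frame.
#' @return logical vector.
#' @export
mesh_contains <- function(mesh, locations) {
  loc <- as.matrix(as.data.frame(locations))
  vapply(seq_len(nrow(loc)), function(i) {
    for (t in locate_triangle(mesh, loc[i, ])) {
      b <- barycentric(loc[i, ], mesh$vertices[mesh$triangles[t, ], , drop = FALSE])
      if (all(b >= -1e-9)) return(TRUE)
    }
    FALSE
  }, logical(1))
}
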