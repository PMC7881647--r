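## Triangulated mesh over the study region.  The Matern field is represented
## on mesh vertices; a regular refinement grid plus the survey locations are
## Delaunay-triangulated (Bowyer-Watson), with an extension ring beyond the
## convex hull so boundary effects do not inflate the variance near the data.

#' Delaunay triangulation (Bowyer-Watson)
#'
#' Deterministic incremental Delaunay triangulation of a planar point set.
#' Intended for the mesh sizes used in SPDE modelling (up to a few thousand
#' points).
#'
#' @param pts two-column coordinate matrix; points must be distinct and not
#'   all collinear.
#' @return integer matrix with three vertex indices per row (triangles).
#' @export
delaunay <- function(pts) {
  pts <- rbind(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  cx <- mean(rng[, 1]); cy <- mean(rng[, 2])
  big <- 50 * span
  ## super-triangle vertices appended after the real points
  sup <- rbind(c(cx - 2 * big, cy - big), c(cx + 2 * big, cy - big), c(cx, cy + 2 * big))
  P <- rbind(pts, sup)
  ## preallocated triangle store with an active-slot mask
  cap <- 4L * n + 16L
  tri <- matrix(0L, cap, 3)
  cc <- matrix(0, cap, 3)
  active <- logical(cap)
  tri[1, ] <- c(n + 1L, n + 2L, n + 3L)
  cc[1, ] <- circumcircle(P, tri[1, , drop = FALSE])
  active[1] <- TRUE
  ntri <- 1L

  for (ip in seq_len(n)) {
    px <- P[ip, 1]; py <- P[ip, 2]
    sl <- seq_len(ntri)
    d2 <- (px - cc[sl, 1])^2 + (py - cc[sl, 2])^2
    bad <- which(active[sl] & d2 < cc[sl, 3] * (1 + 1e-12) + 1e-12)
    if (length(bad) == 0)      # numeric safety: nearest circumcircle
      bad <- which(active[sl])[which.min((d2 - cc[sl, 3])[active[sl]])]
    ## boundary polygon: edges of bad triangles that appear exactly once
    ed <- rbind(tri[bad, c(1, 2), drop = FALSE],
                tri[bad, c(2, 3), drop = FALSE],
                tri[bad, c(3, 1), drop = FALSE])
    lo <- pmin(ed[, 1], ed[, 2]); hi <- pmax(ed[, 1], ed[, 2])
    key <- lo * (n + 4) + hi
    keep <- !(key %in% key[duplicated(key)])
    ed <- ed[keep, , drop = FALSE]
    active[bad] <- FALSE
    free <- c(bad, ntri + seq_len(max(0L, nrow(ed) - length(bad))))
    free <- free[seq_len(nrow(ed))]
    newmax <- max(free)
    if (newmax > cap) {       # grow store
      grow <- max(cap, newmax)
      tri <- rbind(tri, matrix(0L, grow, 3))
      cc <- rbind(cc, matrix(0, grow, 3))
      active <- c(active, logical(grow))
      cap <- cap + grow
    }
    newt <- cbind(ed, ip)
    tri[free, ] <- newt
    cc[free, ] <- circumcircle(P, newt)
    active[free] <- TRUE
    ntri <- max(ntri, newmax)
  }
  tri <- tri[which(active[seq_len(ntri)]), , drop = FALSE]
  tri <- tri[rowSums(matrix(tri > n, ncol = 3)) == 0, , drop = FALSE]
  if (nrow(tri) == 0) stop("triangulation failed (collinear input?)", call. = FALSE)
  storage.mode(tri) <- "integer"
  ## orient counter-clockwise
  a <- P[tri[, 1], , drop = FALSE]
  b <- P[tri[, 2], , drop = FALSE]
  c <- P[tri[, 3], , drop = FALSE]
  det <- (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  flip <- det < 0
  tri[flip, 2:3] <- tri[flip, 3:2]
  tri
}

## circumcenters and squared radii for a set of triangles
circumcircle <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1]; by <- P[tri[, 2], 2]
  cx <- P[tri[, 3], 1]; cy <- P[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-300] <- 1e-300
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) + (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) + (cx^2 + cy^2) * (bx - ax)) / d
  cbind(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Build a triangulated mesh over survey locations
#'
#' Vertices are the (deduplicated) input locations plus a regular refinement
#' grid covering the bounding box extended by `extension` km; the union is
#' Delaunay-triangulated.  Grid vertices receive a tiny deterministic jitter
#' to avoid cocircular degeneracies, so identical inputs always yield the
#' identical mesh.
#'
#' @param points two-column matrix of locations (km).
#' @param max_edge target maximum interior edge length (km).
#' @param cutoff minimum separation (km); input points closer than this are
#'   merged to a single vertex.
#' @param extension width (km) of the ring added beyond the point bounding
#'   box; should be at least the spatial range of the field.
#' @return `spde_mesh` object: `loc` (vertex coordinates), `tri` (triangle
#'   index matrix), `n_data` (vertices 1..n_data are retained input points),
#'   `point_map` (input row -> vertex index).
#' @export
build_mesh <- function(points, max_edge, cutoff = 1e-6, extension = max_edge) {
  points <- rbind(points)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  stop_if_not_scalar_pos(max_edge, "max_edge")
  ## collinearity check on the raw input
  pc <- sweep(points, 2, colMeans(points))
  if (min(svd(pc)$d) < 1e-9 * max(1, max(abs(pc))))
    stop("input points are collinear; cannot build a 2-D mesh", call. = FALSE)

  ## greedy merge of near-duplicates (deterministic: first occurrence wins)
  kept <- integer(0)
  point_map <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    if (length(kept)) {
      d2 <- (points[kept, 1] - points[i, 1])^2 + (points[kept, 2] - points[i, 2])^2
      j <- which(d2 <= cutoff^2)
      if (length(j)) { point_map[i] <- j[1]; next }
    }
    kept <- c(kept, i)
    point_map[i] <- length(kept)
  }
  dat <- points[kept, , drop = FALSE]

  h <- max_edge / sqrt(2)
  xr <- range(points[, 1]) + c(-1, 1) * extension
  yr <- range(points[, 2]) + c(-1, 1) * extension
  gx <- seq(xr[1], xr[2], length.out = max(2L, ceiling(diff(xr) / h) + 1L))
  gy <- seq(yr[1], yr[2], length.out = max(2L, ceiling(diff(yr) / h) + 1L))
  grid <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
  grid <- grid + coord_hash_jitter(grid, 1e-3 * h)
  ## drop grid points crowding a data vertex
  keepg <- rep(TRUE, nrow(grid))
  for (i in seq_len(nrow(dat))) {
    d2 <- (grid[, 1] - dat[i, 1])^2 + (grid[, 2] - dat[i, 2])^2
    keepg <- keepg & d2 > (0.45 * h)^2
  }
  loc <- rbind(dat, grid[keepg, , drop = FALSE])
  tri <- delaunay(loc)
  structure(list(loc = loc, tri = tri, n_data = nrow(dat),
                 point_map = point_map, max_edge = max_edge,
                 extension = extension),
            class = "spde_mesh")
}

#' @export
print.spde_mesh <- function(x, ...) {
  cat(sprintf("<spde_mesh> %d vertices (%d data), %d triangles\n",
              nrow(x$loc), x$n_data, nrow(x$tri)))
  invisible(x)
}

#' Serialize / read a mesh as plain text
#' @param mesh an `spde_mesh`.
#' @param path file path.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("mesh %d %d %d", nrow(mesh$loc), nrow(mesh$tri), mesh$n_data), con)
  writeLines(sprintf("v %.17g %.17g", mesh$loc[, 1], mesh$loc[, 2]), con)
  writeLines(sprintf("t %d %d %d", mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(lines[1], " ")[[1]][-1])
  vs <- lines[startsWith(lines, "v ")]
  ts <- lines[startsWith(lines, "t ")]
  loc <- matrix(scan(text = sub("^v ", "", vs), quiet = TRUE), ncol = 2, byrow = TRUE)
  tri <- matrix(as.integer(scan(text = sub("^t ", "", ts), quiet = TRUE)), ncol = 3, byrow = TRUE)
  structure(list(loc = loc, tri = tri, n_data = hd[3],
                 point_map = seq_len(hd[3]), max_edge = NA, extension = NA),
            class = "spde_mesh")
}

#' Barycentric projection matrix from mesh vertices to points
#'
#' Each target point is located in its enclosing triangle and receives the
#' barycentric weights of that triangle's vertices: a sparse matrix `A` with
#' one row per point and one column per mesh vertex, rows summing to one.
#'
#' @param mesh an `spde_mesh`.
#' @param points two-column matrix of target locations (km); must fall inside
#'   the (extended) mesh.
#' @return sparse `dgCMatrix`, `nrow(points)` x `nrow(mesh$loc)`.
#' @export
projection_matrix <- function(mesh, points) {
  points <- rbind(points)
  loc <- mesh$loc; tri <- mesh$tri
  ax <- loc[tri[, 1], 1]; ay <- loc[tri[, 1], 2]
  bx <- loc[tri[, 2], 1]; by <- loc[tri[, 2], 2]
  cx <- loc[tri[, 3], 1]; cy <- loc[tri[, 3], 2]
  det <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (p in seq_len(nrow(points))) {
    px <- points[p, 1]; py <- points[p, 2]
    w1 <- ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / det
    w2 <- ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / det
    w3 <- 1 - w1 - w2
    tol <- -1e-9
    hit <- which(w1 >= tol & w2 >= tol & w3 >= tol)
    if (length(hit) == 0)
      stop(sprintf("point %d (%.3f, %.3f) lies outside the extended mesh",
                   p, px, py), call. = FALSE)
    t1 <- hit[1]
    w <- pmax(c(w1[t1], w2[t1], w3[t1]), 0)
    w <- w / sum(w)
    ii <- c(ii, rep.int(p, 3L)); jj <- c(jj, tri[t1, ]); xx <- c(xx, w)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(points), nrow(loc)))
  methods::as(A, "CsparseMatrix")
}
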