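#' Triangle mesh
#'
#' Vertices in mm, faces as 1-based vertex-index triples. Degenerate
#' (zero-area) faces are dropped at construction time.
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of vertex indices (1-based).
#' @return an object of class `"tri_mesh"`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L || nrow(faces) == 0L)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("tri_mesh: face index out of range")
    a <- vertices[faces[, 2L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
    b <- vertices[faces[, 3L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 0, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Axis-aligned region selector
#'
#' Selects the vertex subset lying inside a bounding box — the scriptable
#' equivalent of manually isolating a vertex group (e.g. the top plane of a
#' gauge cube) in a mesh editor.
#'
#' @param min,max numeric length-3 vectors (mm), `min <= max` per axis.
#' @return an object of class `"region_spec"`.
#' @export
region_spec <- function(min, max) {
  stopifnot(length(min) == 3L, length(max) == 3L, all(min <= max))
  structure(list(min = as.numeric(min), max = as.numeric(max)),
            class = "region_spec")
}

region_select <- function(mesh, region) {
  v <- mesh$vertices
  which(v[, 1] >= region$min[1] & v[, 1] <= region$max[1] &
        v[, 2] >= region$min[2] & v[, 2] <= region$max[2] &
        v[, 3] >= region$min[3] & v[, 3] <= region$max[3])
}

#' Gauge-cube step height between two vertex regions
#'
#' Implements the gauge-block protocol for quantifying metric reconstruction
#' accuracy: certified blocks of known heights are scanned in pairs and the
#' step between them is measured as the difference of the mean up-axis
#' coordinate of the step cube's top-plane vertices and of the reference
#' cube's top-plane vertices. The spread is reported as the quadrature
#' combination of the two regions' up-coordinate standard deviations.
#'
#' @param mesh a [tri_mesh()].
#' @param top [region_spec()] selecting the step-cube top plane.
#' @param reference [region_spec()] selecting the reference-cube top plane.
#' @param up_axis `"x"`, `"y"` or `"z"` — the vertical axis.
#' @return list with `mean` (mm), `sd` (mm), `n_top`, `n_ref`.
#' @export
step_height <- function(mesh, top, reference, up_axis = c("z", "x", "y")) {
  up_axis <- match.arg(up_axis)
  ax <- match(up_axis, c("x", "y", "z"))
  it <- region_select(mesh, top)
  ir <- region_select(mesh, reference)
  if (length(it) == 0L) stop("step_height: region 'top' selects no vertices")
  if (length(ir) == 0L) stop("step_height: region 'reference' selects no vertices")
  zt <- mesh$vertices[it, ax]; zr <- mesh$vertices[ir, ax]
  sdq <- function(x) if (length(x) > 1L) sd(x) else 0
  list(mean = mean(zt) - mean(zr),
       sd = sqrt(sdq(zt)^2 + sdq(zr)^2),
       n_top = length(it), n_ref = length(ir))
}

mesh_face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas; defined for open and closed meshes alike.
#'
#' @param mesh a [tri_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0)
  sum(sqrt(rowSums(mesh_face_cross(mesh)^2))) / 2
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (closed and consistently oriented) iff every
#' undirected edge is shared by exactly two faces with opposite orientation,
#' i.e. each directed edge appears exactly once and so does its reverse.
#'
#' @param mesh a [tri_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) return(FALSE)        # directed edge reused
  rev_key <- paste(he[, 2], he[, 1])
  all(rev_key %in% key)                        # every edge has its opposite
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume: the absolute value of the sum of signed
#' tetrahedron volumes spanned by each face and the origin, which makes the
#' result independent of global face orientation. Refuses non-watertight
#' meshes (their "volume" is undefined); use [mesh_area()] on open meshes.
#'
#' @param mesh a [tri_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh))
    stop("mesh_volume: mesh is not watertight; volume is undefined")
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  cr <- mesh_face_cross(mesh)
  abs(sum(rowSums(p1 * cr))) / 6
}

#' Surface area and volume of a closed mesh
#'
#' Convenience wrapper returning both [mesh_area()] and [mesh_volume()];
#' errors on non-watertight meshes (area alone is available via
#' [mesh_area()]).
#'
#' @param mesh a [tri_mesh()].
#' @return list with `area` (mm^2) and `volume` (mm^3).
#' @export
surface_and_volume <- function(mesh) {
  list(area = mesh_area(mesh), volume = mesh_volume(mesh))
}

#' Length of the longest body axis
#'
#' Maximum pairwise vertex distance. Exact (blocked brute force) up to
#' `exact_limit` vertices; larger meshes are first reduced to the support
#' vertices over a quasi-uniform set of directions (the diameter endpoints
#' are extreme points of the hull, so support reduction loses at most a
#' discretization error that is negligible at the default direction count).
#'
#' @param mesh a [tri_mesh()] with at least 2 vertices.
#' @param exact_limit vertex count up to which the exact path is used.
#' @return longest axis in mm.
#' @export
longest_axis <- function(mesh, exact_limit = 20000L) {
  v <- unique(mesh$vertices)
  if (nrow(v) < 2L) stop("longest_axis: at least 2 distinct vertices required")
  if (nrow(v) > exact_limit) v <- support_vertices(v)
  max_pairwise_dist(v)
}

## exact maximum pairwise distance, blocked to bound memory
max_pairwise_dist <- function(v) {
  n <- nrow(v)
  sq <- rowSums(v^2)
  best <- 0
  block <- 1024L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    g <- v[s:e, , drop = FALSE] %*% t(v)
    d2 <- outer(sq[s:e], rep(1, n)) + outer(rep(1, e - s + 1L), sq) - 2 * g
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

## support (extreme) vertices over a Fibonacci-sphere direction set
support_vertices <- function(v, n_dirs = 2048L) {
  i <- seq_len(n_dirs) - 0.5
  phi <- acos(1 - 2 * i / n_dirs)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  proj <- v %*% t(dirs)
  idx <- unique(c(apply(proj, 2L, which.max), apply(proj, 2L, which.min)))
  v[idx, , drop = FALSE]
}
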