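#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' Golden-angle spiral lattice; gives near-uniform node spacing for any
#' requested count, which is what the shell meshing needs (arbitrary node
#' numbers, including 393).
#'
#' @param n number of points (>= 4).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 4)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(rho * cos(th), rho * sin(th), z)
}

#' Build a closed triangulated spherical shell
#'
#' Places `n_nodes` quasi-uniformly on a sphere of the given diameter
#' (Fibonacci lattice) and triangulates them by their 3D convex hull. Faces
#' are oriented outward. The as-built edge lengths and triangle areas are
#' stored as the stress-free equilibrium geometry of the elastic network.
#'
#' @param n_nodes number of mesh nodes (>= 12).
#' @param diameter sphere diameter, reduced units.
#' @param blob_diameter soft-sphere diameter ascribed to each node (blob).
#' @return A `triangulated_shell`: list with `positions` (V x 3),
#'   `velocities`, `triangles` (F x 3, 1-based, outward), `edges` (E x 2),
#'   `r0_edge`, `S0_tri`, `blob_diameter`, `diameter`.
#' @examples
#' sh <- make_sphere_mesh(162, diameter = 24, blob_diameter = 3.1)
#' nrow(sh$positions) - nrow(sh$edges) + nrow(sh$triangles)  # Euler: 2
#' @export
make_sphere_mesh <- function(n_nodes, diameter, blob_diameter = 0) {
  if (n_nodes < 12) stop("need at least 12 nodes for a usable shell mesh")
  if (diameter <= 0) stop("diameter must be positive")
  pos <- fibonacci_sphere(n_nodes) * (diameter / 2)
  tri0 <- .convex_hull3d(pos)            # 0-based, from the hull
  tri <- tri0 + 1L
  if (length(unique(as.vector(tri))) != n_nodes)
    stop("degenerate configuration: not all nodes are hull vertices")
  # enforce outward orientation against the face normal test
  for (k in seq_len(nrow(tri))) {
    a <- pos[tri[k, 1], ]; b <- pos[tri[k, 2], ]; c <- pos[tri[k, 3], ]
    nrm <- .cross3(b - a, c - a)
    if (sum(nrm * (a + b + c) / 3) < 0) tri[k, ] <- tri[k, c(1, 3, 2)]
  }
  ed <- .edges_from_triangles(tri)
  r0 <- sqrt(rowSums((pos[ed[, 1], ] - pos[ed[, 2], ])^2))
  S0 <- triangle_areas(pos, tri)
  if (any(S0 <= 0)) stop("degenerate triangle in constructed mesh")
  structure(list(positions = pos,
                 velocities = matrix(0, n_nodes, 3),
                 triangles = tri, edges = ed,
                 r0_edge = r0, S0_tri = S0,
                 blob_diameter = blob_diameter,
                 diameter = diameter),
            class = "triangulated_shell")
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.edges_from_triangles <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  storage.mode(e) <- "integer"
  e
}

#' Triangle areas of a mesh
#' @param pos V x 3 node positions.
#' @param tri F x 3 triangle index matrix (1-based).
#' @return Vector of F areas.
#' @export
triangle_areas <- function(pos, tri) {
  u <- pos[tri[, 2], , drop = FALSE] - pos[tri[, 1], , drop = FALSE]
  v <- pos[tri[, 3], , drop = FALSE] - pos[tri[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Enclosed (signed) volume of a closed triangulated surface
#'
#' Sum of signed tetrahedron volumes (origin, triangle); positive for a
#' closed surface with consistently outward-oriented faces.
#' @inheritParams triangle_areas
#' @export
mesh_volume <- function(pos, tri) {
  a <- pos[tri[, 1], , drop = FALSE]
  b <- pos[tri[, 2], , drop = FALSE]
  c <- pos[tri[, 3], , drop = FALSE]
  cx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  cy <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  cz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

#' Pair two concentric shells node-by-node
#'
#' Matches each outer node to the inner node of maximal radial alignment
#' (greatest direction cosine); the match must be a bijection. Each pair is
#' connected by a harmonic tether whose rest length is the as-built radial
#' separation — (Dout - Din)/2 for concentric construction.
#'
#' @param outer,inner `triangulated_shell` objects with equal node counts.
#' @return A `shell_pair`: list with `outer`, `inner`, `correspondence`
#'   (inner index for each outer node) and `r0_tether`.
#' @export
pair_shells <- function(outer, inner) {
  stopifnot(inherits(outer, "triangulated_shell"),
            inherits(inner, "triangulated_shell"))
  if (nrow(outer$positions) != nrow(inner$positions))
    stop("shells must have equal node counts")
  uo <- outer$positions / sqrt(rowSums(outer$positions^2))
  ui <- inner$positions / sqrt(rowSums(inner$positions^2))
  corr <- max.col(uo %*% t(ui), ties.method = "first")
  if (anyDuplicated(corr))
    stop("node correspondence is not a bijection; shells are not aligned")
  r0 <- sqrt(rowSums((outer$positions - inner$positions[corr, ])^2))
  structure(list(outer = outer, inner = inner,
                 correspondence = corr, r0_tether = r0,
                 wca_excl = .reference_overlaps(outer, inner)),
            class = "shell_pair")
}

# blob pairs that overlap in the as-built reference geometry are excluded
# from the soft-sphere repulsion, so the constructed shells are stress-free;
# contacts formed later (folding, shell-shell approach) still repel
.reference_overlaps <- function(outer, inner) {
  pos <- rbind(outer$positions, inner$positions)
  dd <- c(rep(outer$blob_diameter, nrow(outer$positions)),
          rep(inner$blob_diameter, nrow(inner$positions)))
  D <- as.matrix(stats::dist(pos))
  cut <- outer((dd), (dd), function(a, b) (a + b) / 2)
  idx <- which(D < cut & upper.tri(D), arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  dimnames(idx) <- NULL
  idx
}

#' Thickness of the nanoparticle-accessible intra-membrane layer
#'
#' Half-difference formula: l = (Dout - dout - Din - din) / 2, i.e. the gap
#' between the inner surface of the outer blob layer and the outer surface
#' of the inner blob layer.
#'
#' @param Dout,Din shell diameters (reduced).
#' @param dout,din blob diameters of outer and inner shells.
#' @return Layer thickness in reduced units.
#' @examples
#' layer_thickness(24, 3.1, 16, 2)  # 1.45
#' @export
layer_thickness <- function(Dout, dout, Din, din) {
  l <- (Dout - dout - Din - din) / 2
  if (l <= 0)
    stop("layer cannot accommodate particles: non-positive thickness")
  l
}

#' Export a shell mesh
#'
#' `write_off()` writes the Object File Format; `write_vtk()` writes legacy
#' ASCII VTK polydata. Both are plain text and readable by standard mesh
#' viewers.
#'
#' @param shell a `triangulated_shell`.
#' @param path output file path.
#' @export
write_off <- function(shell, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- nrow(shell$positions); F <- nrow(shell$triangles)
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", V, F), con)
  writeLines(apply(shell$positions, 1, function(p)
    sprintf("%.10g %.10g %.10g", p[1], p[2], p[3])), con)
  writeLines(apply(shell$triangles - 1L, 1, function(t)
    sprintf("3 %d %d %d", t[1], t[2], t[3])), con)
  invisible(path)
}

#' @rdname write_off
#' @export
write_vtk <- function(shell, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- nrow(shell$positions); F <- nrow(shell$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "shell mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", V)), con)
  writeLines(apply(shell$positions, 1, function(p)
    sprintf("%.10g %.10g %.10g", p[1], p[2], p[3])), con)
  writeLines(sprintf("POLYGONS %d %d", F, 4 * F), con)
  writeLines(apply(shell$triangles - 1L, 1, function(t)
    sprintf("3 %d %d %d", t[1], t[2], t[3])), con)
  invisible(path)
}
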