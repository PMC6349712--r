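#' Synthetic ventricle and electrode geometry
#'
#' Builds a desk-scale stand-in for a heart-torso measurement setup: a
#' truncated half-ellipsoid epicardial shell open at the base (long axis
#' along z, apex at the bottom), optionally a nested endocardial shell inset
#' by a uniform wall thickness, and a ring arrangement of electrodes on the
#' lateral surface of a torso cylinder centered on the heart.
#'
#' The construction is fully deterministic for a given configuration; `seed`
#' is accepted for interface uniformity with the stochastic generators.
#'
#' @param semi_axes numeric length-3, ellipsoid semi-axes `(a, b, c)` in mm;
#'   `c` is the apex-base half-length.
#' @param wall_thickness wall thickness in mm, or `NULL` for an
#'   epicardium-only mesh.  Must be smaller than the smallest semi-axis.
#' @param n_target approximate number of epicardial vertices.
#' @param torso_radius,torso_height cylinder radius and height in mm.
#' @param n_electrodes number of electrodes (>= 4) placed in near-uniform
#'   rings on the cylinder.
#' @param seed integer seed (kept for reproducibility bookkeeping).
#' @return A list with elements `mesh` ([surface_mesh()]) and `electrodes`
#'   ([electrode_set()]).
#' @examples
#' g <- make_synthetic_geometry(n_target = 100, n_electrodes = 64)
#' g$mesh
#' @export
make_synthetic_geometry <- function(semi_axes = c(30, 30, 60),
                                    wall_thickness = NULL,
                                    n_target = 100,
                                    torso_radius = 100,
                                    torso_height = 240,
                                    n_electrodes = 64,
                                    seed = 1L) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  if (!is.null(wall_thickness) && wall_thickness >= min(semi_axes))
    stop("wall_thickness (", wall_thickness,
         " mm) must be smaller than the smallest semi-axis (",
         min(semi_axes), " mm)")
  if (n_electrodes < 4) stop("need at least 4 electrodes")
  if (torso_radius <= max(semi_axes[1:2]))
    stop("torso_radius must exceed the transverse heart semi-axes")

  epi <- half_ellipsoid_shell(semi_axes, n_target)
  if (is.null(wall_thickness)) {
    mesh <- surface_mesh(epi$vertices, epi$triangles)
  } else {
    inner_axes <- semi_axes - wall_thickness
    # endo shell a bit coarser, as in clinical-style meshes
    endo <- half_ellipsoid_shell(inner_axes, max(16, round(n_target * 0.7)))
    n_epi <- nrow(epi$vertices)
    mesh <- surface_mesh(rbind(epi$vertices, endo$vertices),
                         rbind(epi$triangles, endo$triangles + n_epi),
                         c(rep("EPI", n_epi), rep("ENDO", nrow(endo$vertices))))
  }
  electrodes <- cylinder_electrodes(torso_radius, torso_height, n_electrodes)
  dmin <- min_pair_distance(mesh$vertices, electrodes$positions)
  if (dmin <= 0) stop("electrode coincides with a mesh vertex")
  list(mesh = mesh, electrodes = electrodes)
}

# Structured triangulation of the half-ellipsoid x=(a sin t cos p,
# b sin t sin p, -c cos t), t in [0, pi/2]: apex point plus rings, open rim
# at the equator (the ventricular base).
half_ellipsoid_shell <- function(semi_axes, n_target) {
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  n_rings <- max(3L, round(sqrt(n_target / 2)))
  m <- max(4L, round((n_target - 1) / n_rings))
  theta <- seq_len(n_rings) / n_rings * (pi / 2)
  verts <- matrix(c(0, 0, -cc), 1, 3)
  ring_start <- integer(n_rings)
  for (r in seq_len(n_rings)) {
    ring_start[r] <- nrow(verts) + 1L
    # stagger alternate rings by half a sector for better-shaped triangles
    phi <- (seq_len(m) - 1 + 0.5 * (r %% 2)) / m * 2 * pi
    verts <- rbind(verts, cbind(a * sin(theta[r]) * cos(phi),
                                b * sin(theta[r]) * sin(phi),
                                -cc * cos(theta[r])))
  }
  tri <- matrix(0L, 0, 3)
  # apex fan
  r1 <- ring_start[1]
  for (j in seq_len(m))
    tri <- rbind(tri, c(1L, r1 + j - 1L, r1 + (j %% m)))
  # ring-to-ring bands
  for (r in seq_len(n_rings - 1)) {
    lo <- ring_start[r]; hi <- ring_start[r + 1]
    for (j in seq_len(m)) {
      j2 <- j %% m + 1L
      tri <- rbind(tri,
                   c(lo + j - 1L, hi + j - 1L, hi + j2 - 1L),
                   c(lo + j - 1L, hi + j2 - 1L, lo + j2 - 1L))
    }
  }
  list(vertices = verts, triangles = tri)
}

cylinder_electrodes <- function(radius, height, n) {
  n_rings <- max(2L, round(sqrt(n / 4)))
  base_per <- n %/% n_rings
  extra <- n - base_per * n_rings
  per_ring <- rep(base_per, n_rings) + c(rep(1L, extra),
                                         rep(0L, n_rings - extra))
  z <- seq(-height / 2, height / 2, length.out = n_rings + 2)[2:(n_rings + 1)]
  pos <- NULL
  for (r in seq_len(n_rings)) {
    k <- per_ring[r]
    phi <- (seq_len(k) - 1 + 0.5 * (r %% 2)) / k * 2 * pi
    pos <- rbind(pos, cbind(radius * cos(phi), radius * sin(phi),
                            rep(z[r], k)))
  }
  electrode_set(pos)
}

min_pair_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

# One round of midpoint (1-to-4) subdivision; original vertices keep their
# indices and labels, edge midpoints inherit the label shared by the edge
# endpoints (EPI wins on mixed edges).
subdivide_mesh <- function(mesh) {
  tr <- mesh$triangles
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  mid <- (mesh$vertices[e[, 1], , drop = FALSE] +
          mesh$vertices[e[, 2], , drop = FALSE]) / 2
  mid_idx <- mesh$n_vertices + seq_len(nrow(e))
  lookup <- setNames(mid_idx, key)
  edge_id <- function(i, j) lookup[paste(pmin(i, j), pmax(i, j))]
  m12 <- edge_id(tr[, 1], tr[, 2])
  m23 <- edge_id(tr[, 2], tr[, 3])
  m13 <- edge_id(tr[, 1], tr[, 3])
  new_tr <- rbind(cbind(tr[, 1], m12, m13),
                  cbind(m12, tr[, 2], m23),
                  cbind(m13, m23, tr[, 3]),
                  cbind(m12, m23, m13))
  lab_e <- ifelse(mesh$surface_label[e[, 1]] == "ENDO" &
                  mesh$surface_label[e[, 2]] == "ENDO", "ENDO", "EPI")
  surface_mesh(rbind(mesh$vertices, mid),
               new_tr,
               c(mesh$surface_label, lab_e))
}
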