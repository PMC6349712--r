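#' Triangulated heart-surface mesh
#'
#' Container for the discrete heart surface: vertex positions in mm, triangle
#' connectivity (1-based vertex indices), and a per-vertex surface label
#' distinguishing epicardium (`"EPI"`) from endocardium (`"ENDO"`).
#'
#' @param vertices numeric matrix, `N_H x 3`, coordinates in mm.
#' @param triangles integer matrix, `M x 3`, 1-based vertex indices.
#' @param surface_label character vector of length `N_H` with values
#'   `"EPI"` or `"ENDO"`; defaults to all `"EPI"`.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `surface_label` and `n_vertices`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' tr <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
#' m <- surface_mesh(v, tr)
#' m$n_vertices
#' @export
surface_mesh <- function(vertices, triangles, surface_label = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns (x, y, z in mm)")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L)
    stop("'triangles' must have 3 columns of vertex indices")
  n <- nrow(vertices)
  if (is.null(surface_label)) surface_label <- rep("EPI", n)
  surface_label <- as.character(surface_label)
  if (length(surface_label) != n)
    stop("'surface_label' must have one entry per vertex")
  if (!all(surface_label %in% c("EPI", "ENDO")))
    stop("surface labels must be 'EPI' or 'ENDO'")
  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         surface_label = surface_label, n_vertices = n),
    class = "surface_mesh")
  validate_surface_mesh(mesh)
  mesh
}

validate_surface_mesh <- function(mesh) {
  tr <- mesh$triangles
  n <- mesh$n_vertices
  if (any(tr < 1L | tr > n)) {
    bad <- which(rowSums(tr < 1L | tr > n) > 0)
    stop("triangle(s) ", paste(head(bad, 5), collapse = ", "),
         " reference vertex indices outside [1, ", n, "]")
  }
  degen <- tr[, 1] == tr[, 2] | tr[, 1] == tr[, 3] | tr[, 2] == tr[, 3]
  if (any(degen))
    stop("degenerate triangle(s) repeating a vertex: ",
         paste(which(degen), collapse = ", "))
  used <- tabulate(tr, nbins = n) > 0
  if (!all(used))
    stop("vertex/vertices not referenced by any triangle: ",
         paste(head(which(!used), 10), collapse = ", "))
  if (!any(mesh$surface_label == "EPI"))
    stop("mesh must contain at least one EPI-labeled vertex")
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", x$n_vertices, "vertices,", nrow(x$triangles),
      "triangles\n")
  cat("  EPI:", sum(x$surface_label == "EPI"),
      " ENDO:", sum(x$surface_label == "ENDO"), "\n")
  invisible(x)
}

#' Body-surface electrode set
#'
#' @param positions numeric matrix, `N_T x 3`, electrode coordinates in mm.
#' @return An object of class `electrode_set` with `positions` and
#'   `n_electrodes`.
#' @export
electrode_set <- function(positions) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L)
    stop("'positions' must have 3 columns (x, y, z in mm)")
  structure(list(positions = positions, n_electrodes = nrow(positions)),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat("electrode_set:", x$n_electrodes, "electrodes\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Mesh I/O: ASCII PLY, OFF, legacy VTK polydata.
## The EPI/ENDO tag travels as an integer field "surface_label" (0 = EPI,
## 1 = ENDO).  PLY carries it as a vertex property and VTK as POINT_DATA
## SCALARS; plain OFF has no per-vertex scalar slot, so the writer appends the
## label as a fourth vertex column which the reader recognises.

label_to_int <- function(lab) ifelse(lab == "ENDO", 1L, 0L)
int_to_label <- function(x) ifelse(as.integer(x) == 1L, "ENDO", "EPI")

#' Read or write a surface mesh (PLY / OFF / legacy VTK)
#'
#' Format is inferred from the file extension (`.ply`, `.off`, `.vtk`).
#' All three formats are ASCII.  A read-write round trip preserves vertices
#' to better than 1e-6 mm, connectivity, and surface labels.
#'
#' @param path file path; extension selects the format.
#' @return For `read_mesh`, a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_mesh_ply(path),
         off = read_mesh_off(path),
         vtk = read_mesh_vtk(path),
         stop("unknown mesh format '.", ext,
              "' (supported: .ply, .off, .vtk)"))
}

#' @rdname read_mesh
#' @param mesh a [surface_mesh()] to write.
#' @param point_data optional named list of per-vertex numeric vectors written
#'   as additional scalar fields (legacy VTK only).
#' @export
write_mesh <- function(mesh, path, point_data = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_mesh_ply(mesh, path),
         off = write_mesh_off(mesh, path),
         vtk = write_mesh_vtk(mesh, path, point_data),
         stop("unknown mesh format '.", ext,
              "' (supported: .ply, .off, .vtk)"))
  invisible(path)
}

num_fmt <- function(x) formatC(x, format = "g", digits = 17)

write_mesh_ply <- function(mesh, path) {
  n <- mesh$n_vertices; m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property double x", "property double y", "property double z",
               "property int surface_label",
               paste("element face", m),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vl <- cbind(format_coords(mesh$vertices), label_to_int(mesh$surface_label))
  writeLines(apply(vl, 1, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
}

format_coords <- function(v) {
  matrix(formatC(v, format = "g", digits = 17), nrow = nrow(v))
}

read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header missing end_header")
  hdr <- trimws(lines[seq_len(hdr_end)])
  n_vert <- n_face <- NA_integer_
  vprops <- character(0)
  in_vertex <- FALSE
  for (l in hdr) {
    tok <- strsplit(l, "\\s+")[[1]]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") n_vert <- as.integer(tok[3])
      if (tok[2] == "face") n_face <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vrows <- body[seq_len(n_vert)]
  vdat <- matrix(scan(text = vrows, quiet = TRUE), nrow = n_vert,
                 byrow = TRUE)
  xyz_idx <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz_idx)) stop("PLY vertex element lacks x/y/z properties")
  vertices <- vdat[, xyz_idx, drop = FALSE]
  lab_idx <- match("surface_label", vprops)
  labels <- if (!is.na(lab_idx)) int_to_label(vdat[, lab_idx]) else NULL
  frows <- body[n_vert + seq_len(n_face)]
  fdat <- lapply(strsplit(trimws(frows), "\\s+"), as.integer)
  if (any(vapply(fdat, `[`, 1L, 1) != 3L))
    stop("non-triangular face in PLY file")
  triangles <- do.call(rbind, lapply(fdat, function(r) r[2:4] + 1L))
  surface_mesh(vertices, triangles, labels)
}

write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines("# vertex rows carry a 4th column: surface_label (0=EPI, 1=ENDO)",
             con)
  writeLines(paste(mesh$n_vertices, nrow(mesh$triangles), 0L), con)
  vl <- cbind(format_coords(mesh$vertices), label_to_int(mesh$surface_label))
  writeLines(apply(vl, 1, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
}

read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  n_vert <- counts[1]; n_face <- counts[2]
  vrows <- strsplit(lines[2 + seq_len(n_vert)], "\\s+")
  ncol_v <- length(vrows[[1]])
  vdat <- matrix(as.numeric(unlist(vrows)), nrow = n_vert, byrow = TRUE)
  vertices <- vdat[, 1:3, drop = FALSE]
  labels <- if (ncol_v >= 4) int_to_label(vdat[, 4]) else NULL
  frows <- strsplit(lines[2 + n_vert + seq_len(n_face)], "\\s+")
  fdat <- lapply(frows, as.integer)
  if (any(vapply(fdat, `[`, 1L, 1) != 3L))
    stop("non-triangular face in OFF file")
  triangles <- do.call(rbind, lapply(fdat, function(r) r[2:4] + 1L))
  surface_mesh(vertices, triangles, labels)
}

write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  n <- mesh$n_vertices; m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "heart surface mesh", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "double")), con)
  writeLines(apply(format_coords(mesh$vertices), 1, paste, collapse = " "),
             con)
  writeLines(paste("POLYGONS", m, 4L * m), con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  writeLines(paste("POINT_DATA", n), con)
  writeLines(c("SCALARS surface_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(label_to_int(mesh$surface_label)), con)
  for (nm in names(point_data)) {
    vals <- point_data[[nm]]
    if (length(vals) != n)
      stop("point_data field '", nm, "' length differs from vertex count")
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"),
               con)
    writeLines(num_fmt(vals), con)
  }
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  lt <- trimws(lines)
  pts_i <- grep("^POINTS", lt)[1]
  if (is.na(pts_i)) stop("not a legacy VTK polydata file: ", path)
  n_vert <- as.integer(strsplit(lt[pts_i], "\\s+")[[1]][2])
  coords <- scan(text = lt[(pts_i + 1):length(lt)], n = 3L * n_vert,
                 quiet = TRUE)
  vertices <- matrix(coords, ncol = 3, byrow = TRUE)
  poly_i <- grep("^POLYGONS", lt)[1]
  n_face <- as.integer(strsplit(lt[poly_i], "\\s+")[[1]][2])
  fdat <- scan(text = lt[(poly_i + 1):length(lt)], n = 4L * n_face,
               quiet = TRUE)
  fmat <- matrix(as.integer(fdat), ncol = 4, byrow = TRUE)
  if (any(fmat[, 1] != 3L)) stop("non-triangular polygon in VTK file")
  triangles <- fmat[, 2:4, drop = FALSE] + 1L
  lab_i <- grep("^SCALARS\\s+surface_label", lt)[1]
  labels <- NULL
  if (!is.na(lab_i)) {
    labels <- int_to_label(scan(text = lt[(lab_i + 2):length(lt)],
                                n = n_vert, quiet = TRUE))
  }
  surface_mesh(vertices, triangles, labels)
}

#' Read or write electrode positions
#'
#' Plain-text table of x, y, z coordinates in mm, whitespace- or
#' comma-separated; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return For `read_electrodes`, an [electrode_set()].
#' @export
read_electrodes <- function(path) {
  if (!file.exists(path)) stop("electrode file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- gsub(",", " ", lines)
  vals <- scan(text = lines, quiet = TRUE)
  if (length(vals) %% 3 != 0)
    stop("electrode file must contain 3 coordinates per electrode")
  electrode_set(matrix(vals, ncol = 3, byrow = TRUE))
}

#' @rdname read_electrodes
#' @param electrodes an [electrode_set()] to write.
#' @export
write_electrodes <- function(electrodes, path) {
  stopifnot(inherits(electrodes, "electrode_set"))
  writeLines(c("# x y z (mm)",
               apply(format_coords(electrodes$positions), 1, paste,
                     collapse = " ")), path)
  invisible(path)
}

## ---------------------------------------------------------------------------

mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mesh_graph <- function(mesh, extra_edges = NULL) {
  e <- mesh_edges(mesh)
  if (!is.null(extra_edges)) {
    extra_edges <- as.matrix(extra_edges)
    e <- rbind(e, cbind(pmin(extra_edges[, 1], extra_edges[, 2]),
                        pmax(extra_edges[, 1], extra_edges[, 2])))
    e <- unique(e)
  }
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = mesh$n_vertices, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(e)))
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distances on the mesh edge graph
#'
#' Shortest-path (Dijkstra) distances from a source vertex over the undirected
#' edge graph of the triangulation, with Euclidean edge lengths in mm.
#' Vertices not connected to the source get `Inf`.
#'
#' @param mesh a [surface_mesh()].
#' @param source 1-based source vertex index.
#' @param extra_edges optional integer matrix of additional edges (e.g.
#'   transmural bridges), one `(i, j)` pair per row.
#' @return Numeric vector of length `n_vertices`; 0 at the source.
#' @export
geodesic_distances <- function(mesh, source, extra_edges = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  source <- as.integer(source)
  if (length(source) != 1L || is.na(source) || source < 1L ||
      source > mesh$n_vertices)
    stop("'source' must be a vertex index in [1, ", mesh$n_vertices, "]")
  g <- mesh_graph(mesh, extra_edges)
  d <- igraph::distances(g, v = source, algorithm = "dijkstra")
  as.numeric(d[1, ])
}

#' Pair each epicardial vertex with its closest endocardial vertex
#'
#' For each EPI-labeled vertex, finds the ENDO-labeled vertex at minimum
#' Euclidean distance (ties broken by smallest vertex index).  Used to
#' measure transmural activation delays.
#'
#' @param mesh a [surface_mesh()] containing both EPI and ENDO vertices.
#' @return A data.frame with columns `epi` (vertex index), `endo` (paired
#'   vertex index) and `distance_mm`.
#' @export
pair_endo_epi <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  epi <- which(mesh$surface_label == "EPI")
  endo <- which(mesh$surface_label == "ENDO")
  if (length(endo) == 0L)
    stop("mesh has no ENDO vertices: endo-epicardial delays are undefined ",
         "on an epicardium-only mesh")
  ve <- mesh$vertices[epi, , drop = FALSE]
  vn <- mesh$vertices[endo, , drop = FALSE]
  # squared distance matrix epi x endo without forming per-pair loops
  d2 <- outer(rowSums(ve^2), rowSums(vn^2), "+") - 2 * ve %*% t(vn)
  d2[d2 < 0] <- 0
  best <- apply(d2, 1, which.min)  # first minimum = smallest endo index
  data.frame(epi = epi, endo = endo[best],
             distance_mm = sqrt(d2[cbind(seq_along(epi), best)]))
}
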