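#' @importFrom stats median approx quantile setNames spline splinefun
#' @importFrom utils head tail read.csv write.csv
#' @importFrom tools file_ext
NULL

#' Triangulated vessel surface mesh
#'
#' Container for a triangulated lumen wall: an oriented triangle mesh whose
#' open boundary loops are the inlet/outlet cross-sections. All coordinates
#' are in millimetres.
#'
#' @param vertices numeric matrix, n x 3, vertex positions (mm).
#' @param triangles integer matrix, m x 3, 1-based vertex indices. Triangles
#'   must be consistently oriented (outward normals).
#' @param validate logical; run the manifold/degeneracy checks (default TRUE).
#'
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles` and `boundary_loops` (a list of ordered vertex-index rings,
#'   one per open boundary).
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  mesh <- structure(
    list(vertices = vertices, triangles = triangles,
         boundary_loops = list()),
    class = "surface_mesh")
  mesh$boundary_loops <- mesh_boundary_loops(mesh)
  if (validate) validate_surface_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, %d open boundaries\n",
              nrow(x$vertices), nrow(x$triangles), length(x$boundary_loops)))
  invisible(x)
}

# Directed edge table; interior edges appear once per direction in a
# consistently oriented manifold mesh.
mesh_directed_edges <- function(mesh) {
  tr <- mesh$triangles
  cbind(c(tr[, 1L], tr[, 2L], tr[, 3L]),
        c(tr[, 2L], tr[, 3L], tr[, 1L]))
}

edge_key <- function(a, b) {
  n <- max(a, b)
  pmin(a, b) * (n + 1) + pmax(a, b)
}

#' Validate a surface mesh
#'
#' Checks that every non-boundary edge is shared by exactly two triangles
#' with opposite directions (manifold + consistent orientation) and that no
#' triangle has zero area.
#'
#' @param mesh a `surface_mesh`.
#' @param area_eps triangles with area below this (mm^2) are degenerate.
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_surface_mesh <- function(mesh, area_eps = 1e-12) {
  de <- mesh_directed_edges(mesh)
  key <- edge_key(de[, 1L], de[, 2L])
  cnt <- table(key)
  if (any(cnt > 2L)) stop("non-manifold mesh: an edge is used by >2 triangles")
  # orientation: an edge used twice must appear once in each direction
  dkey <- paste(de[, 1L], de[, 2L])
  if (anyDuplicated(dkey))
    stop("inconsistently oriented mesh: repeated directed edge")
  if (any(tri_areas(mesh) < area_eps)) stop("degenerate (zero-area) triangle")
  invisible(mesh)
}

#' Triangle unit normals (orientation-defined)
#' @param mesh a `surface_mesh`.
#' @return m x 3 matrix of unit normals.
#' @export
tri_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
}

#' Triangle areas (mm^2)
#' @param mesh a `surface_mesh`.
#' @return numeric vector of length m.
#' @export
tri_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Ordered open-boundary loops of a mesh
#'
#' Boundary edges are directed edges without an opposite partner; they are
#' chained into closed rings (inlets/outlets).
#'
#' @param mesh a `surface_mesh`.
#' @return list of integer vectors (ordered vertex rings).
#' @export
mesh_boundary_loops <- function(mesh) {
  de <- mesh_directed_edges(mesh)
  dkey <- paste(de[, 1L], de[, 2L])
  rkey <- paste(de[, 2L], de[, 1L])
  is_bnd <- !(rkey %in% dkey)
  be <- de[is_bnd, , drop = FALSE]
  if (nrow(be) == 0L) return(list())
  nxt <- setNames(be[, 2L], as.character(be[, 1L]))
  used <- setNames(rep(FALSE, nrow(be)), as.character(be[, 1L]))
  loops <- list()
  for (start in as.character(be[, 1L])) {
    if (used[[start]]) next
    loop <- integer(0)
    cur <- start
    repeat {
      used[[cur]] <- TRUE
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (cur == start) break
      if (length(loop) > nrow(be)) stop("open boundary does not close")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# vertex -> vertex adjacency as a list (used by smoothing)
vertex_neighbors <- function(mesh) {
  de <- mesh_directed_edges(mesh)
  split(de[, 2L], de[, 1L])
}

#' Read a surface mesh from STL or OBJ
#'
#' STL may be ASCII or binary (auto-detected); duplicate vertices arising
#' from the STL soup representation are merged exactly.
#'
#' @param path file path; format chosen by extension (.stl, .obj).
#' @param validate run mesh validation after load.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, validate = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path, validate = validate),
         obj = read_obj(path, validate = validate),
         stop("unsupported mesh format: ", ext))
}

#' Write a surface mesh to STL or OBJ
#' @param mesh a `surface_mesh`.
#' @param path output path (.stl ascii by default, .obj).
#' @param binary for STL: write the 80-byte-header binary layout.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", ext))
  invisible(path)
}

read_stl <- function(path, validate = TRUE) {
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", 80L)
  header <- rawToChar(head_raw[head_raw != as.raw(0)])
  close(con)
  is_ascii <- grepl("^\\s*solid", header) && {
    txt <- readLines(path, n = 5L, warn = FALSE)
    any(grepl("facet|endsolid", txt))
  }
  if (is_ascii) read_stl_ascii(path, validate) else read_stl_binary(path, validate)
}

read_stl_ascii <- function(path, validate = TRUE) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(f)
    as.numeric(f[2:4])))
  soup_to_mesh(nums, validate)
}

read_stl_binary <- function(path, validate = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", ntri * 50L)
  idx <- rep(seq_len(ntri) - 1L, each = 36L) * 50L +
    rep(12L + seq_len(36L), times = ntri)   # skip normal (12B), read 9 floats
  f <- readBin(rec[idx], "numeric", n = ntri * 9L, size = 4L, endian = "little")
  m <- matrix(f, ncol = 3L, byrow = TRUE)
  soup_to_mesh(m, validate)
}

soup_to_mesh <- function(verts9, validate = TRUE) {
  key <- apply(verts9, 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  vertices <- verts9[uk, , drop = FALSE]
  triangles <- matrix(vid, ncol = 3L, byrow = TRUE)
  surface_mesh(vertices, triangles, validate = validate)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; tr <- mesh$triangles; nn <- tri_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(nn[i, ], t(v[tr[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid fusiflow", con)
    for (i in seq_len(nrow(tr))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nn[i, 1], nn[i, 2], nn[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[tr[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid fusiflow", con)
  }
  invisible(path)
}

read_obj <- function(path, validate = TRUE) {
  txt <- readLines(path, warn = FALSE)
  vl <- txt[startsWith(txt, "v ")]
  fl <- txt[startsWith(txt, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(f)
    as.numeric(f[2:4])))
  triangles <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(f) {
    ix <- as.integer(sub("/.*", "", f[-1L]))
    if (length(ix) != 3L) stop("only triangular OBJ faces supported")
    ix
  }))
  surface_mesh(vertices, triangles, validate = validate)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; tr <- mesh$triangles
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  invisible(path)
}
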