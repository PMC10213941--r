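# Iso-surface extraction from labelled voxel volumes (marching tetrahedra on
# a lightly smoothed indicator field), plus binary STL and legacy-ASCII VTK
# export. The 6-tetrahedra cube decomposition shares every cube-face diagonal
# with the neighbouring cube, so the extracted surface is watertight by
# construction for regions closed inside the grid.

# one 3-point box-blur pass along each axis (zero-padded)
box_blur3 <- function(f) {
  d <- dim(f)
  g <- f
  sh <- function(a, axis, by) {
    out <- array(0, dim(a))
    idx_src <- lapply(dim(a), seq_len)
    idx_dst <- idx_src
    n <- dim(a)[axis]
    if (by == 1) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else         { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) g <- (sh(g, axis, -1) + g + sh(g, axis, 1)) / 3
  g
}

# triangles (as lists of edges, each edge a pair of tet-corner ids 1..4)
# separating the "inside" corner set from the rest of a tetrahedron
mt_case <- function(inside) {
  outside <- setdiff(1:4, inside)
  if (length(inside) %in% c(0, 4)) return(list())
  if (length(inside) == 3) { tmp <- inside; inside <- outside; outside <- tmp }
  if (length(inside) == 1) {
    v <- inside; o <- outside
    return(list(rbind(c(v, o[1]), c(v, o[2]), c(v, o[3]))))
  }
  i <- inside; o <- outside  # quad on edges (i1,o1),(i1,o2),(i2,o2),(i2,o1)
  list(rbind(c(i[1], o[1]), c(i[1], o[2]), c(i[2], o[2])),
       rbind(c(i[1], o[1]), c(i[2], o[2]), c(i[2], o[1])))
}

# 6-tet decomposition of the unit cube around the 0-7 main diagonal;
# cube corner ids 1..8 correspond to offsets (x,y,z) in binary order
mt_tets <- rbind(
  c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))

mt_cases <- lapply(0:15, function(m) {
  mt_case(which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0))
})

#' Extract a triangulated iso-surface from a voxel phantom
#'
#' Smooths the binary union of all labelled structures with a separable box
#' filter (emulating the smoothing applied to segmented CT surfaces) and
#' polygonises the 0.5 iso-surface by marching tetrahedra. Vertex coordinates
#' are physical mm.
#'
#' @param phantom A [build_phantom()] result, or a raw 3D numeric array (then
#'   interpreted as a scalar field with `spacing`/`origin` taken from the
#'   remaining arguments).
#' @param iso Iso-level in the smoothed indicator field.
#' @param smooth_passes Box-blur passes (0 disables smoothing).
#' @param spacing,origin Used only when `phantom` is a raw array.
#' @return An object of class `surface_mesh`: `vertices` (n x 3 mm),
#'   `faces` (m x 3 vertex indices).
#' @examples
#' ph <- build_phantom(make_reference_models()$A, spacing = 0.25)
#' mesh <- extract_surface(ph)
#' mesh
#' @export
extract_surface <- function(phantom, iso = 0.5, smooth_passes = 3,
                            spacing = 1, origin = c(0, 0, 0)) {
  if (inherits(phantom, "voxel_phantom")) {
    field <- array(as.numeric(phantom$labels > 0), dim(phantom$labels))
    spacing <- phantom$spacing
    origin <- phantom$origin
  } else if (is.array(phantom) && length(dim(phantom)) == 3) {
    field <- array(as.numeric(phantom), dim(phantom))
    spacing <- rep(spacing, length.out = 3)
  } else stop("phantom must be a voxel_phantom or a 3D array")
  if (sum(field) == 0) stop("empty phantom: nothing to extract")
  for (i in seq_len(smooth_passes)) field <- box_blur3(field)
  field[field == iso] <- iso + 1e-9

  d <- dim(field)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  inside <- field > iso
  # cube corner linear offsets, binary (x,y,z) order
  corner_off <- c(0, 1, nx, nx + 1, nx * ny, nx * ny + 1, nx * ny + nx,
                  nx * ny + nx + 1)
  base <- which(array(TRUE, d - 1L))  # linear ids in the (d-1) cube grid
  cube_ijk <- arrayInd(base, d - 1L)
  cube_lin <- (cube_ijk[, 3] - 1) * nx * ny + (cube_ijk[, 2] - 1) * nx +
    cube_ijk[, 1]
  cnt <- integer(length(cube_lin))
  for (off in corner_off) cnt <- cnt + inside[cube_lin + off]
  active <- cnt > 0L & cnt < 8L
  cube_lin <- cube_lin[active]
  cube_ijk <- cube_ijk[active, , drop = FALSE]
  if (length(cube_lin) == 0) stop("iso-surface is empty at this iso level")

  corner_shift <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  fC <- sapply(1:8, function(c8) field[cube_lin + corner_off[c8]])
  if (is.null(dim(fC))) dim(fC) <- c(1, 8)
  coord <- function(c8, ax)
    origin[ax] + (cube_ijk[, ax] - 0.5 + corner_shift[c8, ax]) * spacing[ax]

  tri_list <- vector("list", 6 * 14)
  ti <- 0
  for (tet in seq_len(6)) {
    cid <- mt_tets[tet, ]
    f4 <- fC[, cid, drop = FALSE]
    msk <- (f4[, 1] > iso) + 2 * (f4[, 2] > iso) + 4 * (f4[, 3] > iso) +
      8 * (f4[, 4] > iso)
    for (m in 1:14) {
      rows <- which(msk == m)
      if (length(rows) == 0) next
      for (tri in mt_cases[[m + 1]]) {
        # interpolate the three edge points for all rows at once
        P <- matrix(0, length(rows), 9)
        for (e in 1:3) {
          i1 <- tri[e, 1]; i2 <- tri[e, 2]
          fa <- f4[rows, i1]; fb <- f4[rows, i2]
          t <- (iso - fa) / (fb - fa)
          for (ax in 1:3) {
            pa <- coord(cid[i1], ax)[rows]
            pb <- coord(cid[i2], ax)[rows]
            P[, 3 * (e - 1) + ax] <- pa + t * (pb - pa)
          }
        }
        ti <- ti + 1
        tri_list[[ti]] <- P
      }
    }
  }
  P <- do.call(rbind, tri_list[seq_len(ti)])
  v1 <- P[, 1:3, drop = FALSE]
  v2 <- P[, 4:6, drop = FALSE]
  v3 <- P[, 7:9, drop = FALSE]

  # deduplicate vertices on a fine snap grid
  verts <- rbind(v1, v2, v3)
  snap <- min(spacing) * 1e-6
  key <- paste(round(verts[, 1] / snap), round(verts[, 2] / snap),
               round(verts[, 3] / snap))
  uid <- match(key, key[!duplicated(key)])
  vertices <- verts[!duplicated(key), , drop = FALSE]
  nf <- nrow(v1)
  faces <- cbind(uid[seq_len(nf)], uid[nf + seq_len(nf)], uid[2 * nf + seq_len(nf)])
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!degen, , drop = FALSE]

  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d faces, area %.3f mm^2%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x),
              if (is_watertight(x)) " (watertight)" else ""))
  invisible(x)
}

#' Total area of a triangulated surface
#' @param mesh A `surface_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Is a surface mesh watertight (edge-manifold, closed)?
#' @param mesh A `surface_mesh`.
#' @return TRUE iff every edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2)
}

#' Write a surface mesh as binary STL
#' @param mesh A `surface_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("aqueduct surface mesh", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
           (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
           (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#' @param path STL file written by [write_stl()] (binary, little-endian).
#' @return A `surface_mesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- matrix(0, nf, 9)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    rec[i, ] <- vals[4:12]
  }
  verts <- rbind(rec[, 1:3, drop = FALSE], rec[, 4:6, drop = FALSE],
                 rec[, 7:9, drop = FALSE])
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, key[!duplicated(key)])
  vertices <- verts[!duplicated(key), , drop = FALSE]
  faces <- cbind(uid[seq_len(nf)], uid[nf + seq_len(nf)], uid[2 * nf + seq_len(nf)])
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' Write a labelled voxel volume as legacy ASCII VTK (structured points)
#' @param phantom A `voxel_phantom`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vtk_volume <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  d <- dim(phantom$labels)
  lines <- c(
    "# vtk DataFile Version 3.0",
    "aqueduct labelled inner-ear phantom",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %g %g %g",
            phantom$origin[1] + phantom$spacing[1] / 2,
            phantom$origin[2] + phantom$spacing[2] / 2,
            phantom$origin[3] + phantom$spacing[3] / 2),
    sprintf("SPACING %g %g %g",
            phantom$spacing[1], phantom$spacing[2], phantom$spacing[3]),
    sprintf("POINT_DATA %d", prod(d)),
    "SCALARS label int 1",
    "LOOKUP_TABLE default")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  # VTK structured points iterate x fastest, matching R's column-major order
  writeLines(paste(as.vector(phantom$labels), collapse = " "), con)
  invisible(path)
}

#' Write a surface mesh as legacy ASCII VTK polydata
#' @param mesh A `surface_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aqueduct surface mesh",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(apply(v, 1, function(p) sprintf("%g %g %g", p[1], p[2], p[3])), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(apply(f, 1, function(tr) sprintf("3 %d %d %d",
                                              tr[1] - 1, tr[2] - 1, tr[3] - 1)), con)
  invisible(path)
}

#' Read a labelled volume from legacy ASCII VTK (structured points)
#'
#' Counterpart of [write_vtk_volume()]; returns a phantom without ground
#' truth (`ground_truth = NULL`), sufficient for [measure_va_widths()].
#'
#' @param path VTK file.
#' @return A `voxel_phantom`.
#' @export
read_vtk_volume <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("DIMENSIONS ", "", lines[grep("^DIMENSIONS", lines)]), " ")[[1]])
  org <- as.numeric(strsplit(sub("ORIGIN ", "", lines[grep("^ORIGIN", lines)]), " ")[[1]])
  spc <- as.numeric(strsplit(sub("SPACING ", "", lines[grep("^SPACING", lines)]), " ")[[1]])
  i0 <- grep("^LOOKUP_TABLE", lines)[1]
  vals <- as.integer(strsplit(paste(lines[(i0 + 1):length(lines)], collapse = " "),
                              "\\s+")[[1]])
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims)) stop("VTK volume is truncated")
  structure(
    list(labels = array(vals, dims), spacing = spc,
         origin = org - spc / 2, ground_truth = NULL,
         membrane_center = NULL, membrane_normal = NULL),
    class = "voxel_phantom")
}
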