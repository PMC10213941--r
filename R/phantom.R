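# Synthetic labelled voxel phantom of the inner ear, standing in for segmented
# temporal-bone CT, and centerline-based VA width morphometry on it.
#
# Coordinate convention: the label array has dimension order (x, y, z),
# 1-based; the physical position of voxel (i, j, k) is
# origin + (c(i, j, k) - 0.5) * spacing, in mm. The VA runs along +x and its
# external aperture (operculum) lies exactly on the max-x boundary face.

#' Label codes used in voxel phantoms
#'
#' @format Named integer vector: background 0, cochlea 1, vestibule 2,
#'   semicircular canal 3, vestibular aqueduct 4.
#' @export
phantom_codes <- c(background = 0L, cochlea = 1L, vestibule = 2L,
                   canal = 3L, va = 4L)

# Fixed anatomy of the synthetic phantom (mm, vestibule-centred frame).
# The cavity is an idealised union: two overlapping ellipsoids (cochlea,
# vestibule) and one torus (lateral semicircular canal); the VA is a tapered
# circular tube along +x. Shapes are deliberately schematic: only the VA
# calibre and centerline length matter to the hydraulics.
phantom_anatomy <- function() {
  list(
    vestibule = list(center = c(0, 0, 0), semi = c(2.0, 1.5, 1.5)),
    cochlea   = list(center = c(-3.2, 0, 0), semi = c(2.2, 1.8, 1.5)),
    canal     = list(center = c(0, 2.0, 0), ring = 2.6, tube = 0.4),
    va_axis_y = 0, va_axis_z = 0,
    va_x_embed = 1.2,   # tube begins inside the vestibule to guarantee fusion
    va_x_inner = 2.0,   # arc length 0 of the taper profile (vestibule apex)
    membrane_center = c(-3.2, -1.8, 0),
    membrane_normal = c(0, -1, 0))
}

#' Rasterize an inner-ear model into a labelled voxel phantom
#'
#' Deterministic (seed-free) rasterization of a schematic inner-ear cavity
#' (cochlea and vestibule ellipsoids, one semicircular-canal torus) plus the
#' model's tapered VA channel. The VA runs along +x; its external aperture is
#' flush with the max-x face of the volume, emulating the aqueduct opening
#' onto the posterior petrous surface. The generating model is stored as
#' ground truth.
#'
#' @param model An [inner_ear_model()].
#' @param spacing Isotropic voxel spacing, mm. The default 0.1 mm is chosen so
#'   the narrowest (normal) aqueduct spans several voxels; at CT-like 1 mm the
#'   0.8 mm normal VA is sub-voxel (a warning is issued whenever
#'   `spacing > width_midpoint / 2`).
#' @return An object of class `voxel_phantom`: integer label array `labels`,
#'   `spacing` (mm), `origin` (mm, corner of the volume), `ground_truth`
#'   (the model), and the membrane patch location.
#' @examples
#' ph <- build_phantom(make_reference_models()$Normal, spacing = 0.2)
#' table(ph$labels)
#' @export
build_phantom <- function(model, spacing = 0.1) {
  stopifnot(inherits(model, "inner_ear_model"))
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive voxel size in mm")
  if (spacing > model$va$width_midpoint / 2)
    warning(sprintf(paste0("spacing %.3g mm exceeds half the VA midpoint ",
                           "width %.3g mm; measured widths will be unreliable"),
                    spacing, model$va$width_midpoint))
  anat <- phantom_anatomy()
  va <- model$va
  x_out <- anat$va_x_inner + va$length
  r_va_max <- max(va$width_operculum, va$width_midpoint, va$width_inner) / 2

  # domain bounds (mm); max-x edge must land exactly on the VA aperture
  x_min <- -5.8
  y_lim <- c(min(-3.0, anat$va_axis_y - r_va_max - 0.4),
             max(5.4, anat$va_axis_y + r_va_max + 0.4))
  z_lim <- c(min(-2.8, anat$va_axis_z - r_va_max - 0.4),
             max(2.8, anat$va_axis_z + r_va_max + 0.4))
  nx <- ceiling((x_out - x_min) / spacing)
  x_min <- x_out - nx * spacing
  ny <- ceiling(diff(y_lim) / spacing)
  nz <- ceiling(diff(z_lim) / spacing)
  origin <- c(x_min, y_lim[1], z_lim[1])

  xs <- origin[1] + (seq_len(nx) - 0.5) * spacing
  ys <- origin[2] + (seq_len(ny) - 0.5) * spacing
  zs <- origin[3] + (seq_len(nz) - 0.5) * spacing
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)

  in_ellipsoid <- function(e) {
    ((X - e$center[1]) / e$semi[1])^2 +
      ((Y - e$center[2]) / e$semi[2])^2 +
      ((Z - e$center[3]) / e$semi[3])^2 <= 1
  }
  cv <- anat$canal
  in_canal <- (sqrt((X - cv$center[1])^2 + (Y - cv$center[2])^2) - cv$ring)^2 +
    (Z - cv$center[3])^2 <= cv$tube^2
  d_local <- va_width_at(va, X - anat$va_x_inner)  # clamps s to [0, length]
  in_va_tube <- X >= anat$va_x_embed & X <= x_out &
    (Y - anat$va_axis_y)^2 + (Z - anat$va_axis_z)^2 <= (d_local / 2)^2

  lab <- integer(nx * ny * nz)
  lab[in_ellipsoid(anat$cochlea)] <- phantom_codes[["cochlea"]]
  lab[in_canal] <- phantom_codes[["canal"]]
  lab[in_ellipsoid(anat$vestibule)] <- phantom_codes[["vestibule"]]
  lab[in_va_tube & lab == 0L] <- phantom_codes[["va"]]
  dim(lab) <- c(nx, ny, nz)

  present <- phantom_codes[-1] %in% unique(as.vector(lab))
  if (!all(present))
    stop("phantom is missing structure(s): ",
         paste(names(phantom_codes[-1])[!present], collapse = ", "))

  structure(
    list(labels = lab, spacing = rep(spacing, 3), origin = origin,
         ground_truth = model,
         membrane_center = anat$membrane_center,
         membrane_normal = anat$membrane_normal),
    class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Voxel phantom of inner-ear model \"%s\"\n",
              if (is.null(x$ground_truth)) "<unknown>" else x$ground_truth$label))
  cat(sprintf("  grid %d x %d x %d at %.3g mm spacing\n",
              d[1], d[2], d[3], x$spacing[1]))
  counts <- tabulate(x$labels + 1L, nbins = 5L)
  names(counts) <- names(phantom_codes)
  cat("  voxels:",
      paste(sprintf("%s=%d", names(counts)[-1], counts[-1]), collapse = ", "),
      "\n")
  invisible(x)
}

# voxel coordinates (mm) of array indices (n x 3 matrix of i, j, k)
voxel_mm <- function(phantom, ijk) {
  sweep(sweep(ijk - 0.5, 2, phantom$spacing, `*`), 2, phantom$origin, `+`)
}

# Single-component check of a voxel set under face (6-)connectivity, via
# igraph. A rasterized tube is always face-connected, so 6-connectivity is
# sufficient and much cheaper than the full 26-neighbourhood.
voxels_connected <- function(ijk, dims) {
  n <- nrow(ijk)
  if (n <= 1) return(TRUE)
  lin <- (ijk[, 3] - 1) * dims[1] * dims[2] + (ijk[, 2] - 1) * dims[1] + ijk[, 1]
  edges <- NULL
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (off in offs) {
    nb <- cbind(ijk[, 1] + off[1], ijk[, 2] + off[2], ijk[, 3] + off[3])
    ok <- nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    nb_lin <- (nb[, 3] - 1) * dims[1] * dims[2] + (nb[, 2] - 1) * dims[1] + nb[, 1]
    hit <- match(nb_lin, lin)
    keep <- ok & !is.na(hit)
    if (any(keep)) edges <- rbind(edges, cbind(which(keep), hit[keep]))
  }
  if (is.null(edges)) return(FALSE)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$no == 1
}

# maximal chord (mm) of a planar point set, hull-accelerated
max_chord <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
  d <- as.matrix(stats::dist(pts))
  max(d)
}

#' Measure VA widths on a voxel phantom
#'
#' Extracts the aqueduct centerline as the ordered sequence of per-slice
#' centroids from the inner opening to the external aperture, locates the
#' arc-length midpoint, and returns the maximal chord of the cross-section
#' there and at the aperture. One voxel spacing is added to each chord so the
#' estimate accounts for the finite voxel extent; the estimator is accurate to
#' within one voxel spacing. Cross-sections are taken perpendicular to the
#' duct axis, which in these phantoms is the +x direction.
#'
#' @param phantom A [build_phantom()] result.
#' @return Named numeric vector `c(width_midpoint = , width_operculum = )`
#'   in mm, with attribute `"lva"` holding the Cincinnati verdict.
#' @examples
#' ph <- build_phantom(make_reference_models()$Normal, spacing = 0.2)
#' measure_va_widths(ph)
#' @export
measure_va_widths <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  lab <- phantom$labels
  dims <- dim(lab)
  va_idx <- which(lab == phantom_codes[["va"]])
  if (length(va_idx) == 0)
    stop("phantom defect: no vestibular-aqueduct voxels present")
  ijk <- arrayInd(va_idx, dims)
  if (!voxels_connected(ijk, dims))
    stop("phantom defect: vestibular-aqueduct voxels are disconnected")
  if (max(ijk[, 1]) != dims[1])
    stop("phantom defect: vestibular aqueduct does not reach the boundary face")
  # adjacency to the vestibule label along -x (the duct emerges from it)
  inner <- ijk[ijk[, 1] > 1, , drop = FALSE]
  touch <- lab[cbind(inner[, 1] - 1L, inner[, 2], inner[, 3])] ==
    phantom_codes[["vestibule"]]
  if (!any(touch))
    stop("phantom defect: vestibular aqueduct is not attached to the vestibule")

  mm <- voxel_mm(phantom, ijk)
  # centerline: per-x-slice centroid, ordered inner -> outer
  xs <- sort(unique(ijk[, 1]))
  cx <- phantom$origin[1] + (xs - 0.5) * phantom$spacing[1]
  cy <- tapply(mm[, 2], factor(ijk[, 1], levels = xs), mean)
  cz <- tapply(mm[, 3], factor(ijk[, 1], levels = xs), mean)
  seg <- sqrt(diff(cx)^2 + diff(cy)^2 + diff(cz)^2)
  arc <- c(0, cumsum(seg))
  i_mid <- which.min(abs(arc - arc[length(arc)] / 2))

  s <- phantom$spacing[1]
  chord_at <- function(slice_x) {
    sel <- ijk[, 1] == slice_x
    max_chord(mm[sel, 2:3, drop = FALSE]) + s
  }
  widths <- c(width_midpoint = chord_at(xs[i_mid]),
              width_operculum = chord_at(xs[length(xs)]))
  attr(widths, "lva") <- classify_lva(widths[["width_midpoint"]],
                                      widths[["width_operculum"]])
  widths
}
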