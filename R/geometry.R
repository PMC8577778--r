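# STL mesh input/output, voxelization on uniform grids, morphometrics
# (volume, body length, bounding-box diagonal), body-part partitioning
# and model editing (leg removal).

.part_legend <- c(air = 0L, head = 1L, thorax = 2L, abdomen = 3L,
                  legs = 4L, other = 5L)

#' Construct a triangle mesh
#'
#' A triangle soup: a numeric matrix with 3 columns (x, y, z) and one row
#' per vertex, rows grouped in threes per facet. Coordinates are metres
#' internally; STL files are interpreted in the units given at read time
#' (millimetres by default, the usual convention for insect-scale
#' models).
#'
#' @param vertices numeric matrix, `3 * n_facets` rows by 3 columns.
#' @return An object of class `rf_mesh`.
#' @export
rf_mesh <- function(vertices) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            nrow(vertices) %% 3 == 0, nrow(vertices) > 0)
  structure(list(vertices = vertices, n_facets = nrow(vertices) / 3L),
            class = "rf_mesh")
}

#' @export
print.rf_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat("rf_mesh:", x$n_facets, "facets, bbox",
      paste(sprintf("[%.3g, %.3g]", bb[1, ], bb[2, ]), collapse = " x "),
      "m\n")
  invisible(x)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed-tetrahedron (divergence-theorem) sum; exact for watertight,
#' consistently wound meshes.
#'
#' @param mesh an [rf_mesh()].
#' @return Volume in cubic metres.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  i0 <- seq(1, nrow(v), by = 3)
  a <- v[i0, , drop = FALSE]; b <- v[i0 + 1, , drop = FALSE]
  d <- v[i0 + 2, , drop = FALSE]
  cx <- b[, 2] * d[, 3] - b[, 3] * d[, 2]
  cy <- b[, 3] * d[, 1] - b[, 1] * d[, 3]
  cz <- b[, 1] * d[, 2] - b[, 2] * d[, 1]
  abs(sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6)
}

#' Check that every mesh edge is shared by exactly two facets
#'
#' @param mesh an [rf_mesh()].
#' @param tol vertex welding tolerance in metres.
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(mesh, tol = 1e-12) {
  v <- round(mesh$vertices / max(tol, 1e-300))
  key <- paste(v[, 1], v[, 2], v[, 3])
  vid <- match(key, key)
  tri <- matrix(vid, ncol = 3, byrow = TRUE)
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(ek) == 2)
}

#' Read an STL file (ASCII or binary)
#'
#' @param path file path.
#' @param units length unit of the file coordinates: `"mm"` (default,
#'   the common convention for insect-scale exports) or `"m"`.
#' @return An [rf_mesh()] with coordinates in metres.
#' @export
read_stl <- function(path, units = c("mm", "m")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  scale <- if (units == "mm") 1e-3 else 1
  sz <- file.info(path)$size
  head_raw <- readBin(path, "raw", n = min(sz, 512))
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  if (is_ascii) {
    ln <- readLines(path, warn = FALSE)
    vx <- grep("^\\s*vertex", ln, value = TRUE)
    if (length(vx) == 0 || length(vx) %% 3 != 0)
      stop("malformed ASCII STL '", path, "': ", length(vx),
           " vertex lines (not a positive multiple of 3)")
    nums <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
      if (length(p) != 4) stop("malformed ASCII STL vertex line: ",
                               paste(p, collapse = " "))
      as.numeric(p[2:4])
    }))
    return(rf_mesh(nums * scale))
  }
  # binary: 80-byte header, uint32 facet count, 50 bytes per facet
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(nf) || nf <= 0)
    stop("malformed binary STL '", path, "': bad facet count at byte 80")
  expected <- 84 + 50 * as.numeric(nf)
  if (sz < expected)
    stop("truncated binary STL '", path, "': file has ", sz,
         " bytes, facet count implies ", expected,
         " (truncation at byte ", sz, ")")
  verts <- matrix(NA_real_, nrow = 3 * nf, ncol = 3)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    verts[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], ncol = 3, byrow = TRUE)
  }
  rf_mesh(verts * scale)
}

#' Write an STL file
#'
#' @param mesh an [rf_mesh()] (coordinates in metres).
#' @param path output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @param units unit the coordinates are written in (`"mm"` default).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii"),
                      units = c("mm", "m")) {
  format <- match.arg(format); units <- match.arg(units)
  scale <- if (units == "mm") 1e3 else 1
  v <- mesh$vertices * scale
  nf <- mesh$n_facets
  i0 <- seq(1, nrow(v), by = 3)
  e1 <- v[i0 + 1, , drop = FALSE] - v[i0, , drop = FALSE]
  e2 <- v[i0 + 2, , drop = FALSE] - v[i0, , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid rfdosim", con)
    for (t in seq_len(nf)) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[t, 1], nrm[t, 2], nrm[t, 3]), con)
      writeLines("    outer loop", con)
      for (q in 0:2)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           v[3 * t - 2 + q, 1], v[3 * t - 2 + q, 2],
                           v[3 * t - 2 + q, 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid rfdosim", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    for (t in seq_len(nf)) {
      writeBin(as.numeric(c(nrm[t, ], t(v[(3 * t - 2):(3 * t), ]))), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Construct a voxel model
#'
#' A uniform isotropic occupancy grid. `origin` is the coordinate of the
#' low corner of voxel (1,1,1); voxel (i,j,k) spans
#' `origin + ((i-1)..i, ...) * h`.
#'
#' @param occupancy 3D logical array.
#' @param spacing isotropic voxel edge length in metres (> 0).
#' @param origin numeric length-3, metres.
#' @param labels optional 3D integer array (same dim as `occupancy`);
#'   0 = air, 1 = head, 2 = thorax, 3 = abdomen, 4 = legs, 5 = other.
#'   Must be nonzero exactly where `occupancy` is `TRUE`.
#' @param body_axis which grid axis the body length lies along
#'   (1, 2, 3 or "x", "y", "z").
#' @return An object of class `voxel_model`.
#' @export
voxel_model <- function(occupancy, spacing, origin = c(0, 0, 0),
                        labels = NULL, body_axis = 1L) {
  stopifnot(is.logical(occupancy), length(dim(occupancy)) == 3,
            is.numeric(spacing), spacing > 0, length(origin) == 3)
  if (is.character(body_axis))
    body_axis <- match(body_axis, c("x", "y", "z"))
  body_axis <- as.integer(body_axis)
  stopifnot(body_axis %in% 1:3)
  if (!is.null(labels)) {
    stopifnot(identical(dim(labels), dim(occupancy)))
    if (!all((labels != 0L) == occupancy))
      stop("labels must be nonzero exactly where occupancy is TRUE")
  }
  structure(list(occupancy = occupancy, spacing = spacing,
                 origin = as.numeric(origin), labels = labels,
                 body_axis = body_axis, legend = .part_legend),
            class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("voxel_model: %d x %d x %d voxels at %.3g um, %d occupied (%.4g mm^3)\n",
              d[1], d[2], d[3], x$spacing * 1e6, sum(x$occupancy),
              sum(x$occupancy) * x$spacing^3 * 1e9))
  if (!is.null(x$labels)) {
    tab <- table(x$labels[x$labels != 0])
    nm <- names(.part_legend)[match(names(tab), as.character(.part_legend))]
    cat("  parts:", paste(sprintf("%s=%s", nm, tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Voxelize a triangle mesh on a uniform grid
#'
#' A voxel is occupied iff its center lies inside the closed surface
#' (parity ray casting along +x with deterministic jitter on degenerate
#' hits). The grid is padded with at least one empty voxel on all sides.
#'
#' @param mesh an [rf_mesh()].
#' @param h voxel edge length in metres (> 0).
#' @param strict if `TRUE` (default), require the mesh to be watertight.
#' @param body_axis passed to [voxel_model()].
#' @return A [voxel_model()].
#' @export
voxelize <- function(mesh, h, strict = TRUE, body_axis = 1L) {
  stopifnot(inherits(mesh, "rf_mesh"), h > 0)
  if (mesh$n_facets == 0) stop("empty mesh")
  if (strict && !is_watertight(mesh))
    stop("mesh is not watertight; rerun with strict = FALSE to force")
  bb <- apply(mesh$vertices, 2, range)
  # the 1.25-cell pad keeps voxel centers off axis-aligned surfaces
  # that coincide with grid planes
  origin <- bb[1, ] - 1.25 * h
  dims <- as.integer(ceiling((bb[2, ] - origin) / h) + 1L)
  occ <- voxelize_cpp(mesh$vertices, h, origin, dims)
  dim(occ) <- dims
  voxel_model(occ, h, origin, body_axis = body_axis)
}

#' Extract the boundary surface of a voxel model as a triangle mesh
#'
#' Emits two triangles per exposed voxel face, outward-wound; the result
#' is watertight by construction and voxelizing it reproduces the mask.
#'
#' @param v a [voxel_model()].
#' @return An [rf_mesh()].
#' @export
voxel_surface_mesh <- function(v) {
  occ <- v$occupancy; h <- v$spacing; o <- v$origin
  d <- dim(occ)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  tris <- list()
  # face templates: for each axis/side, 2 triangles as offsets of the
  # voxel low corner, wound so the normal points out of the voxel
  faces <- list(
    list(ax = 1, side = -1, quad = rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0))),
    list(ax = 1, side = +1, quad = rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1))),
    list(ax = 2, side = -1, quad = rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1))),
    list(ax = 2, side = +1, quad = rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0))),
    list(ax = 3, side = -1, quad = rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0))),
    list(ax = 3, side = +1, quad = rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))))
  idx <- which(pad, arr.ind = TRUE)
  for (f in faces) {
    shift <- c(0L, 0L, 0L); shift[f$ax] <- f$side
    nb <- idx; nb[, 1] <- nb[, 1] + shift[1]
    nb[, 2] <- nb[, 2] + shift[2]; nb[, 3] <- nb[, 3] + shift[3]
    exposed <- !pad[nb]
    if (!any(exposed)) next
    corner <- idx[exposed, , drop = FALSE] - 2L  # 0-based voxel index
    n <- nrow(corner)
    q <- f$quad
    t1 <- rbind(corner + matrix(q[1, ], n, 3, byrow = TRUE),
                corner + matrix(q[2, ], n, 3, byrow = TRUE),
                corner + matrix(q[3, ], n, 3, byrow = TRUE))
    t2 <- rbind(corner + matrix(q[1, ], n, 3, byrow = TRUE),
                corner + matrix(q[3, ], n, 3, byrow = TRUE),
                corner + matrix(q[4, ], n, 3, byrow = TRUE))
    # interleave rows so each facet's 3 vertices are consecutive
    reorder <- function(m) m[as.vector(t(matrix(seq_len(3 * n), ncol = 3))), ,
                             drop = FALSE]
    tris[[length(tris) + 1L]] <- reorder(t1)
    tris[[length(tris) + 1L]] <- reorder(t2)
  }
  verts <- do.call(rbind, tris)
  rf_mesh(sweep(verts * h, 2, o, "+"))
}

#' Morphometrics of a voxel model
#'
#' Volume (occupied count times \eqn{h^3}), body length (occupied extent
#' along the body axis, restricted to trunk labels head/thorax/abdomen
#' when labels are present), and the space diagonal of the bounding box
#' of all occupied voxels.
#'
#' @param v a [voxel_model()].
#' @param axis body axis override (default: the model's `body_axis`).
#' @return A list with `volume_mm3`, `body_length_mm`, `diagonal_mm`.
#' @export
model_metrics <- function(v, axis = NULL) {
  stopifnot(inherits(v, "voxel_model"))
  if (!any(v$occupancy)) stop("empty model")
  if (is.null(axis)) axis <- v$body_axis
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  h <- v$spacing
  occ_idx <- which(v$occupancy, arr.ind = TRUE)
  ext <- apply(occ_idx, 2, function(ix) diff(range(ix)) + 1L) * h
  if (!is.null(v$labels)) {
    trunk <- v$labels %in% 1:3
    dim(trunk) <- dim(v$labels)
    tix <- which(trunk, arr.ind = TRUE)
    body_len <- (diff(range(tix[, axis])) + 1L) * h
  } else {
    body_len <- ext[axis]
  }
  list(volume_mm3 = sum(v$occupancy) * h^3 * 1e9,
       body_length_mm = unname(body_len) * 1e3,
       diagonal_mm = unname(sqrt(sum(ext^2))) * 1e3)
}

.resolve_labels <- function(v, parts) {
  if (is.character(parts)) {
    unknown <- setdiff(parts, names(v$legend))
    if (length(unknown)) stop("unknown part label(s): ",
                              paste(unknown, collapse = ", "))
    unname(v$legend[parts])
  } else as.integer(parts)
}

#' Partition a voxel model into body-part views
#'
#' Selectors are either part label names/ids, or axis-aligned boxes
#' (each a 2 x 3 matrix of low/high corners in metres). Each view is a
#' `voxel_model` restricted to the selector, carrying both its occupied
#' volume and (for boxes) the region volume as attributes.
#'
#' @param v a labeled [voxel_model()].
#' @param parts character/integer vector of part labels, or a list of
#'   2 x 3 box matrices.
#' @return Named list of `voxel_model` views with attributes
#'   `occupied_volume_m3` and `region_volume_m3`.
#' @export
partition_parts <- function(v, parts) {
  stopifnot(inherits(v, "voxel_model"))
  h <- v$spacing
  out <- list()
  if (is.list(parts)) {
    d <- dim(v$occupancy)
    dom_lo <- v$origin; dom_hi <- v$origin + d * h
    centers <- lapply(1:3, function(a) v$origin[a] + (seq_len(d[a]) - 0.5) * h)
    for (q in seq_along(parts)) {
      box <- parts[[q]]
      stopifnot(is.matrix(box), dim(box) == c(2, 3))
      if (any(box[1, ] < dom_lo - 1e-12) || any(box[2, ] > dom_hi + 1e-12))
        stop("region box ", q, " extends outside the model domain")
      # half-open boxes [lo, hi): voxels whose centers land exactly on
      # a shared face go to the box on the high side, so face-adjacent
      # boxes yield disjoint views
      inside <- outer(outer(centers[[1]] >= box[1, 1] & centers[[1]] < box[2, 1],
                            centers[[2]] >= box[1, 2] & centers[[2]] < box[2, 2],
                            "&"),
                      centers[[3]] >= box[1, 3] & centers[[3]] < box[2, 3], "&")
      occ <- v$occupancy & inside
      lab <- v$labels
      if (!is.null(lab)) { lab[!occ] <- 0L }
      vm <- voxel_model(occ, h, v$origin, labels = lab,
                        body_axis = v$body_axis)
      attr(vm, "occupied_volume_m3") <- sum(occ) * h^3
      attr(vm, "region_volume_m3") <- prod(box[2, ] - box[1, ])
      out[[paste0("region", q)]] <- vm
    }
  } else {
    if (is.null(v$labels)) stop("model has no labels; use box selectors")
    ids <- .resolve_labels(v, parts)
    nms <- if (is.character(parts)) parts else as.character(parts)
    for (q in seq_along(ids)) {
      occ <- v$labels == ids[q]
      dim(occ) <- dim(v$occupancy)
      lab <- v$labels; lab[!occ] <- 0L
      vm <- voxel_model(occ, h, v$origin, labels = lab,
                        body_axis = v$body_axis)
      attr(vm, "occupied_volume_m3") <- sum(occ) * h^3
      attr(vm, "region_volume_m3") <- sum(occ) * h^3
      out[[nms[q]]] <- vm
    }
  }
  out
}

#' Remove labeled parts (or boxed regions) from a voxel model
#'
#' @param v a [voxel_model()].
#' @param parts part label names/ids (requires labels), or a list of
#'   2 x 3 box matrices whose contents are cleared.
#' @return The edited `voxel_model`, with attribute `volume_fraction`
#'   (remaining / original occupied volume).
#' @export
remove_parts <- function(v, parts) {
  stopifnot(inherits(v, "voxel_model"))
  n0 <- sum(v$occupancy)
  occ <- v$occupancy
  lab <- v$labels
  if (is.list(parts)) {
    views <- partition_parts(v, parts)
    for (vw in views) occ <- occ & !vw$occupancy
  } else if (length(parts)) {
    if (is.null(lab)) stop("model has no labels")
    ids <- .resolve_labels(v, parts)
    kill <- lab %in% ids
    dim(kill) <- dim(occ)
    occ <- occ & !kill
  }
  if (!is.null(lab)) lab[!occ] <- 0L
  out <- voxel_model(occ, v$spacing, v$origin, labels = lab,
                     body_axis = v$body_axis)
  attr(out, "volume_fraction") <- sum(occ) / n0
  out
}
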