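# STL / VRML97 serialization and mesh statistics.

faceNormals <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Write a mesh as STL
#'
#' Binary STL (default): 80-byte header, little-endian uint32 triangle
#' count, then 50 bytes per triangle (normal and three vertices as 32-bit
#' floats plus a zero 2-byte attribute), so a 12-triangle cube is exactly
#' 684 bytes.  Normals are recomputed from the counter-clockwise winding.
#' STL does not preserve color information: if the mesh carries per-face
#' colors, a warning is emitted and geometry-only output is written.
#'
#' @param mesh a [TriangleMesh]
#' @param file output path.
#' @param binary write binary (default) or ASCII STL.
#' @export
writeSTL <- function(mesh, file, binary = TRUE) {
  if (nrow(mesh@faces) == 0L) stop("mesh has no faces")
  if (nrow(mesh@faceColor))
    warning("STL does not preserve color information; writing geometry only")
  v <- mesh@vertices; f <- mesh@faces
  n <- faceNormals(v, f)
  ntri <- nrow(f)
  tri <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])           # ntri x 12
  if (binary) {
    con <- file(file, "wb"); on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(ntri), con, size = 4L, endian = "little")
    fl <- writeBin(as.vector(t(tri)), raw(), size = 4L, endian = "little")
    body <- rbind(matrix(fl, nrow = 48L),
                  matrix(as.raw(0), nrow = 2L, ncol = ntri))
    writeBin(as.vector(body), con)
  } else {
    con <- file(file, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(ntri)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", tri[i, 1], tri[i, 2], tri[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", tri[i, 4:12][c(1, 4, 7)],
                tri[i, 4:12][c(2, 5, 8)], tri[i, 4:12][c(3, 6, 9)]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(file)
}

#' Read an STL file (binary or ASCII)
#'
#' Vertices equal within exact 32-bit float match are deduplicated; faces
#' are kept in file order.
#'
#' @param file path to an STL file.
#' @return a [TriangleMesh]
#' @export
readSTL <- function(file) {
  sz <- file.info(file)$size
  con <- file(file, "rb"); on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  isAscii <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (84 + 50 * ntri != sz) {
      if (grepl("^solid", rawToChar(header[1:5]))) isAscii <- TRUE
      else stop("truncated binary STL: expected ", 84 + 50 * ntri,
                " bytes for ", ntri, " triangles, file has ", sz)
    }
  } else if (grepl("^solid", rawToChar(header[seq_len(min(5, sz))]))) {
    isAscii <- TRUE
  } else stop("not an STL file (", sz, " bytes)")

  if (isAscii) {
    txt <- readLines(file, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(t) as.numeric(t[2:4]), numeric(3)))
    if (nrow(nums) %% 3 != 0) stop("malformed ASCII STL")
    verts <- nums
  } else {
    body <- readBin(con, "raw", 50L * ntri)
    if (length(body) < 50L * ntri)
      stop("truncated binary STL: expected ", 84 + 50 * ntri,
           " bytes, file has ", 84 + length(body))
    bm <- matrix(body, nrow = 50L)
    fl <- readBin(as.vector(bm[1:48, , drop = FALSE]), "numeric",
                  n = 12L * ntri, size = 4L, endian = "little")
    fm <- matrix(fl, nrow = 12L)                    # per-triangle columns
    verts <- matrix(as.vector(fm[4:12, , drop = FALSE]), ncol = 3L,
                    byrow = TRUE)
  }
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uniq <- !duplicated(key)
  vtab <- verts[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangleMesh(vtab, faces)
}

#' Write a mesh as VRML97 (WRL)
#'
#' Emits a single `IndexedFaceSet` whose `coordIndex` runs are terminated by
#' -1.  When per-face colors are present they are written with
#' `colorPerVertex FALSE` and one color per face (the natural encoding for
#' segment-mapped triangles); unlike STL, WRL preserves color.
#'
#' @param mesh a [TriangleMesh]
#' @param file output path.
#' @export
writeWRL <- function(mesh, file) {
  if (nrow(mesh@faces) == 0L) stop("mesh has no faces")
  v <- mesh@vertices; f <- mesh@faces - 1L
  con <- file(file, "w"); on.exit(close(con))
  writeLines("#VRML V2.0 utf8", con)
  writeLines(c("Shape {",
               "  appearance Appearance { material Material { } }",
               "  geometry IndexedFaceSet {",
               "    coord Coordinate {",
               "      point ["), con)
  writeLines(sprintf("        %.9g %.9g %.9g,", v[, 1], v[, 2], v[, 3]), con)
  writeLines(c("      ]", "    }", "    coordIndex ["), con)
  writeLines(sprintf("      %d, %d, %d, -1,", f[, 1], f[, 2], f[, 3]), con)
  writeLines("    ]", con)
  if (nrow(mesh@faceColor)) {
    fc <- mesh@faceColor
    writeLines(c("    colorPerVertex FALSE", "    color Color {",
                 "      color ["), con)
    writeLines(sprintf("        %.6g %.6g %.6g,", fc[, 1], fc[, 2], fc[, 3]),
               con)
    writeLines(c("      ]", "    }"), con)
  }
  writeLines(c("  }", "}"), con)
  invisible(file)
}

# ------------------------------------------------------------- mesh stats

meshEdges <- function(mesh) {
  f <- mesh@faces
  rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE],
        f[, c(3, 1), drop = FALSE])
}

# numeric edge keys (exact for meshes up to ~90M vertices)
edgeKeys <- function(mesh) {
  e <- meshEdges(mesh)
  base <- nrow(mesh@vertices) + 1
  list(directed = as.numeric(e[, 1]) * base + e[, 2],
       undirected = as.numeric(pmin(e[, 1], e[, 2])) * base +
         pmax(e[, 1], e[, 2]))
}

#' Is a mesh watertight and consistently oriented?
#'
#' TRUE iff every undirected edge is shared by exactly two faces and the two
#' incident faces traverse it in opposite directions (global outward
#' orientation), i.e. the surface is closed and orientable with no boundary
#' edges.
#'
#' @param mesh a [TriangleMesh]
#' @return logical
#' @export
isWatertight <- function(mesh) {
  if (!nrow(mesh@faces)) return(FALSE)
  k <- edgeKeys(mesh)
  if (anyDuplicated(k$directed) > 0) return(FALSE) # repeated directed edge
  s <- sort(k$undirected)
  n <- length(s)
  if (n %% 2L) return(FALSE)
  # sorted keys must come in exactly-two runs
  all(s[seq(1, n, 2)] == s[seq(2, n, 2)]) &&
    (n < 4 || !any(s[seq(2, n - 2, 2)] == s[seq(3, n - 1, 2)]))
}

#' Number of boundary edges (edges not shared by exactly two faces)
#' @param mesh a [TriangleMesh]
#' @return integer
#' @export
boundaryEdgeCount <- function(mesh) {
  k <- edgeKeys(mesh)
  tab <- tabulate(match(k$undirected, unique(k$undirected)))
  sum(tab != 2L)
}

#' Connected components of a mesh (by face adjacency across shared edges)
#' @param mesh a [TriangleMesh]
#' @return integer count
#' @export
meshComponents <- function(mesh) {
  f <- mesh@faces
  if (!nrow(f)) return(0L)
  k <- edgeKeys(mesh)
  faceOf <- rep(seq_len(nrow(f)), 3L)
  o <- order(k$undirected)
  ids <- k$undirected[o]; fo <- faceOf[o]
  first <- !duplicated(ids)
  # connect every face of an edge group to the group's first face
  anchor <- fo[first][cumsum(first)]
  keep <- !first
  g <- igraph::make_empty_graph(n = nrow(f), directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(anchor[keep], fo[keep]))
  as.integer(igraph::components(g)$no)
}

#' Mesh statistics: volume, surface area, bounding box, components
#'
#' Volume by the divergence theorem (sum of signed tetrahedra against the
#' origin), surface area as the triangle-area sum, axis-aligned bounding
#' box, and connected components by face-adjacency traversal.  Requesting
#' the volume of a non-watertight mesh is an error (area and bbox are still
#' available with `volume = FALSE`).
#'
#' @param mesh a [TriangleMesh]
#' @param volume compute the enclosed volume (requires watertightness).
#' @param unit linear unit label recorded in the result (defaults to the
#'   mesh metadata unit, or "unitless").
#' @return a [MeshStats]
#' @export
meshStats <- function(mesh, volume = TRUE, unit = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  if (!nrow(f)) stop("mesh has no faces")
  if (is.null(unit))
    unit <- if (!is.null(mesh@metadata$unit)) mesh@metadata$unit else "unitless"
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- NA_real_
  if (volume) {
    if (!isWatertight(mesh))
      stop("volume requested on a non-watertight mesh (",
           boundaryEdgeCount(mesh), " boundary/inconsistent edges); ",
           "use volume = FALSE for area and bbox")
    vol <- sum(rowSums(a * cr)) / 6
  }
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(n^2))) / 2
  used <- sort(unique(as.vector(f)))
  bbox <- rbind(min = apply(v[used, , drop = FALSE], 2, min),
                max = apply(v[used, , drop = FALSE], 2, max))
  colnames(bbox) <- c("x", "y", "z")
  new("MeshStats", volume = vol, surfaceArea = area, bbox = bbox,
      nComponents = as.integer(meshComponents(mesh)), unit = unit)
}

setMethod("show", "MeshStats", function(object) {
  cat(sprintf(paste0("MeshStats: volume %.4g %s^3, area %.4g %s^2, ",
                     "%d component(s)\n"),
              object@volume, object@unit, object@surfaceArea, object@unit,
              object@nComponents))
  cat(sprintf("  bbox: [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] %s\n",
              object@bbox[1, 1], object@bbox[2, 1], object@bbox[1, 2],
              object@bbox[2, 2], object@bbox[1, 3], object@bbox[2, 3],
              object@unit))
})
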