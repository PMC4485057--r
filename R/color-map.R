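# Mapping surface triangles back to the underlying neurite segments, and
# assigning per-face colors.
#
# The tessellation does not retain logical structure, so color by region or
# by a scalar property requires mapping each triangle back to a frustum:
# the face centroid is assigned to the frustum that contains it "by the
# least amount" (smallest distance from the centroid to that frustum's
# boundary, caps included); centroids contained by no frustum go to the
# frustum with the nearest surface.  Ties are broken by lowest section id,
# then lowest point index.

# vectorized exact signed distance from points to one capped cone
frustumSignedDistance <- function(pts, x0, y0, z0, x1, y1, z1, r0, r1,
                                  sphere = FALSE) {
  px <- pts[, 1]; py <- pts[, 2]; pz <- pts[, 3]
  if (sphere)
    return(sqrt((px - x0)^2 + (py - y0)^2 + (pz - z0)^2) - r0)
  bax <- x1 - x0; bay <- y1 - y0; baz <- z1 - z0
  pax <- px - x0; pay <- py - y0; paz <- pz - z0
  rba <- r1 - r0
  baba <- bax^2 + bay^2 + baz^2
  papa <- pax^2 + pay^2 + paz^2
  paba <- (pax * bax + pay * bay + paz * baz) / baba
  x <- sqrt(pmax(papa - paba^2 * baba, 0))
  cax <- pmax(0, x - ifelse(paba < 0.5, r0, r1))
  cay <- abs(paba - 0.5) - 0.5
  k <- rba^2 + baba
  f <- pmin(pmax((rba * (x - r0) + paba * baba) / k, 0), 1)
  cbx <- x - r0 - f * rba
  cby <- paba - f
  s <- ifelse(cbx < 0 & cay < 0, -1, 1)
  s * sqrt(pmin(cax^2 + cay^2 * baba, cbx^2 + cby^2 * baba))
}

#' Map surface triangles back to neurite segments
#'
#' For each face centroid, among the frusta that contain it, picks the one
#' with minimal interior depth (distance from the centroid to that
#' frustum's boundary surface, lateral or cap); if no frustum contains the
#' centroid, picks the frustum whose surface is closest.  Deterministic:
#' exact ties go to the lowest section id, then the lowest point index.
#'
#' @param mesh a [TriangleMesh]
#' @param frusta data.frame from [skeletonToFrusta] -- the primitives that
#'   generated the mesh.
#' @param tieTol numerical tie tolerance: distances equal within `tieTol`
#'   are treated as exact ties (default 1e-9 um).
#' @return data.frame with one row per face: `face`, `sectionId`,
#'   `pointIndex`, `method` (`"contained"` or `"nearest_surface"`).
#' @export
mapTrianglesToSegments <- function(mesh, frusta, tieTol = 1e-9) {
  if (is.null(frusta) || nrow(frusta) == 0L) stop("empty frusta list")
  cen <- faceCentroids(mesh)
  nf <- nrow(cen)
  ord <- order(frusta$sectionId, frusta$pointIndex)
  bestDepth <- rep(Inf, nf); containIdx <- rep(NA_integer_, nf)
  bestDist <- rep(Inf, nf); nearIdx <- rep(NA_integer_, nf)
  for (j in ord) {
    sd <- frustumSignedDistance(cen, frusta$x0[j], frusta$y0[j], frusta$z0[j],
                                frusta$x1[j], frusta$y1[j], frusta$z1[j],
                                frusta$r0[j], frusta$r1[j], frusta$sphere[j])
    inside <- sd < 0
    depth <- -sd
    upd <- inside & depth < bestDepth - tieTol
    bestDepth[upd] <- depth[upd]; containIdx[upd] <- j
    updN <- !inside & sd < bestDist - tieTol
    bestDist[updN] <- sd[updN]; nearIdx[updN] <- j
  }
  contained <- !is.na(containIdx)
  pick <- ifelse(contained, containIdx, nearIdx)
  data.frame(face = seq_len(nf),
             sectionId = frusta$sectionId[pick],
             pointIndex = frusta$pointIndex[pick],
             method = ifelse(contained, "contained", "nearest_surface"))
}

#' Construct a color scheme
#'
#' @param mode `"by_kind"`, `"by_section_name"` or `"by_scalar"`.
#' @param colors named list of RGB triples in \[0,1\]; keys are structural
#'   kinds (`soma`, `axon`, `dendrite`, `basal_dendrite`,
#'   `apical_dendrite`) or section names, depending on mode.
#' @param scalar named numeric vector keyed by section id (as character),
#'   e.g. a membrane potential or conductance per section.
#' @param stops RGB matrix of colormap stops; the scalar's observed range
#'   is mapped linearly across them (default white to red).
#' @return a [ColorScheme]
#' @export
colorScheme <- function(mode = "by_kind",
                        colors = list(soma = c(0.8, 0.8, 0.8),
                                      axon = c(1, 0, 0),
                                      dendrite = c(1, 1, 1)),
                        scalar = numeric(),
                        stops = rbind(c(1, 1, 1), c(1, 0, 0))) {
  new("ColorScheme", mode = mode, colors = colors,
      scalar = scalar, stops = as.matrix(stops))
}

#' Read a scalar field from a two-column text file
#'
#' Whitespace-delimited `section value` rows; returns a named numeric
#' vector suitable for [colorScheme]'s `scalar`.
#'
#' @param file path.
#' @export
readScalarField <- function(file) {
  tab <- utils::read.table(file, header = FALSE,
                           col.names = c("section", "value"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$value, tab$section)
}

interpStops <- function(t, stops) {
  k <- nrow(stops)
  if (k == 1L) return(matrix(stops[1, ], length(t), 3, byrow = TRUE))
  pos <- t * (k - 1)
  i0 <- pmin(floor(pos), k - 2) + 1
  frac <- pos - (i0 - 1)
  stops[i0, , drop = FALSE] * (1 - frac) +
    stops[i0 + 1, , drop = FALSE] * frac
}

kindColorFor <- function(kind, colors) {
  if (!is.null(colors[[kind]])) return(colors[[kind]])
  if (kind %in% c("basal_dendrite", "apical_dendrite") &&
      !is.null(colors[["dendrite"]])) return(colors[["dendrite"]])
  if (grepl("^custom_", kind) && !is.null(colors[["dendrite"]]))
    return(colors[["dendrite"]])
  c(0.7, 0.7, 0.7)
}

#' Color mesh faces from their segment assignment
#'
#' Every face receives a color: by structural kind, by section name, or by
#' linear interpolation of a per-section scalar over the colormap stops
#' (the scalar's observed range maps onto the full stop sequence).  A
#' scalar missing for a mapped section is an error naming the section.
#'
#' @param mesh a [TriangleMesh]
#' @param assignment data.frame from [mapTrianglesToSegments].
#' @param scheme a [ColorScheme].
#' @param morphology the source [Morphology] (needed to resolve kinds and
#'   names for `by_kind` / `by_section_name`).
#' @return the mesh with `faceColor` and `faceSegment` populated.
#' @export
assignColors <- function(mesh, assignment, scheme, morphology = NULL) {
  if (nrow(assignment) != nrow(mesh@faces))
    stop("assignment must cover every face")
  nf <- nrow(mesh@faces)
  fc <- matrix(0, nf, 3)
  if (scheme@mode %in% c("by_kind", "by_section_name")) {
    if (is.null(morphology))
      stop("morphology required for by_kind / by_section_name coloring")
    ids <- sectionIds(morphology)
    keyOf <- if (scheme@mode == "by_kind") sectionKinds(morphology)
             else vapply(morphology@sections, function(s) s@name, character(1))
    key <- keyOf[match(assignment$sectionId, ids)]
    for (u in unique(key)) {
      col <- if (scheme@mode == "by_kind") kindColorFor(u, scheme@colors)
             else if (!is.null(scheme@colors[[u]])) scheme@colors[[u]]
             else c(0.7, 0.7, 0.7)
      fc[key == u, ] <- matrix(col, sum(key == u), 3, byrow = TRUE)
    }
  } else {                                  # by_scalar
    sv <- scheme@scalar[as.character(assignment$sectionId)]
    if (any(is.na(sv)))
      stop("scalar value missing for section(s): ",
           paste(unique(assignment$sectionId[is.na(sv)]), collapse = ", "))
    rng <- range(sv)
    t <- if (diff(rng) > 0) (sv - rng[1]) / diff(rng) else rep(0, length(sv))
    fc <- interpStops(t, scheme@stops)
  }
  mesh@faceColor <- fc
  mesh@faceSegment <- as.integer(assignment$sectionId)
  validObject(mesh)
  mesh
}
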