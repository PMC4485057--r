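# Independent oracles and fixtures used across the suite.  These
# deliberately avoid the package's SDF/mesh code paths: containment is by
# axial projection, boundary distances by point-to-segment geometry in the
# meridian plane, volumes by analytic formulas or Monte-Carlo rejection
# sampling.

# --- unit cube mesh (12 triangles, CCW outward) ---------------------------
cubeMesh <- function(origin = c(0, 0, 0), size = 1) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * size
  v <- sweep(v, 2, origin, "+")
  colnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  triangleMesh(v, f)
}

# --- subdivided icosphere (vertices projected to radius r) ----------------
icosphereMesh <- function(r = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v); midcache <- new.env()
    newf <- matrix(0L, 0, 3)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      midcache[[key]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v * r / sqrt(rowSums(v^2))
  triangleMesh(v, f)
}

# --- independent point-in-frustum test (axial projection) -----------------
# pts: Nx3; frustum row with columns x0..z1, r0, r1, sphere
oracleInsideFrustum <- function(pts, fr) {
  p0 <- c(fr$x0, fr$y0, fr$z0); p1 <- c(fr$x1, fr$y1, fr$z1)
  if (isTRUE(fr$sphere))
    return(sqrt(colSums((t(pts) - p0)^2)) <= fr$r0)
  ax <- p1 - p0; L2 <- sum(ax^2)
  t <- as.vector((sweep(pts, 2, p0) %*% ax) / L2)
  rad2 <- rowSums((sweep(pts, 2, p0) - outer(t, ax))^2)
  rt <- fr$r0 + t * (fr$r1 - fr$r0)
  t >= 0 & t <= 1 & rad2 <= rt^2
}

oracleInsideUnion <- function(pts, frusta) {
  ins <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(frusta)))
    ins <- ins | oracleInsideFrustum(pts, frusta[j, ])
  ins
}

# Monte-Carlo volume of a union of frusta by rejection sampling in the
# joint bounding box
oracleUnionVolumeMC <- function(frusta, n = 1e6, seed = 42) {
  r <- pmax(frusta$r0, frusta$r1)
  lo <- c(min(pmin(frusta$x0, frusta$x1) - r),
          min(pmin(frusta$y0, frusta$y1) - r),
          min(pmin(frusta$z0, frusta$z1) - r))
  hi <- c(max(pmax(frusta$x0, frusta$x1) + r),
          max(pmax(frusta$y0, frusta$y1) + r),
          max(pmax(frusta$z0, frusta$z1) + r))
  set.seed(seed)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  mean(oracleInsideUnion(pts, frusta)) * prod(hi - lo)
}

# Monte-Carlo center of mass of a frustum chain (soma oracle)
oracleChainCentroidMC <- function(pts4, n = 1e6, seed = 42) {
  fr <- do.call(rbind, lapply(seq_len(nrow(pts4) - 1), function(i) {
    data.frame(x0 = pts4[i, 1], y0 = pts4[i, 2], z0 = pts4[i, 3],
               x1 = pts4[i + 1, 1], y1 = pts4[i + 1, 2], z1 = pts4[i + 1, 3],
               r0 = pts4[i, 4] / 2, r1 = pts4[i + 1, 4] / 2, sphere = FALSE)
  }))
  r <- pmax(fr$r0, fr$r1)
  lo <- c(min(pmin(fr$x0, fr$x1) - r), min(pmin(fr$y0, fr$y1) - r),
          min(pmin(fr$z0, fr$z1) - r))
  hi <- c(max(pmax(fr$x0, fr$x1) + r), max(pmax(fr$y0, fr$y1) + r),
          max(pmax(fr$z0, fr$z1) + r))
  set.seed(seed)
  p <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  ins <- oracleInsideUnion(p, fr)
  colMeans(p[ins, , drop = FALSE])
}

# exact distance from points to a frustum boundary, computed independently
# of the package's SDF formula: the surface of revolution reduces the
# problem to the meridian half-plane (axial coordinate t, radial coordinate
# rho >= 0), where the boundary is the polyline cap0 / lateral / cap1 and
# the distance is a plain min of point-to-segment distances.
oracleFrustumSurfaceDistance <- function(pts, fr) {
  p0 <- c(fr$x0, fr$y0, fr$z0); p1 <- c(fr$x1, fr$y1, fr$z1)
  if (isTRUE(fr$sphere)) {
    return(abs(sqrt(colSums((t(pts) - p0)^2)) - fr$r0))
  }
  ax <- p1 - p0; L <- sqrt(sum(ax^2)); axu <- ax / L
  rel <- sweep(pts, 2, p0)
  t <- as.vector(rel %*% axu)
  rho <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
  segDist <- function(px, py, ax_, ay_, bx_, by_) {
    vx <- bx_ - ax_; vy <- by_ - ay_
    u <- pmin(pmax(((px - ax_) * vx + (py - ay_) * vy) / (vx^2 + vy^2), 0), 1)
    sqrt((px - (ax_ + u * vx))^2 + (py - (ay_ + u * vy))^2)
  }
  pmin(segDist(t, rho, 0, 0, 0, fr$r0),          # cap disk at p0
       segDist(t, rho, L, 0, L, fr$r1),          # cap disk at p1
       segDist(t, rho, 0, fr$r0, L, fr$r1))      # lateral surface
}

# brute-force reimplementation of the assignment rule using the sampled
# surface distances
oracleAssign <- function(mesh, frusta) {
  v <- vertices(mesh); f <- faces(mesh)
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  n <- nrow(cen)
  ord <- order(frusta$sectionId, frusta$pointIndex)
  bestDepth <- rep(Inf, n); ci <- rep(NA_integer_, n)
  bestDist <- rep(Inf, n); ni <- rep(NA_integer_, n)
  for (j in ord) {
    fr <- frusta[j, ]
    dist <- oracleFrustumSurfaceDistance(cen, fr)
    ins <- oracleInsideFrustum(cen, fr)
    upd <- ins & dist < bestDepth - 1e-9
    bestDepth[upd] <- dist[upd]; ci[upd] <- j
    updN <- !ins & dist < bestDist - 1e-9
    bestDist[updN] <- dist[updN]; ni[updN] <- j
  }
  pick <- ifelse(is.na(ci), ni, ci)
  data.frame(sectionId = frusta$sectionId[pick],
             pointIndex = frusta$pointIndex[pick])
}

# minimal VRML97 IndexedFaceSet parser (reference decoder for writeWRL)
parseWRL <- function(file) {
  txt <- paste(readLines(file), collapse = "\n")
  grab <- function(after) {
    m <- regexpr(paste0(after, "\\s*\\["), txt)
    start <- m + attr(m, "match.length")
    rest <- substr(txt, start, nchar(txt))
    sub("\\].*$", "", rest)
  }
  pts <- as.numeric(strsplit(gsub(",", " ", grab("point")), "\\s+")[[1]])
  pts <- matrix(pts[!is.na(pts)], ncol = 3, byrow = TRUE)
  idx <- as.numeric(strsplit(gsub(",", " ", grab("coordIndex")), "\\s+")[[1]])
  idx <- idx[!is.na(idx)]
  fcs <- matrix(idx, ncol = 4, byrow = TRUE)
  stopifnot(all(fcs[, 4] == -1))
  cols <- NULL
  if (grepl("color Color", txt)) {
    cv <- as.numeric(strsplit(gsub(",", " ", grab("color Color \\{\\s*color")),
                              "\\s+")[[1]])
    cols <- matrix(cv[!is.na(cv)], ncol = 3, byrow = TRUE)
  }
  list(vertices = pts, faces = fcs[, 1:3] + 1, colors = cols)
}

# two-section straight cable along x: A on [0,xSplit], B on [xSplit,L]
twoSectionCable <- function(xSplit = 5, L = 10, d = 2) {
  a <- newSectionForTest(1L, "basal_dendrite",
                         rbind(c(0, 0, 0, d), c(xSplit, 0, 0, d)))
  b <- newSectionForTest(2L, "basal_dendrite",
                         rbind(c(xSplit, 0, 0, d), c(L, 0, 0, d)),
                         parentId = 1L, parentPoint = 2L)
  newMorphologyForTest(list(a, b))
}

newSectionForTest <- function(id, kind, points, parentId = NA_integer_,
                              parentPoint = NA_integer_) {
  colnames(points) <- c("x", "y", "z", "diam")
  methods::new("Section", id = as.integer(id), kind = kind, points = points,
               parentId = as.integer(parentId),
               parentPoint = as.integer(parentPoint), name = paste0("s", id))
}

newMorphologyForTest <- function(sections, somaOutline = NULL) {
  methods::new("Morphology", sections = sections, somaOutline = somaOutline,
               sourceFormat = "synthetic", detachedRoots = integer(),
               metadata = list())
}

rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle); C <- 1 - c0
  rbind(c(c0 + a[1]^2 * C, a[1] * a[2] * C - a[3] * s0,
          a[1] * a[3] * C + a[2] * s0),
        c(a[2] * a[1] * C + a[3] * s0, c0 + a[2]^2 * C,
          a[2] * a[3] * C - a[1] * s0),
        c(a[3] * a[1] * C - a[2] * s0, a[3] * a[2] * C + a[1] * s0,
          c0 + a[3]^2 * C))
}

rotateMorphology <- function(m, R, shift = c(0, 0, 0)) {
  for (i in seq_along(m@sections)) {
    p <- m@sections[[i]]@points
    p[, 1:3] <- t(R %*% t(p[, 1:3, drop = FALSE])) +
      rep(shift, each = nrow(p))
    m@sections[[i]]@points <- p
  }
  m
}
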