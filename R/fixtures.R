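# Synthetic morphology generator: trees with analytically known topology
# and geometry, defect injectors, and a converging multi-cell cluster.
# These stand in for repository tracings so every pipeline stage can be
# exercised with exact ground truth and no downloads.

#' Construct a tree specification
#'
#' @param seed integer; the generator is fully deterministic for a fixed
#'   seed (byte-identical SWC output across runs and platforms).
#' @param nBifurcations,nStems tree topology counts.
#' @param segmentLengthRange microns, uniform per segment.
#' @param taper per-branch-order diameter ratio in (0,1].
#' @param somaDiameter,stemDiameter microns.
#' @param planarity `"3d"` or `"planar"` (dendrites confined to z = 0).
#' @return a [TreeSpec]
#' @export
treeSpec <- function(seed = 1L, nBifurcations = 5L, nStems = 2L,
                     segmentLengthRange = c(8, 15), taper = 0.95,
                     somaDiameter = 15, stemDiameter = 2,
                     planarity = "3d") {
  new("TreeSpec", seed = as.integer(seed),
      nBifurcations = as.integer(nBifurcations), nStems = as.integer(nStems),
      segmentLengthRange = as.numeric(segmentLengthRange),
      taper = taper, somaDiameter = somaDiameter,
      stemDiameter = stemDiameter, planarity = planarity)
}

withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# unit vector at a random angle (< maxAngle) from dir
jitterDirection <- function(dir, maxAngle, planar = FALSE) {
  if (planar) {
    th <- atan2(dir[2], dir[1]) + stats::runif(1, -maxAngle, maxAngle)
    return(c(cos(th), sin(th), 0))
  }
  # orthonormal frame around dir
  up <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- up - sum(up * dir) * dir; u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  ang <- stats::runif(1, 0, maxAngle)
  az <- stats::runif(1, 0, 2 * pi)
  d <- cos(ang) * dir + sin(ang) * (cos(az) * u + sin(az) * v)
  d / sqrt(sum(d^2))
}

#' Generate a synthetic morphology with known ground truth
#'
#' Grows `nStems` neurite stems from a spherical soma and applies exactly
#' `nBifurcations` bifurcations at randomly chosen open tips, so the
#' generated tree has exactly `spec@nBifurcations` branch points,
#' `spec@nStems` stems, and `2 * nBifurcations + nStems` branches.  Branch
#' directions are drawn uniformly in a cone about the parent direction and
#' segment lengths uniformly in `segmentLengthRange`, all from one seeded
#' generator.  Analytic ground truth (total cable length, summed frustum
#' volume, soma volume) is recorded in `metadata`.
#'
#' @param spec a [TreeSpec]
#' @return a [Morphology] (`sourceFormat` `"synthetic"`)
#' @examples
#' m <- genTree(treeSpec(seed = 7, nBifurcations = 7, nStems = 2))
#' branchStats(m)   # 7 branch points, 16 branches, 2 stems
#' @export
genTree <- function(spec) {
  validObject(spec)
  withLocalSeed(spec@seed, {
    planar <- spec@planarity == "planar"
    rs <- spec@somaDiameter / 2
    secs <- list(newSection(1L, "soma",
                            matrix(c(0, 0, 0, spec@somaDiameter), 1),
                            name = "soma[0]"))
    nextId <- 1L
    tips <- list()   # each: list(sectionId, pos, dir, diam)
    addSection <- function(kind, firstPt, dir, diam, parentId, parentPoint) {
      nseg <- sample(1:3, 1)
      pts <- matrix(c(firstPt, diam), 1, 4)
      pos <- firstPt
      d <- dir
      for (k in seq_len(nseg)) {
        len <- stats::runif(1, spec@segmentLengthRange[1],
                            spec@segmentLengthRange[2])
        pos <- pos + len * d
        pts <- rbind(pts, c(pos, diam))
        d <- jitterDirection(d, pi / 12, planar)
      }
      nextId <<- nextId + 1L
      secs[[nextId]] <<- newSection(nextId, kind, pts, parentId, parentPoint,
                                    sprintf("dend[%d]", nextId - 2L))
      list(sectionId = nextId, pos = pos, dir = d, diam = diam,
           nPts = nrow(pts))
    }
    for (i in seq_len(spec@nStems)) {
      dir <- if (planar) {
        th <- 2 * pi * (i - 1) / spec@nStems + stats::runif(1, 0, 0.3)
        c(cos(th), sin(th), 0)
      } else {
        v <- stats::rnorm(3); v / sqrt(sum(v^2))
      }
      start <- 0.9 * rs * dir
      tip <- addSection("basal_dendrite", start, dir, spec@stemDiameter,
                        1L, 1L)
      tips[[length(tips) + 1L]] <- tip
    }
    for (b in seq_len(spec@nBifurcations)) {
      ti <- sample(length(tips), 1)
      tip <- tips[[ti]]
      tips[[ti]] <- NULL
      for (side in c(-1, 1)) {
        d <- jitterDirection(tip$dir, pi / 5, planar)
        child <- addSection("basal_dendrite", tip$pos, d,
                            tip$diam * spec@taper, tip$sectionId,
                            tip$nPts)
        tips[[length(tips) + 1L]] <- child
      }
    }
    m <- newMorphology(secs, sourceFormat = "synthetic")
    st <- branchStats(m)
    fr <- skeletonToFrusta(m)
    fvol <- frustumVolumes(fr)
    m@metadata <- list(
      totalLength = st@totalLength,
      frustumVolume = sum(fvol[!fr$sphere]),
      somaVolume = sum(fvol[fr$sphere]),
      nBifurcations = spec@nBifurcations,
      nStems = spec@nStems,
      spec = spec)
    m
  })
}

#' Analytic volume of each frustum / sphere primitive
#'
#' Frusta: \eqn{\pi h (r_0^2 + r_0 r_1 + r_1^2)/3}; spheres:
#' \eqn{4 \pi r^3 / 3}.
#'
#' @param frusta data.frame from [skeletonToFrusta].
#' @return numeric vector of volumes.
#' @export
frustumVolumes <- function(frusta) {
  h <- sqrt((frusta$x1 - frusta$x0)^2 + (frusta$y1 - frusta$y0)^2 +
            (frusta$z1 - frusta$z0)^2)
  ifelse(frusta$sphere, (4 / 3) * pi * frusta$r0^3,
         pi * h * (frusta$r0^2 + frusta$r0 * frusta$r1 + frusta$r1^2) / 3)
}

#' Inject a named defect into a generated tree
#'
#' Emulates the tracing defects encountered in repository reconstructions:
#' `detached_root` (a dendritic stem whose connection to the soma is
#' missing, as flagged by `detachedRoots`); `zero_diameter` (a point with
#' no measured thickness); `amputated_planar` (branches leaving a slab of
#' the given thickness are truncated, as when dendrites are amputated at
#' the faces of a slice preparation, leaving a near-planar tree).
#'
#' @param spec a [TreeSpec]
#' @param defect one of `"detached_root"`, `"zero_diameter"`,
#'   `"amputated_planar"`.
#' @param slab slab thickness in microns (for `amputated_planar`).
#' @return a [Morphology]
#' @export
genDefective <- function(spec, defect, slab = 20) {
  m <- genTree(spec)
  ids <- sectionIds(m)
  kinds <- sectionKinds(m)
  parents <- sectionParents(m)
  stems <- which(kinds != "soma" &
                 kinds[match(parents, ids)] == "soma" & !is.na(parents))
  if (defect == "detached_root") {
    i <- stems[1]
    s <- m@sections[[i]]
    s@parentId <- NA_integer_
    s@parentPoint <- NA_integer_
    m@sections[[i]] <- s
    m@detachedRoots <- s@id
  } else if (defect == "zero_diameter") {
    i <- stems[1]
    s <- m@sections[[i]]
    s@points[nrow(s@points), 4] <- 0
    m@sections[[i]] <- s
  } else if (defect == "amputated_planar") {
    half <- slab / 2
    drop <- rep(FALSE, length(ids))
    for (i in seq_along(ids)) {
      s <- m@sections[[i]]
      if (isSomaKind(s@kind)) next
      out <- abs(s@points[, 3]) > half
      if (out[1]) { drop[i] <- TRUE; next }
      if (any(out)) {
        cut <- which(out)[1] - 1L
        s@points <- s@points[seq_len(cut), , drop = FALSE]
        m@sections[[i]] <- s
        # descendants of a truncated section are amputated with it
        kill <- !is.na(parents) & parents == s@id
        drop <- drop | kill
      }
    }
    repeat {
      more <- !drop & !is.na(parents) & parents %in% ids[drop]
      if (!any(more)) break
      drop <- drop | more
    }
    m@sections <- m@sections[!drop]
  } else stop("unknown defect: ", defect)
  m@metadata$defect <- defect
  m
}

#' Generate a cluster of cells with converging apical dendrites
#'
#' Places `nCells` distinct synthetic cells (differing seeds) with somas on
#' a ring below `convergencePoint`; each cell's apical dendrite passes
#' through the convergence point and ends just beyond it, so after any
#' positive diameter policy the apical tufts overlap and [mergeCells]
#' produces a single connected component -- the printable analogue of
#' mitral cells converging on one glomerulus.  Lateral dendrites interleave
#' between neighbouring cells.
#'
#' @param nCells number of cells (>= 1).
#' @param convergencePoint xyz target of the apical tufts (microns).
#' @param seed base seed; cell i uses `seed + i`.
#' @param somaRingRadius radius of the ring of somas (microns).
#' @return list of [Morphology]
#' @export
genCluster <- function(nCells, convergencePoint = c(0, 0, 60), seed = 1L,
                       somaRingRadius = 25) {
  stopifnot(nCells >= 1)
  cp <- as.numeric(convergencePoint)
  base <- cp - c(0, 0, 60)
  lapply(seq_len(nCells), function(i) {
    withLocalSeed(seed + i, {
      th <- 2 * pi * (i - 1) / max(nCells, 2)
      ctr <- base + c(somaRingRadius * cos(th), somaRingRadius * sin(th), 0)
      secs <- list(newSection(1L, "soma", matrix(c(ctr, 12), 1),
                              name = "soma[0]"))
      nid <- 1L
      # apical: soma -> waypoint -> through the convergence point + 2 um
      dirCP <- cp - ctr; dirCP <- dirCP / sqrt(sum(dirCP^2))
      way <- ctr + 0.5 * (cp - ctr) +
        c(stats::runif(2, -4, 4), stats::runif(1, -2, 2))
      beyond <- cp + 2 * dirCP
      nid <- nid + 1L
      secs[[nid]] <- newSection(nid, "apical_dendrite",
                                rbind(c(ctr + 5 * dirCP, 2.5),
                                      c(way, 2.5), c(cp, 2.5),
                                      c(beyond, 2.5)),
                                1L, 1L, sprintf("apic[%d]", i))
      # two lateral dendrites in the soma plane
      for (k in 1:2) {
        ang <- th + pi / 2 + (k - 1.5) * stats::runif(1, 0.6, 1.2)
        d <- c(cos(ang), sin(ang), 0)
        p1 <- ctr + 6 * d
        p2 <- p1 + stats::runif(1, 25, 40) * jitterDirection(d, pi / 10)
        nid <- nid + 1L
        secs[[nid]] <- newSection(nid, "basal_dendrite",
                                  rbind(c(p1, 2), c(p2, 2)), 1L, 1L,
                                  sprintf("lat[%d]", k))
      }
      newMorphology(secs, sourceFormat = "synthetic",
                    metadata = list(cellIndex = i, seed = seed + i))
    })
  })
}
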