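# SWC / Neurolucida-ASC reading, writing, repair, and morphometrics.

SWC_CODES <- c(soma = 1L, axon = 2L, basal_dendrite = 3L, apical_dendrite = 4L)

kindFromCode <- function(code) {
  k <- names(SWC_CODES)[match(code, SWC_CODES)]
  ifelse(is.na(k), paste0("custom_", code), k)
}

codeFromKind <- function(kind) {
  code <- SWC_CODES[kind]
  custom <- grepl("^custom_", kind)
  code[custom] <- as.integer(sub("^custom_", "", kind[custom]))
  unname(code)
}

isSomaKind <- function(kind) kind == "soma"

newSection <- function(id, kind, points, parentId = NA_integer_,
                       parentPoint = NA_integer_, name = "") {
  colnames(points) <- c("x", "y", "z", "diam")
  new("Section", id = as.integer(id), kind = kind, points = points,
      parentId = as.integer(parentId), parentPoint = as.integer(parentPoint),
      name = name)
}

newMorphology <- function(sections, somaOutline = NULL, sourceFormat = "swc",
                          detachedRoots = integer(), metadata = list()) {
  new("Morphology", sections = sections, somaOutline = somaOutline,
      sourceFormat = sourceFormat, detachedRoots = as.integer(detachedRoots),
      metadata = metadata)
}

#' @rdname Morphology-class
#' @aliases sections,Morphology-method
#' @export
setMethod("sections", "Morphology", function(x) x@sections)

#' @rdname Morphology-class
#' @export
setMethod("detachedRoots", "Morphology", function(x) x@detachedRoots)

#' @rdname Morphology-class
#' @export
setMethod("somaOutline", "Morphology", function(x) x@somaOutline)

sectionIds <- function(m) vapply(m@sections, function(s) s@id, integer(1))
sectionKinds <- function(m) vapply(m@sections, function(s) s@kind, character(1))
sectionParents <- function(m) vapply(m@sections, function(s) s@parentId, integer(1))

getSection <- function(m, id) m@sections[[match(id, sectionIds(m))]]

somaSections <- function(m) m@sections[sectionKinds(m) == "soma"]

hasSoma <- function(m) any(sectionKinds(m) == "soma")

setMethod("show", "Morphology", function(object) {
  kinds <- sectionKinds(object)
  st <- branchStats(object)
  cat(sprintf("Morphology (%s): %d sections (%s), %d points, %.1f um cable\n",
              object@sourceFormat, length(object@sections),
              paste(sprintf("%d %s", as.vector(table(kinds)),
                            names(table(kinds))), collapse = ", "),
              st@nPoints, st@totalLength))
  if (length(object@detachedRoots))
    cat("  detached roots:", paste(object@detachedRoots, collapse = ", "), "\n")
})

setMethod("show", "MorphStats", function(object) {
  cat(sprintf(paste0("MorphStats: %d branch points, %d branches, %d stems, ",
                     "%d points, total length %.2f um\n"),
              object@nBranchPoints, object@nBranches, object@nStems,
              object@nPoints, object@totalLength))
})

# ---------------------------------------------------------------- read_swc

#' Read an SWC reconstruction
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments).  Radii are doubled to diameters.  Consecutive same-type
#' nodes become one [Section]; a single soma node with parent -1 becomes a
#' spherical soma; the NeuroMorpho-style 3-point soma (root plus two soma
#' children) is merged into one cylinder-chain soma section.  Non-soma nodes
#' with parent -1, and nodes whose parent id does not exist, start sections
#' flagged in `detachedRoots` (see [repairDetached]).
#'
#' @param file path to an SWC file, or a character vector of lines.
#' @return a [Morphology]
#' @examples
#' swc <- c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 1", "3 3 20 0 0 1 2")
#' m <- readSWC(swc)
#' branchStats(m)
#' @export
readSWC <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n"))
  raw <- sub("#.*$", "", lines)
  keep <- which(trimws(raw) != "")
  toks <- strsplit(trimws(raw[keep]), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != 7L))
    stop("SWC parse error at line ", keep[which(nf != 7L)[1]],
         ": expected 7 fields, got ", nf[nf != 7L][1])
  tab <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 7L, byrow = TRUE))
  bad <- which(apply(tab, 1L, function(r) any(is.na(r))))
  if (length(bad))
    stop("SWC parse error at line ", keep[bad[1]], ": non-numeric field")

  id <- as.integer(tab[, 1]); type <- as.integer(tab[, 2])
  xyz <- tab[, 3:5, drop = FALSE]
  diam <- 2 * tab[, 6]; parent <- as.integer(tab[, 7])
  if (anyDuplicated(id))
    stop("SWC parse error: duplicate node id ", id[duplicated(id)][1])

  n <- length(id)
  pidx <- match(parent, id)            # NA: root or missing parent
  missingParent <- parent != -1L & is.na(pidx)
  # cyclic parent chains
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- i; seen <- 0L
    while (!is.na(j)) {
      seen <- seen + 1L
      if (seen > n) stop("SWC parse error: cyclic parent chain at node ", id[i])
      j <- pidx[j]
    }
  }

  nchild <- tabulate(pidx[!is.na(pidx)], nbins = n)
  kind <- kindFromCode(type)

  # NeuroMorpho 3-point soma: soma root with two childless soma children
  merged3pt <- NULL
  somaRoots <- which(kind == "soma" & is.na(pidx))
  for (r in somaRoots) {
    ch <- which(!is.na(pidx) & pidx == r & kind == "soma")
    if (length(ch) == 2L && all(nchild[ch] == 0L) && nchild[r] >= 2L)
      merged3pt <- c(ch[1], r, ch[2])
  }

  children <- split(seq_len(n)[!is.na(pidx)], pidx[!is.na(pidx)])
  childrenOf <- function(i) children[[as.character(i)]]

  inMerged <- if (is.null(merged3pt)) rep(FALSE, n) else seq_len(n) %in% merged3pt
  isStart <- is.na(pidx) |
    (!is.na(pidx) & (kind[pidx] != kind | nchild[pidx] > 1L))
  # children of the merged-soma outer nodes re-attach to the merged section
  if (!is.null(merged3pt)) isStart[inMerged] <- FALSE

  secs <- list()
  nodeSection <- integer(n)     # section index per node
  nodePoint <- integer(n)       # row of the node within its section points
  secId <- 0L
  counters <- new.env(parent = emptyenv())

  mkName <- function(kind) {
    base <- switch(kind, soma = "soma", axon = "axon",
                   basal_dendrite = "dend", apical_dendrite = "apic", "custom")
    k <- if (is.null(counters[[base]])) 0L else counters[[base]]
    counters[[base]] <- k + 1L
    sprintf("%s[%d]", base, k)
  }

  if (!is.null(merged3pt)) {
    secId <- secId + 1L
    pts <- cbind(xyz[merged3pt, , drop = FALSE], diam[merged3pt])
    secs[[secId]] <- newSection(secId, "soma", pts, name = mkName("soma"))
    nodeSection[merged3pt] <- secId
    nodePoint[merged3pt] <- seq_along(merged3pt)
  }

  # pass 1: assign every node to a section (runs), in id order of starts
  starts <- order(id)
  starts <- starts[isStart[starts]]
  runs <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    s <- starts[si]
    run <- s; cur <- s
    repeat {
      ch <- childrenOf(cur)
      ch <- ch[!inMerged[ch]]
      if (length(ch) != 1L || isStart[ch]) break
      run <- c(run, ch); cur <- ch
    }
    runs[[si]] <- run
    secIdx <- secId + si
    nodeSection[run] <- secIdx
    prepend <- !is.na(pidx[s]) && !isSomaKind(kind[pidx[s]])
    nodePoint[run] <- seq_along(run) + if (prepend) 1L else 0L
  }

  # pass 2: build Section objects (parent section/point now known everywhere)
  detached <- integer()
  for (si in seq_along(starts)) {
    s <- starts[si]
    run <- runs[[si]]
    p <- pidx[s]
    prepend <- !is.na(p) && !isSomaKind(kind[p])
    rows <- if (prepend) c(p, run) else run
    pts <- cbind(xyz[rows, , drop = FALSE], diam[rows])
    parentSec <- NA_integer_; parentPt <- NA_integer_
    if (!is.na(p)) {
      parentSec <- nodeSection[p]
      parentPt <- nodePoint[p]
    }
    thisId <- secId + si
    secs[[thisId]] <- newSection(thisId, kind[s], pts, parentSec, parentPt,
                                 mkName(kind[s]))
    isDet <- missingParent[s] || (parent[s] == -1L && !isSomaKind(kind[s]))
    if (isDet) detached <- c(detached, thisId)
  }

  if (any(diam[!isSomaKind(kind)] <= 0))
    warning("non-positive diameters present; apply a floor diameter policy ",
            "before tessellation")
  newMorphology(secs, sourceFormat = "swc", detachedRoots = detached)
}

# --------------------------------------------------------------- write_swc

#' Write a morphology as SWC
#'
#' Emits standard 7-column SWC with contiguous node ids starting at 1;
#' diameters are halved to radii.  Shared attachment points (the copy of the
#' parent's point carried as a non-soma child's first point) are not
#' re-emitted, so a read/write round trip preserves topology, coordinates
#' and diameters exactly at the printed precision.  A soma outline that
#' cannot be represented in SWC is dropped with a warning in favour of the
#' soma sections themselves.
#'
#' @param m a [Morphology]
#' @param file output path, or `NULL` to return the lines invisibly.
#' @return (invisibly) the SWC lines.
#' @export
writeSWC <- function(m, file = NULL) {
  ids <- sectionIds(m)
  parents <- sectionParents(m)
  # parents before children
  ord <- integer(); done <- rep(FALSE, length(ids))
  while (any(!done)) {
    ready <- which(!done & (is.na(parents) | parents %in% ids[done]))
    if (!length(ready)) stop("cannot order sections (cycle?)")
    ord <- c(ord, ready); done[ready] <- TRUE
  }
  if (!is.null(m@somaOutline))
    warning("soma outline cannot be represented in SWC; writing soma ",
            "sections (centroid + equivalent radius) only")

  lines <- character(); nextId <- 1L
  nodeIds <- vector("list", length(ids))   # per-section node ids by point row
  fmt <- function(v) sprintf("%.6f", v)
  for (i in ord) {
    s <- m@sections[[i]]
    np <- nrow(s@points)
    pidx <- match(s@parentId, ids)
    prepended <- !is.na(pidx) && !isSomaKind(m@sections[[pidx]]@kind)
    rows <- if (prepended) 2:np else 1:np
    idsHere <- rep(NA_integer_, np)
    parentNode <- if (is.na(pidx)) -1L else nodeIds[[pidx]][s@parentPoint]
    if (prepended) idsHere[1] <- parentNode
    code <- codeFromKind(s@kind)
    for (r in rows) {
      idsHere[r] <- nextId
      par <- if (r == rows[1]) {
        if (is.na(pidx)) -1L else parentNode
      } else idsHere[r - 1L]
      lines <- c(lines, paste(nextId, code, fmt(s@points[r, 1]),
                              fmt(s@points[r, 2]), fmt(s@points[r, 3]),
                              fmt(s@points[r, 4] / 2), par))
      nextId <- nextId + 1L
    }
    nodeIds[[i]] <- idsHere
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# ---------------------------------------------------------------- read_asc

#' Read a restricted Neurolucida ASC reconstruction
#'
#' Supports the common core of the format: an optional `("CellBody" ...)`
#' contour block and parenthesized neurite trees of `(x y z d)` points with
#' `|` branch separators under `Axon` / `Dendrite` / `Apical` headers.
#' Semicolon comments are stripped.  Unknown top-level blocks are skipped
#' with a warning.  When a cell-body contour is present, `somaOutline` is
#' populated and a single-point soma section is placed at the contour
#' centroid with the equivalent (mean-radius) diameter.
#'
#' @param file path to an ASC file, or a character vector of lines.
#' @return a [Morphology]
#' @export
readASC <- function(file) {
  txt <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n"))
  txt <- sub(";.*$", "", txt)
  src <- paste(txt, collapse = "\n")
  # tokenize
  pat <- "\\(|\\)|\\||\"[^\"]*\"|[^()|\"[:space:]]+"
  toks <- regmatches(src, gregexpr(pat, src))[[1]]
  if (sum(toks == "(") != sum(toks == ")"))
    stop("ASC parse error: unbalanced parentheses (",
         sum(toks == "("), " open, ", sum(toks == ")"), " close)")

  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  isNum <- function(t) !is.na(suppressWarnings(as.numeric(t)))

  # parse "( x y z d )" starting just after the '('
  parsePoint <- function() {
    v <- numeric(0)
    while (!is.na(peek()) && peek() != ")") v <- c(v, as.numeric(advance()))
    advance()                                  # ')'
    if (length(v) < 4L) v <- c(v, 1)[1:4]      # tolerate (x y z)
    v
  }

  # parse the body of a branch: points, then optionally a split block
  parseBranch <- function() {
    pts <- NULL; children <- list()
    repeat {
      t <- peek()
      if (is.na(t) || t == ")" || t == "|") break
      if (t == "(") {
        advance()
        if (peek() == "(") {                   # split block
          repeat {
            children[[length(children) + 1L]] <- parseBranch()
            if (peek() == "|") { advance(); next }
            break
          }
          advance()                            # close split block
        } else if (isNum(peek())) {
          pts <- rbind(pts, parsePoint())
        } else {
          # markers like (Color Red) inside a branch: skip block
          depth <- 1L
          while (depth > 0L) {
            t2 <- advance()
            if (t2 == "(") depth <- depth + 1L
            if (t2 == ")") depth <- depth - 1L
          }
        }
      } else advance()                         # stray word, ignore
    }
    list(points = pts, children = children)
  }

  contour <- NULL
  trees <- list()
  while (!is.na(peek())) {
    if (peek() != "(") { advance(); next }
    advance()
    # classify block by first meaningful tokens
    save <- pos
    header <- NULL
    while (!is.na(peek()) && peek() %in% c("(", ")"))
      if (advance() == ")") break
    w <- peek()
    wclean <- gsub("\"", "", w)
    pos <- save
    if (!is.na(w) && wclean == "CellBody") {
      # consume until matching close, collecting points
      depth <- 1L; pts <- NULL
      while (depth > 0L) {
        t <- advance()
        if (t == "(") {
          if (isNum(peek())) { pts <- rbind(pts, parsePoint()) }
          else depth <- depth + 1L
        } else if (t == ")") depth <- depth - 1L
      }
      contour <- pts
    } else if (!is.na(w) && wclean %in% c("Axon", "Dendrite", "Apical")) {
      # skip the header (possibly parenthesized), then parse the branch
      if (peek() == "(") { advance(); advance(); advance() } # ( Word )
      else advance()
      kind <- switch(wclean, Axon = "axon", Dendrite = "basal_dendrite",
                     Apical = "apical_dendrite")
      br <- parseBranch()
      advance()                                # closing ')'
      trees[[length(trees) + 1L]] <- list(kind = kind, branch = br)
    } else {
      warning("skipping unknown ASC block starting with '", wclean, "'")
      depth <- 1L
      while (depth > 0L) {
        t <- advance()
        if (t == "(") depth <- depth + 1L
        if (t == ")") depth <- depth - 1L
      }
    }
  }

  secs <- list(); secId <- 0L
  somaId <- NA_integer_
  outline <- NULL
  if (!is.null(contour)) {
    outline <- contour[, 1:3, drop = FALSE]
    colnames(outline) <- c("x", "y", "z")
    ctr <- colMeans(outline)
    rad <- mean(sqrt(rowSums(sweep(outline, 2, ctr)^2)))
    secId <- secId + 1L; somaId <- secId
    secs[[secId]] <- newSection(secId, "soma",
                                matrix(c(ctr, 2 * rad), 1), name = "soma[0]")
  }

  addBranch <- function(br, kind, parentId, parentPoint, prependPt) {
    pts <- br$points
    if (!is.null(prependPt)) pts <- rbind(prependPt, pts)
    secId <<- secId + 1L
    myId <- secId
    secs[[myId]] <<- newSection(myId, kind, pts[, 1:4, drop = FALSE],
                                parentId, parentPoint,
                                sprintf("%s[%d]", kind, myId))
    lastPt <- pts[nrow(pts), , drop = TRUE]
    for (ch in br$children)
      addBranch(ch, kind, myId, nrow(pts), lastPt)
    myId
  }

  detached <- integer()
  for (tr in trees) {
    rootId <- addBranch(tr$branch, tr$kind,
                        if (is.na(somaId)) NA_integer_ else somaId,
                        if (is.na(somaId)) NA_integer_ else 1L, NULL)
    if (is.na(somaId)) detached <- c(detached, rootId)
  }
  newMorphology(secs, somaOutline = outline, sourceFormat = "asc",
                detachedRoots = detached)
}

# ------------------------------------------------------------------ repair

#' Soma centroid (volume-weighted)
#'
#' Center of mass of the soma solid: spheres for single-point soma sections,
#' frustum chains otherwise, combined by analytic per-primitive volumes and
#' centroids.
#'
#' @param m a [Morphology] with a soma
#' @return numeric xyz
#' @export
somaCentroid <- function(m) {
  ss <- somaSections(m)
  if (!length(ss)) stop("morphology has no soma")
  wsum <- c(0, 0, 0); vtot <- 0
  for (s in ss) {
    p <- s@points
    if (nrow(p) == 1L) {
      v <- (4 / 3) * pi * (p[1, 4] / 2)^3
      wsum <- wsum + v * p[1, 1:3]; vtot <- vtot + v
    } else {
      for (i in seq_len(nrow(p) - 1L)) {
        r0 <- p[i, 4] / 2; r1 <- p[i + 1, 4] / 2
        h <- sqrt(sum((p[i + 1, 1:3] - p[i, 1:3])^2))
        v <- pi * h * (r0^2 + r0 * r1 + r1^2) / 3
        # axial centroid offset from the r0 end
        tcen <- if (v > 0) h * (r0^2 + 2 * r0 * r1 + 3 * r1^2) /
          (4 * (r0^2 + r0 * r1 + r1^2)) else h / 2
        ctr <- p[i, 1:3] + if (h > 0) tcen * (p[i + 1, 1:3] - p[i, 1:3]) / h
               else c(0, 0, 0)
        wsum <- wsum + v * ctr; vtot <- vtot + v
      }
    }
  }
  if (vtot <= 0) stop("soma has zero volume")
  unname(wsum / vtot)
}

#' @describeIn repairDetached Reattach each detached root by prepending a
#'   straight run at constant diameter from the soma centroid to the root's
#'   first measured point; measured coordinates are never moved.
#' @export
setMethod("repairDetached", "Morphology", function(m, ...) {
  if (!length(m@detachedRoots)) return(m)
  if (!hasSoma(m)) stop("cannot repair detached roots: no soma present")
  ctr <- somaCentroid(m)
  ids <- sectionIds(m)
  soma <- somaSections(m)[[1]]
  sp <- soma@points[, 1:3, drop = FALSE]
  attachPt <- which.min(rowSums(sweep(sp, 2, ctr)^2))
  for (id in m@detachedRoots) {
    i <- match(id, ids)
    s <- m@sections[[i]]
    d <- s@points[1, 4]
    s@points <- rbind(c(ctr, d), s@points)
    colnames(s@points) <- c("x", "y", "z", "diam")
    s@parentId <- soma@id
    s@parentPoint <- as.integer(attachPt)
    m@sections[[i]] <- s
  }
  m@detachedRoots <- integer()
  validObject(m)
  m
})

#' @describeIn removeAxon Drop all axonal sections and their descendants.
#' @export
setMethod("removeAxon", "Morphology", function(m) {
  ids <- sectionIds(m)
  parents <- sectionParents(m)
  kinds <- sectionKinds(m)
  drop <- kinds == "axon"
  repeat {
    more <- !drop & !is.na(parents) & parents %in% ids[drop]
    if (!any(more)) break
    drop <- drop | more
  }
  if (!any(drop)) return(m)
  m@sections <- m@sections[!drop]
  m@detachedRoots <- setdiff(m@detachedRoots, ids[drop])
  m
})

# ------------------------------------------------------------ branch_stats

sectionLength <- function(s) {
  p <- s@points
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, 1:3, drop = FALSE] -
                    p[-nrow(p), 1:3, drop = FALSE])^2)))
}

#' @describeIn branchStats Branch points are non-soma sections with at least
#'   two children; stems are neurite sections attached to the soma (or
#'   unattached roots); branches are maximal unbranched neurite paths.
#'   `totalLength` sums 3D point-to-point distances over all sections;
#'   `nPoints` counts unique sample points (shared attachment copies are not
#'   double counted).
#' @export
setMethod("branchStats", "Morphology", function(m) {
  if (!length(m@sections)) stop("empty morphology")
  ids <- sectionIds(m)
  kinds <- sectionKinds(m)
  parents <- sectionParents(m)
  pidx <- match(parents, ids)
  neur <- kinds != "soma"
  nchild <- tabulate(pidx[!is.na(pidx) & neur], nbins = length(ids))
  branchPoints <- sum(neur & nchild >= 2L)
  stems <- sum(neur & (is.na(pidx) | kinds[pidx] == "soma"))
  # a branch starts at a stem or just after a branch point
  starts <- neur & ((is.na(pidx) | kinds[pidx] == "soma") |
                    (nchild[pidx] >= 2L))
  lens <- vapply(m@sections, sectionLength, numeric(1))
  shared <- vapply(seq_along(ids), function(i) {
    p <- pidx[i]
    !is.na(p) && !isSomaKind(kinds[p])
  }, logical(1))
  npts <- sum(vapply(m@sections, function(s) nrow(s@points), integer(1))) -
    sum(shared)
  new("MorphStats", nBranchPoints = as.integer(branchPoints),
      nBranches = as.integer(sum(starts)), nStems = as.integer(stems),
      totalLength = sum(lens), nPoints = as.integer(npts))
})
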