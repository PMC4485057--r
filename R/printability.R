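# Printability validation against printer wall-thickness rules, and the
# printable-version metadata record.
#
# Thickness is evaluated on the logical skeleton (point diameters), not on
# the tessellated mesh: the extracted surface may be slightly thinner than
# the logical structure describes, and skeleton checks are independent of
# the tessellation resolution.  The soma is exempt from the wirey-structure
# rules but its extent still contributes to the bounding box.

#' @describeIn checkThickness Printed diameter per non-soma point is the
#'   diameter times the coordinate scale (microns in, millimeters out).  A
#'   point below `minThickness` is a violation; a point meeting the minimum
#'   but below `recommendedThickness` is an advisory.  Structural-risk
#'   advisories (longest unbranched neurite path; soma volume) are reported
#'   in the metadata, with no pass/fail claim attached.
#' @export
setMethod("checkThickness", c("Morphology", "PrintSpec"), function(m, spec) {
  if (!length(m@sections)) stop("empty morphology")
  mag <- magnification(spec)
  toMM <- unitFactor(spec@inputUnit) / unitFactor("mm")   # input unit -> mm
  rows <- list()
  for (s in m@sections) {
    if (isSomaKind(s@kind)) next
    printed <- s@points[, 4] * toMM * mag
    rows[[length(rows) + 1L]] <- data.frame(
      sectionId = s@id, pointIndex = seq_len(nrow(s@points)),
      printedDiameter = printed)
  }
  pts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sectionId = integer(), pointIndex = integer(),
               printedDiameter = numeric())
  # sub-nanometer slack so exact-boundary diameters (e.g. the output of
  # suggestDiameter) are not flagged through floating-point rounding
  eps <- 1e-9
  viol <- pts[pts$printedDiameter < spec@minThickness - eps, , drop = FALSE]
  adv <- pts[pts$printedDiameter >= spec@minThickness - eps &
             pts$printedDiameter < spec@recommendedThickness - eps, ,
             drop = FALSE]
  per <- if (nrow(pts)) {
    agg <- stats::aggregate(printedDiameter ~ sectionId, pts, min)
    names(agg)[2] <- "minPrintedDiameter"
    agg
  } else data.frame(sectionId = integer(), minPrintedDiameter = numeric())
  notes <- character()
  lp <- longestUnbranchedPath(m)
  if (is.finite(lp) && lp > 0)
    notes <- c(notes, sprintf(
      "longest unbranched neurite path: %.1f um (%.1f mm printed); long unbranched neurites are the common feature of models with imperfect print records",
      lp, lp * toMM * mag))
  rownames(viol) <- rownames(adv) <- NULL
  rep <- new("ThicknessReport", violations = viol, advisories = adv,
             perSection = per, passFlag = nrow(viol) == 0L,
             minThickness = spec@minThickness,
             recommendedThickness = spec@recommendedThickness,
             metadata = list(notes = notes, magnification = mag))
  validObject(rep)
  rep
})

# longest unbranched neurite path (microns): branches are merged runs of
# sections between soma/branch point/termination
longestUnbranchedPath <- function(m) {
  ids <- sectionIds(m)
  kinds <- sectionKinds(m)
  parents <- sectionParents(m)
  pidx <- match(parents, ids)
  neur <- kinds != "soma"
  if (!any(neur)) return(0)
  nchild <- tabulate(pidx[!is.na(pidx) & neur], nbins = length(ids))
  starts <- which(neur & ((is.na(pidx) | kinds[pidx] == "soma") |
                          nchild[pidx] >= 2L))
  childIdx <- split(seq_along(ids)[!is.na(pidx)], pidx[!is.na(pidx)])
  best <- 0
  for (s in starts) {
    len <- sectionLength(m@sections[[s]])
    cur <- s
    repeat {
      ch <- childIdx[[as.character(cur)]]
      if (is.null(ch) || length(ch) != 1L) break
      cur <- ch
      len <- len + sectionLength(m@sections[[cur]])
    }
    if (len > best) best <- len
  }
  best
}

setMethod("show", "ThicknessReport", function(object) {
  cat(sprintf(paste0("ThicknessReport: %s (%d violation(s) < %g mm, ",
                     "%d advisory point(s) < %g mm)\n"),
              if (object@passFlag) "PASS" else "FAIL",
              nrow(object@violations), object@minThickness,
              nrow(object@advisories), object@recommendedThickness))
  if (nrow(object@violations)) {
    cat("  violating sections:",
        paste(unique(object@violations$sectionId), collapse = ", "), "\n")
  }
  for (n in object@metadata$notes) cat("  note:", n, "\n")
})

#' Fixed neurite diameter achieving the recommended printed thickness
#'
#' Inverts the thickness rule: returns `recommendedThickness` divided by
#' the effective scale, i.e. the diameter (microns) at which every neurite
#' prints exactly at the recommended thickness.  Feeding the result to a
#' `fixed` [DiameterPolicy] guarantees a passing [checkThickness].
#'
#' @param spec a [PrintSpec]
#' @return diameter in input units (microns)
#' @examples
#' suggestDiameter(printSpec(0.2))  # 6 um at 200x
#' suggestDiameter(printSpec(0.8))  # 1.5 um at 800x
#' @export
suggestDiameter <- function(spec) {
  toMM <- unitFactor(spec@inputUnit) / unitFactor("mm")
  spec@recommendedThickness / (toMM * magnification(spec))
}

#' Assemble the printable-version metadata record
#'
#' Combines the thickness report with the measured mesh statistics into the
#' catalogue record kept for each printable model: magnification, printed
#' volume, bounding box, generating algorithm, creator, date, unique id.
#'
#' @param m the (configured, pre-scaling) [Morphology]
#' @param spec the [PrintSpec] used
#' @param stats [MeshStats] of the scaled (printed-size) mesh
#' @param name,comment,creator free-text metadata.
#' @param algorithm name of the surface algorithm.
#' @return list with elements `version` ([PrintableVersion]) and `report`
#'   ([ThicknessReport]).
#' @export
printabilityReport <- function(m, spec, stats, name = "model",
                               comment = "", creator = "neuroprint",
                               algorithm = "sdf-marching-tetrahedra") {
  if (missing(stats) || is.null(stats)) stop("mesh stats missing")
  ver <- new("PrintableVersion", name = name, comment = comment,
             magnification = magnification(spec),
             printedVolume = stats@volume, bbox = stats@bbox,
             algorithm = algorithm, creator = creator,
             dateAdded = format(Sys.time(), "%Y-%m-%d"),
             uniqueId = makeUniqueId())
  list(version = ver, report = checkThickness(m, spec))
}

makeUniqueId <- function() {
  sprintf("%s-%06d-%04x",
          format(Sys.time(), "%Y%m%d%H%M%S"),
          as.integer(Sys.getpid()) %% 1000000L,
          sample.int(65535L, 1L))
}

#' Serialize / deserialize a PrintableVersion to JSON
#'
#' @param ver a [PrintableVersion]
#' @param file optional path; when given the JSON is written there.
#' @return JSON string (invisibly when written to a file).
#' @export
printableVersionToJSON <- function(ver, file = NULL) {
  x <- list(name = ver@name, comment = ver@comment,
            magnification = ver@magnification,
            printed_volume = ver@printedVolume,
            bbox = list(min = as.numeric(ver@bbox[1, ]),
                        max = as.numeric(ver@bbox[2, ])),
            algorithm = ver@algorithm, creator = ver@creator,
            date_added = ver@dateAdded, unique_id = ver@uniqueId)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}

#' @rdname printableVersionToJSON
#' @param json JSON string or path to a JSON file.
#' @export
printableVersionFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  bbox <- rbind(min = x$bbox$min, max = x$bbox$max)
  colnames(bbox) <- c("x", "y", "z")
  new("PrintableVersion", name = x$name, comment = x$comment,
      magnification = x$magnification, printedVolume = x$printed_volume,
      bbox = bbox, algorithm = x$algorithm, creator = x$creator,
      dateAdded = x$date_added, uniqueId = x$unique_id)
}

setMethod("show", "PrintableVersion", function(object) {
  cat(sprintf(paste0("PrintableVersion '%s' [%s]: %gx magnification, ",
                     "printed volume %.4g mm^3, algorithm %s\n"),
              object@name, object@uniqueId, object@magnification,
              object@printedVolume, object@algorithm))
})
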