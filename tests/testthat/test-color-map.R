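# Triangle-to-segment mapping and face coloring

test_that("all faces of a single-cylinder mesh map to its one section", {
  m <- newMorphologyForTest(list(newSectionForTest(
    1L, "basal_dendrite", rbind(c(0, 0, 0, 2), c(10, 0, 0, 2)))))
  mesh <- tessellate(m, meshResolution(0.25))
  fr <- skeletonToFrusta(m)
  asg <- mapTrianglesToSegments(mesh, fr)
  expect_identical(nrow(asg), nrow(faces(mesh)))          # total
  expect_true(all(asg$sectionId == 1L))
  expect_true(all(asg$method %in% c("contained", "nearest_surface")))
  expect_error(mapTrianglesToSegments(mesh, fr[0, ]), "empty")
})

test_that("two collinear sections split faces at the boundary plane", {
  m <- twoSectionCable(xSplit = 5, L = 10, d = 2)
  mesh <- tessellate(m, meshResolution(0.25))
  fr <- skeletonToFrusta(m)
  asg <- mapTrianglesToSegments(mesh, fr)
  v <- vertices(mesh); f <- faces(mesh)
  cx <- (v[f[, 1], 1] + v[f[, 2], 1] + v[f[, 3], 1]) / 3
  step <- mesh@metadata$spatialStep
  expect_true(all(asg$sectionId[cx < 5 - step] == 1L))
  expect_true(all(asg$sectionId[cx > 5 + step] == 2L))
})

test_that("faces on the soma far cap use the nearest-surface rule", {
  # soma sphere + one dendrite leaving it: faces on the cap opposite the
  # dendrite lie outside every frustum
  soma <- newSectionForTest(1L, "soma", matrix(c(0, 0, 0, 10), 1))
  dend <- newSectionForTest(2L, "basal_dendrite",
                            rbind(c(4, 0, 0, 2), c(15, 0, 0, 2)),
                            parentId = 1L, parentPoint = 1L)
  m <- newMorphologyForTest(list(soma, dend))
  mesh <- tessellate(m, meshResolution(0.4))
  fr <- skeletonToFrusta(m)
  asg <- mapTrianglesToSegments(mesh, fr)
  v <- vertices(mesh); f <- faces(mesh)
  cx <- (v[f[, 1], 1] + v[f[, 2], 1] + v[f[, 3], 1]) / 3
  farCap <- cx < -4.5
  expect_true(any(farCap))
  expect_true(all(asg$sectionId[farCap] == 1L))
  # exhaustive distance check: those centroids really are nearer the
  # sphere surface than the dendrite frustum surface
  cen <- cbind(cx, (v[f[, 1], 2] + v[f[, 2], 2] + v[f[, 3], 2]) / 3,
               (v[f[, 1], 3] + v[f[, 2], 3] + v[f[, 3], 3]) / 3)
  idx <- which(farCap)[1:10]
  dS <- oracleFrustumSurfaceDistance(cen[idx, , drop = FALSE], fr[1, ])
  dD <- oracleFrustumSurfaceDistance(cen[idx, , drop = FALSE], fr[2, ])
  expect_true(all(dS < dD))
})

test_that("assignment agrees with the brute-force depth oracle on every face", {
  # two-section cable
  m1 <- twoSectionCable(xSplit = 5, L = 10, d = 2)
  mesh1 <- tessellate(m1, meshResolution(0.4))
  fr1 <- skeletonToFrusta(m1)
  asg1 <- mapTrianglesToSegments(mesh1, fr1)
  ora1 <- oracleAssign(mesh1, fr1)
  expect_identical(asg1$sectionId, ora1$sectionId)
  expect_identical(asg1$pointIndex, ora1$pointIndex)

  # nested frusta: thin long cable through a fat short sleeve; composite
  # faces near the thin cable's ends must map to the thin cable
  thin <- newSectionForTest(1L, "basal_dendrite",
                            rbind(c(0, 0, 0, 1), c(10, 0, 0, 1)))
  fat <- newSectionForTest(2L, "basal_dendrite",
                           rbind(c(4, 0, 0, 4), c(6, 0, 0, 4)))
  m2 <- newMorphologyForTest(list(thin, fat))
  mesh2 <- tessellate(m2, meshResolution(0.25))
  fr2 <- skeletonToFrusta(m2)
  asg2 <- mapTrianglesToSegments(mesh2, fr2)
  ora2 <- oracleAssign(mesh2, fr2)
  expect_identical(asg2$sectionId, ora2$sectionId)
  v <- vertices(mesh2); f <- faces(mesh2)
  cx <- (v[f[, 1], 1] + v[f[, 2], 1] + v[f[, 3], 1]) / 3
  expect_true(all(asg2$sectionId[cx < 3.5] == 1L))
  expect_true(all(asg2$sectionId[cx > 6.5] == 1L))
  expect_true(any(asg2$sectionId == 2L))
})

test_that("assignment is deterministic and stable under face reordering", {
  m <- twoSectionCable()
  mesh <- tessellate(m, meshResolution(0.4))
  fr <- skeletonToFrusta(m)
  a1 <- mapTrianglesToSegments(mesh, fr)
  # reorder frusta rows; tie rule is by section/point id, not row order
  a2 <- mapTrianglesToSegments(mesh, fr[rev(seq_len(nrow(fr))), ])
  expect_identical(a1$sectionId, a2$sectionId)
})

test_that("by_kind coloring partitions faces exactly per assignment", {
  soma <- newSectionForTest(1L, "soma", matrix(c(0, 0, 0, 10), 1))
  axon <- newSectionForTest(2L, "axon",
                            rbind(c(4, 0, 0, 2), c(15, 0, 0, 2)),
                            parentId = 1L, parentPoint = 1L)
  dend <- newSectionForTest(3L, "basal_dendrite",
                            rbind(c(-4, 0, 0, 2), c(-15, 0, 0, 2)),
                            parentId = 1L, parentPoint = 1L)
  m <- newMorphologyForTest(list(soma, axon, dend))
  mesh <- tessellate(m, meshResolution(0.4))
  fr <- skeletonToFrusta(m)
  asg <- mapTrianglesToSegments(mesh, fr)
  scheme <- colorScheme("by_kind", colors = list(
    soma = c(0.5, 0.5, 0.5), axon = c(1, 0, 0), dendrite = c(1, 1, 1)))
  colored <- assignColors(mesh, asg, scheme, m)
  fc <- faceColor(colored)
  expect_identical(nrow(fc), nrow(faces(mesh)))
  expect_true(all(fc[asg$sectionId == 2L, 1] == 1 &
                  fc[asg$sectionId == 2L, 2] == 0))
  expect_true(all(fc[asg$sectionId == 3L, 2] == 1))
  expect_identical(faceSegment(colored), asg$sectionId)
})

test_that("constant scalar gives one color; missing scalar errors by name", {
  m <- twoSectionCable()
  mesh <- tessellate(m, meshResolution(0.4))
  asg <- mapTrianglesToSegments(mesh, skeletonToFrusta(m))
  sch <- colorScheme("by_scalar", scalar = c("1" = 5, "2" = 5))
  colored <- assignColors(mesh, asg, sch)
  expect_identical(nrow(unique(faceColor(colored))), 1L)
  schBad <- colorScheme("by_scalar", scalar = c("1" = 5))
  expect_error(assignColors(mesh, asg, schBad), "section")
})

test_that("a scalar linear in distance colors an unbranched cable monotonically", {
  # 5 collinear sections with scalar = distance from origin
  pts <- lapply(0:4, function(i)
    rbind(c(2 * i, 0, 0, 2), c(2 * (i + 1), 0, 0, 2)))
  secs <- lapply(seq_along(pts), function(i)
    newSectionForTest(i, "basal_dendrite", pts[[i]],
                      parentId = if (i > 1) i - 1L else NA_integer_,
                      parentPoint = if (i > 1) 2L else NA_integer_))
  m <- newMorphologyForTest(secs)
  mesh <- tessellate(m, meshResolution(0.25))
  asg <- mapTrianglesToSegments(mesh, skeletonToFrusta(m))
  sch <- colorScheme("by_scalar",
                     scalar = stats::setNames(seq(0, 1, length.out = 5),
                                              as.character(1:5)),
                     stops = rbind(c(1, 1, 1), c(1, 0, 0)))
  colored <- assignColors(mesh, asg, sch)
  v <- vertices(mesh); f <- faces(mesh)
  cx <- (v[f[, 1], 1] + v[f[, 2], 1] + v[f[, 3], 1]) / 3
  o <- order(cx)
  g <- faceColor(colored)[o, 2]              # green falls white -> red
  # monotone per section: green channel non-increasing along x up to
  # boundary jitter of one section
  secOfFace <- asg$sectionId[o]
  expect_true(all(tapply(g, secOfFace, function(x) diff(range(x))) == 0))
  means <- tapply(g, secOfFace, mean)
  expect_true(all(diff(means[order(as.integer(names(means)))]) <= 0))
})

test_that("scalar fields load from two-column text files", {
  f <- tempfile()
  writeLines(c("1 0.25", "2 0.75"), f)
  sv <- readScalarField(f)
  expect_identical(sv, c("1" = 0.25, "2" = 0.75))
  m <- twoSectionCable()
  mesh <- tessellate(m, meshResolution(0.5))
  asg <- mapTrianglesToSegments(mesh, skeletonToFrusta(m))
  colored <- assignColors(mesh, asg, colorScheme("by_scalar", scalar = sv))
  expect_identical(nrow(unique(faceColor(colored))), 2L)
})
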