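# Diameter policies, soma rescaling, scaling to print units

somaChainMorph <- function() {
  # two-frustum soma chain along x plus one dendrite
  soma <- newSectionForTest(1L, "soma",
                            rbind(c(0, 0, 0, 8), c(6, 0, 0, 12),
                                  c(12, 0, 0, 6)))
  dend <- newSectionForTest(2L, "basal_dendrite",
                            rbind(c(14, 0, 0, 2), c(30, 0, 0, 2)),
                            parentId = 1L, parentPoint = 3L)
  newMorphologyForTest(list(soma, dend))
}

test_that("diameter policies transform diameters and nothing else", {
  m <- genTree(treeSpec(seed = 2, nBifurcations = 3, nStems = 2,
                        stemDiameter = 1.5))
  len0 <- branchStats(m)@totalLength
  somaD0 <- sections(m)[[1]]@points[1, 4]

  fx <- applyDiameterPolicy(m, diameterPolicy("fixed", 9))
  d <- unlist(lapply(sections(fx), function(s)
    if (s@kind == "soma") NULL else s@points[, 4]))
  expect_true(all(d == 9))
  expect_identical(branchStats(fx)@totalLength, len0)     # coords untouched
  expect_identical(unname(sections(fx)[[1]]@points[1, 4]), unname(somaD0))

  fl <- applyDiameterPolicy(m, diameterPolicy("floor", 2))
  d <- unlist(lapply(sections(fl), function(s)
    if (s@kind == "soma") NULL else s@points[, 4]))
  expect_true(all(d >= 2))

  sc <- applyDiameterPolicy(m, diameterPolicy("scale", 2))
  d0 <- unlist(lapply(sections(m), function(s)
    if (s@kind == "soma") NULL else s@points[, 4]))
  d2 <- unlist(lapply(sections(sc), function(s)
    if (s@kind == "soma") NULL else s@points[, 4]))
  expect_equal(d2, 2 * d0, tolerance = 1e-12)
  expect_equal(branchStats(sc)@totalLength, len0, tolerance = 1e-12)
})

test_that("per-kind policy hits axon and dendrites separately", {
  # dentate-granule-style print configuration: 6 um axon, 9 um dendrites
  swc <- c("1 1 0 0 0 5 -1",
           "2 2 10 0 0 0.3 1",
           "3 2 20 0 0 0.3 2",
           "4 3 -10 0 0 1 1",
           "5 4 0 10 0 1.2 1")
  m <- readSWC(swc)
  p <- diameterPolicy("per_kind", perKind = list(
    axon = list(mode = "fixed", value = 6),
    dendrite = list(mode = "fixed", value = 9)))
  m2 <- applyDiameterPolicy(m, p)
  for (s in sections(m2)) {
    if (s@kind == "axon") expect_true(all(s@points[, 4] == 6))
    if (grepl("dendrite", s@kind)) expect_true(all(s@points[, 4] == 9))
    if (s@kind == "soma") expect_equal(unname(s@points[1, 4]), 10)
  }
})

test_that("invalid policies error", {
  m <- genTree(treeSpec(seed = 1))
  expect_error(diameterPolicy("fixed", -1), "positive")
  expect_error(diameterPolicy("nope", 1), "mode")
  expect_error(diameterPolicy("per_kind",
                              perKind = list(soma = list(mode = "fixed",
                                                         value = 2))),
               "soma")
  z <- genDefective(treeSpec(seed = 1), "zero_diameter")
  expect_error(applyDiameterPolicy(z, diameterPolicy("scale", 2)),
               "non-positive")
})

test_that("policies compose: floor(v) after fixed(v) equals fixed(v)", {
  m <- genTree(treeSpec(seed = 9, nBifurcations = 4))
  for (v in c(0.5, 3, 9)) {
    a <- applyDiameterPolicy(applyDiameterPolicy(m, diameterPolicy("fixed", v)),
                             diameterPolicy("floor", v))
    b <- applyDiameterPolicy(m, diameterPolicy("fixed", v))
    expect_equal(a, b)
  }
})

test_that("scaleSoma on a sphere keeps its center and scales its diameter", {
  swc <- c("1 1 3 4 5 5 -1", "2 3 13 4 5 1 1", "3 3 23 4 5 1 2")
  m <- scaleSoma(readSWC(swc), 2)
  soma <- sections(m)[[which(vapply(sections(m), function(s) s@kind,
                                    character(1)) == "soma")]]
  expect_equal(unname(soma@points[1, 1:3]), c(3, 4, 5))
  expect_equal(unname(soma@points[1, 4]), 20)
  # dendrite untouched
  dend <- sections(m)[[which(vapply(sections(m), function(s) s@kind,
                                    character(1)) != "soma")]]
  expect_equal(unname(dend@points[1, 1:3]), c(13, 4, 5))
  expect_equal(unname(dend@points[, 4]), c(2, 2))
  # identity at factor 1
  m0 <- readSWC(swc)
  expect_equal(scaleSoma(m0, 1), m0)
  expect_error(scaleSoma(m0, -1), "positive")
  expect_error(scaleSoma(readSWC("1 3 0 0 0 1 -1"), 2), "soma")
})

test_that("scaleSoma preserves the center of mass of a frustum chain", {
  m <- somaChainMorph()
  com0 <- somaCentroid(m)
  # Monte-Carlo oracle for the original chain centroid
  somaPts <- sections(m)[[1]]@points
  mc <- oracleChainCentroidMC(somaPts, n = 1e6)
  expect_lt(max(abs(mc - com0)), 0.05)   # MC sanity on the analytic centroid

  m2 <- scaleSoma(m, 2)
  com2 <- somaCentroid(m2)
  expect_lt(max(abs(com2 - com0)), 1e-6)
  mc2 <- oracleChainCentroidMC(sections(m2)[[1]]@points, n = 1e6)
  expect_lt(max(abs(mc2 - com0)), 0.1)

  # volume multiplies by factor^3 (analytic frustum volumes)
  v0 <- sum(frustumVolumes(skeletonToFrusta(
    newMorphologyForTest(list(sections(m)[[1]])))))
  v2 <- sum(frustumVolumes(skeletonToFrusta(
    newMorphologyForTest(list(sections(m2)[[1]])))))
  expect_equal(v2 / v0, 8, tolerance = 1e-9)
})

test_that("scaleModel reports the standard magnification arithmetic", {
  m <- genTree(treeSpec(seed = 1))
  r1 <- scaleModel(m, printSpec(coordinateScale = 0.2))
  expect_equal(r1$magnification, 200)
  r2 <- scaleModel(m, printSpec(coordinateScale = 1, inputUnit = "um",
                                outputUnit = "um"))
  expect_equal(r2$magnification, 1)
  r3 <- scaleModel(m, printSpec(coordinateScale = 0.8))
  expect_equal(r3$magnification, 800)
  # total length scales linearly, frustum volume cubically
  st0 <- branchStats(m); st1 <- branchStats(r1$model)
  expect_equal(st1@totalLength, 0.2 * st0@totalLength, tolerance = 1e-9)
  v0 <- sum(frustumVolumes(skeletonToFrusta(m)))
  v1 <- sum(frustumVolumes(skeletonToFrusta(r1$model)))
  expect_equal(v1, 0.2^3 * v0, tolerance = 1e-9)
})

test_that("scaleModel on a mesh scales vertices and mesh volume cubically", {
  cube <- cubeMesh()
  r <- scaleModel(cube, printSpec(coordinateScale = 0.5))
  expect_equal(meshStats(r$model)@volume, 0.125)
  expect_equal(r$magnification, 500)
})

test_that("print spec validity is enforced", {
  expect_error(printSpec(coordinateScale = -1), "positive")
  expect_error(printSpec(minThickness = 2, recommendedThickness = 1),
               "exceed")
})
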