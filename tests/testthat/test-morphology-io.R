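# SWC / ASC parsing, repair, and morphometrics

test_that("minimal SWC parses into soma + dendrite sections", {
  swc <- c("# a comment",
           "1 1 0 0 0 5 -1",
           "2 3 10 0 0 1 1",
           "3 3 20 0 0 1 2")
  m <- readSWC(swc)
  expect_s4_class(m, "Morphology")
  expect_length(sections(m), 2L)
  expect_identical(detachedRoots(m), integer())
  st <- branchStats(m)
  expect_identical(st@nPoints, 3L)
  expect_identical(st@nStems, 1L)
  expect_identical(st@nBranches, 1L)
  # radius doubled to diameter
  kinds <- vapply(sections(m), function(s) s@kind, character(1))
  soma <- sections(m)[[which(kinds == "soma")]]
  expect_equal(unname(soma@points[1, "diam"]), 10)
})

test_that("dendrite with parent -1 is flagged as a detached root", {
  swc <- c("1 1 0 0 0 5 -1",
           "2 3 10 0 0 1 -1",
           "3 3 20 0 0 1 2")
  m <- readSWC(swc)
  expect_length(detachedRoots(m), 1L)
  det <- sections(m)[[match(detachedRoots(m), vapply(sections(m),
                            function(s) s@id, integer(1)))]]
  expect_identical(det@kind, "basal_dendrite")
  # a node referencing a nonexistent parent is detached too
  m2 <- readSWC(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 99"))
  expect_length(detachedRoots(m2), 1L)
})

test_that("SWC parse errors name the offending line / node", {
  expect_error(readSWC(c("1 1 0 0 0 5 -1", "2 3 x 0 0 1 1")), "line 2")
  expect_error(readSWC(c("1 1 0 0 0 5 -1", "1 3 1 0 0 1 1")), "duplicate")
  expect_error(readSWC(c("1 3 0 0 0 5 2", "2 3 1 0 0 1 1")), "cycl")
  expect_error(readSWC(c("1 1 0 0 0 5")), "7 fields")
})

test_that("SWC write/read round trip is exact (topology, coords, diameters)", {
  m <- genTree(treeSpec(seed = 11, nBifurcations = 4, nStems = 3))
  f1 <- tempfile(fileext = ".swc")
  writeSWC(m, f1)
  m2 <- readSWC(f1)
  f2 <- tempfile(fileext = ".swc")
  writeSWC(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s1 <- branchStats(m); s2 <- branchStats(m2)
  expect_identical(s1@nBranchPoints, s2@nBranchPoints)
  expect_identical(s1@nBranches, s2@nBranches)
  expect_identical(s1@nStems, s2@nStems)
  expect_identical(s1@nPoints, s2@nPoints)
  expect_equal(s1@totalLength, s2@totalLength, tolerance = 1e-6)
  expect_length(detachedRoots(m2), 0L)
})

test_that("NeuroMorpho-style 3-point soma becomes one cylinder-chain section", {
  swc <- c("1 1 0 0 0 5 -1",
           "2 1 0 -5 0 5 1",
           "3 1 0 5 0 5 1",
           "4 3 10 0 0 1 1")
  m <- readSWC(swc)
  kinds <- vapply(sections(m), function(s) s@kind, character(1))
  expect_identical(sum(kinds == "soma"), 1L)
  soma <- sections(m)[[which(kinds == "soma")]]
  expect_identical(nrow(soma@points), 3L)
})

test_that("restricted ASC dialect parses contour, trees and branch splits", {
  asc <- c(
    '("CellBody"',
    ' (CellBody)',
    ' (-5 0 0 1)',
    ' (0 5 0 1)',
    ' (5 0 0 1)',
    ' (0 -5 0 1)',
    ')',
    '((Dendrite)',
    ' (10 0 0 2)',
    ' (20 0 0 2)',
    ' (',
    '  (30 5 0 1.5)',
    '  |',
    '  (30 -5 0 1.5)',
    ' )',
    ')')
  m <- readASC(asc)
  expect_false(is.null(somaOutline(m)))
  expect_identical(nrow(somaOutline(m)), 4L)
  kinds <- vapply(sections(m), function(s) s@kind, character(1))
  expect_identical(sum(kinds == "soma"), 1L)
  dend <- which(kinds == "basal_dendrite")
  expect_length(dend, 3L)           # root + 2 children after the split
  parents <- vapply(sections(m), function(s) s@parentId, integer(1))
  expect_identical(sum(!is.na(parents) & parents == sections(m)[[dend[1]]]@id),
                   2L)
  st <- branchStats(m)
  expect_identical(st@nBranchPoints, 1L)
  expect_identical(st@nBranches, 3L)
})

test_that("ASC and SWC encodings of the same toy cell give equal stats", {
  # soma sphere d=10 at origin; one dendrite 10->20 um with a bifurcation
  swc <- c("1 1 0 0 0 5 -1",
           "2 3 10 0 0 1 1",
           "3 3 20 0 0 1 2",
           "4 3 30 5 0 1 3",
           "5 3 30 -5 0 1 3")
  asc <- c('("CellBody"',
           ' (0 0 5 1) (0 0 -5 1) (5 0 0 1) (-5 0 0 1)',   # mean radius 5
           ')',
           '((Dendrite)',
           ' (10 0 0 2)',
           ' (20 0 0 2)',
           ' ( (30 5 0 2) | (30 -5 0 2) )',
           ')')
  sa <- branchStats(readSWC(swc))
  sb <- branchStats(readASC(asc))
  expect_identical(sa@nBranchPoints, sb@nBranchPoints)
  expect_identical(sa@nBranches, sb@nBranches)
  expect_identical(sa@nStems, sb@nStems)
  expect_equal(sa@totalLength, sb@totalLength, tolerance = 1e-9)
})

test_that("unbalanced ASC parentheses are an error; unknown blocks warn", {
  expect_error(readASC('((Dendrite) (1 2 3 1)'), "unbalanced")
  expect_warning(readASC(c('(Weirdness 1 2 3)',
                           '((Dendrite) (1 0 0 1) (2 0 0 1))')), "unknown")
})

test_that("repairDetached extends to the soma centroid at constant diameter", {
  swc <- c("1 1 0 0 0 5 -1",
           "2 3 10 0 0 1 -1",
           "3 3 20 0 0 1 2")
  m <- readSWC(swc)
  r <- repairDetached(m)
  expect_length(detachedRoots(r), 0L)
  ids <- vapply(sections(r), function(s) s@id, integer(1))
  det <- sections(r)[[match(detachedRoots(m), ids)]]
  expect_equal(unname(det@points[1, 1:3]), c(0, 0, 0))    # soma centroid
  expect_equal(unname(det@points[1, 4]), 2)               # first point's diam
  expect_equal(unname(det@points[2, 1:3]), c(10, 0, 0))   # measured pts kept
  expect_false(is.na(det@parentId))
  # no-op on a clean morphology
  clean <- readSWC(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 1"))
  expect_identical(repairDetached(clean), clean)
  # no soma -> error
  expect_error(repairDetached(readSWC("1 3 0 0 0 1 -1")), "soma")
})

test_that("repairing two detached roots yields one connected component", {
  swc <- c("1 1 0 0 0 5 -1",
           "2 3 10 0 0 1 -1",
           "3 3 -10 0 0 1 -1",
           "4 3 -20 0 0 1 3")
  m <- repairDetached(readSWC(swc))
  expect_length(detachedRoots(m), 0L)
  # independent connectivity check by graph traversal over parent links
  ids <- vapply(sections(m), function(s) s@id, integer(1))
  parents <- vapply(sections(m), function(s) s@parentId, integer(1))
  g <- igraph::graph_from_edgelist(
    cbind(match(parents[!is.na(parents)], ids),
          which(!is.na(parents))), directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("removeAxon drops axonal sections and their descendants", {
  swc <- c("1 1 0 0 0 5 -1",
           "2 2 10 0 0 1 1",     # axon
           "3 2 20 0 0 1 2",
           "4 3 -10 0 0 1 1",    # dendrites
           "5 3 -20 0 0 1 4")
  m <- removeAxon(readSWC(swc))
  expect_false(any(vapply(sections(m), function(s) s@kind, character(1)) ==
                   "axon"))
  st <- branchStats(m)
  expect_identical(st@nStems, 1L)
  # axon with a custom-typed child: both go
  swc2 <- c("1 1 0 0 0 5 -1",
            "2 2 10 0 0 1 1",
            "3 5 20 0 0 1 2")
  m2 <- removeAxon(readSWC(swc2))
  expect_length(sections(m2), 1L)
  # no axon: identity
  m3 <- readSWC(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 1"))
  expect_identical(removeAxon(m3), m3)
})

test_that("branch identity 2b + s holds on bifurcating fixtures", {
  for (spec in list(c(7, 2), c(3, 1), c(12, 5))) {
    m <- genTree(treeSpec(seed = spec[1] * 10 + spec[2],
                          nBifurcations = spec[1], nStems = spec[2]))
    st <- branchStats(m)
    expect_identical(st@nBranchPoints, as.integer(spec[1]))
    expect_identical(st@nStems, as.integer(spec[2]))
    expect_identical(st@nBranches, as.integer(2 * spec[1] + spec[2]))
  }
  expect_error(branchStats(newMorphologyForTest(list())), "empty")
})

test_that("total length is invariant under rigid motion", {
  m <- genTree(treeSpec(seed = 5, nBifurcations = 6, nStems = 2))
  R <- rotationMatrix(c(1, 2, 3), 0.83)
  m2 <- rotateMorphology(m, R, shift = c(12, -7, 3))
  expect_equal(branchStats(m2)@totalLength, branchStats(m)@totalLength,
               tolerance = 1e-9)
})
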