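test_that("edge lists transcribe to binary matrices with frozen registries", {
  f <- withr::local_tempfile()
  writeLines(c("d1\tp1", "d2\tp2"), f)
  a <- readEdgeList(f, "drug", "protein",
                    rowIds = c("d1", "d2"), colIds = c("p1", "p2"))
  expect_equal(unname(as.matrix(a)), diag(2))

  writeLines(character(0), f)
  a0 <- readEdgeList(f, "drug", "protein",
                     rowIds = c("d1", "d2"), colIds = c("p1", "p2"))
  expect_equal(unname(as.matrix(a0)), matrix(0, 2, 2))
})

test_that("intra-type edge lists are mirrored symmetric", {
  f <- withr::local_tempfile()
  writeLines("d1\td2", f)
  a <- readEdgeList(f, "drug", "drug", rowIds = c("d1", "d2"))
  expect_equal(unname(as.matrix(a)), matrix(c(0, 1, 1, 0), 2))
})

test_that("edge list parse errors name the offending line and id", {
  f <- withr::local_tempfile()
  writeLines(c("d1\tp1", "oops"), f)
  expect_error(readEdgeList(f, "drug", "protein"), "line 2")
  writeLines(c("d1\tp1", "dX\tp2"), f)
  expect_error(
    readEdgeList(f, "drug", "protein", rowIds = c("d1"), colIds = c("p1", "p2")),
    "unknown drug.*dX")
  writeLines(c("d1\tp1\tnotanumber"), f)
  expect_error(readEdgeList(f, "drug", "protein"), "non-numeric weight")
})

test_that("matrix order is invariant to edge-list line order", {
  f <- withr::local_tempfile()
  lines <- c("d2\tp3", "d1\tp1", "d3\tp2", "d1\tp3")
  reg <- list(r = paste0("d", 1:3), c = paste0("p", 1:3))
  writeLines(lines, f)
  a1 <- readEdgeList(f, "drug", "protein", rowIds = reg$r, colIds = reg$c)
  writeLines(rev(lines), f)
  a2 <- readEdgeList(f, "drug", "protein", rowIds = reg$r, colIds = reg$c)
  expect_identical(as.matrix(a1), as.matrix(a2))
})

test_that("similarity tables validate, symmetrise and clip on load", {
  f <- withr::local_tempfile()
  writeLines(c("1\t0", "0\t1"), f)
  s <- readSimilarityMatrix(f, "drug")
  expect_equal(unname(as.matrix(s)), diag(2))

  writeLines(c("1\t1.5", "1.5\t1"), f)
  expect_error(readSimilarityMatrix(f, "drug"), "outside")

  writeLines(c("1\t0.3", "0.3000000001\t1"), f)
  s2 <- readSimilarityMatrix(f, "drug")
  expect_equal(as.matrix(s2)[1, 2], 0.30000000005, tolerance = 0)

  writeLines(c("1\t0\t0", "0\t1\t0"), f)
  expect_error(readSimilarityMatrix(f, "drug"), "not square")

  writeLines(c("1\t0.4", "0.3\t1"), f)
  expect_error(readSimilarityMatrix(f, "drug"), "asymmetric")
})

test_that("similarity tables with id headers align to a frozen registry", {
  f <- withr::local_tempfile()
  writeLines(c("id\tb\ta", "b\t1\t0.2", "a\t0.2\t1"), f)
  s <- readSimilarityMatrix(f, "protein", ids = c("a", "b"))
  expect_identical(nodeIds(s), c("a", "b"))
  expect_equal(as.matrix(s)[1, 2], 0.2)
})

test_that("score matrices rank descending with lexicographic tie-breaks", {
  f <- withr::local_tempfile()
  m1 <- matrix(0.7, 1, 1, dimnames = list("d1", "p1"))
  writeScoreMatrix(m1, f)
  expect_identical(readLines(f), "d1\tp1\t0.7")

  set.seed(1)
  m <- matrix(runif(100), 10, 10,
              dimnames = list(sprintf("d%02d", 1:10), sprintf("p%02d", 1:10)))
  writeScoreMatrix(m, f, topK = 10)
  expect_length(readLines(f), 10)

  mt <- matrix(c(0.5, 0.5, 0.5, 0.1), 2, 2,
               dimnames = list(c("db", "da"), c("p1", "p2")))
  writeScoreMatrix(mt, f)
  got <- read.table(f, sep = "\t")
  # the three tied 0.5 scores sort by (drug id, protein id); 0.1 comes last
  expect_identical(got$V1, c("da", "db", "db", "da"))
  expect_identical(got$V2, c("p1", "p1", "p2", "p2"))

  # training pairs are excluded when a mask is given
  mask <- matrix(c(1, 0, 0, 0), 2, 2)
  writeScoreMatrix(mt, f, trainMask = mask)
  expect_length(readLines(f), 3)
})

test_that("binary matrices round-trip through edge-list write/read exactly", {
  set.seed(3)
  for (rep in 1:3) {
    m <- matrix(rbinom(30, 1, 0.3), 5, 6,
                dimnames = list(paste0("d", 1:5), paste0("p", 1:6)))
    a <- BipartiteAssociation(m, "drug", "protein")
    f <- withr::local_tempfile()
    writeEdgeList(a, f)
    back <- readEdgeList(f, "drug", "protein",
                         rowIds = rownames(m), colIds = colnames(m))
    expect_identical(as.matrix(back), as.matrix(a))
  }
})

test_that("a full collection round-trips through a directory", {
  sim <- tinyDataset()
  dir <- withr::local_tempdir()
  writeHetNetSet(sim$set, dir)
  back <- readHetNetSet(dir, dropIsolated = FALSE)
  expect_identical(labelMatrix(back), labelMatrix(sim$set))
  expect_identical(nodeIds(back, "disease"), nodeIds(sim$set, "disease"))
  expect_equal(as.matrix(back@precomputed$drug_chemical),
               as.matrix(sim$set@precomputed$drug_chemical), tolerance = 1e-10)
})

test_that("nodes isolated across all networks are dropped at assembly", {
  # drug d3 has no edge anywhere and zero chemical similarity off-diagonal
  ids <- list(d = paste0("d", 1:3), p = paste0("p", 1:2),
              z = "z1", s = "s1")
  zero <- function(r, c) matrix(0, length(r), length(c),
                                dimnames = list(r, c))
  dp <- zero(ids$d, ids$p); dp["d1", "p1"] <- 1; dp["d2", "p2"] <- 1
  dd <- zero(ids$d, ids$z); dd["d1", "z1"] <- 1
  pd <- zero(ids$p, ids$z); pd["p1", "z1"] <- 1; pd["p2", "z1"] <- 1
  ds <- zero(ids$d, ids$s); ds["d2", "s1"] <- 1
  ddr <- zero(ids$d, ids$d); ddr["d1", "d2"] <- 1; ddr["d2", "d1"] <- 1
  pp <- zero(ids$p, ids$p); pp["p1", "p2"] <- 1; pp["p2", "p1"] <- 1
  chem <- diag(3); dimnames(chem) <- list(ids$d, ids$d)
  seqs <- matrix(c(1, .5, .5, 1), 2, dimnames = list(ids$p, ids$p))
  expect_message(
    set <- hetNetSet(
      BipartiteAssociation(dp, "drug", "protein"),
      BipartiteAssociation(dd, "drug", "disease"),
      BipartiteAssociation(pd, "protein", "disease"),
      BipartiteAssociation(ds, "drug", "side_effect"),
      BipartiteAssociation(ddr, "drug", "drug"),
      BipartiteAssociation(pp, "protein", "protein"),
      SimilarityMatrix(chem, "drug"),
      SimilarityMatrix(seqs, "protein")),
    "isolated")
  expect_identical(nodeIds(set, "drug"), c("d1", "d2"))
  expect_identical(dim(labelMatrix(set)), c(2L, 2L))
})

test_that("class validity rejects malformed objects", {
  expect_error(SimilarityMatrix(matrix(c(1, 0.9, 0.1, 1), 2), "drug"),
               "asymmetric")
  expect_error(BipartiteAssociation(matrix(c(0, 1, 0, 0), 2), "drug", "drug"),
               "symmetric")
  expect_error(validObject(new("BipartiteAssociation",
                               matrix = matrix(0.5, 1, 1),
                               rowType = "drug", colType = "protein")),
               "binary")
})
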