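test_that("exact group structure is recovered with zero inertia", {
  tpl <- diag(3)[rep(1:3, each = 10), rep(1:3, each = 20)]  # orthogonal rows
  cl <- kmeansBinary(tpl, k = 3L, seed = 1, nInit = 5L)
  expect_equal(matchLabels(rep(1:3, each = 10), clusterLabels(cl))$agreement, 1)
  expect_equal(cl@inertia, 0)
  expect_true(all(cl@distances == 0))
})

test_that("row permutation permutes labels identically", {
  withr::local_seed(2)
  # grouped rows with light corruption: the optimum is unique, so the
  # best-of-restarts clustering must be equivariant under row permutation
  tpl <- ptrburst:::stateTemplates(40L)
  m <- tpl[rep(1:3, each = 10), ]
  flip <- matrix(runif(length(m)) < 0.1, nrow(m))
  m[flip] <- 1 - m[flip]
  cl1 <- kmeansBinary(m, k = 3L, seed = 5, nInit = 10L)
  perm <- sample(30)
  cl2 <- kmeansBinary(m[perm, ], k = 3L, seed = 5, nInit = 10L)
  expect_equal(matchLabels(clusterLabels(cl1)[perm], clusterLabels(cl2))$agreement, 1)
})

test_that("clustering tolerates moderate noise but not extreme noise", {
  tpl <- ptrburst:::stateTemplates(18L)
  truth <- rep(1:3, each = 78L)
  agreeAt <- function(noise, s) {
    rows <- ptrburst:::withLocalSeed(s, {
      m <- tpl[truth, , drop = FALSE]
      flip <- matrix(runif(length(m)) < noise, nrow(m))
      coin <- matrix(rbinom(length(m), 1, 0.5), nrow(m))
      m[flip] <- coin[flip]
      m
    })
    cl <- kmeansBinary(rows, k = 3L, seed = s, nInit = 5L)
    matchLabels(truth, clusterLabels(cl))$agreement
  }
  expect_gte(median(vapply(1:5, function(s) agreeAt(0.2, s), 0)), 0.95)
  expect_lte(median(vapply(1:5, function(s) agreeAt(0.85, s), 0)), 0.6)
})

test_that("cluster result is an inertia fixed point", {
  withr::local_seed(6)
  m <- matrix(rbinom(20 * 30, 1, 0.5), 20)
  cl <- kmeansBinary(m, k = 3L, seed = 2, nInit = 5L)
  # inertia equals the recomputed within-cluster sum of squares
  expect_equal(cl@inertia, sum(cl@distances^2), tolerance = 1e-9)
  # each row is closest to its own centroid
  d2 <- as.matrix(dist(rbind(m, cl@centroids)))[1:20, 21:23]
  expect_true(all(abs(apply(d2, 1, min) - cl@distances) < 1e-9))
})

test_that("probability evolutions average correctly over blocks", {
  design <- blockDesign(instructionDur = 0, taskDur = 2, restDur = 2,
                        nBlocks = 10L, ptrWindow = c(0, 1))
  fs <- 10
  bl <- 40L
  # on exactly in every PTR window (samples 21-30 of each block)
  row <- rep(c(rep(0, 20), rep(1, 10), rep(0, 10)), 10)
  evo <- probabilityEvolution(matrix(row, 1, byrow = TRUE), design, fs)
  expect_equal(evo@evolution[1, ], c(rep(0, 20), rep(1, 10), rep(0, 10)))
  # block-shuffled input leaves the evolution unchanged
  blocks <- matrix(row, nrow = 10, byrow = TRUE)
  shuf <- as.vector(t(blocks[sample(10), ]))
  evo2 <- probabilityEvolution(matrix(shuf, 1, byrow = TRUE), design, fs)
  expect_equal(evo2@evolution, evo@evolution)
  # i.i.d. Bernoulli(p) evolution is flat at p within binomial error
  p <- 0.3
  nb <- 50L
  design2 <- blockDesign(instructionDur = 0, taskDur = 2, restDur = 2,
                         nBlocks = nb, ptrWindow = c(0, 1))
  bern <- withr::with_seed(9, rbinom(nb * bl, 1, p))
  evo3 <- probabilityEvolution(matrix(bern, 1), design2, fs)
  expect_true(all(abs(evo3@evolution - p) < 3 * sqrt(p * (1 - p) / nb)))
})

test_that("the PTR cluster is the one elevated after task cessation", {
  design <- blockDesign(instructionDur = 2, taskDur = 10, restDur = 20,
                        nBlocks = 4L, ptrWindow = c(0, 5))
  fs <- 10
  bl <- round(32 * fs)
  blockSamples <- seq_len(bl) / fs
  mkRows <- function(profile, n) {
    matrix(rep(rep(profile, 4), n), n, byrow = TRUE)
  }
  ptrProfile <- as.numeric(blockSamples > 12 & blockSamples <= 17) * 0.8
  taskProfile <- as.numeric(blockSamples > 2 & blockSamples <= 12) * 0.8
  flatProfile <- rep(0.2, bl)
  m <- rbind(mkRows(ptrProfile, 3), mkRows(taskProfile, 3),
             mkRows(flatProfile, 3))
  evo <- probabilityEvolution(m, design, fs)
  labels <- rep(1:3, each = 3)
  sel <- identifyPtrCluster(evo, labels)
  expect_equal(as.integer(sel), 1L)
  # task-elevated cluster is never picked over the post-task one
  expect_gt(attr(sel, "contrast")[1], attr(sel, "contrast")[2])
  # invariant to cluster label permutation
  perm <- c(3L, 1L, 2L)
  sel2 <- identifyPtrCluster(evo, perm[labels])
  expect_equal(perm[as.integer(sel)], as.integer(sel2))
  # all-flat evolutions cannot be disambiguated
  evoFlat <- probabilityEvolution(mkRows(flatProfile, 6), design, fs)
  expect_error(identifyPtrCluster(evoFlat, rep(1:3, each = 2)), "tied")
})

test_that("stacked state timecourses preserve region and state order", {
  b1 <- thresholdPosterior(matrix(c(0.9, 0.05, 0.05), 3, 10), fs = 10)
  b2 <- thresholdPosterior(matrix(c(0.05, 0.9, 0.05), 3, 10), fs = 10)
  stm <- stateTimecourseMatrix(list(A = b1, B = b2))
  expect_equal(dim(stm@matrix), c(6L, 10L))
  expect_equal(stm@regions, rep(c("A", "B"), each = 3))
  expect_equal(stm@states, rep(1:3, 2))
  expect_equal(stm@matrix[1, ], rep(1, 10))
  expect_equal(stm@matrix[5, ], rep(1, 10))
})
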