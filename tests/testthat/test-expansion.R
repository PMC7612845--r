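test_that("buildBranchModel counts stages and cycling per donor/tissue", {
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:400), donor = "D1", tissue = "BM",
    cluster = c(rep("e1", 100), rep("l1", 300)),
    phase = c(rep("S", 30), rep("G1", 70), rep("G1", 300)),
    stringsAsFactors = FALSE)
  bm <- buildBranchModel(cells, list(early = "e1", late = "l1"), "demo")
  d <- branchData(bm)
  expect_equal(d$n_cells, c(100L, 300L))
  expect_equal(d$f_sg2m, c(0.3, 0))
  ## permuting cells leaves the model unchanged
  bm2 <- buildBranchModel(cells[sample(nrow(cells)), ],
                          list(early = "e1", late = "l1"), "demo")
  expect_equal(branchData(bm2), d)
  ## overlapping stage cluster sets are rejected
  expect_error(buildBranchModel(cells, list(early = "e1", late = c("e1", "l1"))),
               "more than one stage")
})

test_that("estimateExpansion reproduces the deterministic worked examples", {
  memb <- BranchModel(paste0("s", 1:4), c(1000, 2000, 4000, 8000),
                      rep(0.5, 4), "MEMB")
  res <- estimateExpansion(memb)
  tr <- transitions(res)
  expect_equal(tr$amplification, c(4, 4, 4))
  expect_equal(tr$divisions, c(2, 2, 2))
  expect_equal(unname(totalDivisions(res)), 6)
  expect_equal(cumulativeOutput(res)$cum_output, c(1, 4, 16, 64))

  my <- BranchModel(c("s1", "s2"), c(1000, 4000), c(0.5, 0.5), "My")
  expect_equal(unname(totalDivisions(estimateExpansion(my))), 3)

  ## a shrinking stage floors to zero divisions and is flagged
  shrink <- BranchModel(c("s1", "s2"), c(1000, 500), c(1, 1), "x")
  resS <- estimateExpansion(shrink)
  expect_equal(transitions(resS)$amplification, 1)
  expect_equal(unname(totalDivisions(resS)), 0)
  expect_true(transitions(resS)$flagged)
})

test_that("expansion invariances: scaling, cycling monotonicity, floors", {
  N <- c(800, 1500, 6000); f <- c(0.4, 0.25, 0.5)
  D <- function(N, f) unname(totalDivisions(estimateExpansion(
    BranchModel(paste0("s", seq_along(N)), N, f))))
  ## depends only on abundance ratios
  expect_equal(D(N, f), D(N * 7, f))
  expect_equal(D(N, f), D(N / sum(N) * 1e6, f))
  ## increasing any cycling fraction weakly decreases D
  base <- D(N, f)
  for (i in 1:2) {
    f2 <- f; f2[i] <- min(1, f[i] + 0.3)
    expect_lte(D(N, f2), base)
  }
  ## transitions with next-stage count below active cells contribute zero
  expect_equal(D(c(1000, 100, 1000), c(0.5, 0.5, 0.5)),
               log2(1000 / 50))
})

test_that("division estimate is recovered from sampled branch observations", {
  ## multinomial samples of the 4-stage geometric fixture: the estimator is
  ## unbiased and its root-mean-square error stays below 0.1 divisions
  errs <- vapply(1:100, function(s) {
    obs <- simulateBranchCounts(c(1000, 2000, 4000, 8000), rep(0.5, 4),
                                nSample = 50000, seed = s)
    unname(totalDivisions(estimateExpansion(obs))) - 6
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.1)
  expect_lt(sqrt(mean(errs^2)), 0.1)
})

test_that("normalizeOutput aligns conditions against the reference curve", {
  ctrl <- estimateExpansion(BranchModel(paste0("s", 1:3), c(1000, 2000, 4000),
                                        rep(0.5, 3), "MEMB"))
  same <- normalizeOutput(list(a = ctrl, b = ctrl), reference = "a")
  expect_equal(same$output[same$condition == "a"],
               same$output[same$condition == "b"])
  expect_equal(same$ref_output, rep(c(1, 4, 16), 2))

  ## no-expansion condition is a flat curve at 1
  flat <- estimateExpansion(BranchModel(paste0("s", 1:3), c(1000, 400, 100),
                                        rep(1, 3), "MEMB"))
  out <- normalizeOutput(list(ctrl = ctrl, flat = flat), reference = "ctrl")
  expect_equal(out$output[out$condition == "flat"], c(1, 1, 1))

  ## doubled amplification on the first (Ery-like) transition raises the
  ## final output; an untouched (My-like) branch is unchanged
  hs <- estimateExpansion(BranchModel(paste0("s", 1:3), c(1000, 4000, 8000),
                                      rep(0.5, 3), "MEMB"))
  outHS <- normalizeOutput(list(ctrl = ctrl, hs = hs), reference = "ctrl")
  fin <- function(cond) max(outHS$output[outHS$condition == cond])
  expect_gt(fin("hs"), fin("ctrl"))

  mismatch <- estimateExpansion(BranchModel(c("a", "b"), c(10, 20), c(1, 1)))
  expect_error(normalizeOutput(list(ctrl = ctrl, bad = mismatch)),
               "same ordered stage")
})
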