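cellsDf <- function(cluster, donor = "D1", tissue = "BM", phase = NULL) {
  d <- data.frame(cell_id = sprintf("c%03d", seq_along(cluster)),
                  donor = rep_len(donor, length(cluster)),
                  tissue = rep_len(tissue, length(cluster)),
                  cluster = cluster, stringsAsFactors = FALSE)
  if (!is.null(phase)) d$phase <- phase
  d
}

test_that("clusterFractions counts, aggregates and sums to one", {
  one <- clusterFractions(cellsDf(rep("A", 10)))
  expect_equal(one$fraction, 1)

  two <- clusterFractions(cellsDf(c(rep("A", 3), rep("B", 7))))
  expect_equal(setNames(two$fraction, two$group), c(A = 0.3, B = 0.7))

  grp <- clusterFractions(cellsDf(c(rep("A", 3), rep("B", 7))),
                          groupMap = c(A = "G", B = "G"))
  expect_equal(grp$fraction, 1)
  expect_identical(grp$group, "G")

  expect_error(clusterFractions(cellsDf(c("A", "B")), groupMap = c(A = "G")),
               "B")

  ## per-(donor, tissue) fractions always sum to 1
  set.seed(3)
  cells <- cellsDf(sample(LETTERS[1:4], 200, TRUE),
                   donor = sample(c("D1", "D2"), 200, TRUE),
                   tissue = sample(c("BM", "SPL"), 200, TRUE))
  cf <- clusterFractions(cells)
  sums <- tapply(cf$fraction, paste(cf$donor, cf$tissue), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  ## invariant to cell order
  cf2 <- clusterFractions(cells[sample(nrow(cells)), ])
  o <- function(x) x[order(x$donor, x$tissue, x$group), ]
  expect_equal(o(cf2), o(cf), ignore_attr = TRUE)
})

test_that("groupRatio handles direct, zero and degenerate cases", {
  comp <- data.frame(donor = "D1", tissue = "BM",
                     group = c("early", "late", "other"),
                     n_cells = c(4, 2, 4), fraction = c(0.4, 0.2, 0.4))
  r <- groupRatio(comp, "early", "late")
  expect_equal(r$ratio, 2)
  expect_false(r$degenerate)

  expect_equal(groupRatio(comp, "missing", "late")$ratio, 0)

  noLate <- comp[comp$group != "late", ]
  rInf <- groupRatio(noLate, "early", "late")
  expect_identical(rInf$ratio, Inf)
  expect_true(rInf$degenerate)

  expect_error(groupRatio(comp, c("early", "late"), "late"), "disjoint")
})

test_that("cyclingFractions counts S-G2-M per cluster and flags empties", {
  cells <- cellsDf(rep("A", 10), phase = c(rep("S", 2), rep("G2M", 2),
                                           rep("G1", 6)))
  cf <- cyclingFractions(cells)
  expect_equal(cf$fraction_sg2m, 0.4)
  expect_equal(cf$n_sg2m, 4L)

  allG1 <- cellsDf(rep("A", 5), phase = rep("G1", 5))
  expect_equal(cyclingFractions(allG1)$fraction_sg2m, 0)

  ## cluster level with no cells in one donor/tissue -> flagged empty row
  cells$cluster <- factor(cells$cluster, levels = c("A", "B"))
  cf2 <- cyclingFractions(cells)
  b <- cf2[cf2$cluster == "B", ]
  expect_true(b$empty)
  expect_equal(b$fraction_sg2m, 0)

  noPhase <- cellsDf(rep("A", 3), phase = c("S", NA, "G1"))
  expect_error(cyclingFractions(noPhase), "c002")
})

test_that("exact binomial comparison matches enumeration oracle exhaustively", {
  ## spec-style worked values
  expect_equal(compareCyclingBinomial(5, 10, 1, 10), 22 / 1024,
               tolerance = 1e-12)
  expect_equal(compareCyclingBinomial(5, 10, 5, 10), 1)
  ## degenerate reference fractions
  expect_equal(compareCyclingBinomial(0, 10, 0, 10), 1)
  expect_equal(compareCyclingBinomial(0, 10, 3, 10), 0)
  expect_equal(compareCyclingBinomial(10, 10, 9, 10), 0)

  ## full agreement with the enumeration oracle for all n <= 12
  for (p0 in seq(0.1, 0.9, by = 0.1)) {
    xA <- round(p0 * 10); nA <- 10
    if (xA / nA != p0) next
    for (nB in 1:12) for (xB in 0:nB) {
      expect_equal(compareCyclingBinomial(xA, nA, xB, nB),
                   binomMinlikeOracle(xB, nB, p0), tolerance = 1e-9,
                   label = sprintf("p0=%.1f x=%d n=%d", p0, xB, nB))
    }
  }
})

test_that("exact binomial test holds its size under the null", {
  ## equal cycling fractions: rejection rate at alpha = 0.05 stays at or
  ## below 0.05 up to Monte Carlo error (exact tests are conservative)
  nA <- 400; nB <- 120; pTrue <- 0.3
  set.seed(99)
  xA <- 120  # reference pooled fraction 0.3
  pv <- vapply(0:nB, function(x) compareCyclingBinomial(xA, nA, x, nB),
               numeric(1))
  draws <- rbinom(10000, nB, pTrue)
  rate <- mean(pv[draws + 1] < 0.05)
  mcse <- sqrt(0.05 * 0.95 / 10000)
  expect_lte(rate, 0.05 + 3 * mcse)
})
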