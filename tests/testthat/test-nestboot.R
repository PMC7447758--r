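## Build a SupportMatrix directly for the counting tests.
supMat <- function(support, sgn, source = "measured", n_boot = 20L) {
  new("SupportMatrix", support = support,
      sign = matrix(as.integer(sgn), nrow(support)), source = source,
      run_id = 1L, n_boot = n_boot)
}

test_that("bootstrapNetworks is reproducible, stratified and consistent on clean data", {
  fx <- simFixture(6, 3, snr = Inf, seed = 101)
  nets <- bootstrapNetworks(fx$ds, "lsco", 0.05, n_boot = 5, seed = 3)
  expect_length(nets, 5)
  nets2 <- bootstrapNetworks(fx$ds, "lsco", 0.05, n_boot = 5, seed = 3)
  expect_identical(lapply(nets, interactionMatrix),
                   lapply(nets2, interactionMatrix))

  # noiseless, high-information data: every bootstrap recovers the truth
  truth <- abs(interactionMatrix(fx$net)) > 0
  for (n in nets)
    expect_identical(abs(interactionMatrix(n)) > 1e-6, truth,
                     ignore_attr = TRUE)

  # with a single experiment per target the stratified resample is the
  # identity, so all bootstrap networks coincide
  fx1 <- simFixture(5, 2, replicates = 1, snr = 5, seed = 102)
  nets1 <- bootstrapNetworks(fx1$ds, "lsco", 0, n_boot = 4, seed = 4)
  for (k in 2:4)
    expect_identical(interactionMatrix(nets1[[k]]),
                     interactionMatrix(nets1[[1]]))
})

test_that("linkSupport counts majority-sign occurrences with + tie-break", {
  mk <- function(w) GeneNetwork(matrix(c(w, 0, 0, -1), 2, 2))
  # + in 19 of 20, absent in 1
  nets <- c(lapply(1:19, function(i) mk(0.5)), list(mk(0)))
  s <- linkSupport(nets)
  expect_equal(supportValues(s)[1, 1], 0.95)
  expect_equal(supportSigns(s)[1, 1], 1L)
  # 10 + and 10 -: support 0.5, tie broken toward +
  nets2 <- c(lapply(1:10, function(i) mk(1)), lapply(1:10, function(i) mk(-1)))
  s2 <- linkSupport(nets2)
  expect_equal(supportValues(s2)[1, 1], 0.5)
  expect_equal(supportSigns(s2)[1, 1], 1L)
  # never present
  expect_equal(supportValues(s)[1, 2], 0)
  expect_equal(supportSigns(s)[1, 2], 0L)
  # sign zero exactly where support zero
  expect_true(all((supportSigns(s) == 0) == (supportValues(s) == 0)))
})

test_that("nestedSupport aggregates identical noiseless runs exactly", {
  fx <- simFixture(5, 2, replicates = 1, snr = Inf, seed = 111)
  ns <- nestedSupport(fx$ds, "lsco", 0.05, n_nested = 3, n_boot = 5,
                      seed = 9)
  for (r in ns$runs)
    expect_equal(supportValues(r), supportValues(ns$runs[[1]]))
  expect_equal(supportValues(ns$aggregate), supportValues(ns$runs[[1]]))
  expect_true(all(supportValues(ns$aggregate) >= 0 &
                    supportValues(ns$aggregate) <= 1))
})

test_that("strong true links reach high aggregate support on noisy data", {
  fx <- simFixture(8, 3, snr = 10, seed = 121)
  z <- penaltyForDensity(fx$ds, "lsco", 3)
  ns <- nestedSupport(fx$ds, "lsco", z, n_nested = 4, n_boot = 15, seed = 5)
  truth <- abs(interactionMatrix(fx$net)) > 0
  expect_gt(min(supportValues(ns$aggregate)[truth]), 0.9)
})

test_that("fdrCurve implements the shuffled-over-measured count ratio", {
  g <- c("a", "b", "c")
  zero3 <- matrix(0, 3, 3, dimnames = list(g, g))
  meas <- zero3; meas[1, 2] <- 0.9; meas[2, 3] <- 0.8
  sgn <- (meas > 0) * 1
  measured <- supMat(meas, sgn)
  # shuffled runs with no supported links: FDR 0 for all s > 0
  shuf0 <- list(supMat(zero3, zero3 * 0, "shuffled"),
                supMat(zero3, zero3 * 0, "shuffled"))
  # FDR is 0 wherever measured links remain, and 1 by convention once no
  # measured link reaches the cutoff (here above support 0.9)
  fc <- fdrCurve(measured, shuf0, grid = seq(0, 1, 0.25), alpha = 0.05)
  expect_equal(fdrValues(fc), c(1, 0, 0, 0, 1), ignore_attr = TRUE)
  expect_equal(supportCutoff(fc), 0.25)

  # a spurious link at support 0.9 in 2 of 5 shuffled runs aggregates to
  # (0.9 + 0.9)/5 = 0.36; against 8 measured links at 0.9 the FDR is 1/8
  # at s = 0.3 and 0 at s = 0.5
  meas8 <- matrix(0, 4, 4); meas8[1:8] <- 0.9
  measured8 <- supMat(meas8, (meas8 > 0) * 1)
  zero4 <- matrix(0, 4, 4)
  one <- zero4; one[16] <- 0.9
  shuf <- c(list(supMat(one, (one > 0) * 1, "shuffled"),
                 supMat(one, (one > 0) * 1, "shuffled")),
            lapply(1:3, function(i) supMat(zero4, zero4, "shuffled")))
  fc8 <- fdrCurve(measured8, shuf, grid = c(0, 0.3, 0.5), alpha = 0.05)
  expect_equal(fdrValues(fc8), c(1, 1 / 8, 0), ignore_attr = TRUE)
  expect_equal(supportCutoff(fc8), 0.5)
})

test_that("fdrCurve is ~1 when measured and shuffled supports share a distribution", {
  set.seed(17)
  rmat <- function() {
    m <- matrix(pmax(runif(400) - 0.3, 0) / 0.7, 20, 20)
    supMat(m, (m > 0) * 1)
  }
  measured <- perturbGRN:::.aggregateSupport(lapply(1:8, function(i) rmat()))
  shufAgg <- perturbGRN:::.aggregateSupport(lapply(1:8, function(i) rmat()))
  fc <- fdrCurve(measured, shufAgg, grid = seq(0, 0.4, 0.1), alpha = 0.05)
  expect_true(all(abs(fdrValues(fc) - 1) < 0.25))
  expect_true(is.na(supportCutoff(fc)))
})

test_that("fdr curve is non-increasing while measured counts stay positive", {
  fx <- simFixture(8, 3, snr = 7, seed = 131)
  z <- penaltyForDensity(fx$ds, "lsco", 3)
  nb <- nestBoot(fx$ds, "lsco", z, n_nested = 3, n_boot = 10, seed = 7)
  pos <- vapply(nb$fdr@grid, function(s)
    sum(supportValues(nb$measured$aggregate) >= s &
          supportValues(nb$measured$aggregate) > 0) > 0, logical(1))
  f <- fdrValues(nb$fdr)[pos]
  expect_true(all(diff(f) <= 1e-12))
})

test_that("selectNetwork filters by cutoff and refits; unreachable alpha yields no network", {
  g <- c("a", "b")
  sup <- matrix(c(0, 1, 0.99, 0), 2, 2, dimnames = list(g, g))
  sgn <- matrix(c(0, 1, -1, 0), 2, 2)
  agg <- supMat(sup, sgn, "aggregate")
  fdr <- new("FDRCurve", grid = c(0, 0.975), fdr = c(1, 0.01),
             alpha = 0.05, cutoff = 0.975)
  fx <- simFixture(2, 1.5, snr = 20, seed = 141)
  net <- selectNetwork(fx$ds, agg, fdr, "lsco", 0.1)
  A <- interactionMatrix(net)
  # only the two entries at or above the cutoff may carry weight, with the
  # consensus sign enforced by the refit
  expect_true(all(which(A != 0) %in% c(2, 3)))
  expect_gte(A[2, 1], 0)
  expect_lte(A[1, 2], 0)
  expect_equal(networkMetadata(net)$support_cutoff, 0.975)

  fdrNA <- new("FDRCurve", grid = c(0, 0.975), fdr = c(1, 0.5),
               alpha = 0.05, cutoff = NA_real_)
  expect_message(out <- selectNetwork(fx$ds, agg, fdrNA), "no network")
  expect_null(out)
})

test_that("overlapCurve computes mean pairwise Jaccard", {
  g <- letters[1:3]
  m1 <- matrix(0, 3, 3, dimnames = list(g, g)); m1[c(1, 5, 9, 2, 3)] <- 1
  r1 <- supMat(m1, (m1 > 0) * 1)
  oc <- overlapCurve(list(r1, r1), grid = c(0.5, 1))
  expect_equal(unname(oc), c(1, 1))

  # disjoint single-link runs
  d1 <- matrix(0, 3, 3); d1[2] <- 1
  d2 <- matrix(0, 3, 3); d2[3] <- 1
  oc2 <- overlapCurve(list(supMat(d1, (d1 > 0) * 1),
                           supMat(d2, (d2 > 0) * 1)), grid = 0.5)
  expect_equal(unname(oc2), 0)

  # 3 shared of 5 and 4 (union 6) -> 0.5
  a <- matrix(0, 3, 3); a[1:5] <- 1
  b <- matrix(0, 3, 3); b[c(1, 2, 3, 6)] <- 1
  oc3 <- overlapCurve(list(supMat(a, (a > 0) * 1), supMat(b, (b > 0) * 1)),
                      grid = 0.5)
  expect_equal(unname(oc3), 0.5)
})

test_that("shuffled-data supports do not dominate measured supports", {
  fx <- simFixture(8, 3, snr = 10, seed = 151)
  z <- penaltyForDensity(fx$ds, "lsco", 3)
  nb <- nestBoot(fx$ds, "lsco", z, n_nested = 3, n_boot = 10, seed = 13)
  mShuf <- mean(vapply(nb$shuffled$runs,
                       function(r) mean(supportValues(r)), numeric(1)))
  expect_lte(mShuf, mean(supportValues(nb$measured$aggregate)))
})
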