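test_that("balanceErrors returns zero errors on exactly consistent data", {
  fx <- simFixture(5, 2, snr = Inf, seed = 201)
  b <- balanceErrors(fx$net, foldChanges(fx$ds), designMatrix(fx$ds))
  expect_equal(b$t, 0)
  expect_equal(max(abs(b$Ehat)), 0)
  expect_equal(max(abs(b$Fhat)), 0)
})

test_that("balanceErrors is homogeneous: scaling data scales errors, not relative errors", {
  fx <- simFixture(5, 2, snr = 3, seed = 202)
  Y <- foldChanges(fx$ds); P <- designMatrix(fx$ds)
  b1 <- balanceErrors(fx$net, Y, P)
  cc <- 2.5
  b2 <- balanceErrors(fx$net, cc * Y, cc * P)
  expect_equal(b2$Ehat, cc * b1$Ehat, tolerance = 1e-6)
  expect_equal(b2$Fhat, cc * b1$Fhat, tolerance = 1e-6)
  expect_equal(b2$Erel, b1$Erel, tolerance = 1e-8)
  expect_equal(b2$Frel, b1$Frel, tolerance = 1e-8)
})

test_that("balanceErrors equalizes the two relative errors when both are active", {
  set.seed(23)
  for (r in 1:20) {
    n <- sample(3:6, 1); m <- sample(3:8, 1)
    A <- matrix(rnorm(n * n, sd = 0.4), n); diag(A) <- diag(A) - 1.5
    Yp <- matrix(rnorm(n * m), n)
    Pp <- matrix(rnorm(n * m), n)
    b <- balanceErrors(GeneNetwork(A), Yp, Pp)
    if (b$Erel > 1e-8 && b$Frel > 1e-8)
      expect_lt(abs(b$Erel - b$Frel), 1e-6)
    # model constraint holds exactly by construction
    resid <- (Pp - b$Fhat) + A %*% (Yp - b$Ehat)
    expect_lt(sqrt(sum(resid^2)), 1e-6 * sqrt(sum(Pp^2)))
  }
})

test_that("balanceErrors matches an independent convex-solver oracle", {
  set.seed(31)
  for (r in 1:5) {
    n <- 2 + (r %% 3); m <- sample(2:4, 1)
    A <- matrix(rnorm(n * n, sd = 0.5), n); diag(A) <- diag(A) - 2
    Yp <- matrix(rnorm(n * m), n); Pp <- matrix(rnorm(n * m), n)
    b <- balanceErrors(GeneNetwork(A), Yp, Pp)
    o <- minimaxOracle(A, Yp, Pp)
    expect_equal(b$t, o$t, tolerance = 1e-6)
  }
  expect_error(balanceErrors(toyNet2(), matrix(0, 2, 2), diag(-1, 2)),
               "all zero")
})

test_that("predictLeftout maps perturbations and responses through the model", {
  n <- 4
  netI <- GeneNetwork(diag(-1, n))
  des <- makeDesign(n, "single", replicates = 1, genes = networkGenes(netI))
  dsI <- simulateDataset(netI, des, snr = Inf)
  pr <- predictLeftout(netI, dsI, 2)
  expect_equal(unname(pr$Ypred[, 1]), c(0, -1, 0, 0))

  fx <- simFixture(5, 2, snr = Inf, seed = 211)
  for (g in c(1, 3)) {
    pr <- predictLeftout(fx$net, fx$ds, g)
    expect_equal(pr$Ypred, foldChanges(fx$ds)[, pr$cols, drop = FALSE],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(pr$Ppred, designMatrix(fx$ds)[, pr$cols, drop = FALSE],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  # hand matrix-vector product: p_hat = -A y
  dn <- list(c("gA", "gB"), "e1")
  ds2 <- PerturbationDataset(matrix(c(-1, -1), 2, 1, dimnames = dn),
                             matrix(c(-1, 0), 2, 1, dimnames = dn))
  pr2 <- predictLeftout(toyNet2(), ds2, 1)
  expect_equal(unname(pr2$Ppred[, 1]), c(-1, 0))
})

test_that("bfecv is exact on noiseless data and separates wrong topologies", {
  fx <- simFixture(6, 3, snr = Inf, seed = 221)
  fit <- bfecv(fx$net, fx$ds, truncate = FALSE)
  expect_equal(wRSS(fit), 0, tolerance = 1e-10)
  expect_equal(fit@R2, 1, tolerance = 1e-9)

  # the empty (self-degradation only) network must fit strictly worse
  empty <- GeneNetwork(diag(-1, 6), genes = networkGenes(fx$net))
  fitE <- bfecv(empty, fx$ds, truncate = FALSE)
  expect_gt(wRSS(fitE), wRSS(fit))
})

test_that("per-fold balanced errors satisfy the model constraint", {
  fx <- simFixture(6, 3, snr = 5, seed = 231)
  fit <- bfecv(fx$net, fx$ds, truncate = FALSE)
  A <- interactionMatrix(fx$net)
  Y <- foldChanges(fx$ds); P <- designMatrix(fx$ds)
  for (g in names(fit@Ehat)) {
    cols <- which(!vapply(targetList(fx$ds), function(t) g %in% t,
                          logical(1)))
    Pp <- P[, cols]; Yp <- Y[, cols]
    resid <- (Pp - fit@Fhat[[g]]) + A %*% (Yp - fit@Ehat[[g]])
    expect_lt(sqrt(sum(resid^2)), 1e-6 * sqrt(sum(Pp^2)))
  }
})

test_that("prediction error under fixed weights falls as noise falls", {
  w1 <- list(wE = 1, wF = 1)
  m <- vapply(c(2, 5, 10), function(snr) {
    mean(vapply(1:10, function(s) {
      fx <- simFixture(8, 3, snr = snr, seed = 300 + s)
      wRSS(bfecv(fx$net, fx$ds, truncate = FALSE, weights = w1))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("svdTruncate removes near-null directions and respects the range bound", {
  # well-conditioned network already in range: unchanged up to round-off
  fx <- simFixture(5, 2, snr = 10, seed = 241)
  tr <- svdTruncate(fx$net, fx$ds)
  expect_equal(interactionMatrix(tr), interactionMatrix(fx$net),
               tolerance = 1e-9)
  expect_equal(networkMetadata(tr)$svd_rank, 5)

  # constructed 3x3 with a 1e-9 singular value: direction removed,
  # predictions bounded
  set.seed(8)
  Q1 <- qr.Q(qr(matrix(rnorm(9), 3)))
  Q2 <- qr.Q(qr(matrix(rnorm(9), 3)))
  A <- Q1 %*% diag(c(2, 1, 1e-9)) %*% t(Q2)
  bad <- GeneNetwork(A)
  P <- -diag(3); rownames(P) <- networkGenes(bad)
  Y <- matrix(rnorm(9), 3, dimnames = dimnames(P))
  dsb <- PerturbationDataset(Y, P)
  trb <- svdTruncate(bad, dsb)
  expect_lte(networkMetadata(trb)$svd_rank, 2)
  pred <- -pseudoInverse(interactionMatrix(trb)) %*% P
  delta <- 0.1 * diff(range(Y))
  expect_true(all(pred >= min(Y) - delta & pred <= max(Y) + delta))

  # tighter slack can only retain fewer singular values
  ranks <- vapply(c(0.5, 0.1, 0.02), function(d)
    networkMetadata(svdTruncate(bad, dsb, delta = d))$svd_rank, integer(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("shuffleTopology preserves degrees, diagonal, signs and weights", {
  fx <- simFixture(10, 3, snr = Inf, seed = 251)
  A <- interactionMatrix(fx$net)
  sh <- interactionMatrix(shuffleTopology(fx$net, seed = 33))
  expect_equal(rowSums(sh != 0), rowSums(A != 0))        # in-degree
  expect_equal(diag(sh), diag(A))
  off <- row(A) != col(A)
  expect_equal(sort(sh[off][sh[off] != 0]), sort(A[off][A[off] != 0]))
  expect_equal(sum(sh > 0), sum(A > 0))
  # reproducible, and different seeds move links
  expect_identical(sh, interactionMatrix(shuffleTopology(fx$net, seed = 33)))
  expect_false(identical(sh,
                         interactionMatrix(shuffleTopology(fx$net, seed = 34))))
})

test_that("compareToNull follows the add-one empirical p and median ratio", {
  r <- compareToNull(2, c(1, 2, 3, 4))
  expect_equal(r$ratio_to_median, 2 / 2.5)
  expect_equal(r$empirical_p, 3 / 5)

  r0 <- compareToNull(0, c(1, 2, 3, 4))
  expect_equal(r0$ratio_to_median, 0)
  expect_equal(r0$empirical_p, 1 / 5)

  rmax <- compareToNull(4, c(1, 2, 3, 4))
  expect_equal(rmax$empirical_p, 1)

  expect_equal(compareToNull(1, c(0, 0, 0))$ratio_to_median, Inf)
})

test_that("nullDistribution is reproducible and favors the generating topology", {
  fx <- simFixture(8, 3, snr = 10, seed = 261)
  nd1 <- nullDistribution(fx$net, fx$ds, "shuffled_topology", n = 10,
                          seed = 55)
  nd2 <- nullDistribution(fx$net, fx$ds, "shuffled_topology", n = 10,
                          seed = 55)
  expect_identical(nullSamples(nd1), nullSamples(nd2))
  expect_lt(nd1@ratioToMedian, 1)

  ndd <- nullDistribution(fx$net, fx$ds, "shuffled_data", n = 10, seed = 56)
  expect_lt(ndd@ratioToMedian, 1)
})

test_that("knockdownQC reproduces textbook one-sample t-tests", {
  Y <- matrix(0, 3, 9)
  genes <- c("g1", "g2", "g3")
  dimnames(Y) <- list(genes, paste0("s", 1:9))
  P <- Y
  for (i in 1:3) P[i, (3 * i - 2):(3 * i)] <- -1
  Y[1, 1:3] <- c(-3.0, -3.1, -2.9)
  Y[2, 4:6] <- c(-0.1, 0.1, 0.0)
  Y[3, 7:9] <- c(1.0, -6.0, -2.5)
  qc <- knockdownQC(PerturbationDataset(Y, P))
  expect_equal(qc$mean_lfc, c(-3.0, 0.0, -2.5), tolerance = 1e-12)
  expect_equal(qc$t[1], -3 / (0.1 / sqrt(3)), tolerance = 1e-4)
  expect_true(qc$significant[1])
  expect_equal(qc$t[2], 0)
  expect_equal(qc$p[2], 0.5)
  expect_false(qc$significant[2])
  # passes the fold-change bound but not the p-value bound
  expect_equal(qc$t[3], -2.5 / (3.5 / sqrt(3)), tolerance = 1e-6)
  expect_gt(qc$p[3], 0.1)
  expect_false(qc$significant[3])
})

test_that("networkOverlapTest matches closed-form and summed hypergeometric tails", {
  # identical 10-link sets in a 100-pair universe
  set.seed(3)
  A <- matrix(0, 5, 5); A[sample(25, 10)] <- 1
  net <- GeneNetwork(A)
  links <- with(expand.grid(i = 1:5, j = 1:5)[which(A != 0), ],
                paste(networkGenes(net)[j], networkGenes(net)[i], sep = "->"))
  r <- networkOverlapTest(net, links, universe_size = 100)
  expect_equal(r$overlap, 10)
  expect_equal(r$p, 1 / choose(100, 10), tolerance = 1e-12)

  # disjoint sets: upper tail at 0 is ~1
  rd <- networkOverlapTest(net, c("x->y", "y->z"), universe_size = 100)
  expect_equal(rd$overlap, 0)
  expect_equal(rd$p, 1, tolerance = 1e-9)

  # overlap 3 with |net|=5, |ref|=4, universe 30: direct summation oracle
  A5 <- matrix(0, 5, 5)
  A5[c(2, 7, 13, 19, 24)] <- 1
  net5 <- GeneNetwork(A5)
  g5 <- networkGenes(net5)
  mkLinks <- function(M) with(expand.grid(i = 1:5, j = 1:5)[which(M != 0), ],
                              paste(g5[j], g5[i], sep = "->"))
  linksB <- c(mkLinks(A5)[1:3], paste(g5[1], g5[5], sep = "->"))
  r3 <- networkOverlapTest(net5, linksB, universe_size = 30)
  oracle <- sum(vapply(3:4, function(k)
    choose(4, k) * choose(30 - 4, 5 - k), numeric(1))) / choose(30, 5)
  expect_equal(r3$overlap, 3)
  expect_equal(r3$p, oracle, tolerance = 1e-12)

  expect_error(networkOverlapTest(net, links, universe_size = 0), "positive")
  expect_error(networkOverlapTest(net, links, universe_size = 5), "smaller")
})

test_that("undirected overlap collapses reciprocal links to gene pairs", {
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A[1, 2] <- 1; A[2, 1] <- -1; A[3, 3] <- -1
  net <- GeneNetwork(A)
  r <- networkOverlapTest(net, c("a--b", "c--c"), universe_size = 6,
                          directed = FALSE)
  expect_equal(r$overlap, 2)
  expect_equal(r$n_net, 2)  # a--b counted once, c--c kept
})
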