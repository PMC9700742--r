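test_that("expectedRate evaluates the assortative Poisson rate", {
  # K = 1, both memberships 1 -> rate is w alone
  st <- latentState(matrix(1, 2, 1), matrix(0.7, 1, 1))
  expect_equal(expectedRate(st, c(1, 2)), 0.7)

  # a single all-zero membership row nullifies every containing hyperedge
  u <- matrix(1, 3, 2); u[2, ] <- 0
  st0 <- latentState(u, matrix(1, 2, 2))
  expect_equal(expectedRate(st0, c(1, 2)), 0)
  expect_equal(expectedRate(st0, c(1, 2, 3)), 0)

  # hand evaluation, K = 2, size 3
  u <- rbind(c(1, 0), c(1, 0), c(0.5, 0.5))
  st2 <- latentState(u, rbind(c(1, 1), c(2, 4)))
  expect_equal(expectedRate(st2, 1:3), 2 * 0.5 + 4 * 0)

  expect_error(expectedRate(st2, c(1, 2, 3, 3)), "range|size")
  expect_error(expectedRate(st, 1), "size")
})

test_that("symmetric-polynomial cache counts subsets and satisfies deflation", {
  # all-ones memberships: C_k(d) = choose(N, d)
  C <- buildSymPoly(matrix(1, 6, 2), D = 4)
  expect_equal(C, matrix(rep(choose(6, 0:4), 2), 5, 2))

  # deflation identity C(d) = C^(-i)(d) + u_ik C^(-i)(d-1) for every node
  set.seed(7)
  u <- matrix(runif(8 * 2), 8, 2)
  D <- 4
  C <- buildSymPoly(u, D)
  for (i in 1:8) {
    Cm <- bruteEsp(u[-i, , drop = FALSE], D)
    for (k in 1:2)
      expect_equal(C[2:(D + 1), k],
                   Cm[2:(D + 1), k] + u[i, k] * Cm[1:D, k],
                   tolerance = 1e-10)
  }

  # equality with explicit subset enumeration
  expect_equal(buildSymPoly(u, D), bruteEsp(u, D), tolerance = 1e-10)
})

test_that("log-likelihood matches the brute-force evaluation of the model", {
  # N=3, K=1, single pair, all parameters 1: Omega = 3 pairs + 1 triple
  h <- Hypergraph(list(c("1", "2")), nodeLabels = c("1", "2", "3"))
  st <- latentState(matrix(1, 3, 1), matrix(1, 2, 1))
  expect_equal(hyperLogLik(st, h), -4)

  # observed hyperedge with zero rate -> -Inf, reported not raised
  u0 <- matrix(1, 3, 1); u0[1, ] <- 0
  expect_equal(hyperLogLik(latentState(u0, matrix(1, 2, 1)), h), -Inf)

  for (seed in 1:10) {
    inst <- randomInstance(seed, N = sample(5:10, 1), D = sample(2:4, 1),
                           K = sample(1:3, 1))
    expect_equal(hyperLogLik(inst$state, inst$h),
                 bruteLogLik(inst$u, inst$w, inst$h), tolerance = 1e-8)
  }
})

test_that("E-step responsibilities normalize and follow the rate shares", {
  h <- toyHypergraph()
  # K = 1: everything attributed to the single community
  st1 <- latentState(matrix(runif(4), 4, 1), matrix(1, 2, 1))
  expect_equal(unname(eStep(st1, h)[, 1]), rep(1, numHyperedges(h)))

  # fully symmetric state: uniform responsibilities
  st2 <- latentState(matrix(1, 4, 3), matrix(0.5, 2, 3))
  expect_equal(unname(eStep(st2, h)), matrix(1 / 3, numHyperedges(h), 3),
               ignore_attr = TRUE)

  # hand example: one community's product vanishes
  h2 <- Hypergraph(list(c("1", "2")), nodeLabels = c("1", "2"))
  st3 <- latentState(rbind(c(1, 1), c(1, 0)), rbind(c(3, 5)))
  expect_equal(unname(eStep(st3, h2)[1, ]), c(1, 0))

  # degenerate row: zero rate -> uniform + flag
  st4 <- latentState(matrix(0, 2, 2), rbind(c(1, 1)))
  rho <- eStep(st4, h2)
  expect_equal(unname(rho[1, ]), c(0.5, 0.5))
  expect_true(attr(rho, "degenerate")[1])

  # rows sum to 1 on random instances
  for (seed in 1:5) {
    inst <- randomInstance(seed)
    rho <- eStep(inst$state, inst$h)
    expect_equal(unname(rowSums(rho)), rep(1, nrow(rho)), tolerance = 1e-12)
  }
})

test_that("membership update matches enumeration of incident hyperedges", {
  # derived example: numerator 2, denominator w2*C^(-0)(1) + w3*C^(-0)(2) = 3
  h <- Hypergraph(list(c("1", "2")), weights = 2, nodeLabels = c("1", "2", "3"))
  st <- latentState(matrix(1, 3, 1), matrix(1, 2, 1))
  rho <- eStep(st, h)
  up <- updateU(st, h, rho)
  expect_equal(up$u[1, 1], 2 / 3)

  # node absent from every observed hyperedge -> row zeroed
  expect_equal(up$u[3, 1], 0)

  # zero absorption: zero entries stay zero
  u0 <- matrix(runif(8), 4, 2); u0[2, 1] <- 0
  h4 <- toyHypergraph()
  st0 <- latentState(u0, matrix(0.5, 2, 2))
  up0 <- updateU(st0, h4, eStep(st0, h4))
  expect_equal(up0$u[2, 1], 0)
})

test_that("cached update denominators equal brute-force enumeration", {
  for (seed in 1:10) {
    inst <- randomInstance(seed, N = sample(5:10, 1), D = sample(2:4, 1),
                           K = sample(1:3, 1))
    u <- inst$u; w <- inst$w; h <- inst$h
    rho <- eStep(inst$state, h)
    up <- updateU(inst$state, h, rho)
    # replicate the sequential sweep with brute-force denominators
    uref <- u
    num <- matrix(0, nrow(u), ncol(u))
    for (e in seq_along(hyperedges(h)))
      for (i in hyperedges(h)[[e]])
        num[i, ] <- num[i, ] + edgeWeights(h)[e] * rho[e, ]
    for (i in seq_len(nrow(u))) {
      den <- bruteUDenom(uref, w, i)
      for (k in seq_len(ncol(u)))
        uref[i, k] <- if (num[i, k] == 0) 0
                      else if (den[k] == 0) uref[i, k]
                      else num[i, k] / den[k]
    }
    expect_equal(up$u, uref, tolerance = 1e-8)
    # refolded cache agrees with a fresh build on the new memberships
    expect_equal(up$cache, buildSymPoly(up$u, nrow(w) + 1),
                 tolerance = 1e-6)
  }
})

test_that("affinity update divides responsibilities by subset sums", {
  # derived example: w = 2 * 1 / C(2) with C(2) = 3
  h <- Hypergraph(list(c("1", "2")), weights = 2, nodeLabels = c("1", "2", "3"))
  st <- latentState(matrix(1, 3, 1), matrix(1, 2, 1))
  rho <- eStep(st, h)
  w <- updateW(h, rho, buildSymPoly(st))
  expect_equal(w[1, 1], 2 / 3)
  # size 3 has no observed hyperedge -> zero row
  expect_equal(w[2, 1], 0)

  for (seed in 1:8) {
    inst <- randomInstance(seed + 50, N = sample(6:12, 1), D = 3,
                           K = sample(1:3, 1))
    rho <- eStep(inst$state, inst$h)
    w <- updateW(inst$h, rho, buildSymPoly(inst$u, 3))
    sizes <- edgeSizes(inst$h)
    for (d in 2:3) {
      sel <- sizes == d
      numRef <- if (any(sel))
        colSums(rho[sel, , drop = FALSE] * edgeWeights(inst$h)[sel])
      else numeric(ncol(inst$u))
      denRef <- bruteWDenom(inst$u, d)
      wRef <- ifelse(denRef > 0 & numRef > 0, numRef / denRef, 0)
      expect_equal(unname(w[d - 1, ]), unname(wRef), tolerance = 1e-8)
    }
  }
})

test_that("EM fit is seed-reproducible and the objective is monotone", {
  inst <- randomInstance(3, N = 12, D = 3, K = 2, nEdges = 14)
  f1 <- suppressWarnings(
    fitHypergraphMT(inst$h, K = 2, nRestarts = 2, maxIter = 80, seed = 5))
  f2 <- suppressWarnings(
    fitHypergraphMT(inst$h, K = 2, nRestarts = 2, maxIter = 80, seed = 5))
  expect_identical(f1@traces, f2@traces)
  expect_identical(memberships(f1), memberships(f2))

  for (tr in f1@traces) {
    fin <- tr[is.finite(tr)]
    expect_true(all(diff(fin) >= -1e-9 * pmax(1, abs(fin[-length(fin)]))))
  }
})

test_that("the likelihood reported by the fit matches the brute-force model", {
  inst <- randomInstance(9, N = 9, D = 3, K = 1, nEdges = 10)
  fit <- fitHypergraphMT(inst$h, K = 1, nRestarts = 2, maxIter = 120, seed = 2)
  expect_equal(fit@logLik,
               bruteLogLik(memberships(fit), affinity(fit), inst$h),
               tolerance = 1e-8)
  # K = 1 balance: total responsibility-weighted count equals total weight
  expect_equal(sum(fit@rho * edgeWeights(inst$h)), totalWeight(inst$h))
})

test_that("on a pairs-only input the fit is the assortative pairwise model", {
  set.seed(21)
  st <- plantedState(N = 12, K = 2, DMax = 2, wStrength = 0.8)
  h <- pairsOnly(sampleHypergraph(st, seed = 4))
  K <- 2
  set.seed(31)
  u <- matrix(runif(numNodes(h) * K), numNodes(h), K)
  w2 <- runif(K)
  stI <- latentState(u, matrix(w2, 1, K, byrow = TRUE))
  uPkg <- u; wPkg <- matrix(w2, 1, K)
  uRef <- u; w2Ref <- w2
  for (it in 1:5) {
    stPkg <- latentState(uPkg, wPkg)
    rho <- eStep(stPkg, h)
    up <- updateU(stPkg, h, rho)
    uPkg <- up$u
    wPkg <- updateW(h, rho, up$cache)
    ref <- refPairwiseIteration(uRef, w2Ref, h)
    uRef <- ref$u; w2Ref <- ref$w2
    expect_equal(uPkg, uRef, tolerance = 1e-10)
    expect_equal(unname(wPkg[1, ]), unname(w2Ref), tolerance = 1e-10)
  }
})

test_that("estimation modes: sparsity shrinks, normalization keeps simplex rows", {
  inst <- randomInstance(11, N = 10, D = 3, K = 2, nEdges = 12)
  fitN <- suppressWarnings(fitHypergraphMT(inst$h, K = 2, nRestarts = 2,
                                           maxIter = 60, seed = 3,
                                           mode = "normalized"))
  expect_equal(unname(rowSums(memberships(fitN))),
               rep(1, numNodes(inst$h)), tolerance = 1e-9)

  st <- latentState(inst$u, inst$w)
  rho <- eStep(st, inst$h)
  plain <- updateU(st, inst$h, rho, gamma = 0)$u
  shrunk <- updateU(st, inst$h, rho, gamma = 5)$u
  pos <- plain > 0
  expect_true(all(shrunk[pos] < plain[pos]))
  fitS <- suppressWarnings(fitHypergraphMT(inst$h, K = 2, nRestarts = 2,
                                           maxIter = 60, seed = 3,
                                           mode = "sparsity", gamma = 1))
  expect_true(is.finite(fitS@logLik))
})

test_that("planted two-block hypergraphs are recovered by the fit", {
  st <- plantedState(N = 40, K = 2, DMax = 3, overlap = 0,
                     wStrength = c(0.25, 0.02))
  h <- sampleHypergraph(st, seed = 17)
  fit <- fitHypergraphMT(h, K = 2, nRestarts = 5, maxIter = 300, seed = 6)
  hard <- max.col(memberships(fit), ties.method = "first")
  truth <- max.col(st@u[as.integer(sub("n", "", nodeLabels(h))), ])
  acc <- max(mean(hard == truth), mean(hard == 3 - truth))
  expect_gte(acc, 0.9)
})
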