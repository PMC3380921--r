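mekChain <- function() cascade(3, names = c("A", "MEK", "ERK"))

test_that("inhibition augments the graph by one complementary node per target", {
  g <- randomSignedNetwork(n_nodes = 10, n_ligands = 2, seed = 8)
  w <- weightAllEdges(g)
  spec <- perturbationSpec(inhibit = "N3")
  aug <- applyInhibition(g, w, spec)
  expect_equal(numNodes(aug$graph), 11L)
  expect_equal(numEdges(aug$graph), numEdges(g) + 1L)
  extra <- edges(aug$graph)[numEdges(g) + 1L, ]
  expect_equal(extra$from, "anti_N3")
  expect_equal(extra$to, "N3")
  expect_equal(extra$sign, -1L)
  # original edges and weights untouched; complementary weight 1
  expect_identical(edges(aug$weights)[seq_len(numEdges(g)), ], edges(w))
  expect_equal(edges(aug$weights)$weight[numEdges(g) + 1L], 1)
  expect_equal(aug$clamp, c(anti_N3 = 1))

  expect_error(applyInhibition(g, w, perturbationSpec(inhibit = "nope")),
               "not in network")
  clash <- signedDigraph(rbind(edges(g),
    data.frame(from = "anti_N3", to = "N3", sign = 1L)))
  expect_error(
    applyInhibition(clash, weightAllEdges(clash),
                    perturbationSpec(inhibit = "N3")),
    "already exist")
  expect_error(perturbationSpec(inhibit = "X", fix = c(X = 1)),
               "both inhibited and fixed")
})

test_that("complementary-node inhibition lowers but does not silence downstream", {
  g <- mekChain()
  base <- simulationConfig(c(A = 1), iterations = 100, seed = 11,
                           halfLifeMode = "long")
  inh <- simulationConfig(c(A = 1), iterations = 100, seed = 11,
                          halfLifeMode = "long",
                          perturbations = perturbationSpec(inhibit = "MEK"))
  trN <- simulateNetwork(g, base)[[1]]
  trI <- simulateNetwork(g, inh)[[1]]
  erkN <- mean(activityMatrix(trN)["ERK", -1])
  erkI <- mean(activityMatrix(trI)["ERK", -1])
  expect_lt(erkI, erkN)
  expect_gt(erkI, 0)   # signal still passes through the inhibited node
  # and the inhibited target itself never gains activity
  expect_lte(mean(activityMatrix(trI)["MEK", -1]),
             mean(activityMatrix(trN)["MEK", -1]))
})

test_that("a null inhibition leaves the run bytewise unchanged", {
  g <- mekChain()
  mk <- function(p) simulationConfig(c(A = 0.9), iterations = 50, seed = 3,
                                     perturbations = p)
  plain <- simulateNetwork(g, mk(perturbationSpec()))
  null <- simulateNetwork(g, mk(perturbationSpec(inhibit = "MEK",
                                                 activity = 0)))
  expect_identical(lapply(plain, activityMatrix),
                   lapply(null, activityMatrix))

  # removing the inhibition restores identical output too
  withI <- simulateNetwork(g, mk(perturbationSpec(inhibit = "MEK")))
  again <- simulateNetwork(g, mk(perturbationSpec()))
  expect_identical(lapply(plain, activityMatrix),
                   lapply(again, activityMatrix))
  expect_false(identical(activityMatrix(plain[[1]]),
                         activityMatrix(withI[[1]])))
})

test_that("inhibition never raises the target's mean activity (paired seeds)", {
  for (seed in 1:6) {
    g <- randomSignedNetwork(n_nodes = 12, n_ligands = 2, seed = seed)
    target <- setdiff(nodes(reachableSubnetwork(g, c("L1", "L2"))),
                      c("L1", "L2"))[1]
    if (is.na(target)) next
    mk <- function(p) simulationConfig(c(L1 = 1, L2 = 0.5),
                                       iterations = 60, seed = seed,
                                       halfLifeMode = "short",
                                       perturbations = p)
    trN <- simulateNetwork(g, mk(perturbationSpec()))[[1]]
    trI <- simulateNetwork(g,
             mk(perturbationSpec(inhibit = target)))[[1]]
    expect_lte(mean(activityMatrix(trI)[target, -1]),
               mean(activityMatrix(trN)[target, -1]))
  }
})

test_that("fixed assignments clamp a node from t = 1 on", {
  g <- cascade(4, names = c("EGF", "Ras", "MEK", "ERK"))
  cfg <- simulationConfig(c(EGF = 0.5), iterations = 30, seed = 2,
                          perturbations = perturbationSpec(fix = c(Ras = 1)))
  X <- activityMatrix(simulateNetwork(g, cfg)[[1]])
  expect_equal(unname(X["Ras", -1]), rep(1, 30))
  expect_equal(X["Ras", "t0"], 0)

  off <- simulationConfig(c(EGF = 1), iterations = 30, seed = 2,
                          perturbations = perturbationSpec(fix = c(MEK = 0)))
  Xoff <- activityMatrix(simulateNetwork(g, off)[[1]])
  expect_true(all(Xoff["MEK", -1] == 0))

  # clamping a mid-chain node decouples downstream from the stimulus
  run <- function(a) {
    cfg <- simulationConfig(c(EGF = a), iterations = 40, seed = 7,
                            perturbations = perturbationSpec(
                              fix = c(MEK = 0.6)))
    activityMatrix(simulateNetwork(g, cfg)[[1]])["ERK", ]
  }
  expect_identical(run(0.1), run(1.0))
})

test_that("masking replaces reported rows only", {
  g <- mekChain()
  spec <- perturbationSpec(inhibit = "MEK")
  cfg <- simulationConfig(c(A = 1), iterations = 40, seed = 1,
                          perturbations = spec)
  tr <- simulateNetwork(g, cfg)[[1]]
  masked <- maskInhibitedReadouts(tr, spec)
  expect_true(all(activityMatrix(masked)["MEK", ] == 0))
  expect_equal(activityMatrix(masked)["ERK", ],
               activityMatrix(tr)["ERK", ])
  expect_equal(masked@masked, "MEK")

  spec5 <- perturbationSpec(inhibit = "MEK", report = 0.5)
  expect_true(all(activityMatrix(
    maskInhibitedReadouts(tr, spec5))["MEK", ] == 0.5))
})
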