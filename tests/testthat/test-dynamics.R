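test_that("BFS layers are shortest directed distances from the sources", {
  expect_equal(bfsLayers(cascade(3), "v1"), c(v1 = 0L, v2 = 1L, v3 = 2L))

  diamond <- readNetwork(c("A B +1", "A C +1", "B D +1", "C D +1"))
  lay <- bfsLayers(diamond, "A")
  expect_equal(lay[["D"]], 2L)

  two <- readNetwork(c("A B +1", "E F +1"))
  lay <- bfsLayers(two, c("A", "E"))
  expect_equal(lay[order(names(lay))], c(A = 0L, B = 1L, E = 0L, F = 1L))

  expect_error(bfsLayers(diamond, "Z"), "unknown source")
  # unreachable nodes don't appear
  vee <- readNetwork(c("A B +1", "C B +1"))
  expect_named(bfsLayers(vee, "A"), c("A", "B"))
})

test_that("the source ramp is linear and capped by the divisor", {
  expect_equal(sourceActivity(37, 100, 0), 0)
  expect_equal(sourceActivity(100, 100, 1, 10), 0.1)
  expect_equal(sourceActivity(50, 100, 1, 10), 0.05)
  expect_equal(sourceActivity(0, 100, 1), 0)
  # never exceeds a_user/divisor, monotone in t
  v <- sapply(0:100, sourceActivity, T = 100, a_user = 0.8, divisor = 10)
  expect_true(all(diff(v) > 0))
  expect_lte(max(v), 0.08)
  expect_error(sourceActivity(1, 10, 0.5, divisor = 0), "divisor")
})

test_that("the node update rule matches its closed form", {
  one <- function(value, sign, weight) data.frame(value = value,
                                                  sign = sign,
                                                  weight = weight)
  expect_equal(nodeUpdate(0, one(1, 1L, 1), R = 0), 1)
  # no activators: pure decay to R * x_prev
  expect_equal(nodeUpdate(0.8, one(0.9, -1L, 1), R = 0.5), 0.4)
  expect_equal(nodeUpdate(0, one(0.5, 1L, 0.5), R = 0), 0.25)

  # mixed regulators, manual arithmetic:
  # act = 1-(1-0.6*0.5)(1-0.8*1) = 1-0.7*0.2 = 0.86
  # rep = 1-0.3*0.5 = 0.85; retained = 0.4*0.5 = 0.2
  # x = 0.2 + 0.8*0.86*0.85 = 0.7848
  regs <- data.frame(value = c(0.6, 0.8, 0.3), sign = c(1L, 1L, -1L),
                     weight = c(0.5, 1, 0.5))
  expect_equal(nodeUpdate(0.5, regs, R = 0.4), 0.7848)

  # order independence and clamping
  expect_equal(nodeUpdate(0.5, regs[c(3, 1, 2), ], R = 0.4), 0.7848)
  expect_equal(nodeUpdate(0.9, one(1, 1L, 1), R = 1, xi = 0.5), 1)
  expect_equal(nodeUpdate(0, one(0, 1L, 1), R = 0, xi = -0.5), 0)
})

test_that("semi-synchronous sweeps propagate one full chain per step", {
  ch <- cascade(3)
  # deterministic: no noise, zero retained fraction, chain weights 1/2
  mk <- function(schedule) simulationConfig(c(v1 = 1), iterations = 10,
                                            seed = 1, noise = 0,
                                            fixedStability = 0,
                                            schedule = schedule)
  semi <- simulateNetwork(ch, mk("semi"))[["short"]]
  sync <- simulateNetwork(ch, mk("synchronous"))[["short"]]
  Xsemi <- activityMatrix(semi)
  Xsync <- activityMatrix(sync)

  # semi: v3 reflects v1's fresh value in the same sweep
  expect_equal(Xsemi["v3", "t1"], 0.25 * Xsemi["v1", "t1"])
  # synchronous: v3 needs 2 extra steps for the same signal depth
  expect_equal(Xsync["v3", "t1"], 0)
  expect_equal(Xsync["v3", "t2"], 0)
  expect_equal(Xsync["v3", "t3"], 0.25 * Xsync["v1", "t1"])
  # the two schedules differ exactly by layer-depth shifts
  expect_equal(unname(Xsync["v2", paste0("t", 2:10)]),
               unname(Xsemi["v2", paste0("t", 1:9)]))
  expect_equal(unname(Xsync["v3", paste0("t", 3:10)]),
               unname(Xsemi["v3", paste0("t", 1:8)]))
})

test_that("same-layer feedback uses the in-order fresh value, reproducibly", {
  g <- readNetwork(c("A B +1", "A C +1", "B C +1", "C B +1"))
  cfg <- simulationConfig(c(A = 1), iterations = 30, seed = 5)
  t1 <- simulateNetwork(g, cfg)
  t2 <- simulateNetwork(g, cfg)
  expect_identical(lapply(t1, activityMatrix), lapply(t2, activityMatrix))

  t3 <- simulateNetwork(g, simulationConfig(c(A = 1), iterations = 30,
                                            seed = 6))
  expect_false(identical(activityMatrix(t1[[1]]), activityMatrix(t3[[1]])))
})

test_that("a silent network stays at the all-zero fixed point", {
  g <- randomSignedNetwork(n_nodes = 15, n_ligands = 2, seed = 3)
  cfg <- simulationConfig(c(L1 = 0, L2 = 0), iterations = 40, seed = 9,
                          noise = 0)
  for (tr in simulateNetwork(g, cfg))
    expect_true(all(activityMatrix(tr) == 0))
})

test_that("activity decays when all activators are silent", {
  # B starts active but its only activator A is pinned at 0
  ch <- cascade(2, names = c("A", "B"))
  cfg <- simulationConfig(c(A = 0), iterations = 1, seed = 4, noise = 0)
  w <- weightAllEdges(ch)
  state <- c(A = 0, B = 0.9)
  for (t in 1:6) {
    nxt <- sweepStep(ch, w, state, t = 1, config = cfg)
    expect_lte(nxt[["B"]], state[["B"]])
    state <- nxt
  }
  expect_lt(state[["B"]], 0.9)
})

test_that("trajectories start at zero, stay in [0,1], and honour the seed", {
  set.seed(24)
  for (seed in 1:12) {
    g <- randomSignedNetwork(n_nodes = sample(8:16, 1),
                             n_ligands = sample(1:3, 1),
                             edge_density = runif(1, 0.05, 0.3),
                             inhibitor_fraction = runif(1, 0, 0.5),
                             seed = seed)
    srcs <- grep("^L", nodes(g), value = TRUE)
    act <- setNames(runif(length(srcs)), srcs)
    cfg <- simulationConfig(act, iterations = 15, seed = seed,
                            noise = runif(1, 0, 0.05))
    trajs <- simulateNetwork(g, cfg)
    for (tr in trajs) {
      X <- activityMatrix(tr)
      expect_true(all(X >= 0 & X <= 1))
      expect_true(all(X[setdiff(rownames(X), names(act)), "t0"] == 0))
    }
    again <- simulateNetwork(g, cfg)
    expect_identical(lapply(trajs, activityMatrix),
                     lapply(again, activityMatrix))
  }
})

test_that("half-life variants exist only when ambiguity exists", {
  # every node of a cycle has in- and out-degree 1 and degree < 6
  cyc <- readNetwork(c("A B +1", "B C +1", "C A +1"))
  tr <- simulateNetwork(cyc, simulationConfig(c(A = 0.5), iterations = 10,
                                              seed = 1))
  expect_named(tr, "default")

  tr2 <- simulateNetwork(cascade(3), simulationConfig(c(v1 = 0.5),
                                                      iterations = 10,
                                                      seed = 1))
  expect_named(tr2, c("short", "long"))

  tr3 <- simulateNetwork(cascade(3),
                         simulationConfig(c(v1 = 0.5), iterations = 10,
                                          seed = 1, halfLifeMode = "short"))
  expect_named(tr3, "short")

  # short and long variants differ only through the stability draws:
  # long half-life retains more activity on average
  cfgB <- simulationConfig(c(v1 = 1), iterations = 60, seed = 2)
  both <- simulateNetwork(cascade(4), cfgB)
  expect_gt(mean(activityMatrix(both$long)["v4", ]),
            mean(activityMatrix(both$short)["v4", ]))
})

test_that("config validation reports every failure at once", {
  err <- tryCatch(simulationConfig(setNames(rep(0.5, 11), letters[1:11]),
                                   iterations = 0, noise = -1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "10 source")
  expect_match(err, "iterations")
  expect_match(err, "noise")

  expect_error(simulationConfig(c(A = 1.2)), "\\[0, 1\\]")
  expect_error(
    simulateNetwork(cascade(3), simulationConfig(c(nosuch = 1))),
    "source node")
})

test_that("raising the stimulus raises mean downstream activity", {
  g <- cascade(4)
  doses <- c(0.2, 0.6, 1.0)
  means <- sapply(doses, function(a) {
    runs <- sapply(1:10, function(s) {
      tr <- simulateNetwork(g, simulationConfig(c(v1 = a),
                                                iterations = 50, seed = s,
                                                halfLifeMode = "long"))
      summarizeActivity(tr[[1]])
    })
    rowMeans(runs)
  })
  for (nd in rownames(means))
    expect_true(all(diff(means[nd, ]) >= 0))
})
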