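# Semi-synchronized stochastic propagation of activity levels.
#
# The state X_j(t) of node j is the proportion of its molecules in
# active form, in [0,1]. Per time step, in ascending BFS-layer order
# (ties broken lexicographically):
#
#   act = 1 - prod over activators i (1 - w_ij * x_i)
#   rep =     prod over repressors i (1 - w_ij * x_i)
#   X_j(t) = clamp01( R * X_j(t-1)
#                     + (1 - R * X_j(t-1)) * act * rep + xi )
#
# where a regulator contributes its step-t value if it was already
# updated in the current sweep (its own or an upstream layer), else
# its step t-1 value; R is the relative stability of the active form,
# drawn fresh per node per step (default U(0,1); short half-life
# U(0,0.5); long U(0.5,1)); xi is uniform noise on [-eps, +eps].
# Source nodes are driven by a capped linear ramp
# a_user * t / (divisor * T); the default divisor 10 reflects that
# roughly a tenth of a receptor pool is in high-affinity form.

#' BFS layer assignment
#'
#' Layer of a node = length of the shortest directed path from any
#' source (sources are layer 0). Only reachable nodes appear.
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param sources character vector of source node ids.
#' @return Named integer vector of layers, in \code{nodes(g)} order
#'   restricted to reachable nodes.
#' @examples
#' bfsLayers(cascade(3), "v1")
#' @export
bfsLayers <- function(g, sources) {
  stopifnot(is(g, "SignedDigraph"))
  sources <- as.character(sources)
  unknown <- setdiff(sources, nodes(g))
  if (length(unknown))
    stop("unknown source node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ig <- asIgraph(g)
  d <- igraph::distances(ig, v = sources, to = igraph::V(ig),
                         mode = "out")
  lay <- apply(d, 2L, min)
  lay <- lay[is.finite(lay)]
  out <- as.integer(lay)
  names(out) <- names(lay)
  out[order(match(names(out), nodes(g)))]
}

#' Source driving ramp
#'
#' Activity of a source (ligand/receptor) node at step t: a monotone
#' linear ramp \code{a_user * t / (divisor * T)} that reaches
#' \code{a_user / divisor} at \code{t = T}. The divisor (default 10)
#' caps the proportion of receptors in active, ligand-bound form.
#'
#' @param t current step, \code{1 <= t <= T} (0 gives the initial 0).
#' @param T total number of iterations.
#' @param a_user user-specified source activity in \code{[0, 1]}.
#' @param divisor receptor-cap divisor, > 0.
#' @return Activity in \code{[0, a_user / divisor]}.
#' @examples
#' sourceActivity(100, 100, 1)  # 0.1
#' @export
sourceActivity <- function(t, T, a_user, divisor = 10) {
  if (divisor <= 0) stop("divisor must be > 0", call. = FALSE)
  stopifnot(t >= 0, t <= T, a_user >= 0, a_user <= 1)
  (a_user / divisor) * (t / T)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Single-node update rule
#'
#' @param x_prev the node's activity at the previous step.
#' @param regulators \code{data.frame} (possibly empty) with columns
#'   \code{value}, \code{sign} (+1/-1), \code{weight}, one row per
#'   regulator feeding into the node. The result is independent of row
#'   order.
#' @param R relative stability of the active form, in \code{[0, 1]}.
#' @param xi additive noise term.
#' @return Updated activity, clamped to \code{[0, 1]}. With no
#'   activators the node purely decays to \code{R * x_prev}.
#' @examples
#' nodeUpdate(0, data.frame(value = 0.5, sign = 1, weight = 0.5), R = 0)
#' @export
nodeUpdate <- function(x_prev, regulators, R, xi = 0) {
  a <- regulators$sign == 1L
  act <- if (any(a)) 1 - prod(1 - regulators$weight[a] * regulators$value[a])
         else 0
  rep <- if (any(!a)) prod(1 - regulators$weight[!a] * regulators$value[!a])
         else 1
  retained <- R * x_prev
  clamp01(retained + (1 - retained) * act * rep + xi)
}

# Precompute everything a sweep needs. g must already be restricted to
# the reachable subnetwork; anti-nodes (complementary inhibitors) are
# passed separately as clamped constants.
.buildContext <- function(g, weights, config, antiValues = numeric(),
                          antiEdges = NULL) {
  real <- nodes(g)
  srcs <- names(config@sources)
  lay <- bfsLayers(g, intersect(srcs, real))
  e <- edges(weights)[, c("from", "to", "sign", "weight")]
  if (!is.null(antiEdges)) e <- rbind(e, antiEdges)

  drawOrder <- real[order(real, method = "radix")]
  updOrder <- real[order(lay[real], real, method = "radix")]

  regs <- split(e[, c("from", "sign", "weight")], factor(e$to, levels = real))

  cls <- classifyHalfLife(g, config@halfLifeOverrides)
  classOf <- setNames(cls$class, cls$node)

  list(real = real, sources = config@sources[intersect(srcs, real)],
       layers = lay, drawOrder = drawOrder, updOrder = updOrder,
       regulators = regs, classOf = classOf,
       antiValues = antiValues,
       fixed = config@perturbations@fixed[
         names(config@perturbations@fixed) %in% real],
       T = config@iterations, eps = config@noise,
       divisor = config@divisor, schedule = config@schedule,
       fixedStability = config@fixedStability)
}

# stability range per node under a half-life variant
.stabilityRange <- function(classOf, variant) {
  lo <- setNames(rep(0, length(classOf)), names(classOf))
  hi <- setNames(rep(1, length(classOf)), names(classOf))
  short <- classOf == "short" | (classOf == "ambiguous" & variant == "short")
  long <- classOf == "long" | (classOf == "ambiguous" & variant == "long")
  hi[short] <- 0.5
  lo[long] <- 0.5
  list(lo = lo, hi = hi)
}

# One sweep: prev is the named state vector over real + anti nodes at
# t-1; uR, uXi are uniform(0,1) / uniform(-eps,eps) draws named by real
# node (in draw order). Returns the state at t.
.runSweep <- function(ctx, prev, t, uR, uXi, range) {
  cur <- prev
  cur[names(ctx$antiValues)] <- ctx$antiValues
  # fixed assignments are clamped constants for the whole sweep, so
  # same-sweep readers see the clamp, never a transient formula value
  if (length(ctx$fixed)) cur[names(ctx$fixed)] <- ctx$fixed
  updated <- setNames(rep(FALSE, length(prev)), names(prev))
  updated[names(ctx$antiValues)] <- TRUE   # constants count as fresh
  updated[names(ctx$fixed)] <- TRUE

  R <- if (!is.na(ctx$fixedStability))
    setNames(rep(ctx$fixedStability, length(uR)), names(uR))
  else range$lo[names(uR)] + (range$hi[names(uR)] - range$lo[names(uR)]) * uR

  for (j in ctx$updOrder) {
    if (updated[[j]]) next                 # clamped this sweep
    if (j %in% names(ctx$sources)) {
      cur[j] <- sourceActivity(t, ctx$T, ctx$sources[[j]], ctx$divisor)
    } else {
      rg <- ctx$regulators[[j]]
      vals <- if (ctx$schedule == "semi")
        ifelse(updated[rg$from], cur[rg$from], prev[rg$from])
      else prev[rg$from]
      # list, not data.frame: nodeUpdate only needs $ access and this
      # sits in the innermost loop
      cur[j] <- nodeUpdate(prev[[j]],
                           list(value = as.numeric(vals),
                                sign = rg$sign, weight = rg$weight),
                           R[[j]], uXi[[j]])
    }
    updated[j] <- TRUE
  }
  cur
}

#' One semi-synchronous sweep (diagnostic surface)
#'
#' Advances a state vector by one time step under the package's update
#' schedule. [simulateNetwork()] is the normal entry point; this
#' exposes a single sweep for schedule tracing and testing.
#'
#' @param g a \linkS4class{SignedDigraph}, already restricted to the
#'   subnetwork reachable from the configured sources.
#' @param weights an \linkS4class{EdgeWeightMap} for \code{g}.
#' @param statePrev named numeric state vector at step \code{t - 1}
#'   covering \code{nodes(g)}.
#' @param t the step being computed (\code{1..T}).
#' @param config a \linkS4class{SimulationConfig}.
#' @param variant half-life variant for stability ranges
#'   (\code{"default"}, \code{"short"}, \code{"long"}).
#' @param uR,uXi optional named draws (uniform(0,1) stability quantile
#'   and additive noise per node); drawn from the current RNG stream
#'   when missing.
#' @return Named numeric state vector at step \code{t}.
#' @export
sweepStep <- function(g, weights, statePrev, t, config,
                      variant = "default", uR = NULL, uXi = NULL) {
  stopifnot(is(g, "SignedDigraph"), is(weights, "EdgeWeightMap"),
            is(config, "SimulationConfig"))
  ctx <- .buildContext(g, weights, config)
  if (is.null(uR))
    uR <- setNames(runif(length(ctx$drawOrder)), ctx$drawOrder)
  if (is.null(uXi))
    uXi <- setNames(runif(length(ctx$drawOrder), -ctx$eps, ctx$eps),
                    ctx$drawOrder)
  range <- .stabilityRange(ctx$classOf, variant)
  .runSweep(ctx, statePrev, t, uR, uXi, range)[nodes(g)]
}

#' Simulate signal propagation through a weighted network
#'
#' Restricts the network to the subnetwork reachable from the source
#' nodes (unreachable nodes are ignored), initializes every non-source
#' activity to 0, and runs \code{T} semi-synchronous sweeps. When
#' \code{halfLifeMode = "both"} and half-life-ambiguous nodes exist,
#' two trajectories are returned (short and long variant, sharing the
#' same random draws); otherwise one.
#'
#' Perturbations in the config are honoured: each inhibition adds a
#' complementary \code{anti_<target>} node clamped at its constant
#' activity with a single inhibitory edge onto the target (the target
#' keeps transmitting signal); fixed assignments clamp their node at
#' the assigned constant for every step t >= 1, dominating dynamics,
#' noise and the source ramp, and same-sweep readers always see the
#' clamped value. Complementary nodes are internal and do not appear
#' in the returned trajectory.
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param config a \linkS4class{SimulationConfig}; all validation
#'   failures are reported together.
#' @param weights an \linkS4class{EdgeWeightMap} for \code{g};
#'   computed by [weightAllEdges()] when missing.
#' @return A list of \linkS4class{StateTrajectory} objects, named by
#'   half-life variant (\code{"default"}, or \code{"short"} and
#'   \code{"long"}). Bit-reproducible given the config seed.
#' @examples
#' g <- cascade(3)
#' tr <- simulateNetwork(g, simulationConfig(c(v1 = 1), iterations = 20,
#'                                           seed = 7))
#' activityMatrix(tr[[1]])[, 1:5]
#' @export
simulateNetwork <- function(g, config, weights = weightAllEdges(g)) {
  stopifnot(is(g, "SignedDigraph"), is(config, "SimulationConfig"),
            is(weights, "EdgeWeightMap"))
  validObject(config)
  srcs <- names(config@sources)
  unknown <- setdiff(srcs, nodes(g))
  if (length(unknown))
    stop("source node(s) not in network: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  reach <- reachableSubnetwork(g, srcs)
  wsub <- new("EdgeWeightMap",
              table = edges(weights)[
                paste(edges(weights)$from, edges(weights)$to, sep = "\r") %in%
                paste(edges(reach)$from, edges(reach)$to, sep = "\r"), ,
                drop = FALSE])

  pert <- config@perturbations
  inh <- pert@inhibitions
  badInh <- setdiff(inh$target, nodes(g))
  if (length(badInh))
    stop("inhibition target(s) not in network: ",
         paste(badInh, collapse = ", "), call. = FALSE)
  droppedInh <- setdiff(inh$target, nodes(reach))
  if (length(droppedInh)) {
    message("inhibition target(s) not reachable from sources, ignored: ",
            paste(droppedInh, collapse = ", "))
    pert <- new("PerturbationSpec",
                inhibitions = inh[!inh$target %in% droppedInh, ,
                                  drop = FALSE],
                fixed = pert@fixed)
  }
  aug <- applyInhibition(reach, wsub, pert)
  badFix <- setdiff(names(pert@fixed), nodes(g))
  if (length(badFix))
    stop("fixed assignment for unknown node(s): ",
         paste(badFix, collapse = ", "), call. = FALSE)
  droppedFix <- setdiff(names(pert@fixed), nodes(reach))
  if (length(droppedFix))
    message("fixed node(s) not reachable from sources, ignored: ",
            paste(droppedFix, collapse = ", "))

  ctx <- .buildContext(reach, wsub, config,
                       antiValues = aug$clamp, antiEdges = aug$antiEdges)
  cls <- ctx$classOf
  variants <- if (config@halfLifeMode == "both") {
    if (any(cls == "ambiguous")) c("short", "long") else "default"
  } else config@halfLifeMode

  T <- config@iterations
  real <- ctx$real
  lapply(setNames(variants, variants), function(variant) {
    set.seed(config@seed)        # variants share common random numbers
    range <- .stabilityRange(cls, variant)
    X <- matrix(0, nrow = length(real), ncol = T + 1L,
                dimnames = list(real, paste0("t", 0:T)))
    state <- setNames(rep(0, length(real) + length(aug$clamp)),
                      c(real, names(aug$clamp)))
    for (t in seq_len(T)) {
      uR <- setNames(runif(length(ctx$drawOrder)), ctx$drawOrder)
      uXi <- setNames(runif(length(ctx$drawOrder), -ctx$eps, ctx$eps),
                      ctx$drawOrder)
      state <- .runSweep(ctx, state, t, uR, uXi, range)
      X[, t + 1L] <- state[real]
    }
    new("StateTrajectory", activity = X, variant = variant,
        sources = names(ctx$sources), masked = character(),
        config = list(iterations = T, seed = config@seed,
                      noise = config@noise, divisor = config@divisor,
                      halfLifeMode = config@halfLifeMode,
                      schedule = config@schedule,
                      sources = as.list(config@sources),
                      inhibit = pert@inhibitions$target,
                      fix = as.list(pert@fixed)))
  })
}

#' Summarize a trajectory into one activity value per node
#'
#' The per-node activity reported for a whole run: by default the mean
#' of X over iterations \code{1..T} (the reduction paired with the
#' per-iteration Wilcoxon comparison); alternatively the mean of the
#' last \code{k} iterations.
#'
#' @param traj a \linkS4class{StateTrajectory}.
#' @param summary \code{"mean"} (default) or \code{"last-k"}.
#' @param k window size for \code{"last-k"} (default 10).
#' @return Named numeric vector, one value in \code{[0, 1]} per node.
#' @export
summarizeActivity <- function(traj, summary = c("mean", "last-k"),
                              k = 10L) {
  stopifnot(is(traj, "StateTrajectory"))
  summary <- match.arg(summary)
  X <- traj@activity[, -1L, drop = FALSE]          # drop t0
  if (summary == "last-k")
    X <- X[, max(1L, ncol(X) - k + 1L):ncol(X), drop = FALSE]
  rowMeans(X)
}

#' Write trajectories and their config echo
#'
#' One \code{trajectories[_<variant>].csv} per half-life variant
#' (first column \code{node}, then \code{t0..tT}) plus a YAML config
#' echo alongside.
#'
#' @param trajs list of \linkS4class{StateTrajectory} objects as
#'   returned by [simulateNetwork()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeTrajectories <- function(trajs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(trajs, function(tr) {
    suffix <- if (tr@variant == "default") "" else paste0("_", tr@variant)
    p <- file.path(dir, paste0("trajectories", suffix, ".csv"))
    df <- data.frame(node = rownames(tr@activity), tr@activity,
                     check.names = FALSE)
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  yaml::write_yaml(trajs[[1]]@config, file.path(dir, "config.yaml"))
  invisible(c(paths, file.path(dir, "config.yaml")))
}
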