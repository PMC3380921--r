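# Central S4 classes. A signed digraph is stored as a plain edge table
# (from, to, sign) plus the declared node set; igraph objects are built
# on demand for traversal, never stored.

#' Signed directed signaling network
#'
#' Nodes are signaling components (ligands, receptors, kinases, second
#' messengers, transcription factors); a directed edge carries the
#' direction of information flow and a sign: \code{+1} activation,
#' \code{-1} inhibition.
#'
#' @slot nodes character vector of unique node identifiers.
#' @slot edges \code{data.frame} with character columns \code{from},
#'   \code{to} and integer column \code{sign} (\code{+1}/\code{-1});
#'   at most one edge per ordered pair.
#' @slot labels optional named character vector of free-text node
#'   annotations (e.g. cellular compartment).
#'
#' @seealso [signedDigraph()], [readNetwork()], [nsiMotif()]
#' @export
setClass("SignedDigraph",
  representation(nodes = "character", edges = "data.frame",
                 labels = "character"),
  prototype(nodes = character(),
            edges = data.frame(from = character(), to = character(),
                               sign = integer(),
                               stringsAsFactors = FALSE),
            labels = character()))

setValidity("SignedDigraph", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "sign") %in% names(e)))
    return("edges must have columns from, to, sign")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  if (nrow(e)) {
    if (!all(e$sign %in% c(-1L, 1L)))
      msg <- c(msg, "edge signs must be +1 or -1")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msg <- c(msg, "more than one edge for an ordered (from, to) pair")
    bad <- setdiff(unique(c(e$from, e$to)), object@nodes)
    if (length(bad))
      msg <- c(msg, paste0("edge endpoint(s) not declared as nodes: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(object@labels) &&
      !all(names(object@labels) %in% object@nodes))
    msg <- c(msg, "labels refer to unknown nodes")
  if (length(msg)) msg else TRUE
})

#' Construct a SignedDigraph
#'
#' @param edges \code{data.frame} (or coercible) with columns
#'   \code{from}, \code{to}, \code{sign}; signs may be given as
#'   \code{+1}/\code{-1} numbers or the strings \code{"activate"} /
#'   \code{"inhibit"}.
#' @param nodes optional character vector of node ids; defaults to the
#'   ids appearing in \code{edges}. Extra isolated nodes are allowed.
#' @param labels optional named character vector of node annotations.
#' @return A \linkS4class{SignedDigraph}.
#' @examples
#' g <- signedDigraph(data.frame(from = "A", to = "B", sign = 1))
#' numNodes(g)
#' @export
signedDigraph <- function(edges, nodes = NULL, labels = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges$from <- trimws(as.character(edges$from))
    edges$to <- trimws(as.character(edges$to))
    edges$sign <- parseSign(edges$sign)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  }
  nodes <- unique(c(trimws(as.character(nodes %||% character())),
                    edges$from, edges$to))
  rownames(edges) <- NULL
  new("SignedDigraph", nodes = nodes, edges = edges,
      labels = as.character(labels) |> setNames(names(labels)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accepted sign spellings: 1, +1, -1, activate(s), inhibit(s)
parseSign <- function(x) {
  if (is.numeric(x)) {
    s <- as.integer(x)
  } else {
    tok <- tolower(trimws(as.character(x)))
    s <- ifelse(tok %in% c("1", "+1", "activate", "activates"), 1L,
         ifelse(tok %in% c("-1", "−1", "inhibit", "inhibits"), -1L,
                NA_integer_))
  }
  if (anyNA(s) || !all(s %in% c(-1L, 1L)))
    stop("unparsable edge sign(s): ",
         paste(unique(x[is.na(s) | !(s %in% c(-1L, 1L))]), collapse = ", "),
         call. = FALSE)
  s
}

#' @rdname nodes
#' @export
setMethod("nodes", "SignedDigraph", function(x) x@nodes)

#' @rdname edges
#' @export
setMethod("edges", "SignedDigraph", function(x) x@edges)

#' @rdname numNodes
#' @export
setMethod("numNodes", "SignedDigraph", function(x) length(x@nodes))

#' @rdname numNodes
#' @export
setMethod("numEdges", "SignedDigraph", function(x) nrow(x@edges))

setMethod("show", "SignedDigraph", function(object) {
  e <- object@edges
  cat("SignedDigraph with", length(object@nodes), "nodes and",
      nrow(e), "edges (", sum(e$sign == 1L), "activating,",
      sum(e$sign == -1L), "inhibiting )\n")
  if (length(object@nodes))
    cat("  nodes:", paste(utils::head(object@nodes, 8), collapse = ", "),
        if (length(object@nodes) > 8) "..." else "", "\n")
})

#' Per-edge NSI weight map
#'
#' Associates every directed edge of a network with its Normalized
#' Similarity Index weight, the efficiency of signal transmission along
#' the edge, a value in \code{(0, 1]}.
#'
#' @slot table \code{data.frame} with columns \code{from}, \code{to},
#'   \code{sign}, \code{weight}.
#' @seealso [weightAllEdges()]
#' @export
setClass("EdgeWeightMap", representation(table = "data.frame"))

setValidity("EdgeWeightMap", function(object) {
  t <- object@table
  msg <- character()
  if (!all(c("from", "to", "sign", "weight") %in% names(t)))
    return("table must have columns from, to, sign, weight")
  if (nrow(t) && (any(t$weight <= 0) || any(t$weight > 1)))
    msg <- c(msg, "weights must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname edges
#' @export
setMethod("edges", "EdgeWeightMap", function(x) x@table)

#' Look up the weight of one directed edge
#'
#' @param w an \linkS4class{EdgeWeightMap}.
#' @param from,to node identifiers of an edge present in the map.
#' @return Numeric weight in \code{(0, 1]}.
#' @export
weightOf <- function(w, from, to) {
  stopifnot(is(w, "EdgeWeightMap"))
  i <- which(w@table$from == from & w@table$to == to)
  if (!length(i))
    stop("no edge ", from, " -> ", to, " in weight map", call. = FALSE)
  w@table$weight[i]
}

setMethod("show", "EdgeWeightMap", function(object) {
  cat("EdgeWeightMap over", nrow(object@table), "edges; weight range [",
      if (nrow(object@table))
        paste(signif(range(object@table$weight), 4), collapse = ", ")
      else "", "]\n")
})

#' Perturbation specification
#'
#' Declares in silico experiments: chemical/siRNA-style inhibitions
#' realized as complementary nodes sending a constant inhibitory signal
#' to their target, and gain-of-function clamps fixing a node's
#' activity to a constant.
#'
#' @slot inhibitions \code{data.frame} with columns \code{target}
#'   (node id), \code{activity} (constant activity of the complementary
#'   node, in \code{[0,1]}), \code{weight} (complementary edge weight in
#'   \code{(0,1]}) and \code{report} (value shown for the inhibited
#'   readout in masked output).
#' @slot fixed named numeric vector of fixed activity assignments.
#' @seealso [perturbationSpec()], [applyInhibition()]
#' @export
setClass("PerturbationSpec",
  representation(inhibitions = "data.frame", fixed = "numeric"),
  prototype(inhibitions = data.frame(target = character(),
                                     activity = numeric(),
                                     weight = numeric(),
                                     report = numeric(),
                                     stringsAsFactors = FALSE),
            fixed = numeric()))

setValidity("PerturbationSpec", function(object) {
  msg <- character()
  i <- object@inhibitions
  if (!all(c("target", "activity", "weight", "report") %in% names(i)))
    return("inhibitions needs columns target, activity, weight, report")
  if (nrow(i)) {
    if (any(i$activity < 0 | i$activity > 1))
      msg <- c(msg, "complementary activities must lie in [0, 1]")
    if (any(i$weight <= 0 | i$weight > 1))
      msg <- c(msg, "complementary edge weights must lie in (0, 1]")
    if (any(i$report < 0 | i$report > 1))
      msg <- c(msg, "report values must lie in [0, 1]")
    if (anyDuplicated(i$target))
      msg <- c(msg, "a node may be inhibited only once")
  }
  if (length(object@fixed)) {
    if (is.null(names(object@fixed)) || any(!nzchar(names(object@fixed))))
      msg <- c(msg, "fixed assignments must be a named vector")
    if (any(object@fixed < 0 | object@fixed > 1))
      msg <- c(msg, "fixed activities must lie in [0, 1]")
  }
  both <- intersect(i$target, names(object@fixed))
  if (length(both))
    msg <- c(msg, paste0("node(s) both inhibited and fixed: ",
                         paste(both, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PerturbationSpec
#'
#' @param inhibit character vector of target node ids, or a
#'   \code{data.frame} with columns \code{target} and optionally
#'   \code{activity}, \code{weight}, \code{report}.
#' @param activity,weight,report defaults applied to every inhibition
#'   given as a bare character vector: complementary-node activity 1
#'   (saturating inhibitor), complementary edge weight 1, reported
#'   value 0 for masked readouts.
#' @param fix named numeric vector of fixed (gain-of-function style)
#'   activity assignments.
#' @return A \linkS4class{PerturbationSpec}.
#' @examples
#' perturbationSpec(inhibit = "MEK", fix = c(Ras = 1))
#' @export
perturbationSpec <- function(inhibit = character(), activity = 1,
                             weight = 1, report = 0, fix = numeric()) {
  if (is.data.frame(inhibit)) {
    inh <- inhibit
    if (is.null(inh$activity)) inh$activity <- activity
    if (is.null(inh$weight)) inh$weight <- weight
    if (is.null(inh$report)) inh$report <- report
  } else if (length(inhibit)) {
    inh <- data.frame(target = as.character(inhibit),
                      activity = activity, weight = weight,
                      report = report, stringsAsFactors = FALSE)
  } else {
    inh <- data.frame(target = character(), activity = numeric(),
                      weight = numeric(), report = numeric(),
                      stringsAsFactors = FALSE)
  }
  inh$target <- as.character(inh$target)
  rownames(inh) <- NULL
  new("PerturbationSpec", inhibitions = inh[, c("target", "activity",
                                                "weight", "report")],
      fixed = fix)
}

setMethod("show", "PerturbationSpec", function(object) {
  cat("PerturbationSpec:", nrow(object@inhibitions), "inhibition(s),",
      length(object@fixed), "fixed assignment(s)\n")
  if (nrow(object@inhibitions))
    cat("  inhibit:", paste(object@inhibitions$target, collapse = ", "), "\n")
  if (length(object@fixed))
    cat("  fix:", paste(names(object@fixed), "=", object@fixed,
                        collapse = ", "), "\n")
})

#' Simulation configuration
#'
#' Bundles every tunable of a propagation run: the ligand source nodes
#' and their user activities, the iteration count, the PRNG seed, the
#' noise amplitude, the receptor-cap divisor of the source ramp, the
#' perturbation spec, and the half-life handling for ambiguous nodes.
#'
#' @slot sources named numeric vector (1 to 10 entries), user activity
#'   per source node, each in \code{[0, 1]}.
#' @slot iterations positive integer T; the run produces states
#'   \code{t0..tT}.
#' @slot seed integer PRNG seed.
#' @slot noise noise amplitude \eqn{\epsilon \ge 0}; per-step noise is
#'   uniform on \eqn{[-\epsilon, +\epsilon]}.
#' @slot divisor receptor-cap divisor of the source ramp (> 0); the
#'   default 10 caps receptor activity at one tenth of the user value,
#'   matching the typical fraction of a receptor pool in high-affinity
#'   form.
#' @slot perturbations a \linkS4class{PerturbationSpec}.
#' @slot halfLifeMode \code{"short"}, \code{"long"} or \code{"both"}:
#'   which stability variant(s) to simulate for half-life-ambiguous
#'   nodes.
#' @slot halfLifeOverrides named character vector of per-node
#'   \code{"short"}/\code{"long"} overrides of the degree rule.
#' @slot inhibitedReportValue default reported value for inhibited
#'   readouts, in \code{[0, 1]}.
#' @slot fixedStability \code{NA} (stochastic stability, the model
#'   proper) or a constant in \code{[0, 1]} replacing every relative
#'   stability draw — a deterministic diagnostic mode.
#' @slot schedule \code{"semi"} (semi-synchronous, the model proper) or
#'   \code{"synchronous"} (all regulators read at t-1; comparison mode).
#' @seealso [simulationConfig()], [simulateNetwork()]
#' @export
setClass("SimulationConfig",
  representation(sources = "numeric", iterations = "integer",
                 seed = "integer", noise = "numeric", divisor = "numeric",
                 perturbations = "PerturbationSpec",
                 halfLifeMode = "character",
                 halfLifeOverrides = "character",
                 inhibitedReportValue = "numeric",
                 fixedStability = "numeric", schedule = "character"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  s <- object@sources
  if (length(s) < 1L || length(s) > 10L)
    msg <- c(msg, "between 1 and 10 source nodes are required (up to 10 inputs)")
  if (is.null(names(s)) || any(!nzchar(names(s))))
    msg <- c(msg, "sources must be a named numeric vector")
  if (length(s) && (any(s < 0) || any(s > 1)))
    msg <- c(msg, "source activities must lie in [0, 1]")
  if (object@iterations < 1L)
    msg <- c(msg, "iterations must be a positive integer")
  if (object@noise < 0)
    msg <- c(msg, "noise amplitude must be >= 0")
  if (object@divisor <= 0)
    msg <- c(msg, "receptor-cap divisor must be > 0")
  if (!object@halfLifeMode %in% c("short", "long", "both"))
    msg <- c(msg, "halfLifeMode must be one of short, long, both")
  if (length(object@halfLifeOverrides) &&
      !all(object@halfLifeOverrides %in% c("short", "long")))
    msg <- c(msg, "halfLifeOverrides values must be short or long")
  if (object@inhibitedReportValue < 0 || object@inhibitedReportValue > 1)
    msg <- c(msg, "inhibitedReportValue must lie in [0, 1]")
  if (!is.na(object@fixedStability) &&
      (object@fixedStability < 0 || object@fixedStability > 1))
    msg <- c(msg, "fixedStability must be NA or in [0, 1]")
  if (!object@schedule %in% c("semi", "synchronous"))
    msg <- c(msg, "schedule must be semi or synchronous")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param sources named numeric vector of ligand/receptor source nodes
#'   and their user activities in \code{[0, 1]}; 1 to 10 entries
#'   (single vs set run mode).
#' @param iterations number of update steps T (default 100).
#' @param seed PRNG seed (default 1).
#' @param noise noise amplitude (default 0.01).
#' @param divisor receptor-cap divisor of the source ramp (default 10).
#' @param perturbations a \linkS4class{PerturbationSpec}.
#' @param halfLifeMode \code{"both"} (default), \code{"short"} or
#'   \code{"long"}.
#' @param halfLifeOverrides named character vector
#'   (\code{"short"}/\code{"long"}).
#' @param inhibitedReportValue reported value for inhibited readouts
#'   (default 0).
#' @param fixedStability \code{NA} for stochastic stability (default)
#'   or a constant replacing every stability draw.
#' @param schedule \code{"semi"} (default) or \code{"synchronous"}.
#' @return A \linkS4class{SimulationConfig}. Invalid settings raise one
#'   error listing every violated constraint.
#' @examples
#' simulationConfig(c(EGF = 0.8), iterations = 100, seed = 42)
#' @export
simulationConfig <- function(sources, iterations = 100L, seed = 1L,
                             noise = 0.01, divisor = 10,
                             perturbations = perturbationSpec(),
                             halfLifeMode = c("both", "short", "long"),
                             halfLifeOverrides = character(),
                             inhibitedReportValue = 0,
                             fixedStability = NA_real_,
                             schedule = c("semi", "synchronous")) {
  new("SimulationConfig", sources = sources,
      iterations = as.integer(iterations), seed = as.integer(seed),
      noise = noise, divisor = divisor, perturbations = perturbations,
      halfLifeMode = match.arg(halfLifeMode),
      halfLifeOverrides = halfLifeOverrides,
      inhibitedReportValue = inhibitedReportValue,
      fixedStability = as.numeric(fixedStability),
      schedule = match.arg(schedule))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: T =", object@iterations,
      "| seed =", object@seed, "| noise =", object@noise,
      "| divisor =", object@divisor,
      "| half-life mode =", object@halfLifeMode,
      "| schedule =", object@schedule, "\n")
  cat("  sources:", paste(names(object@sources), "=", object@sources,
                          collapse = ", "), "\n")
})

#' Simulated state trajectory
#'
#' The primary simulator output: the activity level X (proportion of
#' molecules in active form) of every reachable node at every time step
#' t = 0..T, for one half-life variant.
#'
#' @slot activity numeric matrix, nodes in rows (rownames = node ids),
#'   columns \code{t0..tT}; all values in \code{[0, 1]}.
#' @slot variant \code{"default"}, \code{"short"} or \code{"long"}.
#' @slot sources character vector of source node ids.
#' @slot masked character vector of inhibited readouts whose rows were
#'   replaced by their report value (empty until
#'   [maskInhibitedReadouts()] is applied).
#' @slot config list echo of the generating configuration.
#' @export
setClass("StateTrajectory",
  representation(activity = "matrix", variant = "character",
                 sources = "character", masked = "character",
                 config = "list"))

setValidity("StateTrajectory", function(object) {
  msg <- character()
  a <- object@activity
  if (is.null(rownames(a))) msg <- c(msg, "activity matrix needs rownames")
  if (length(a) && (min(a) < 0 || max(a) > 1))
    msg <- c(msg, "activities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname activityMatrix
#' @export
setMethod("activityMatrix", "StateTrajectory", function(x) x@activity)

setMethod("show", "StateTrajectory", function(object) {
  cat("StateTrajectory (", object@variant, "half-life variant ):",
      nrow(object@activity), "nodes x", ncol(object@activity),
      "time points\n")
  cat("  sources:", paste(object@sources, collapse = ", "), "\n")
  if (length(object@masked))
    cat("  masked readouts:", paste(object@masked, collapse = ", "), "\n")
})

#' Validation report
#'
#' Pairing of simulated and experimental activity levels with the
#' Pearson agreement statistic.
#'
#' @slot pairs \code{data.frame} with columns \code{condition},
#'   \code{node}, \code{simulated}, \code{experimental}.
#' @slot r Pearson correlation coefficient.
#' @slot p two-sided p-value of the correlation (t transform, n-2 df).
#' @slot unmatched \code{data.frame} of (condition, node) keys present
#'   in only one of the two tables.
#' @seealso [correlateExperiment()]
#' @export
setClass("ValidationReport",
  representation(pairs = "data.frame", r = "numeric", p = "numeric",
                 unmatched = "data.frame"))

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", nrow(object@pairs), "matched (condition, node)",
      "pairs\n  Pearson r =", signif(object@r, 4),
      ", p =", format(object@p, digits = 3), "\n")
  if (nrow(object@unmatched))
    cat("  unmatched keys:", nrow(object@unmatched), "\n")
})
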