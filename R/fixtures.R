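# Synthetic signed networks and experiment tables, so every analysis
# step is testable without downloading curated pathway files. All
# generators are pure functions of their arguments (and seed): calling
# twice gives byte-identical fixtures.

#' The two-endpoint NSI demonstration motif
#'
#' Ten nodes: an edge i -> j whose endpoints share four common
#' neighbours (m1..m4) and have two private neighbours each (a, b for
#' i; c, d for j), eight distinct neighbours in total. Its NSI is
#' (4 + 1) / (8 + 1) = 5/9.
#'
#' @return A \linkS4class{SignedDigraph} (all edges activating).
#' @examples
#' edgeNSI(nsiMotif(), "i", "j") * 9  # 5
#' @export
nsiMotif <- function() {
  e <- data.frame(
    from = c("i", "i", "i", "i", "i", "i", "i", "j", "j", "j", "j",
             "j", "j"),
    to = c("j", "m1", "m2", "m3", "m4", "a", "b", "m1", "m2", "m3",
           "m4", "c", "d"),
    sign = 1L, stringsAsFactors = FALSE)
  signedDigraph(e, nodes = c("i", "j", paste0("m", 1:4), "a", "b",
                             "c", "d"))
}

#' Linear signaling cascade
#'
#' Chain \code{v1 -> v2 -> ... -> vn}; the k-th edge is inhibitory
#' when k is listed in \code{inhibitor_positions}, activating
#' otherwise.
#'
#' @param n chain length (>= 2).
#' @param inhibitor_positions integer vector of 1-based edge indices
#'   to sign \code{-1}.
#' @param names optional node names (length \code{n}); defaults to
#'   \code{v1..vn}.
#' @return A \linkS4class{SignedDigraph}.
#' @examples
#' cascade(3, inhibitor_positions = 2)
#' @export
cascade <- function(n, inhibitor_positions = integer(), names = NULL) {
  stopifnot(n >= 2)
  nm <- names %||% paste0("v", seq_len(n))
  stopifnot(length(nm) == n)
  sgn <- rep(1L, n - 1L)
  sgn[inhibitor_positions] <- -1L
  signedDigraph(data.frame(from = nm[-n], to = nm[-1L], sign = sgn,
                           stringsAsFactors = FALSE), nodes = nm)
}

#' Random signed signaling network
#'
#' Seeded generator emulating the shape of curated signaling networks:
#' a set of ligand nodes with in-degree 0 (signal entry points), a
#' sparse random body, every non-ligand node reachable from the ligand
#' set (chain edges are added where sampling left a node unreachable),
#' and a given fraction of inhibitory edges in expectation. Defaults
#' emulate a hepatocyte-scale inflammatory/growth network: 7 ligands,
#' 40 nodes, ~15% inhibitory edges.
#'
#' @param n_nodes total node count.
#' @param n_ligands number of in-degree-0 ligand nodes
#'   (< \code{n_nodes}).
#' @param edge_density probability of each admissible ordered pair
#'   being an edge, in (0, 1).
#' @param inhibitor_fraction expected fraction of \code{-1} edges, in
#'   \code{[0, 1]}.
#' @param seed PRNG seed; the generator restores the caller's RNG
#'   state.
#' @return A \linkS4class{SignedDigraph} with nodes \code{L1..Lk}
#'   (ligands) and \code{N1..}.
#' @examples
#' g <- randomSignedNetwork(seed = 1)
#' numNodes(g)
#' @export
randomSignedNetwork <- function(n_nodes = 40L, n_ligands = 7L,
                                edge_density = 0.06,
                                inhibitor_fraction = 0.15, seed = 1L) {
  stopifnot(n_ligands >= 1L, n_ligands < n_nodes,
            edge_density > 0, edge_density < 1,
            inhibitor_fraction >= 0, inhibitor_fraction <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ligands <- paste0("L", seq_len(n_ligands))
  others <- paste0("N", seq_len(n_nodes - n_ligands))
  nodes <- c(ligands, others)

  cand <- expand.grid(from = nodes, to = others, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)    # ligands keep in-degree 0
  cand <- cand[cand$from != cand$to, , drop = FALSE]
  e <- cand[runif(nrow(cand)) < edge_density, , drop = FALSE]

  # enforce reachability from the ligand set
  repeat {
    g <- signedDigraph(if (nrow(e))
      data.frame(e, sign = 1L) else
      data.frame(from = character(), to = character(), sign = integer()),
      nodes = nodes)
    reach <- nodes(reachableSubnetwork(g, ligands))
    miss <- setdiff(nodes, reach)
    if (!length(miss)) break
    e <- rbind(e, data.frame(from = sample(reach, 1L), to = miss[1L],
                             stringsAsFactors = FALSE))
  }

  sgn <- ifelse(runif(nrow(e)) < inhibitor_fraction, -1L, 1L)
  signedDigraph(data.frame(from = e$from, to = e$to, sign = sgn,
                           stringsAsFactors = FALSE), nodes = nodes)
}

#' Synthetic experimental activity table
#'
#' Emulates a normalized (micro-ELISA style) readout of a simulation:
#' the per-node activity summary plus i.i.d. Gaussian measurement
#' noise, clamped to \code{[0, 1]}.
#'
#' @param traj a \linkS4class{StateTrajectory}.
#' @param noise_sd measurement noise standard deviation (>= 0).
#' @param seed PRNG seed (caller's RNG state is restored).
#' @param condition condition label for the table (default
#'   \code{"cond1"}).
#' @param summary,k passed to [summarizeActivity()].
#' @return \code{data.frame} with columns \code{condition},
#'   \code{node}, \code{value}.
#' @export
syntheticExperimentTable <- function(traj, noise_sd = 0.05, seed = 1L,
                                     condition = "cond1",
                                     summary = "mean", k = 10L) {
  stopifnot(noise_sd >= 0)
  s <- summarizeActivity(traj, summary = summary, k = k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- clamp01(s + rnorm(length(s), 0, noise_sd))
  data.frame(condition = condition, node = names(s), value = unname(v),
             stringsAsFactors = FALSE)
}
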