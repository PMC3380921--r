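# In silico perturbation experiments.
#
# Inhibition is NOT modeled by deleting the target node (deletion
# breaks all downstream signal flow, contradicting inhibitor
# experiments where some signal still passes through). Instead each
# inhibited target receives a constant inhibitory message from a
# fresh complementary node anti_<target>; the target keeps
# transmitting whatever activity it retains. Gain-of-function
# mutations (e.g. constitutively active Ras) are fixed activity
# assignments overwriting the node after every sweep.

#' Augment a network with complementary inhibitor nodes
#'
#' For each inhibition in the spec, adds one fresh node
#' \code{anti_<target>} with a single inhibitory (\code{-1}) edge onto
#' the target, carrying the specified constant edge weight. The
#' augmentation happens AFTER NSI weighting and NSI is not recomputed:
#' edge weights reflect the biology, not the intervention. (A
#' complementary node has no other neighbours, so the NSI of its edge
#' would be 1 anyway; the default weight 1 is consistent.)
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param w an \linkS4class{EdgeWeightMap} for \code{g}.
#' @param spec a \linkS4class{PerturbationSpec}.
#' @return List with elements \code{graph} (augmented
#'   \linkS4class{SignedDigraph}), \code{weights} (augmented
#'   \linkS4class{EdgeWeightMap}), \code{clamp} (named numeric vector:
#'   constant activity per complementary node) and \code{antiEdges}
#'   (the added weighted edges).
#' @examples
#' aug <- applyInhibition(cascade(3), weightAllEdges(cascade(3)),
#'                        perturbationSpec(inhibit = "v2"))
#' numNodes(aug$graph)
#' @export
applyInhibition <- function(g, w, spec) {
  stopifnot(is(g, "SignedDigraph"), is(w, "EdgeWeightMap"),
            is(spec, "PerturbationSpec"))
  validObject(spec)
  inh <- spec@inhibitions
  if (!nrow(inh))
    return(list(graph = g, weights = w, clamp = numeric(),
                antiEdges = NULL))
  unknown <- setdiff(inh$target, nodes(g))
  if (length(unknown))
    stop("inhibition target(s) not in network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  anti <- paste0("anti_", inh$target)
  clash <- intersect(anti, nodes(g))
  if (length(clash))
    stop("complementary node name(s) already exist in the network: ",
         paste(clash, collapse = ", "), call. = FALSE)
  antiEdges <- data.frame(from = anti, to = inh$target, sign = -1L,
                          weight = inh$weight, stringsAsFactors = FALSE)
  gAug <- signedDigraph(rbind(edges(g), antiEdges[, c("from", "to", "sign")]),
                        nodes = c(nodes(g), anti), labels = g@labels)
  wAug <- new("EdgeWeightMap", table = rbind(edges(w), antiEdges))
  list(graph = gAug, weights = wAug,
       clamp = setNames(inh$activity, anti), antiEdges = antiEdges)
}

#' Overwrite fixed activity assignments in a state vector
#'
#' The clamp dominates dynamics and noise; inside [simulateNetwork()]
#' fixed nodes are held at their constant for the whole sweep, so
#' same-sweep readers never see a transient value.
#'
#' @param state named numeric state vector.
#' @param spec a \linkS4class{PerturbationSpec}; only fixed nodes
#'   present in \code{state} are touched.
#' @return The state vector with fixed nodes overwritten.
#' @export
applyFixedAssignments <- function(state, spec) {
  stopifnot(is(spec, "PerturbationSpec"))
  fx <- spec@fixed[names(spec@fixed) %in% names(state)]
  state[names(fx)] <- fx
  state
}

#' Mask inhibited readouts in a reported trajectory
#'
#' When a measured molecule is itself inhibited, its measurement is
#' unusable; the reported trajectory row of each inhibited target is
#' replaced by its user-specified report value (often 0). Internal
#' dynamics — and downstream nodes — are unaffected.
#'
#' @param traj a \linkS4class{StateTrajectory}.
#' @param spec a \linkS4class{PerturbationSpec}.
#' @return A \linkS4class{StateTrajectory} with masked rows and the
#'   \code{masked} slot recording which readouts were replaced.
#' @export
maskInhibitedReadouts <- function(traj, spec) {
  stopifnot(is(traj, "StateTrajectory"), is(spec, "PerturbationSpec"))
  inh <- spec@inhibitions
  hit <- inh$target %in% rownames(traj@activity)
  X <- traj@activity
  for (k in which(hit))
    X[inh$target[k], ] <- inh$report[k]
  initialize(traj, activity = X,
             masked = union(traj@masked, inh$target[hit]))
}
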