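#' @import methods
#' @importFrom stats runif rnorm cor.test pnorm setNames
#' @importFrom utils read.table write.table packageVersion
NULL

#' Node identifiers of a signed digraph
#'
#' @param x a \linkS4class{SignedDigraph}.
#' @return Character vector of node identifiers.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Edge table of a signed digraph or edge-weight map
#'
#' @param x a \linkS4class{SignedDigraph} or \linkS4class{EdgeWeightMap}.
#' @return A \code{data.frame} with columns \code{from}, \code{to},
#'   \code{sign} (and \code{weight} for an \linkS4class{EdgeWeightMap}).
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Number of nodes / edges
#'
#' @param x a \linkS4class{SignedDigraph}.
#' @return Integer count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Activity matrix of a simulated trajectory
#'
#' @param x a \linkS4class{StateTrajectory}.
#' @return Numeric matrix, nodes in rows, time steps \code{t0..tT} in
#'   columns; every entry lies in \code{[0, 1]}.
#' @export
setGeneric("activityMatrix", function(x) standardGeneric("activityMatrix"))
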