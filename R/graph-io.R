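# Reading/writing signed networks and topological annotation.
# Canonical edge format: 3-column TSV (source, target, sign), '#'
# comments allowed, optional header auto-detected by a non-numeric,
# non-sign third column. Cytoscape-style SIF lines
# ("A activates B" / "A inhibits B") are accepted transparently.

#' Read a signed directed signaling network
#'
#' Parses an edge list (and optionally a node list) into a
#' \linkS4class{SignedDigraph}. Edge lines are whitespace- or
#' tab-separated triples \code{source target sign}; accepted sign
#' spellings are \code{1}, \code{+1}, \code{-1}, \code{activate(s)},
#' \code{inhibit(s)}. Duplicate identical edges are collapsed with a
#' warning; the same ordered pair with conflicting signs is an error.
#' Self-loops are accepted but flagged with a message.
#'
#' @param edge_source path to the edge file, or a character vector of
#'   lines.
#' @param node_source optional path (or lines) of a one-node-per-line
#'   node file; nodes are inferred from the edges when absent.
#' @return A \linkS4class{SignedDigraph}.
#' @examples
#' readNetwork(c("A\tB\t+1", "B\tC\t-1"))
#' @export
readNetwork <- function(edge_source, node_source = NULL) {
  lines <- readSourceLines(edge_source)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("edge source contains no edges", call. = FALSE)

  toks <- strsplit(trimws(lines), "[\t ]+")
  nt <- lengths(toks)
  if (any(nt != 3L))
    stop("line ", lineno[which(nt != 3L)[1L]],
         ": expected 3 fields (source, target, sign), found ",
         nt[which(nt != 3L)[1L]], call. = FALSE)
  m <- do.call(rbind, toks)

  # SIF dialect puts the relation in the middle column
  sif <- tolower(m[, 2L]) %in% c("activate", "activates", "inhibit",
                                 "inhibits")
  if (any(sif))
    m[sif, ] <- m[sif, c(1L, 3L, 2L), drop = FALSE]

  # header detection: non-parsable sign token on the first line only
  signOK <- function(x) tolower(x) %in%
    c("1", "+1", "-1", "−1", "activate", "activates", "inhibit",
      "inhibits")
  if (!signOK(m[1L, 3L]) && nrow(m) > 1L && all(signOK(m[-1L, 3L]))) {
    m <- m[-1L, , drop = FALSE]
    lineno <- lineno[-1L]
  }
  bad <- which(!signOK(m[, 3L]))
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": unparsable sign token '",
         m[bad[1L], 3L], "'", call. = FALSE)

  e <- data.frame(from = trimws(m[, 1L]), to = trimws(m[, 2L]),
                  sign = parseSign(m[, 3L]), stringsAsFactors = FALSE)

  key <- paste(e$from, e$to, sep = "\r")
  if (anyDuplicated(key)) {
    firstSign <- tapply(e$sign, key, function(s) s[1L])
    conflict <- tapply(e$sign, key, function(s) length(unique(s)) > 1L)
    if (any(conflict)) {
      k <- names(conflict)[conflict][1L]
      pair <- strsplit(k, "\r")[[1L]]
      stop("conflicting signs for duplicated edge ", pair[1L], " -> ",
           pair[2L], call. = FALSE)
    }
    warning(sum(duplicated(key)), " duplicate identical edge line(s) collapsed",
            call. = FALSE)
    e <- e[!duplicated(key), , drop = FALSE]
  }
  if (any(e$from == e$to))
    message("self-loop edge(s) present: ",
            paste(unique(e$from[e$from == e$to]), collapse = ", "))

  nodes <- NULL
  if (!is.null(node_source)) {
    nl <- readSourceLines(node_source)
    nl <- trimws(nl[!grepl("^\\s*(#|$)", nl)])
    nodes <- nl[nzchar(nl)]
  }
  signedDigraph(e, nodes = nodes)
}

# a path (length-1, existing file) or literal character lines
readSourceLines <- function(src) {
  if (length(src) == 1L && !grepl("[\n\t]", src) && file.exists(src))
    readLines(src, warn = FALSE)
  else unlist(strsplit(src, "\n", fixed = TRUE), use.names = FALSE)
}

#' Write a network in the canonical TSV dialect
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param edge_path destination for the 3-column TSV edge list.
#' @param node_path optional destination for a one-node-per-line file
#'   (captures isolated nodes, which the edge list cannot).
#' @return Invisibly, \code{edge_path}.
#' @export
writeNetwork <- function(g, edge_path, node_path = NULL) {
  stopifnot(is(g, "SignedDigraph"))
  e <- edges(g)
  write.table(data.frame(source = e$from, target = e$to,
                         sign = sprintf("%+d", e$sign)),
              edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path))
    writeLines(nodes(g), node_path)
  invisible(edge_path)
}

# igraph view used for traversal only
asIgraph <- function(g) {
  igraph::graph_from_data_frame(edges(g)[, c("from", "to")],
                                directed = TRUE,
                                vertices = data.frame(name = nodes(g)))
}

#' Subnetwork reachable from source nodes
#'
#' Nodes not reachable from any source by a directed path are ignored
#' by the simulation; this returns the induced subgraph on the
#' reachable set (sources included), signs preserved.
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param sources character vector of source node ids, all in \code{g}.
#' @return A \linkS4class{SignedDigraph}.
#' @examples
#' g <- readNetwork(c("A B +1", "B C -1", "D C +1"))
#' nodes(reachableSubnetwork(g, "A"))
#' @export
reachableSubnetwork <- function(g, sources) {
  stopifnot(is(g, "SignedDigraph"))
  sources <- as.character(sources)
  if (!length(sources)) stop("at least one source is required", call. = FALSE)
  unknown <- setdiff(sources, nodes(g))
  if (length(unknown))
    stop("unknown source node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ig <- asIgraph(g)
  reach <- unique(unlist(lapply(sources, function(s)
    names(igraph::subcomponent(ig, s, mode = "out")))))
  e <- edges(g)
  e <- e[e$from %in% reach & e$to %in% reach, , drop = FALSE]
  lbl <- g@labels[names(g@labels) %in% reach]
  signedDigraph(e, nodes = intersect(nodes(g), reach), labels = lbl)
}

#' Degree table
#'
#' In-, out- and total degree per node, counting directed edges
#' regardless of sign (a self-loop contributes to both in and out).
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @return \code{data.frame} with columns \code{node},
#'   \code{in_degree}, \code{out_degree}, \code{total_degree}, one row
#'   per node in \code{nodes(g)} order.
#' @export
degreeTable <- function(g) {
  stopifnot(is(g, "SignedDigraph"))
  n <- nodes(g)
  e <- edges(g)
  data.frame(node = n,
             in_degree = as.integer(table(factor(e$to, levels = n))),
             out_degree = as.integer(table(factor(e$from, levels = n))),
             total_degree = as.integer(table(factor(e$to, levels = n)) +
                                       table(factor(e$from, levels = n))),
             stringsAsFactors = FALSE)
}

#' Half-life classification from topology
#'
#' Protein half-life is predicted from topology alone: highly connected
#' nodes (total degree >= 6) are enriched for long-half-life proteins,
#' and ligand/receptor sources (in-degree 0) and sink outputs
#' (out-degree 0) have uncertain stability. Such nodes are classed
#' \code{ambiguous} and are simulated in both a short- and a
#' long-half-life variant unless a user override picks one; all other
#' nodes are \code{default}.
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param overrides named character vector mapping node ids to
#'   \code{"short"} or \code{"long"}; an override wins over the degree
#'   rule.
#' @return \code{data.frame} with columns \code{node}, \code{class}
#'   (\code{default}/\code{ambiguous}/\code{short}/\code{long}) and
#'   \code{override} (logical).
#' @export
classifyHalfLife <- function(g, overrides = character()) {
  stopifnot(is(g, "SignedDigraph"))
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), nodes(g))
    if (length(unknown))
      stop("half-life override(s) for unknown node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (!all(overrides %in% c("short", "long")))
      stop("overrides must be 'short' or 'long'", call. = FALSE)
  }
  d <- degreeTable(g)
  cls <- ifelse(d$total_degree >= 6L | d$in_degree == 0L |
                d$out_degree == 0L, "ambiguous", "default")
  ov <- d$node %in% names(overrides)
  cls[ov] <- overrides[d$node[ov]]
  data.frame(node = d$node, class = cls, override = ov,
             stringsAsFactors = FALSE)
}

#' Write the degree/half-life annotation table
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param path destination TSV.
#' @param overrides passed to [classifyHalfLife()].
#' @return Invisibly, the table written.
#' @export
writeDegreeTable <- function(g, path, overrides = character()) {
  d <- degreeTable(g)
  d$half_life_class <- classifyHalfLife(g, overrides)$class
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
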