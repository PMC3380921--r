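# Normalized Similarity Index (NSI) edge weighting.
#
# For an edge (i, j): neighbourhoods N(i), N(j) are taken ignoring
# edge direction and sign, excluding i and j themselves;
#   M = |N(i) & N(j)|   matching connections,
#   D = |N(i) | N(j)|   distinct neighbours,
#   C = number of directed edges between i and j (1 or 2),
#   NSI = (M + C) / (D + C), a weight in (0, 1].
# Worked example: endpoints with 4 common neighbours, 8 distinct
# neighbours and one connecting edge give NSI = 5/9.

# undirected neighbour sets, self-loops excluded
neighborSets <- function(g) {
  e <- edges(g)
  e <- e[e$from != e$to, , drop = FALSE]
  both <- rbind(data.frame(a = e$from, b = e$to),
                data.frame(a = e$to, b = e$from))
  split(both$b, factor(both$a, levels = nodes(g)))
}

#' Matching and distinct neighbour counts of an edge's endpoints
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param i,j distinct node ids in \code{g}.
#' @return Named integer vector \code{c(M =, D =, C =)}: matching
#'   connections, distinct neighbours (both excluding \code{i},
#'   \code{j} themselves, ignoring direction and sign), and the number
#'   of directed edges between \code{i} and \code{j} (0, 1 or 2).
#' @examples
#' neighborCounts(nsiMotif(), "i", "j")  # M 4, D 8, C 1
#' @export
neighborCounts <- function(g, i, j) {
  stopifnot(is(g, "SignedDigraph"))
  if (identical(i, j))
    stop("self-similarity is undefined: i and j must differ", call. = FALSE)
  if (!all(c(i, j) %in% nodes(g)))
    stop("node(s) not in graph: ",
         paste(setdiff(c(i, j), nodes(g)), collapse = ", "), call. = FALSE)
  ns <- neighborSets(g)
  ni <- setdiff(unique(ns[[i]]), c(i, j))
  nj <- setdiff(unique(ns[[j]]), c(i, j))
  e <- edges(g)
  C <- sum((e$from == i & e$to == j) | (e$from == j & e$to == i))
  c(M = length(intersect(ni, nj)), D = length(union(ni, nj)), C = C)
}

#' NSI weight of one directed edge
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param i,j endpoints of an edge \code{i -> j} present in \code{g}.
#' @return The weight \code{(M + C) / (D + C)} in \code{(0, 1]}.
#'   A self-loop gets weight 1 (neutral efficiency).
#' @examples
#' edgeNSI(nsiMotif(), "i", "j")  # 5/9
#' @export
edgeNSI <- function(g, i, j) {
  stopifnot(is(g, "SignedDigraph"))
  e <- edges(g)
  if (!any(e$from == i & e$to == j))
    stop("no edge ", i, " -> ", j, " in graph", call. = FALSE)
  if (identical(i, j)) return(1)
  k <- neighborCounts(g, i, j)
  unname((k["M"] + k["C"]) / (k["D"] + k["C"]))
}

#' NSI weights for every edge of a network
#'
#' Deterministic: depends only on topology. Reciprocal edges
#' \code{i -> j} and \code{j -> i} receive equal weights (the index is
#' symmetric in its endpoints).
#'
#' @param g a nonempty \linkS4class{SignedDigraph}.
#' @return An \linkS4class{EdgeWeightMap}.
#' @examples
#' edges(weightAllEdges(nsiMotif()))
#' @export
weightAllEdges <- function(g) {
  stopifnot(is(g, "SignedDigraph"))
  if (!numNodes(g)) stop("empty network", call. = FALSE)
  e <- edges(g)
  w <- vapply(seq_len(nrow(e)),
              function(k) edgeNSI(g, e$from[k], e$to[k]), numeric(1))
  t <- e
  t$weight <- w
  new("EdgeWeightMap", table = t)
}

#' Export a similarity-weighted edge list
#'
#' Writes a TSV (source, target, sign, nsi_weight) consumable by
#' similarity-layout/clustering tools; weights rendered with 6
#' decimals.
#'
#' @param g a \linkS4class{SignedDigraph}.
#' @param w an \linkS4class{EdgeWeightMap} covering \code{g}'s edges;
#'   computed with [weightAllEdges()] when missing.
#' @param path destination file.
#' @return Invisibly, \code{path}.
#' @export
exportSimilarity <- function(g, path, w = weightAllEdges(g)) {
  stopifnot(is(g, "SignedDigraph"), is(w, "EdgeWeightMap"))
  e <- edges(g)
  t <- w@table
  missing <- setdiff(paste(e$from, e$to), paste(t$from, t$to))
  if (length(missing))
    stop("weight map does not cover edge(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  out <- data.frame(source = t$from, target = t$to,
                    sign = sprintf("%+d", t$sign),
                    nsi_weight = sprintf("%.6f", t$weight))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
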