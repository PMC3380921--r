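# Validation statistics: Pearson agreement between simulated and
# experimental activity levels, and paired Wilcoxon signed-rank
# comparison of per-iteration trajectories before vs after a
# perturbation, summarized as up/down/none trend calls at alpha 0.01.

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors of equal length >= 3, both with nonzero
#'   variance.
#' @return Named numeric vector \code{c(r =, p =)}: the sample Pearson
#'   coefficient and the two-sided p-value from the t transform with
#'   n - 2 degrees of freedom.
#' @examples
#' pearsonAgreement(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearsonAgreement <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("at least 3 paired observations are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = unname(ct$p.value))
}

#' Paired Wilcoxon signed-rank statistic (normal approximation)
#'
#' Compares per-iteration activity values of one node before and
#' after a perturbation. Zero differences are dropped; absolute
#' differences are ranked with midranks for ties; W is the smaller of
#' the positive/negative rank sums and
#' \deqn{Z = (W - n'(n'+1)/4) / \sqrt{n'(n'+1)(2n'+1)/24}}
#' is reported with its (non-positive) sign, no continuity
#' correction. With n = 100 pairs all differing in the same
#' direction, Z saturates at -8.68. The two-sided p comes from the
#' normal approximation, which requires n >= 10 informative pairs.
#'
#' @param normal,perturbed equal-length numeric vectors of paired
#'   per-iteration values (typically T = 100 iterations).
#' @return Named numeric vector \code{c(Z =, p =)}.
#' @examples
#' wilcoxonSignedRank(rep(0, 10), seq(0.1, 1, by = 0.1))  # Z = -2.80
#' @export
wilcoxonSignedRank <- function(normal, perturbed) {
  if (length(normal) != length(perturbed))
    stop("vectors must have equal length", call. = FALSE)
  d <- perturbed - normal
  d <- d[d != 0]
  if (!length(d))
    stop("degenerate input: all paired differences are zero",
         call. = FALSE)
  n <- length(d)
  if (n < 10L)
    warning("fewer than 10 informative pairs; ",
            "normal approximation is unreliable")
  r <- rank(abs(d))                       # midranks for ties
  W <- min(sum(r[d > 0]), sum(r[d < 0]))
  Z <- (W - n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  c(Z = Z, p = min(1, 2 * pnorm(Z)))
}

#' Trend call for a perturbation response
#'
#' \code{"up"} if the change is significant and the perturbed mean is
#' higher, \code{"down"} if significant and lower, \code{"none"}
#' otherwise (including the equal-means tie).
#'
#' @param Z Wilcoxon Z statistic (unused by the decision; carried for
#'   reporting).
#' @param p two-sided p-value.
#' @param mean_normal,mean_perturbed mean activity before/after.
#' @param alpha significance level (default 0.01).
#' @return \code{"up"}, \code{"down"} or \code{"none"}.
#' @export
trendCall <- function(Z, p, mean_normal, mean_perturbed, alpha = 0.01) {
  if (p < alpha && mean_perturbed > mean_normal) "up"
  else if (p < alpha && mean_perturbed < mean_normal) "down"
  else "none"
}

#' Per-node Wilcoxon comparison of two trajectories
#'
#' Pairs the per-iteration values (t = 1..T) of every shared node in
#' an unperturbed and a perturbed trajectory and reports the
#' signed-rank statistic, means and trend call per node. Nodes whose
#' trajectories are identical (all differences zero) get \code{NA}
#' statistics and trend \code{"none"}.
#'
#' @param normal,perturbed \linkS4class{StateTrajectory} objects from
#'   paired runs (same seed).
#' @param alpha significance level for the trend call (default 0.01).
#' @return \code{data.frame} with columns \code{node}, \code{Z},
#'   \code{p}, \code{mean_normal}, \code{mean_perturbed},
#'   \code{trend}.
#' @export
wilcoxonComparison <- function(normal, perturbed, alpha = 0.01) {
  stopifnot(is(normal, "StateTrajectory"), is(perturbed, "StateTrajectory"))
  shared <- intersect(rownames(normal@activity),
                      rownames(perturbed@activity))
  if (!length(shared)) stop("no shared nodes", call. = FALSE)
  rows <- lapply(shared, function(nd) {
    a <- normal@activity[nd, -1L]
    b <- perturbed@activity[nd, -1L]
    zp <- tryCatch(suppressWarnings(wilcoxonSignedRank(a, b)),
                   error = function(e) c(Z = NA_real_, p = NA_real_))
    tr <- if (is.na(zp[["p"]])) "none"
          else trendCall(zp[["Z"]], zp[["p"]], mean(a), mean(b), alpha)
    data.frame(node = nd, Z = zp[["Z"]], p = zp[["p"]],
               mean_normal = mean(a), mean_perturbed = mean(b),
               trend = tr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate simulation summaries with an experimental table
#'
#' Inner-joins the two tables on (condition, node), computes the
#' Pearson agreement over all matched pairs and records unmatched
#' keys. Experimental values are expected pre-normalized to
#' \code{[0, 1]} (micro-ELISA style).
#'
#' @param sim_summary,exp_table \code{data.frame}s with columns
#'   \code{condition}, \code{node}, \code{value}.
#' @return A \linkS4class{ValidationReport}.
#' @export
correlateExperiment <- function(sim_summary, exp_table) {
  need <- c("condition", "node", "value")
  stopifnot(all(need %in% names(sim_summary)),
            all(need %in% names(exp_table)))
  m <- merge(sim_summary[need], exp_table[need],
             by = c("condition", "node"),
             suffixes = c(".sim", ".exp"))
  if (!nrow(m))
    stop("no (condition, node) keys shared between the tables",
         call. = FALSE)
  keyS <- paste(sim_summary$condition, sim_summary$node, sep = "\r")
  keyE <- paste(exp_table$condition, exp_table$node, sep = "\r")
  un <- unique(c(setdiff(keyS, keyE), setdiff(keyE, keyS)))
  unm <- if (length(un)) {
    parts <- do.call(rbind, strsplit(un, "\r", fixed = TRUE))
    data.frame(condition = parts[, 1L], node = parts[, 2L],
               stringsAsFactors = FALSE)
  } else data.frame(condition = character(), node = character(),
                    stringsAsFactors = FALSE)
  rp <- pearsonAgreement(m$value.sim, m$value.exp)
  new("ValidationReport",
      pairs = data.frame(condition = m$condition, node = m$node,
                         simulated = m$value.sim,
                         experimental = m$value.exp,
                         stringsAsFactors = FALSE),
      r = rp[["r"]], p = rp[["p"]], unmatched = unm)
}

#' Write validation outputs
#'
#' \code{validation_report.tsv}: the matched pairs plus a trailing
#' comment header with r and p. \code{wilcoxon.tsv}: the per-node
#' comparison table.
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param path destination TSV.
#' @return Invisibly, \code{path}.
#' @export
writeValidationReport <- function(report, path) {
  stopifnot(is(report, "ValidationReport"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pearson_r=%.6f\tpearson_p=%.6g",
                     report@r, report@p), con)
  write.table(report@pairs, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeValidationReport
#' @param tab a \code{data.frame} as returned by
#'   [wilcoxonComparison()].
#' @export
writeWilcoxonTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
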