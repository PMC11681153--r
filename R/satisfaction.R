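#' Dominance adjacency matrix
#'
#' \eqn{P_{aa'} = 1} iff the converged score of `a` strictly exceeds that
#' of `a'`; ties (and the diagonal) are 0 both ways.
#'
#' @param scores Named numeric vector of converged alternative scores.
#' @return A binary matrix with zero diagonal.
#' @export
dominance_adjacency <- function(scores) {
  p <- outer(scores, scores, ">") * 1
  diag(p) <- 0
  dimnames(p) <- list(names(scores), names(scores))
  p
}

#' Net dominance
#'
#' Per alternative, wins minus losses in the dominance digraph:
#' \eqn{\sum_{a'} (P_{aa'} - P_{a'a})}.  Sums to zero over any tournament.
#'
#' @param p A [dominance_adjacency()] matrix.
#' @return A named numeric vector.
#' @export
net_dominance <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop("adjacency must be square", call. = FALSE)
  rowSums(p) - colSums(p)
}

#' Outranking flows
#'
#' Leaving (positive) flow \eqn{F^+_a}: the share of the other
#' alternatives that `a` dominates, row sum over \eqn{f - 1}; entering
#' (negative) flow \eqn{F^-_a}: column sum over \eqn{f - 1}; net flow
#' \eqn{F = F^+ - F^-}.
#'
#' @param p A [dominance_adjacency()] matrix with at least two
#'   alternatives.
#' @return A tibble with columns `alternative`, `flow_pos`, `flow_neg`,
#'   `flow_net`.
#' @export
outranking_flows <- function(p) {
  p <- as.matrix(p)
  f <- nrow(p)
  if (f < 2) stop("flows need at least two alternatives", call. = FALSE)
  lab <- if (is.null(rownames(p))) paste0("d", seq_len(f)) else rownames(p)
  pos <- rowSums(p) / (f - 1)
  neg <- colSums(p) / (f - 1)
  tibble::tibble(alternative = lab, flow_pos = unname(pos),
                 flow_neg = unname(neg), flow_net = unname(pos - neg))
}

#' Satisfaction measure
#'
#' Ranks the alternatives a second time by net outranking flow
#' (competition ranking, descending) and compares with the BAM ranking:
#' `satisfaction = rank_flow - rank_bam`.  Zero marks the most optimal
#' placements, positive values acceptable ones, negative values less
#' optimal ones.  With a strict-dominance adjacency built from distinct
#' scores the two rankings coincide (net dominance is monotone in score),
#' so non-zero satisfaction only arises from ties or from an externally
#' supplied flow vector (`flow_override`), which is accepted to reproduce
#' alternative analyses.
#'
#' @param scores Named converged scores (used to build the adjacency).
#' @param rank_bam Integer BAM ranking aligned with `scores`.
#' @param flow_override Optional numeric vector replacing the net flows.
#' @return A tibble of class `appss_satisfaction` with columns
#'   `alternative`, `score`, `flow_pos`, `flow_neg`, `flow_net`,
#'   `rank_bam`, `rank_flow`, `satisfaction`, `class`.
#' @export
satisfactory_measure <- function(scores, rank_bam = rank_alternatives(scores),
                                 flow_override = NULL) {
  if (length(scores) != length(rank_bam)) {
    stop("scores and ranks must align", call. = FALSE)
  }
  p <- dominance_adjacency(scores)
  fl <- outranking_flows(p)
  net <- if (is.null(flow_override)) fl$flow_net else flow_override
  rank_flow <- rank_alternatives(stats::setNames(net, fl$alternative))
  sat <- as.integer(rank_flow) - as.integer(rank_bam)
  cls <- dplyr::case_when(sat == 0 ~ "most_optimal",
                          sat > 0 ~ "acceptable",
                          TRUE ~ "less_optimal")
  out <- tibble::tibble(
    alternative = fl$alternative, score = unname(scores),
    flow_pos = fl$flow_pos, flow_neg = fl$flow_neg, flow_net = net,
    rank_bam = as.integer(rank_bam), rank_flow = as.integer(rank_flow),
    satisfaction = sat,
    class = factor(cls, levels = c("most_optimal", "acceptable",
                                   "less_optimal")))
  structure(out, class = c("appss_satisfaction", class(out)))
}

#' @method tidy appss_satisfaction
#' @export
tidy.appss_satisfaction <- function(x, ...) tibble::as_tibble(x)

#' @export
print.appss_satisfaction <- function(x, ...) {
  cat("Satisfaction measure (rank_flow - rank_bam; 0 = most optimal)\n")
  NextMethod()
}
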