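#' Aggregate CPM edge coefficients to the network level
#'
#' Sums each model edge's regression weight into the cell of the
#' (network_i, network_j) pair holding it and into both endpoint
#' nodes' totals. The default mode uses absolute coefficients so the
#' aggregate is a nonnegative predictive mass whose between-network
#' share is a meaningful proportion; `mode = "signed"` sums raw
#' coefficients for inspection. Within-network (diagonal) mass counts
#' once in the conservation total.
#'
#' @param model A [cpm_train()] model (or any list with `edges` and
#'   `coefficients`).
#' @param assignment Data frame with columns `node_id` (0-based) and
#'   `network`, covering every node referenced by the model's edges.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return Object of class `network_weights`: list with `labels`
#'   (sorted network names), `pair_weights` (symmetric K x K matrix),
#'   `node_weights` (named per-node totals), `between_fraction`,
#'   `mode`.
#' @export
aggregate_network_weights <- function(model, assignment,
                                      mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  edges <- model$edges
  w <- if (mode == "absolute") abs(model$coefficients) else model$coefficients
  if (!all(c("node_id", "network") %in% names(assignment))) {
    stop("assignment needs columns node_id and network")
  }
  net_of <- stats::setNames(as.character(assignment$network),
                            as.character(assignment$node_id))
  ni <- net_of[as.character(edges[, 1L])]
  nj <- net_of[as.character(edges[, 2L])]
  if (anyNA(ni) || anyNA(nj)) {
    missing_nodes <- unique(c(edges[, 1L][is.na(ni)], edges[, 2L][is.na(nj)]))
    stop("unassigned node(s): ", paste(missing_nodes, collapse = ", "))
  }
  labels <- sort(unique(as.character(assignment$network)))
  K <- length(labels)
  pair <- matrix(0, K, K, dimnames = list(labels, labels))
  for (e in seq_along(w)) {
    pair[ni[e], nj[e]] <- pair[ni[e], nj[e]] + w[e]
    if (ni[e] != nj[e]) pair[nj[e], ni[e]] <- pair[nj[e], ni[e]] + w[e]
  }
  node <- stats::setNames(numeric(nrow(assignment)),
                          as.character(assignment$node_id))
  for (e in seq_along(w)) {
    node[as.character(edges[e, 1L])] <- node[as.character(edges[e, 1L])] + w[e]
    node[as.character(edges[e, 2L])] <- node[as.character(edges[e, 2L])] + w[e]
  }
  total <- sum(pair[upper.tri(pair, diag = TRUE)])
  between <- sum(pair[upper.tri(pair)])
  structure(
    list(labels = labels,
         pair_weights = pair,
         node_weights = node,
         between_fraction = if (total == 0) NA_real_ else between / total,
         mode = mode),
    class = "network_weights"
  )
}

#' @export
print.network_weights <- function(x, ...) {
  cat("Network-level predictive weights (", x$mode, " mode)\n", sep = "")
  cat("  networks:", length(x$labels),
      "  between-network fraction:",
      format(x$between_fraction, digits = 4), "\n")
  invisible(x)
}

#' Top network pairs by aggregated weight
#'
#' Ranks the nonzero (unordered) network pairs by descending aggregated
#' weight and returns the top `ceiling(fraction * K)` of the K nonzero
#' pairs. Ties at the cut are broken deterministically by lexicographic
#' order of the (network_i, network_j) name pair.
#'
#' @param nw A [aggregate_network_weights()] result.
#' @param fraction Fraction in (0, 1]; 0.5 reproduces the customary
#'   "top half of network pairs" summary.
#' @return Data frame with columns `network_i`, `network_j`, `weight`,
#'   sorted by rank.
#' @export
top_network_pairs <- function(nw, fraction = 0.5) {
  stopifnot(inherits(nw, "network_weights"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  pw <- nw$pair_weights
  ut <- which(upper.tri(pw, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(network_i = rownames(pw)[ut[, 1L]],
                   network_j = colnames(pw)[ut[, 2L]],
                   weight = pw[ut])
  df <- df[df$weight != 0, , drop = FALSE]
  if (nrow(df) == 0L) stop("all network-pair weights are zero")
  ord <- order(-df$weight, df$network_i, df$network_j)
  df <- df[ord, , drop = FALSE]
  k <- ceiling(fraction * nrow(df))
  rownames(df) <- NULL
  df[seq_len(k), , drop = FALSE]
}
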