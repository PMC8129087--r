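# Marginal ancestral-state probabilities and transition counting.
#
# The marginal at a node is computed by clamping that node to each observed
# state in turn and renormalising the resulting log-likelihoods
# (log-sum-exp). This is algebraically identical to the classical up-down
# pass, honours root policies, user clamps and hidden categories without
# special cases, and costs O(nodes^2 * states) vector operations in the
# C++ core — negligible for trees of a few hundred tips.

#' Marginal ancestral state reconstruction
#'
#' Exact posterior `P(observed state at node | all tip data, Q, root)` for
#' every internal node (and optionally tips, where missing data yield a
#' genuine posterior). Hidden-category mass is summed into observed states;
#' set `expanded = TRUE` to also return the full expanded-state marginals.
#'
#' @inheritParams prune_loglik
#' @param include_tips also reconstruct tip nodes (informative for tips with
#'   missing data; observed tips get probability 1 on their state).
#' @param expanded attach the expanded-state marginal matrix as attribute
#'   `"expanded"`.
#' @return a data.frame of class `mk_marginal`: `node`, one probability
#'   column `p_<state>` per observed state, `map_state`, `map_prob`.
#' @export
marginal_reconstruct <- function(phy, tips, Q, root = root_policy("flat"),
                                 clamps = list(), include_tips = FALSE,
                                 expanded = FALSE) {
  st <- prune_setup(phy, tips, Q, root, clamps)
  spec <- st$spec
  ntip <- ape::Ntip(phy)
  nodes <- if (include_tips) seq_len(ntip + phy$Nnode) else
    ntip + seq_len(phy$Nnode)
  masks <- t(vapply(seq_len(spec$k), obs_state_mask, numeric(spec$m),
                    spec = spec))
  ll <- cpp_clamped_logliks(st$edge, st$P, st$partials, st$root_pi, st$root,
                            as.integer(nodes), masks)
  probs <- softmax_rows(ll)
  map_idx <- apply(probs, 1, which.max)
  out <- data.frame(node = nodes)
  for (a in seq_len(spec$k)) {
    out[[paste0("p_", spec$obs_labels[a])]] <- probs[, a]
  }
  out$map_state <- spec$obs_labels[map_idx]
  out$map_prob <- probs[cbind(seq_len(nrow(probs)), map_idx)]
  if (expanded) {
    em <- diag(spec$m)
    elp <- cpp_clamped_logliks(st$edge, st$P, st$partials, st$root_pi,
                               st$root, as.integer(nodes), em)
    ex <- softmax_rows(elp)
    dimnames(ex) <- list(nodes, spec$labels)
    attr(out, "expanded") <- ex
  }
  attr(out, "obs_labels") <- spec$obs_labels
  class(out) <- c("mk_marginal", class(out))
  out
}

softmax_rows <- function(ll) {
  mx <- apply(ll, 1, max)
  if (any(!is.finite(mx))) {
    stop("marginal reconstruction impossible: data have zero likelihood ",
         "under every state at some node", call. = FALSE)
  }
  w <- exp(ll - mx)
  w / rowSums(w)
}

#' Count state transitions along the tree from a marginal reconstruction
#'
#' Assigns each node its maximum-a-posteriori (MAP) observed state and
#' counts each ordered parent -> child state change over branches. Branches
#' with an endpoint whose MAP probability is below `map_threshold` (or
#' exactly tied) are flagged ambiguous; counts are reported as a
#' `[min, max]` range (min excludes ambiguous changes, max includes them) —
#' interpretations of marginal maps are ranges, not single numbers.
#'
#' @param marginals an `mk_marginal` computed with `include_tips = TRUE`
#'   (tip states are needed to count changes on pendant branches).
#' @param phy the tree the reconstruction was computed on.
#' @param map_threshold ambiguity threshold in `(0.5, 1]` (default 0.7).
#' @return a list of class `transition_tally`: `counts` (data.frame `from`,
#'   `to`, `min`, `max`), `branches` (one row per change: `parent`, `child`,
#'   `from`, `to`, `ambiguous`), `total_min`, `total_max`.
#' @export
count_transitions <- function(marginals, phy, map_threshold = 0.7) {
  stopifnot(inherits(marginals, "mk_marginal"))
  if (!(map_threshold > 0.5 && map_threshold <= 1)) {
    stop("map_threshold must be in (0.5, 1]", call. = FALSE)
  }
  n_all <- ape::Ntip(phy) + phy$Nnode
  if (!all(seq_len(n_all) %in% marginals$node)) {
    stop("marginals must cover every node (use include_tips = TRUE)",
         call. = FALSE)
  }
  labs <- attr(marginals, "obs_labels")
  state <- character(n_all)
  prob <- numeric(n_all)
  state[marginals$node] <- marginals$map_state
  prob[marginals$node] <- marginals$map_prob
  # a tie (e.g. exactly 0.5/0.5) is never called; flag as ambiguous
  k <- length(labs)
  pcols <- as.matrix(marginals[, paste0("p_", labs), drop = FALSE])
  tied <- apply(pcols, 1, function(p) sum(abs(p - max(p)) < 1e-12) > 1)
  ambiguous_node <- logical(n_all)
  ambiguous_node[marginals$node] <- tied | prob[marginals$node] <
    map_threshold
  br <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2])
  br$from <- state[br$parent]
  br$to <- state[br$child]
  br$ambiguous <- ambiguous_node[br$parent] | ambiguous_node[br$child]
  changed <- br$from != br$to
  branches <- br[changed, , drop = FALSE]
  rownames(branches) <- NULL
  pairs <- expand.grid(from = labs, to = labs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$min <- 0L
  pairs$max <- 0L
  for (i in seq_len(nrow(pairs))) {
    sel <- branches$from == pairs$from[i] & branches$to == pairs$to[i]
    pairs$min[i] <- sum(sel & !branches$ambiguous)
    pairs$max[i] <- sum(sel)
  }
  rownames(pairs) <- NULL
  structure(list(counts = pairs, branches = branches,
                 total_min = sum(pairs$min), total_max = sum(pairs$max),
                 map_threshold = map_threshold),
            class = "transition_tally")
}

#' @export
print.transition_tally <- function(x, ...) {
  cat("Transition tally (MAP threshold ", x$map_threshold, "): total ",
      x$total_min, "-", x$total_max, " changes\n", sep = "")
  print(x$counts[x$counts$max > 0, ])
  invisible(x)
}

#' Write marginal reconstruction to CSV
#' @param marginals an `mk_marginal`.
#' @param file output path.
#' @export
write_marginal_csv <- function(marginals, file) {
  write.csv(as.data.frame(marginals), file, row.names = FALSE)
  invisible(file)
}

#' Write a Newick string annotated with MAP states as node labels
#'
#' @param phy the tree.
#' @param marginals an `mk_marginal` covering all internal nodes.
#' @param file optional output path; when `NULL` the string is returned.
#' @export
write_annotated_newick <- function(phy, marginals, file = NULL) {
  ntip <- ape::Ntip(phy)
  lab <- rep("", phy$Nnode)
  int <- marginals$node[marginals$node > ntip]
  lab[int - ntip] <- paste0("MAP=", marginals$map_state[marginals$node > ntip],
                            ":p=", sprintf("%.4f",
                            marginals$map_prob[marginals$node > ntip]))
  phy$node.label <- lab
  s <- write_newick(phy)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(file)
}
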