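# Likelihood of tip data on a tree under a generator matrix, via the
# pruning algorithm (C++ core with per-edge rescaling), with root policies
# and internal-node state clamps; plus a brute-force enumeration oracle.

#' Build per-tip partial-likelihood vectors over the expanded states
#'
#' An observed state `s` puts 1 at `(s, every hidden category)` and 0
#' elsewhere; a missing state puts 1 everywhere. For joint (`k = 4`) specs
#' two binary characters are combined in the fixed order
#' (trait1, trait2) -> `(0,0), (0,1), (1,0), (1,1)`; a species missing
#' either trait gets the all-ones vector (kept in the analysis rather than
#' dropped, so the AICc sample size stays the number of tips).
#'
#' @param phy a `phylo` object.
#' @param traits a `trait_table` (see [read_trait_table()]); tips absent
#'   from the table are treated as missing (with a warning via
#'   [match_tree_and_traits()]).
#' @param spec an `mk_spec`; `spec$k` must be 2 (one character) or 4 (two).
#' @param characters names (or indices) of the character column(s) to use;
#'   default: the first `1` or `2` non-species columns.
#' @return a numeric matrix, one row per tip (rownames = tip labels),
#'   `spec$m` columns.
#' @export
tip_partials <- function(phy, traits, spec, characters = NULL) {
  stopifnot(inherits(spec, "mk_spec"))
  n_char <- if (spec$k == 2) 1L else 2L
  aligned <- match_tree_and_traits(phy, traits)$traits
  char_cols <- setdiff(names(aligned), "species")
  if (is.null(characters)) characters <- char_cols[seq_len(n_char)]
  if (is.numeric(characters)) characters <- char_cols[characters]
  if (length(characters) != n_char || anyNA(characters) ||
      !all(characters %in% char_cols)) {
    stop("need ", n_char, " valid character column(s)", call. = FALSE)
  }
  ntip <- ape::Ntip(phy)
  obs <- matrix(0, ntip, spec$k)
  if (n_char == 1L) {
    v <- aligned[[characters]]
    for (i in seq_len(ntip)) {
      obs[i, ] <- if (is.na(v[i])) 1 else replace(numeric(spec$k),
                                                 v[i] + 1L, 1)
    }
  } else {
    v1 <- aligned[[characters[1]]]
    v2 <- aligned[[characters[2]]]
    if (any(!v1 %in% c(0L, 1L, NA)) || any(!v2 %in% c(0L, 1L, NA))) {
      stop("joint coding requires binary characters", call. = FALSE)
    }
    for (i in seq_len(ntip)) {
      if (is.na(v1[i]) || is.na(v2[i])) {
        obs[i, ] <- 1
      } else {
        obs[i, 2L * v1[i] + v2[i] + 1L] <- 1
      }
    }
  }
  out <- do.call(cbind, rep(list(obs), spec$R))
  rownames(out) <- phy$tip.label
  colnames(out) <- spec$labels
  out
}

#' Root state policy
#'
#' `"flat"` weights all expanded states uniformly. `"fixed"` puts all mass
#' on one observed state; with hidden categories the mass is split uniformly
#' across that state's `R` categories (the analysis fixes only the observed
#' state — the category is unobservable).
#'
#' @param mode `"flat"` or `"fixed"`.
#' @param state for `"fixed"`: the observed state, as an index (1-based), a
#'   0/1 code, or an observed-state label such as `"0"` or `"0,0"`.
#' @return an object of class `root_policy`.
#' @export
root_policy <- function(mode = c("flat", "fixed"), state = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && is.null(state)) {
    stop("fixed root policy needs a state", call. = FALSE)
  }
  structure(list(mode = mode, state = state), class = "root_policy")
}

obs_state_index <- function(state, spec) {
  if (is.character(state)) {
    i <- match(state, spec$obs_labels)
    if (is.na(i)) stop("unknown observed state '", state, "'; expected one ",
                       "of: ", paste(spec$obs_labels, collapse = ", "),
                       call. = FALSE)
    return(i)
  }
  i <- as.integer(state)
  if (spec$k == 2) {
    # binary states are always 0/1 codes, never 1-based indices
    if (!i %in% c(0L, 1L)) {
      stop("binary observed states are coded 0/1", call. = FALSE)
    }
    return(i + 1L)
  }
  if (i >= 1L && i <= spec$k) return(i)
  stop("observed state out of range", call. = FALSE)
}

root_vector <- function(root, spec) {
  stopifnot(inherits(root, "root_policy"))
  if (root$mode == "flat") return(rep(1 / spec$m, spec$m))
  s <- obs_state_index(root$state, spec)
  pi <- numeric(spec$m)
  pi[s + spec$k * (seq_len(spec$R) - 1L)] <- 1 / spec$R
  pi
}

#' Clamp an internal node to an observed state
#'
#' At the clamped node, expanded states whose observed state differs from
#' the clamp are zeroed during pruning; all hidden categories of the clamped
#' observed state are kept (the clamp constrains the trait, not the rate
#' regime). Used e.g. to force a most recent common ancestor to "absent",
#' enforcing independent origins of a trait in its descendant clades.
#'
#' @param state required observed state (index, 0/1 code, or label).
#' @param node internal node id, or
#' @param tips a set of tip labels whose mrca is clamped.
#' @return an object of class `clade_clamp`.
#' @export
clade_clamp <- function(state, node = NULL, tips = NULL) {
  if (is.null(node) && is.null(tips)) {
    stop("clamp needs a node id or a set of tip labels", call. = FALSE)
  }
  structure(list(state = state, node = node, tips = tips),
            class = "clade_clamp")
}

resolve_clamp_node <- function(clamp, phy) {
  node <- if (!is.null(clamp$node)) clamp$node else mrca_node(phy, clamp$tips)
  if (node <= ape::Ntip(phy)) {
    stop("clamp resolves to a tip; clamps apply to internal nodes only",
         call. = FALSE)
  }
  node
}

# 0/1 mask over expanded states for an observed state
obs_state_mask <- function(s, spec) {
  mask <- numeric(spec$m)
  mask[s + spec$k * (seq_len(spec$R) - 1L)] <- 1
  mask
}

# shared preparation for pruning-based computations
prune_setup <- function(phy, tips, Q, root, clamps) {
  spec <- q_spec(Q)
  validate_phylogeny(phy)
  ntip <- ape::Ntip(phy)
  if (!is.matrix(tips) || ncol(tips) != spec$m) {
    stop("tip data must be a matrix with ", spec$m, " columns", call. = FALSE)
  }
  idx <- if (!is.null(rownames(tips))) {
    match(phy$tip.label, rownames(tips))
  } else if (nrow(tips) == ntip) {
    seq_len(ntip)
  } else {
    NA_integer_
  }
  if (anyNA(idx)) stop("tip data rows do not match tree tips", call. = FALSE)
  if (any(rowSums(tips) == 0)) {
    stop("every tip partial vector needs at least one nonzero entry",
         call. = FALSE)
  }
  partials <- matrix(1, ntip + phy$Nnode, spec$m)
  partials[seq_len(ntip), ] <- tips[idx, , drop = FALSE]
  if (inherits(clamps, "clade_clamp")) clamps <- list(clamps)
  for (cl in clamps) {
    node <- resolve_clamp_node(cl, phy)
    s <- obs_state_index(cl$state, spec)
    partials[node, ] <- partials[node, ] * obs_state_mask(s, spec)
  }
  po <- postorder_edge_idx(phy)
  list(spec = spec, partials = partials,
       edge = matrix(as.integer(phy$edge[po, ]), ncol = 2),
       P = cpp_branch_P(unclass(Q), phy$edge.length[po]),
       root_pi = root_vector(root, spec), root = root_id(phy))
}

#' Pruning-algorithm log-likelihood
#'
#' Computes `ln P(tip data | tree, Q, root policy, clamps)` by Felsenstein's
#' post-order dynamic program with per-edge rescaling (no underflow for
#' hundreds of tips). A clamp that makes the data impossible yields `-Inf`,
#' not an error, so model search over clamps stays total.
#'
#' @param phy a `phylo` object.
#' @param tips tip partial matrix from [tip_partials()] (rows matched to
#'   `phy$tip.label` by rowname).
#' @param Q a `rate_matrix` from [build_q()] (or a bare generator, in which
#'   case all states are treated as observed, single category).
#' @param root a [root_policy()] (default flat).
#' @param clamps a list of [clade_clamp()] objects (or a single one).
#' @return the log-likelihood (possibly `-Inf`).
#' @export
prune_loglik <- function(phy, tips, Q, root = root_policy("flat"),
                         clamps = list()) {
  st <- prune_setup(phy, tips, Q, root, clamps)
  cpp_prune(st$edge, st$P, st$partials, st$root_pi, st$root)
}

#' Brute-force log-likelihood by enumeration (test oracle)
#'
#' Sums the complete-data likelihood over every assignment of expanded
#' states to internal nodes. Exponential in the number of internal nodes;
#' refuses more than 12. Kept deliberately independent of the pruning code
#' path.
#'
#' @inheritParams prune_loglik
#' @return the log-likelihood.
#' @export
brute_force_loglik <- function(phy, tips, Q, root = root_policy("flat"),
                               clamps = list()) {
  log(sum(brute_force_weights(phy, tips, Q, root, clamps)$w))
}

# per-assignment likelihood weights; shared by the loglik and marginal
# oracles. Returns list(w = weights, grid = assignments, int_ids).
brute_force_weights <- function(phy, tips, Q, root, clamps) {
  spec <- q_spec(Q)
  validate_phylogeny(phy)
  ntip <- ape::Ntip(phy)
  if (phy$Nnode > 12) stop("too many internal nodes for enumeration",
                           call. = FALSE)
  m <- spec$m
  int_ids <- ntip + seq_len(phy$Nnode)
  pos <- function(node) match(node, int_ids)
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), phy$Nnode)))
  root_pi <- root_vector(root, spec)
  w <- root_pi[grid[, pos(root_id(phy))]]
  if (inherits(clamps, "clade_clamp")) clamps <- list(clamps)
  for (cl in clamps) {
    node <- resolve_clamp_node(cl, phy)
    mask <- obs_state_mask(obs_state_index(cl$state, spec), spec)
    w <- w * mask[grid[, pos(node)]]
  }
  tip_idx <- if (!is.null(rownames(tips))) {
    match(phy$tip.label, rownames(tips))
  } else {
    seq_len(ntip)
  }
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    c <- phy$edge[e, 2]
    Pe <- transition_prob(Q, phy$edge.length[e])
    sp <- grid[, pos(p)]
    if (c <= ntip) {
      below <- as.vector(Pe %*% tips[tip_idx[c], ])
      w <- w * below[sp]
    } else {
      w <- w * Pe[cbind(sp, grid[, pos(c)])]
    }
  }
  list(w = w, grid = grid, int_ids = int_ids, spec = spec)
}

#' Brute-force marginal posteriors at internal nodes (test oracle)
#'
#' Exact enumeration posterior `P(observed state at node | data)`, hidden
#' categories summed out.
#'
#' @inheritParams prune_loglik
#' @param nodes internal node ids (default: all).
#' @return matrix: one row per node, one column per observed state.
#' @export
brute_force_marginal <- function(phy, tips, Q, root = root_policy("flat"),
                                 clamps = list(), nodes = NULL) {
  bw <- brute_force_weights(phy, tips, Q, root, clamps)
  spec <- bw$spec
  if (is.null(nodes)) nodes <- bw$int_ids
  obs_of <- rep(seq_len(spec$k), spec$R)
  out <- matrix(0, length(nodes), spec$k,
                dimnames = list(nodes, spec$obs_labels))
  for (i in seq_along(nodes)) {
    st <- obs_of[bw$grid[, match(nodes[i], bw$int_ids)]]
    for (a in seq_len(spec$k)) out[i, a] <- sum(bw$w[st == a])
  }
  sweep(out, 1, rowSums(out), "/")
}
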