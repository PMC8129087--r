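# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# a small random tree with branch lengths on the order of a few time units
rand_tree <- function(ntip, seed) {
  simulate_tree(ntip, birth = 0.5, height = runif(1, 2, 8), seed = seed)
}

# a star tree (root polytomy) with equal pendant branches
star_tree <- function(n, len) {
  phy <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
              edge.length = rep(len, n),
              tip.label = paste0("t", seq_len(n)),
              Nnode = 1L)
  class(phy) <- "phylo"
  phy
}

# random model spec drawn from the supported families
rand_spec <- function(k, R) {
  fam <- if (k == 2) {
    sample(c("ER", "ARD"), 1)
  } else {
    sample(c("ER", "ARD", "IND", "ARD_loss"), 1)
  }
  if (R == 1) {
    make_spec(fam, k = k)
  } else {
    make_spec(fam, k = k, R = 2,
              category_family = sample(c("ER", "ARD"), 2, replace = TRUE),
              category_switch = sample(c("distinct", "shared"), 1))
  }
}

# a complete random instance: tree, spec, Q, tip partials (some missing),
# root policy, and possibly a clamp on a random internal node
rand_instance <- function(seed, ntip = 5, k = 2, R = 1, p_missing = 0.2,
                          p_clamp = 0.4) {
  set.seed(seed)
  phy <- rand_tree(ntip, seed = seed + 10000)
  set.seed(seed + 1)
  spec <- rand_spec(k, R)
  Q <- build_q(spec, 10^runif(spec$k_free, -1.5, -0.2))
  tips <- matrix(0, ntip, spec$m, dimnames = list(phy$tip.label, spec$labels))
  for (i in seq_len(ntip)) {
    if (runif(1) < p_missing) {
      tips[i, ] <- 1
    } else {
      tips[i, ] <- obs_mask_for_tests(sample.int(k, 1), spec)
    }
  }
  root <- if (runif(1) < 0.5) {
    root_policy("flat")
  } else {
    root_policy("fixed", state = spec$obs_labels[sample.int(k, 1)])
  }
  clamps <- list()
  if (runif(1) < p_clamp && phy$Nnode > 1) {
    cand <- setdiff(ape::Ntip(phy) + seq_len(phy$Nnode),
                    ape::Ntip(phy) + 1L)
    node <- cand[sample.int(length(cand), 1)]
    clamps <- list(clade_clamp(state = spec$obs_labels[sample.int(k, 1)],
                               node = node))
  }
  list(phy = phy, spec = spec, Q = Q, tips = tips, root = root,
       clamps = clamps)
}

# expanded-state 0/1 vector for an observed state (test-side re-derivation,
# independent of the package's internal mask helper)
obs_mask_for_tests <- function(s, spec) {
  v <- numeric(spec$m)
  v[s + spec$k * (seq_len(spec$R) - 1L)] <- 1
  v
}

# analytic 2-state transition probability, the closed-form oracle:
# P01(t) = q01/(q01+q10) * (1 - exp(-(q01+q10) t))
closed_form_P <- function(q01, q10, t) {
  r <- q01 + q10
  p01 <- q01 / r * (1 - exp(-r * t))
  p10 <- q10 / r * (1 - exp(-r * t))
  matrix(c(1 - p01, p01, p10, 1 - p10), 2, 2, byrow = TRUE)
}

# state occupancy time per expanded state, reconstructed from a simulated
# history (independent tally used by the simulator's constraint checks);
# history$edge indexes rows of tree$edge
occupancy_from_sim <- function(sim) {
  phy <- sim$tree
  spec <- sim$spec
  depth <- traitmk:::node_depths(phy)
  occ <- setNames(numeric(spec$m), spec$labels)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    ev <- sim$history[sim$history$edge == e, , drop = FALSE]
    tcur <- depth[p]
    t1 <- depth[phy$edge[e, 2]]
    s <- spec$labels[sim$node_states[p]]
    if (nrow(ev) > 0) {
      for (j in seq_len(nrow(ev))) {
        occ[s] <- occ[s] + (ev$time[j] - tcur)
        tcur <- ev$time[j]
        s <- ev$to[j]
      }
    }
    occ[s] <- occ[s] + (t1 - tcur)
  }
  occ
}
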