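tip_mat2 <- function(phy, states, spec) {
  m <- matrix(0, length(states), spec$m,
              dimnames = list(phy$tip.label, spec$labels))
  for (i in seq_along(states)) {
    m[i, ] <- if (is.na(states[i])) 1 else obs_mask_for_tests(states[i], spec)
  }
  m
}

test_that("no-change limit concentrates the root marginal", {
  phy <- read_newick("(A:1,B:1);")
  spec <- make_spec("ER")
  tips <- tip_mat2(phy, c(1, 1), spec)
  marg <- marginal_reconstruct(phy, tips, build_q(spec, 1e-8))
  expect_equal(marg$p_0, 1, tolerance = 1e-6)
  expect_equal(marg$map_state, "0")
})

test_that("marginals equal brute-force posteriors on random instances", {
  for (seed in 1:15) {
    inst <- rand_instance(seed + 900, ntip = sample(3:5, 1),
                          k = sample(c(2, 4), 1), R = sample(1:2, 1))
    marg <- marginal_reconstruct(inst$phy, inst$tips, inst$Q, inst$root,
                                 inst$clamps)
    oracle <- brute_force_marginal(inst$phy, inst$tips, inst$Q, inst$root,
                                   inst$clamps)
    got <- as.matrix(marg[, paste0("p_", inst$spec$obs_labels)])
    expect_lt(max(abs(got - oracle)), 1e-8)
    expect_equal(unname(rowSums(got)), rep(1, nrow(got)), tolerance = 1e-10)
  }
})

test_that("all-missing tips reproduce the propagated prior", {
  phy <- read_newick("((A:1,B:1):1,C:2);")
  spec <- make_spec("ER") # symmetric: uniform prior is stationary
  tips <- tip_mat2(phy, c(NA, NA, NA), spec)
  marg <- marginal_reconstruct(phy, tips, build_q(spec, 0.3))
  expect_equal(marg$p_0, rep(0.5, 2), tolerance = 1e-10)
})

test_that("root marginal honors a fixed root; clamps pin their node", {
  inst <- rand_instance(123, ntip = 6, k = 2, R = 1, p_clamp = 0)
  root <- root_policy("fixed", 1) # binary code 1 -> observed state "1"
  marg <- marginal_reconstruct(inst$phy, inst$tips, inst$Q, root)
  expect_equal(marg$p_1[marg$node == 7], 1, tolerance = 1e-12)
  node <- 9L
  marg2 <- marginal_reconstruct(inst$phy, inst$tips, inst$Q, inst$root,
                                clamps = list(clade_clamp("1", node = node)))
  expect_equal(marg2$p_1[marg2$node == node], 1, tolerance = 1e-12)
})

test_that("a tip's parent marginal converges to the tip state", {
  for (len in c(1, 0.1, 1e-4)) {
    phy <- read_newick(sprintf("((A:%g,B:2):1,C:2);", len))
    spec <- make_spec("ARD")
    tips <- tip_mat2(phy, c(2, 1, 1), spec)
    marg <- marginal_reconstruct(phy, tips, build_q(spec, c(0.2, 0.3)))
    p1 <- marg$p_1[marg$node == mrca_node(phy, c("A", "B"))]
    if (len == 1e-4) expect_gt(p1, 0.99)
  }
})

test_that("marginals are invariant to edge-row serialization order", {
  inst <- rand_instance(77, ntip = 6, k = 2, R = 2, p_clamp = 0)
  marg <- marginal_reconstruct(inst$phy, inst$tips, inst$Q, inst$root)
  phy2 <- inst$phy
  rev_idx <- rev(seq_len(nrow(phy2$edge)))
  phy2$edge <- phy2$edge[rev_idx, ]
  phy2$edge.length <- phy2$edge.length[rev_idx]
  marg2 <- marginal_reconstruct(phy2, inst$tips, inst$Q, inst$root)
  expect_equal(marg2$p_0, marg$p_0, tolerance = 1e-12)
})

test_that("expanded marginals sum into observed-state marginals", {
  inst <- rand_instance(31, ntip = 5, k = 2, R = 2, p_clamp = 0)
  marg <- marginal_reconstruct(inst$phy, inst$tips, inst$Q, inst$root,
                               expanded = TRUE)
  ex <- attr(marg, "expanded")
  expect_equal(unname(ex[, 1] + ex[, 3]), marg$p_0, tolerance = 1e-9)
  expect_equal(unname(rowSums(ex)), rep(1, nrow(ex)), tolerance = 1e-10)
})

test_that("count_transitions finds a single deep gain where it happened", {
  # 4-tip tree with a state-1 cherry on a long stem: one 0->1 gain on that
  # stem under MAP
  phy <- read_newick("(((A:1,B:1):8,C:9):1,D:10);")
  spec <- make_spec("ARD")
  tips <- tip_mat2(phy, c(2, 2, 1, 1), spec)
  Q <- build_q(spec, c(0.02, 0.02))
  marg <- marginal_reconstruct(phy, tips, Q, root_policy("fixed", 0),
                               include_tips = TRUE)
  tally <- count_transitions(marg, phy)
  gains <- tally$counts[tally$counts$from == "0" & tally$counts$to == "1", ]
  expect_equal(gains$max, 1)
  ab <- mrca_node(phy, c("A", "B"))
  stem <- which(phy$edge[, 2] == ab)
  expect_equal(tally$branches$child[tally$branches$to == "1"][1],
               phy$edge[stem, 2])
})

test_that("near-zero rates with uniform tips yield zero changes", {
  phy <- simulate_tree(20, height = 50, seed = 5)
  spec <- make_spec("ER")
  tips <- tip_mat2(phy, rep(1, 20), spec)
  marg <- marginal_reconstruct(phy, tips, build_q(spec, 1e-7),
                               include_tips = TRUE)
  tally <- count_transitions(marg, phy)
  expect_equal(tally$total_max, 0)
})

test_that("exact ties are flagged ambiguous, never called", {
  phy <- read_newick("(A:1,B:1);")
  spec <- make_spec("ER")
  tips <- tip_mat2(phy, c(1, 2), spec)
  marg <- marginal_reconstruct(phy, tips, build_q(spec, 0.2),
                               include_tips = TRUE)
  expect_equal(marg$p_0[marg$node == 3], 0.5, tolerance = 1e-12)
  tally <- count_transitions(marg, phy)
  expect_true(all(tally$branches$ambiguous))
  expect_equal(tally$total_min, 0) # ambiguous changes excluded from min
  expect_error(count_transitions(marg, phy, map_threshold = 0.4), "0.5")
})

test_that("ambiguity threshold splits the tally into a [min, max] range", {
  phy <- read_newick("(((A:1,B:1):8,C:9):1,D:10);")
  spec <- make_spec("ARD")
  tips <- tip_mat2(phy, c(2, 2, 1, 1), spec)
  Q <- build_q(spec, c(0.02, 0.02))
  marg <- marginal_reconstruct(phy, tips, Q, root_policy("fixed", 0),
                               include_tips = TRUE)
  strict <- count_transitions(marg, phy, map_threshold = 1)
  loose <- count_transitions(marg, phy, map_threshold = 0.51)
  expect_lte(strict$total_min, loose$total_min)
  expect_equal(strict$total_max, loose$total_max)
})

test_that("marginal exports produce readable artifacts", {
  inst <- rand_instance(5, ntip = 5, k = 2, R = 1, p_clamp = 0)
  marg <- marginal_reconstruct(inst$phy, inst$tips, inst$Q, inst$root,
                               include_tips = TRUE)
  f <- tempfile(fileext = ".csv")
  write_marginal_csv(marg, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(marg))
  s <- write_annotated_newick(inst$phy, marg)
  t2 <- read_newick(s)
  expect_equal(sort(t2$tip.label), sort(inst$phy$tip.label))
  expect_true(any(grepl("MAP=", t2$node.label)))
})
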