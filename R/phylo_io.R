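# Tree and trait-table input/output, plus the tree queries (mrca, pruning,
# tip/trait matching) used by every downstream stage. Trees are held as
# ape "phylo" objects; branch lengths are interpreted as absolute time.

# -- newick syntax pre-check ---------------------------------------------

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quote_char <- ""
  quote_pos <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (quote_char != "") {
      if (ch == quote_char) quote_char <- ""
      next
    }
    if (ch == "'" || ch == "\"") {
      quote_char <- ch
      quote_pos <- i
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error: unmatched ')' at character ", i,
             call. = FALSE)
      }
    }
  }
  if (quote_char != "") {
    stop("newick parse error: unclosed quote opened at character ",
         quote_pos, call. = FALSE)
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' at end of input ",
         "(character ", length(chars), ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Replace quoted labels by placeholders so ape's reader never sees spaces
# or punctuation inside quotes; returns list(text=..., labels=named chr).
shield_quoted_labels <- function(text) {
  labels <- character(0)
  out <- character(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "'" || ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != ch) j <- j + 1L
      lab <- paste(chars[seq(i + 1L, length.out = max(0L, j - i - 1L))],
                   collapse = "")
      key <- sprintf("QLBL%dX", length(labels) + 1L)
      labels[key] <- lab
      out <- c(out, key)
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  list(text = paste(out, collapse = ""), labels = labels)
}

restore_labels <- function(labs, shield) {
  if (length(shield$labels) == 0 || is.null(labs)) return(labs)
  hit <- labs %in% names(shield$labels)
  labs[hit] <- unname(shield$labels[labs[hit]])
  labs
}

#' Read a rooted, time-calibrated tree from a Newick string
#'
#' Branch lengths are required on every non-root edge (the likelihood engine
#' needs a chronogram) and are kept to full input precision. Polytomies are
#' preserved, not resolved. Labels are compared after stripping surrounding
#' quotes and leading/trailing whitespace; underscores are left untouched
#' unless `normalize_underscores = TRUE`.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @param normalize_underscores map `_` to spaces in labels (off by default;
#'   silent conversion is a classic source of label-mismatch bugs).
#' @return an object of class `phylo`.
#' @export
read_newick <- function(text, normalize_underscores = FALSE) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick input", call. = FALSE)
  check_newick_syntax(text)
  shield <- shield_quoted_labels(text)
  phy <- tryCatch(ape::read.tree(text = shield$text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("newick parse error: ape could not parse the input",
                         call. = FALSE)
  phy$tip.label <- restore_labels(phy$tip.label, shield)
  phy$node.label <- restore_labels(phy$node.label, shield)
  phy$tip.label <- trimws(phy$tip.label)
  if (normalize_underscores) {
    phy$tip.label <- gsub("_", " ", phy$tip.label, fixed = TRUE)
  }
  validate_phylogeny(phy)
  phy
}

validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; a time-calibrated tree is required",
         call. = FALSE)
  }
  if (anyNA(phy$edge.length)) {
    stop("missing branch length on a non-root edge; ",
         "a time-calibrated tree is required", call. = FALSE)
  }
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  }
  if (any(!nzchar(phy$tip.label))) stop("empty tip label", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  # connected rooted tree: every non-root node appears exactly once as child
  n_all <- ape::Ntip(phy) + phy$Nnode
  child_counts <- tabulate(phy$edge[, 2], n_all)
  root <- root_id(phy)
  if (child_counts[root] != 0 || any(child_counts[-root] != 1)) {
    stop("edge matrix is not a rooted tree", call. = FALSE)
  }
  invisible(phy)
}

root_id <- function(phy) ape::Ntip(phy) + 1L

needs_quoting <- function(lab) {
  grepl("[]\\[():;,'\"[:space:]]", lab)
}

quote_label <- function(lab) {
  if (needs_quoting(lab)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else {
    lab
  }
}

#' Write a tree as a Newick string
#'
#' Inverse of [read_newick()]: `read_newick(write_newick(t))` reproduces the
#' topology, labels and branch lengths (lengths to full double precision).
#' Labels containing whitespace or Newick metacharacters are single-quoted.
#'
#' @param phy a `phylo` object.
#' @return a single Newick string terminated by `;`.
#' @export
write_newick <- function(phy) {
  validate_phylogeny(phy)
  ntip <- ape::Ntip(phy)
  n_all <- ntip + phy$Nnode
  kids <- vector("list", n_all)
  elen <- rep(NA_real_, n_all)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    c <- phy$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c)
    elen[c] <- phy$edge.length[e]
  }
  node_lab <- character(n_all)
  node_lab[seq_len(ntip)] <- vapply(phy$tip.label, quote_label, "")
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[!nzchar(nl)] <- ""
    node_lab[ntip + seq_len(phy$Nnode)] <-
      ifelse(nzchar(nl), vapply(nl, quote_label, ""), "")
  }
  fmt_len <- function(x) {
    if (is.na(x)) "" else paste0(":", sprintf("%.17g", x))
  }
  strs <- character(n_all)
  for (v in seq_len(ntip)) strs[v] <- paste0(node_lab[v], fmt_len(elen[v]))
  # internal nodes in the order they appear as children in postorder edges
  # (all of a node's descendants are serialized before the node itself),
  # then the root, which never appears as a child
  po_children <- phy$edge[postorder_edge_idx(phy), 2]
  root <- root_id(phy)
  internal_order <- c(po_children[po_children > ntip], root)
  for (v in internal_order) {
    strs[v] <- paste0("(", paste(strs[kids[[v]]], collapse = ","), ")",
                      node_lab[v], fmt_len(elen[v]))
  }
  paste0(strs[root], ";")
}

#' Read a per-species binary trait table from CSV
#'
#' The first column holds species labels; every further column is a binary
#' character coded `0`/`1` with a configurable missing code (default `"?"`).
#' An empty cell is an error, never a silent missing value.
#'
#' @param file path to a CSV file, or a literal CSV string (anything
#'   containing a newline is treated as text).
#' @param missing the missing-data code (default `"?"`).
#' @return a data.frame of class `trait_table`: column `species` plus one
#'   integer column (0/1/`NA`) per character; attribute `missing_count`
#'   holds the number of missing entries.
#' @export
read_trait_table <- function(file, missing = "?") {
  con <- if (grepl("\n", file, fixed = TRUE)) textConnection(file) else file
  df <- read.csv(con, colClasses = "character", check.names = FALSE,
                 strip.white = TRUE)
  if (ncol(df) < 2) stop("trait table needs a species column and at least ",
                         "one character column", call. = FALSE)
  names(df)[1] <- "species"
  df$species <- trimws(df$species)
  if (anyDuplicated(df$species)) {
    stop("duplicate species in trait table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "),
         call. = FALSE)
  }
  n_missing <- 0L
  for (j in seq(2, ncol(df))) {
    v <- trimws(df[[j]])
    bad <- !(v %in% c("0", "1", missing))
    if (any(bad)) {
      stop("invalid state '", v[bad][1], "' for character '", names(df)[j],
           "' in row ", which(bad)[1], " (species ",
           df$species[which(bad)[1]], "); allowed: 0, 1, ", missing,
           call. = FALSE)
    }
    n_missing <- n_missing + sum(v == missing)
    vi <- rep(NA_integer_, length(v))
    vi[v != missing] <- as.integer(v[v != missing])
    df[[j]] <- vi
  }
  attr(df, "missing_count") <- n_missing
  class(df) <- c("trait_table", class(df))
  df
}

#' Write a trait table to CSV
#'
#' @param traits a `trait_table` (or compatible data.frame).
#' @param file output path.
#' @param missing code used for `NA` entries.
#' @export
write_trait_table <- function(traits, file, missing = "?") {
  out <- as.data.frame(traits)
  for (j in seq(2, ncol(out))) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- missing
    out[[j]] <- v
  }
  write.csv(out, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Most recent common ancestor of a set of tips
#'
#' @param phy a `phylo` object.
#' @param tips character vector of tip labels (or integer tip indices).
#' @return the node id of the deepest node ancestral to all given tips; for
#'   a single tip, the tip itself.
#' @export
mrca_node <- function(phy, tips) {
  validate_phylogeny(phy)
  if (is.character(tips)) {
    idx <- match(tips, phy$tip.label)
    if (anyNA(idx)) {
      stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(tips)
    if (any(idx < 1 | idx > ape::Ntip(phy))) {
      stop("tip index out of range", call. = FALSE)
    }
  }
  idx <- unique(idx)
  if (length(idx) == 1) return(idx)
  ape::getMRCA(phy, idx)
}

#' Extract the subtree rooted at an internal node
#'
#' Branch lengths within the clade are preserved exactly; the clade root
#' becomes the new tree's root (its stem branch is dropped).
#'
#' @param phy a `phylo` object.
#' @param node internal node id (> number of tips).
#' @return a `phylo` object.
#' @export
prune_to_clade <- function(phy, node) {
  validate_phylogeny(phy)
  ntip <- ape::Ntip(phy)
  if (node <= ntip) stop("cannot prune to a tip; node must be internal",
                         call. = FALSE)
  if (node > ntip + phy$Nnode) stop("node id out of range", call. = FALSE)
  if (node == root_id(phy)) return(phy)
  ape::extract.clade(phy, node)
}

#' Align a tree with a trait table
#'
#' Tips absent from the trait table are kept and treated as missing data
#' (with a warning); trait rows for species absent from the tree are dropped
#' (with a warning). Errors if the intersection is empty.
#'
#' @param phy a `phylo` object.
#' @param traits a `trait_table`.
#' @return a list with `tree`, `traits` (rows aligned to `phy$tip.label`,
#'   `NA` states for tips without data), `tips_without_traits`, and
#'   `dropped_species`.
#' @export
match_tree_and_traits <- function(phy, traits) {
  validate_phylogeny(phy)
  common <- intersect(phy$tip.label, traits$species)
  if (length(common) == 0) {
    stop("no overlap between tree tip labels and trait table species",
         call. = FALSE)
  }
  extra <- setdiff(traits$species, phy$tip.label)
  absent <- setdiff(phy$tip.label, traits$species)
  if (length(extra) > 0) {
    warning(length(extra), " trait row(s) without a matching tip dropped: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "", call. = FALSE)
  }
  if (length(absent) > 0) {
    warning(length(absent), " tip(s) without trait data treated as missing: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "", call. = FALSE)
  }
  aligned <- data.frame(species = phy$tip.label, stringsAsFactors = FALSE)
  idx <- match(phy$tip.label, traits$species)
  for (j in seq(2, ncol(traits))) {
    aligned[[names(traits)[j]]] <- traits[[j]][idx]
  }
  class(aligned) <- c("trait_table", class(aligned))
  list(tree = phy, traits = aligned,
       tips_without_traits = absent, dropped_species = extra)
}

# edge indices in preorder: every edge appears before all edges in the
# subtree below it; works for polytomies and degree-2 (singleton) nodes
preorder_edge_idx <- function(phy) {
  edge <- phy$edge
  kids_e <- vector("list", ape::Ntip(phy) + phy$Nnode)
  for (e in seq_len(nrow(edge))) {
    kids_e[[edge[e, 1]]] <- c(kids_e[[edge[e, 1]]], e)
  }
  out <- integer(nrow(edge))
  stack <- root_id(phy)
  n <- 0L
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (e in kids_e[[v]]) {
      n <- n + 1L
      out[n] <- e
      stack <- c(stack, edge[e, 2])
    }
  }
  out
}

# postorder: every edge after all edges below it (reverse preorder)
postorder_edge_idx <- function(phy) rev(preorder_edge_idx(phy))

# depth of every node measured from the root (root = 0)
node_depths <- function(phy) {
  n_all <- ape::Ntip(phy) + phy$Nnode
  depth <- numeric(n_all)
  for (e in preorder_edge_idx(phy)) {
    depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + phy$edge.length[e]
  }
  depth
}
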