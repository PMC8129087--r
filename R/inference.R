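# Maximum-likelihood fitting with multi-start optimization in log-rate
# space, AICc model comparison and Akaike weights.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)` with `n` the number of
#' terminal taxa of the tree analysed.
#'
#' @param lnL maximized log-likelihood.
#' @param k_free number of free parameters.
#' @param n sample size (terminal taxa); must exceed `k_free + 1`.
#' @return the AICc value, unrounded.
#' @export
aicc <- function(lnL, k_free, n) {
  stopifnot(is.finite(lnL), k_free >= 0)
  if (n <= k_free + 1) {
    stop("AICc undefined: need n > k_free + 1 (n = ", n, ", k = ", k_free,
         ")", call. = FALSE)
  }
  -2 * lnL + 2 * k_free + (2 * k_free * (k_free + 1)) / (n - k_free - 1)
}

# crude Fitch parsimony change count on observed states (missing tips and
# hidden categories ignored); seeds the heuristic starting rate
parsimony_changes <- function(phy, tips, spec) {
  ntip <- ape::Ntip(phy)
  obs_of <- rep(seq_len(spec$k), spec$R)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    s <- unique(obs_of[tips[i, ] > 0])
    sets[[i]] <- if (length(s) == spec$k) seq_len(spec$k) else s
  }
  changes <- 0L
  po_edge <- phy$edge[postorder_edge_idx(phy), , drop = FALSE]
  kids <- split(po_edge[, 2], po_edge[, 1])
  order_nodes <- c(unique(po_edge[, 2][po_edge[, 2] > ntip]), root_id(phy))
  for (v in order_nodes) {
    inter <- NULL
    uni <- NULL
    first <- TRUE
    for (k in kids[[as.character(v)]]) {
      sk <- sets[[k]]
      if (first) {
        inter <- sk
        uni <- sk
        first <- FALSE
      } else {
        inter <- intersect(inter, sk)
        uni <- union(uni, sk)
      }
    }
    if (length(inter) > 0) {
      sets[[v]] <- inter
    } else {
      sets[[v]] <- uni
      changes <- changes + 1L
    }
  }
  changes
}

# cheap content fingerprint so model comparisons can verify that fits share
# one dataset
dataset_fingerprint <- function(phy, tips) {
  key <- paste(c(write_newick(phy), rownames(tips),
                 format(tips, digits = 12)), collapse = "|")
  sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
}

#' Fit a model by maximum likelihood with multi-start optimization
#'
#' Optimizes the pruning log-likelihood over log-transformed rates within
#' bounds `[lower, upper]` (events per unit branch length). Start 1 is a
#' parsimony heuristic (all rates = observed changes / total tree length);
#' further starts are drawn log-uniformly. Deterministic given `seed`. All
#' per-start optima are stored so multimodality stays visible.
#'
#' @inheritParams prune_loglik
#' @param spec an `mk_spec`.
#' @param nstarts number of optimization starts (>= 1).
#' @param seed integer seed for the start draws.
#' @param lower,upper rate bounds (default `1e-9` and `1e2`).
#' @param init optional list of extra starting rate vectors (e.g. the MLE of
#'   a nested model) appended to the start list.
#' @return an object of class `mk_fit`: `spec`, `params` (MLE rates), `lnL`,
#'   `k_free`, `AICc` (with `n` = number of tips), `start_lnL`, `converged`
#'   (best two starts within `1e-4` lnL, or `nstarts = 1`), `seed`,
#'   `fingerprint`, plus the `root` and `clamps` used.
#' @export
fit_model <- function(phy, tips, spec, root = root_policy("flat"),
                      clamps = list(), nstarts = 10, seed = 1,
                      lower = 1e-9, upper = 1e2, init = NULL) {
  stopifnot(inherits(spec, "mk_spec"), nstarts >= 1)
  sel <- spec$index > 0
  idx <- spec$index[sel]
  Q0 <- matrix(0, spec$m, spec$m)
  st <- prune_setup(phy, tips, build_q(spec, rep(1, spec$k_free)),
                    root, clamps)
  po_len <- phy$edge.length[postorder_edge_idx(phy)]
  negloglik <- function(logr) {
    r <- exp(logr)
    Q0[sel] <- r[idx]
    diag(Q0) <- 0
    diag(Q0) <- -rowSums(Q0)
    ll <- cpp_prune(st$edge, cpp_branch_P(Q0, po_len), st$partials,
                    st$root_pi, st$root)
    if (!is.finite(ll)) 1e10 else -ll
  }
  total_len <- sum(phy$edge.length)
  heuristic <- max(parsimony_changes(phy, tips, spec), 1L) / total_len
  heuristic <- min(max(heuristic, lower * 10), upper / 10)
  set.seed(seed)
  starts <- list(rep(heuristic, spec$k_free))
  if (nstarts > 1) {
    for (i in seq_len(nstarts - 1)) {
      starts[[i + 1]] <- 10^runif(spec$k_free, -5, 1)
    }
  }
  for (v in init) starts[[length(starts) + 1]] <- pmin(pmax(v, lower), upper)
  fits <- lapply(starts, function(s) {
    tryCatch(nlminb(log(s), negloglik, lower = log(lower), upper = log(upper),
                    control = list(rel.tol = 1e-8, iter.max = 500)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("optimizer failed on every start", call. = FALSE)
  fits <- fits[ok]
  lnLs <- vapply(fits, function(f) -f$objective, 0)
  best <- which.max(lnLs)
  sorted <- sort(lnLs, decreasing = TRUE)
  converged <- length(lnLs) == 1 || (sorted[1] - sorted[2]) < 1e-4
  params <- exp(fits[[best]]$par)
  names(params) <- paste0("q", seq_len(spec$k_free))
  n <- ape::Ntip(phy)
  structure(list(spec = spec, params = params, lnL = lnLs[best],
                 k_free = spec$k_free, n = n,
                 # the small-sample correction is undefined for n <= k + 1
                 AICc = if (n > spec$k_free + 1) {
                   aicc(lnLs[best], spec$k_free, n)
                 } else {
                   NA_real_
                 },
                 nstarts = length(starts), start_lnL = lnLs,
                 converged = converged, seed = seed,
                 # fingerprint over the observed-state block only, so fits
                 # of hidden and non-hidden variants of one dataset compare
                 fingerprint = dataset_fingerprint(phy, st$partials[
                   seq_len(ape::Ntip(phy)), seq_len(spec$k), drop = FALSE]),
                 root = root, clamps = clamps),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit: ", x$spec$family, " (k_free = ", x$k_free, ", n = ", x$n,
      ")\n", sep = "")
  cat("  lnL = ", format(x$lnL, digits = 8), ",  AICc = ",
      format(x$AICc, digits = 8), "\n", sep = "")
  cat("  rates:", format(x$params, digits = 4), "\n")
  cat("  starts = ", x$nstarts, ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Compare fitted models by AICc
#'
#' Produces the standard comparison table: models sorted by ascending AICc
#' with `dAICc = AICc - min(AICc)` and Akaike weights
#' `w_i = exp(-dAICc_i/2) / sum_j exp(-dAICc_j/2)`.
#'
#' @param fits a (optionally named) list of `mk_fit` objects on the same
#'   dataset (verified via a dataset fingerprint).
#' @return a data.frame of class `mk_comparison` with columns `model`,
#'   `neg_lnL`, `k`, `AICc`, `dAICc`, `weight`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "mk_fit")))
  fps <- vapply(fits, function(f) f$fingerprint, 0)
  if (length(unique(fps)) > 1) {
    stop("fits were computed on different datasets", call. = FALSE)
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$spec$family, "")
  nm[!nzchar(nm)] <- vapply(fits[!nzchar(nm)], function(f) f$spec$family, "")
  tab <- data.frame(model = nm,
                    neg_lnL = -vapply(fits, function(f) f$lnL, 0),
                    k = vapply(fits, function(f) as.integer(f$k_free), 0L),
                    AICc = vapply(fits, function(f) f$AICc, 0),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), ]
  tab$dAICc <- tab$AICc - min(tab$AICc)
  rel <- exp(-tab$dAICc / 2)
  tab$weight <- rel / sum(rel)
  rownames(tab) <- NULL
  class(tab) <- c("mk_comparison", "data.frame")
  tab
}
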