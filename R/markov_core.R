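# Declarative construction of constrained and hidden-rate generator (Q)
# matrices. A model spec maps every allowed off-diagonal cell of the expanded
# (observed state x rate category) generator to a free-parameter index;
# structural zeros stay exactly zero. Expanded states are ordered
# category-major: all observed states of category R1, then of R2. For joint
# two-trait models (k = 4) the observed order is fixed as
# (0,0), (0,1), (1,0), (1,1) and simultaneous changes of both traits are
# structurally disallowed.

joint_labels <- c("0,0", "0,1", "1,0", "1,1")

# off-diagonal cells reachable in one step: any for k = 2, single-trait
# changes only for k = 4
allowed_cells <- function(k) {
  if (k == 2) {
    cbind(from = c(1L, 2L), to = c(2L, 1L))
  } else {
    # states (habitat, gland): 1=(0,0) 2=(0,1) 3=(1,0) 4=(1,1);
    # one-trait moves: 1<->2, 3<->4 (gland), 1<->3, 2<->4 (habitat)
    cbind(from = c(1L, 2L, 1L, 3L, 2L, 4L, 3L, 4L),
          to   = c(2L, 1L, 3L, 1L, 4L, 2L, 4L, 3L))
  }
}

# per-category index matrix (k x k, 0 on diagonal and structural zeros)
category_index <- function(family, k) {
  cells <- allowed_cells(k)
  # canonical cell order: by row, then column
  ord <- order(cells[, "from"], cells[, "to"])
  cells <- cells[ord, , drop = FALSE]
  idx <- matrix(0L, k, k)
  if (family == "ER") {
    idx[cells] <- 1L
  } else if (family == "ARD") {
    idx[cells] <- seq_len(nrow(cells))
  } else if (family == "IND") {
    if (k != 4) stop("IND is defined for joint (k = 4) models", call. = FALSE)
    # one rate per trait-direction, shared across the other trait's states
    idx[1, 3] <- idx[2, 4] <- 1L  # habitat 0 -> 1
    idx[3, 1] <- idx[4, 2] <- 2L  # habitat 1 -> 0
    idx[1, 2] <- idx[3, 4] <- 3L  # gland 0 -> 1
    idx[2, 1] <- idx[4, 3] <- 4L  # gland 1 -> 0
  } else if (family == "ARD_loss") {
    if (k != 4) stop("ARD_loss is defined for joint (k = 4) models",
                     call. = FALSE)
    idx[cells] <- seq_len(nrow(cells))
    # gland loss rate independent of habitat: (0,1)->(0,0) == (1,1)->(1,0)
    idx[4, 3] <- idx[2, 1]
    idx <- renumber_index(idx)
  } else {
    stop("unknown model family: ", family, call. = FALSE)
  }
  idx
}

renumber_index <- function(idx) {
  used <- sort(unique(idx[idx > 0]))
  idx[idx > 0] <- match(idx[idx > 0], used)
  idx
}

expanded_labels <- function(k, R) {
  obs <- if (k == 2) c("0", "1") else joint_labels
  if (R == 1) return(obs)
  as.vector(vapply(seq_len(R), function(r) paste0(obs, "|R", r),
                   character(k)))
}

#' Construct a rate-matrix model specification
#'
#' Builds the parameter-sharing map for the named model families on a binary
#' trait (`k = 2`) or the joint coding of two binary traits (`k = 4`,
#' observed-state order `(0,0), (0,1), (1,0), (1,1)`), optionally with two
#' hidden rate categories (`R = 2`). Families:
#'
#' * `ER` — all permitted transitions share one rate.
#' * `ARD` — every permitted transition has its own rate.
#' * `IND` (`k = 4`) — independent evolution of the two traits: one rate per
#'   trait and direction, shared across the other trait's states (4 rates).
#' * `ARD_loss` (`k = 4`) — ARD with the gland-loss rate tied across
#'   habitats: the `(0,1) -> (0,0)` rate equals the `(1,1) -> (1,0)` rate
#'   (7 rates).
#' * `custom` — an explicit `k x k` (or `kR x kR`) integer index matrix via
#'   `index`: 0 marks a structural zero, equal positive entries share a rate.
#'
#' With `R = 2`, `category_family` names the family of each category's
#' matrix (e.g. `c("ER", "ARD")`); category switches connect the same
#' observed state across categories, with either `distinct` rates for
#' R1->R2 and R2->R1 or one `shared` rate. Hidden-model parameter counts
#' follow: ER/ER (k=2, distinct) has 1+1+2 = 4 free rates; ER/ARD (k=2,
#' distinct) has 5; joint ER/ARD (k=4, shared) has 1+8+1 = 10.
#'
#' @param family one of `"ER"`, `"ARD"`, `"IND"`, `"ARD_loss"`, `"custom"`,
#'   or a compound like `"ER/ARD"` (equivalent to `R = 2` with
#'   `category_family = c("ER", "ARD")`).
#' @param k observed alphabet size, 2 or 4.
#' @param R number of hidden rate categories, 1 or 2.
#' @param category_family character vector of length `R` (hidden models).
#' @param category_switch `"distinct"` or `"shared"` category-switch rates.
#' @param index explicit integer index matrix for `family = "custom"`.
#' @return an object of class `mk_spec` with elements `k`, `R`, `m = k*R`,
#'   `index` (the `m x m` parameter map), `k_free`, `labels`, `obs_labels`.
#' @export
make_spec <- function(family = "ER", k = 2, R = 1, category_family = NULL,
                      category_switch = c("distinct", "shared"),
                      index = NULL) {
  category_switch <- match.arg(category_switch)
  if (!k %in% c(2, 4)) stop("k must be 2 or 4", call. = FALSE)
  if (!R %in% c(1, 2)) stop("R must be 1 or 2", call. = FALSE)
  if (grepl("/", family, fixed = TRUE)) {
    category_family <- strsplit(family, "/", fixed = TRUE)[[1]]
    if (length(category_family) != 2) {
      stop("compound family must name two categories", call. = FALSE)
    }
    R <- 2
  }
  m <- as.integer(k * R)
  if (identical(family, "custom")) {
    if (is.null(index)) stop("custom spec requires an index matrix",
                             call. = FALSE)
    index <- as.matrix(index)
    if (nrow(index) == k && R == 2) {
      index <- expand_hidden(index, index, k, category_switch)
    }
    if (!all(dim(index) == m)) stop("index matrix must be ", m, " x ", m,
                                    call. = FALSE)
    storage.mode(index) <- "integer"
    diag(index) <- 0L
    index <- renumber_index(index)
    fam_name <- "custom"
  } else if (R == 1) {
    index <- category_index(family, k)
    fam_name <- family
  } else {
    if (is.null(category_family)) category_family <- rep(family, 2)
    idx1 <- category_index(category_family[1], k)
    idx2 <- category_index(category_family[2], k)
    index <- expand_hidden(idx1, idx2, k, category_switch)
    fam_name <- paste(category_family, collapse = "/")
  }
  labels <- expanded_labels(k, R)
  dimnames(index) <- list(labels, labels)
  spec <- structure(list(family = fam_name, k = as.integer(k),
                         R = as.integer(R), m = m, index = index,
                         k_free = max(index), labels = labels,
                         obs_labels = expanded_labels(k, 1),
                         category_switch = if (R == 2) category_switch),
                    class = "mk_spec")
  spec
}

# block-diagonal category matrices plus category-switch cells linking the
# same observed state; a switch never changes the observed state
expand_hidden <- function(idx1, idx2, k, category_switch) {
  off1 <- max(idx1)
  idx2s <- idx2
  idx2s[idx2s > 0] <- idx2s[idx2s > 0] + off1
  m <- 2L * k
  index <- matrix(0L, m, m)
  index[seq_len(k), seq_len(k)] <- idx1
  index[k + seq_len(k), k + seq_len(k)] <- idx2s
  p <- off1 + max(idx2)
  for (s in seq_len(k)) {
    index[s, k + s] <- p + 1L                                   # R1 -> R2
    index[k + s, s] <- if (category_switch == "shared") p + 1L else p + 2L
  }
  index
}

#' @export
print.mk_spec <- function(x, ...) {
  cat("Mk model spec: ", x$family,
      " (k = ", x$k, ", rate categories = ", x$R,
      ", free parameters = ", x$k_free, ")\n", sep = "")
  cat("parameter index matrix (0 = structural zero):\n")
  print(x$index)
  invisible(x)
}

#' Build a generator matrix from a spec and parameter vector
#'
#' Fills the parameter-sharing map with rates (events per unit branch
#' length), sets structural zeros to exactly zero and the diagonal to minus
#' the row sum.
#'
#' @param spec an `mk_spec`.
#' @param params numeric vector of length `spec$k_free`, all finite and > 0.
#' @return a `spec$m` x `spec$m` generator of class `rate_matrix` carrying
#'   the spec as attribute `spec`.
#' @export
build_q <- function(spec, params) {
  stopifnot(inherits(spec, "mk_spec"))
  params <- as.numeric(params)
  if (length(params) != spec$k_free) {
    stop("expected ", spec$k_free, " parameters, got ", length(params),
         call. = FALSE)
  }
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("rates must be finite and strictly positive", call. = FALSE)
  }
  Q <- matrix(0, spec$m, spec$m, dimnames = dimnames(spec$index))
  sel <- spec$index > 0
  Q[sel] <- params[spec$index[sel]]
  diag(Q) <- -rowSums(Q)
  structure(Q, spec = spec, class = c("rate_matrix", "matrix"))
}

q_spec <- function(Q) {
  spec <- attr(Q, "spec")
  if (is.null(spec)) {
    # bare matrix: treat every state as observed, single category
    m <- nrow(Q)
    spec <- structure(list(family = "custom", k = m, R = 1L, m = m,
                           index = NULL, k_free = NA_integer_,
                           labels = as.character(seq_len(m) - 1L),
                           obs_labels = as.character(seq_len(m) - 1L)),
                      class = "mk_spec")
  }
  spec
}

#' Transition probabilities over a branch
#'
#' Computes `P(t) = exp(Qt)` (eigendecomposition fast path, Pade
#' scaling-and-squaring fallback). Entries are clamped into `[0, 1]` and
#' rows renormalised to sum to one.
#'
#' @param Q a generator matrix (rows summing to zero).
#' @param t branch duration, finite and >= 0.
#' @return a stochastic matrix of the same dimension as `Q`.
#' @export
transition_prob <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("t must be a single finite value >= 0", call. = FALSE)
  }
  P <- cpp_branch_P(unclass(Q), t)[, , 1]
  dimnames(P) <- dimnames(Q)
  P
}
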