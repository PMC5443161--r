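# Ternary classification strategies: direct multiclass (MCS) and the four
# binary decompositions (OAO with pairwise coupling, OAA, DBT, DDAG), with
# balanced subproblem construction and deterministic routing.

TERNARY_METHODS <- c("mcs", "oao", "oaa", "dbt", "ddag")

ddag_order_vec <- function(ddag_order) {
  ddag_order <- match.arg(toupper(ddag_order), c("RIL", "ILR", "RLI"))
  strsplit(ddag_order, "")[[1]]
}

subsample_idx <- function(idx, n, seed) {
  if (length(idx) <= n) return(idx)
  sort(with_seed(seed, sample(idx, n)))
}

# Subsample a pool of epochs down to n, keeping the pool's class mix
# (largest-remainder rounding of the proportional allocation).
subsample_proportional <- function(labels, idx, n, seed) {
  if (length(idx) <= n) return(idx)
  cls <- canonical_classes(labels[idx])
  exact <- vapply(cls, function(cl) n * sum(labels[idx] == cl) / length(idx),
                  numeric(1))
  take <- floor(exact)
  rem <- n - sum(take)
  if (rem > 0) {
    extra <- order(exact - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  out <- integer(0)
  for (i in seq_along(cls)) {
    out <- c(out, subsample_idx(intersect(which(labels == cls[i]), idx),
                                take[i], derive_seed(seed, "prop", cls[i])))
  }
  sort(out)
}

#' Build the balanced binary (or ternary) training subproblems of a scheme
#'
#' For each class pair or superclass split required by the chosen
#' decomposition, selects the relevant epochs and balances the two sides by
#' subsampling the larger side down to the smaller, without replacement,
#' seeded. Superclass pools (`A` = all-others in OAA, `M` = movement in DBT)
#' are subsampled class-proportionally. The direct multiclass scheme (`mcs`)
#' yields one ternary problem with every class subsampled to the smallest
#' class count.
#'
#' @param method One of `"mcs"`, `"oao"`, `"oaa"`, `"dbt"`, `"ddag"`.
#' @param train Training `epoch_set` containing all three classes.
#' @param seed Integer seed for the subsampling draws.
#' @return Named list of problems; each has `id`, `classes` (the two labels
#'   the node separates, in canonical order) and `es`, the balanced
#'   `epoch_set` whose labels are the node labels.
#' @export
build_binary_problems <- function(method, train, seed = 1L) {
  method <- match.arg(method, TERNARY_METHODS)
  y <- train$labels
  present <- canonical_classes(y)
  if (!all(CLASS_ORDER %in% present)) {
    stop("all three classes (R, I, L) must be present; found: ",
         paste(present, collapse = ", "))
  }
  if (any(vapply(CLASS_ORDER, function(cl) sum(y == cl), integer(1)) == 0L)) {
    stop("class with zero epochs")
  }
  pair_problem <- function(a, b) {
    ia <- which(y == a)
    ib <- which(y == b)
    n <- min(length(ia), length(ib))
    ia <- subsample_idx(ia, n, derive_seed(seed, "pair", a, b, a))
    ib <- subsample_idx(ib, n, derive_seed(seed, "pair", a, b, b))
    idx <- sort(c(ia, ib))
    cls <- canonical_classes(c(a, b))
    list(id = paste(cls, collapse = "-"), classes = cls,
         es = subset_epochs(train, idx))
  }
  super_problem <- function(target, pool_classes, pool_label, id) {
    it <- which(y == target)
    ip <- which(y %in% pool_classes)
    n <- min(length(it), length(ip))
    it <- subsample_idx(it, n, derive_seed(seed, id, "target"))
    ip <- subsample_proportional(y, ip, n, derive_seed(seed, id, "pool"))
    idx <- sort(c(it, ip))
    labs <- ifelse(y[idx] == target, target, pool_label)
    list(id = id, classes = canonical_classes(c(target, pool_label)),
         es = subset_epochs(train, idx, labels = labs))
  }
  probs <- switch(
    method,
    mcs = {
      n <- min(vapply(CLASS_ORDER, function(cl) sum(y == cl), integer(1)))
      idx <- sort(unlist(lapply(CLASS_ORDER, function(cl) {
        subsample_idx(which(y == cl), n, derive_seed(seed, "mcs", cl))
      })))
      list(list(id = "R-I-L", classes = CLASS_ORDER,
                es = subset_epochs(train, idx)))
    },
    oao = ,
    ddag = list(pair_problem("R", "I"), pair_problem("L", "I"),
                pair_problem("R", "L")),
    oaa = list(super_problem("R", c("I", "L"), "A", "R-A"),
               super_problem("I", c("L", "R"), "A", "I-A"),
               super_problem("L", c("R", "I"), "A", "L-A")),
    dbt = list(super_problem("I", c("L", "R"), "M", "I-M"),
               pair_problem("R", "L"))
  )
  names(probs) <- vapply(probs, `[[`, character(1), "id")
  probs
}

#' Couple pairwise class probabilities into a single posterior
#'
#' Given a matrix `r` with `r[i, j]` the estimated probability of class `i`
#' against class `j` (so `r[i, j] + r[j, i] = 1`), finds the probability
#' vector `p` on the simplex minimizing
#' `sum_{i<j} (r[j, i] p_i - r[i, j] p_j)^2` — the second pairwise-coupling
#' formulation of Wu, Lin and Weng — by its standard fixed-point iteration,
#' which converges to the constrained least-squares solution with
#' nonnegative components.
#'
#' @param r Square matrix of pairwise probabilities (diagonal unused),
#'   rows/columns optionally named by class.
#' @param max_iter,tol Iteration controls.
#' @return Named probability vector over the classes.
#' @export
pairwise_couple <- function(r, max_iter = 10000L, tol = 1e-14) {
  r <- as.matrix(r)
  m <- nrow(r)
  stopifnot(m == ncol(r), m >= 2)
  off <- row(r) != col(r)
  if (max(abs(r[off] + t(r)[off] - 1)) > 1e-6) {
    stop("r[i,j] + r[j,i] must equal 1")
  }
  q <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) {
        q[i, i] <- sum(r[-i, i]^2)
      } else {
        q[i, j] <- -r[j, i] * r[i, j]
      }
    }
  }
  p <- rep(1 / m, m)
  for (it in seq_len(max_iter)) {
    qp <- as.numeric(q %*% p)
    pqp <- sum(p * qp)
    if (max(abs(qp - pqp)) < tol) break
    for (t in seq_len(m)) {
      qtt <- if (q[t, t] > 0) q[t, t] else 1e-12
      p[t] <- (-sum(q[t, -t] * p[-t]) + sum(p * as.numeric(q %*% p))) / qtt
      p <- p / sum(p)
    }
  }
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- rownames(r)
  p
}

#' Route a test case through a decision directed acyclic graph
#'
#' For the ordered class list `c(c1, c2, c3)`, the root node runs the
#' `c1`-vs-`c3` classifier; the losing class is eliminated and the next node
#' compares the remaining first and last candidates, until one class
#' survives. The `"RIL"` structure therefore has root R-vs-L. Ties resolve
#' toward the earlier class in canonical (R, I, L) order.
#'
#' @param order Character vector, a permutation of `c("R", "I", "L")` (or the
#'   string `"RIL"`/`"ILR"`/`"RLI"`).
#' @param pair_prob Function `(a, b) -> P(a | {a, b})` giving the binary
#'   posterior for class `a` at the node comparing `a` and `b`.
#' @return The surviving class label.
#' @export
ddag_route <- function(order, pair_prob) {
  if (length(order) == 1L) order <- ddag_order_vec(order)
  stopifnot(setequal(order, CLASS_ORDER))
  cand <- order
  while (length(cand) > 1L) {
    a <- cand[1L]
    b <- cand[length(cand)]
    pa <- pair_prob(a, b)
    winner <- if (pa > 0.5) a
    else if (pa < 0.5) b
    else canonical_classes(c(a, b))[1L]
    cand <- if (winner == a) cand[-length(cand)] else cand[-1L]
  }
  cand
}

#' Route a test case through the directed binary tree
#'
#' The root discriminates idle from movement; a movement decision is refined
#' into left vs right at the second node.
#'
#' @param p_idle Posterior probability of idle at the root (vs movement).
#' @param p_right Posterior probability of right at the L-R node (vs left).
#' @return `"I"`, `"R"` or `"L"`.
#' @export
dbt_route <- function(p_idle, p_right) {
  if (p_idle >= 0.5) return("I") # tie at root: idle precedes movement
  if (p_right >= 0.5) "R" else "L"
}

#' Combine one-vs-all posteriors by maximum probability
#'
#' @param target_probs Named numeric vector: for each class, the posterior of
#'   that class from its own one-vs-all classifier.
#' @return The label with the highest probability; ties resolve to the
#'   earlier class in canonical order.
#' @export
oaa_combine <- function(target_probs) {
  p <- target_probs[canonical_classes(names(target_probs))]
  argmax_label(p)
}
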