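# Gini recursive partitioning over binary claims predictors.
#
# Hand-rolled rather than delegated: the splitting rule (Gini decrease),
# leaf tie rule (tie labels screening) and split tie rule (first variable
# in the configured order) are pinned down exactly so repeated runs and
# re-implementations agree node for node; rpart is used as an independent
# cross-check in the test suite.

gini_impurity <- function(n0, n1) {
  n <- n0 + n1
  if (n == 0) return(0)
  1 - (n0 / n)^2 - (n1 / n)^2
}

tree_leaf <- function(n0, n1) {
  list(leaf = TRUE,
       label = label_string(as.integer(n1 >= n0)),  # tie -> screening
       n = n0 + n1, counts = c(non_screening = n0, screening = n1))
}

grow_tree <- function(Xm, y, idx, used, vars, min_node, min_decrease) {
  n1 <- sum(y[idx]); n0 <- length(idx) - n1
  if (n0 == 0 || n1 == 0 || length(idx) < min_node) return(tree_leaf(n0, n1))
  g_parent <- gini_impurity(n0, n1)
  best_var <- NULL; best_dec <- min_decrease
  for (v in setdiff(vars, used)) {
    x <- Xm[idx, v]
    nl <- sum(x == 0L); nr <- length(idx) - nl
    if (nl == 0 || nr == 0) next
    n1l <- sum(y[idx][x == 0L]); n1r <- n1 - n1l
    dec <- g_parent -
      (nl / length(idx)) * gini_impurity(nl - n1l, n1l) -
      (nr / length(idx)) * gini_impurity(nr - n1r, n1r)
    if (dec > best_dec + 1e-12) { best_var <- v; best_dec <- dec }
  }
  if (is.null(best_var)) return(tree_leaf(n0, n1))
  x <- Xm[idx, best_var]
  list(leaf = FALSE, var = best_var, n = n0 + n1,
       counts = c(non_screening = n0, screening = n1),
       left = grow_tree(Xm, y, idx[x == 0L], c(used, best_var), vars, min_node, min_decrease),
       right = grow_tree(Xm, y, idx[x == 1L], c(used, best_var), vars, min_node, min_decrease))
}

#' Fit a classification tree by recursive partitioning
#'
#' Greedy binary tree over 0/1 predictors: at each node the split
#' maximizing the Gini impurity decrease is chosen (ties to the earlier
#' variable in `variables`; a variable is never reused on one path);
#' growth stops when a node is pure, smaller than `min_node`, or no split
#' decreases impurity by more than `min_decrease`. Leaves take the
#' majority class, ties labelling screening. By default age and sex are
#' excluded and the tree is left unpruned; `prune = TRUE` applies
#' cost-complexity pruning with the complexity penalty chosen by k-fold
#' cross-validated misclassification.
#'
#' @inheritParams fit_logistic
#' @param variables Binary predictor names; defaults to every feature
#'   column except `patient_id`, `age`, `sex`.
#' @param min_node Minimum node size eligible for splitting.
#' @param min_decrease Minimum Gini decrease for a split.
#' @param prune Apply cost-complexity pruning?
#' @param cv_folds,seed Folds and fold-assignment seed for pruning.
#' @return Object of class `screenlca_tree`: nested `root` node plus the
#'   settings.
#' @export
fit_tree <- function(features, outcome,
                     variables = setdiff(names(features), c("patient_id", "age", "sex")),
                     min_node = 20, min_decrease = 0,
                     prune = FALSE, cv_folds = 10, seed = 1L) {
  y <- as_binary_label(outcome, "outcome")
  if (nrow(features) == 0) stop("empty feature table", call. = FALSE)
  Xm <- as.matrix(features[variables])
  if (!all(Xm %in% c(0, 1))) stop("tree predictors must be binary 0/1", call. = FALSE)
  storage.mode(Xm) <- "integer"
  root <- grow_tree(Xm, y, seq_along(y), character(), variables, min_node, min_decrease)
  if (prune) root <- cv_prune(Xm, y, variables, min_node, min_decrease, cv_folds, seed)
  structure(list(root = root, variables = variables, min_node = min_node,
                 min_decrease = min_decrease, pruned = prune, n = length(y)),
            class = "screenlca_tree")
}

# ---- cost-complexity pruning -------------------------------------------

node_error <- function(node) min(node$counts)           # resubstitution errors at the node
subtree_error <- function(node) {
  if (node$leaf) return(node_error(node))
  subtree_error(node$left) + subtree_error(node$right)
}
n_leaves <- function(node) {
  if (node$leaf) return(1L)
  n_leaves(node$left) + n_leaves(node$right)
}

# smallest weakest-link value g(t) = (R(t) - R(T_t)) / (|leaves| - 1)
min_g <- function(node) {
  if (node$leaf) return(Inf)
  g <- (node_error(node) - subtree_error(node)) / (n_leaves(node) - 1)
  min(g, min_g(node$left), min_g(node$right))
}

collapse_at <- function(node, g_cut) {
  if (node$leaf) return(node)
  node$left <- collapse_at(node$left, g_cut)
  node$right <- collapse_at(node$right, g_cut)
  g <- (node_error(node) - subtree_error(node)) / (n_leaves(node) - 1)
  if (g <= g_cut + 1e-12) return(tree_leaf(node$counts[1], node$counts[2]))
  node
}

# prune weakest links until every remaining internal node has g > alpha
prune_at <- function(node, alpha) {
  repeat {
    g <- min_g(node)
    if (!is.finite(g) || g > alpha + 1e-12) return(node)
    node <- collapse_at(node, g)
  }
}

alpha_sequence <- function(node) {
  alphas <- 0
  while (!node$leaf) {
    g <- min_g(node)
    alphas <- c(alphas, g)
    node <- collapse_at(node, g)
  }
  unique(alphas)
}

cv_prune <- function(Xm, y, vars, min_node, min_decrease, cv_folds, seed) {
  full <- grow_tree(Xm, y, seq_along(y), character(), vars, min_node, min_decrease)
  alphas <- alpha_sequence(full)
  if (length(alphas) <= 1) return(full)
  # geometric midpoints between successive thresholds (standard CART)
  trial <- sqrt(pmax(alphas[-length(alphas)], 1e-12) * alphas[-1])
  trial <- c(0, trial, alphas[length(alphas)] + 1)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(cv_folds), length(y)))
  cv_err <- numeric(length(trial))
  for (f in seq_len(cv_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    sub <- grow_tree(Xm[tr, , drop = FALSE], y[tr], seq_along(tr),
                     character(), vars, min_node, min_decrease)
    for (a in seq_along(trial)) {
      pr <- prune_at(sub, trial[a])
      pred <- route_all(pr, Xm[te, , drop = FALSE])
      cv_err[a] <- cv_err[a] + sum(pred != y[te])
    }
  }
  prune_at(full, trial[which.min(cv_err)])
}

# ---- prediction ---------------------------------------------------------

route_all <- function(node, Xm) {
  out <- integer(nrow(Xm))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- as.integer(node$label == "screening")
      return()
    }
    x <- Xm[idx, node$var]
    route(node$left, idx[x == 0L])
    route(node$right, idx[x == 1L])
  }
  route(node, seq_len(nrow(Xm)))
  out
}

#' Classify patients with a fitted tree
#'
#' Routes each row deterministically to a leaf; classification depends only
#' on the variables along the row's path.
#'
#' @param tree A `screenlca_tree`.
#' @param features Feature table containing every split variable.
#' @return Character vector of "screening"/"non-screening" labels.
#' @export
tree_classify <- function(tree, features) {
  stopifnot(inherits(tree, "screenlca_tree"))
  used <- tree_variables(tree)
  missing_v <- setdiff(used, names(features))
  if (length(missing_v)) {
    stop("features missing split variables: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  Xm <- as.matrix(features[tree$variables[tree$variables %in% names(features)]])
  storage.mode(Xm) <- "integer"
  label_string(route_all(tree$root, Xm))
}

#' Variables used by a fitted tree, in first-split (pre-order) order
#' @param tree A `screenlca_tree`.
#' @return Character vector of split variable names.
#' @export
tree_variables <- function(tree) {
  acc <- character()
  walk <- function(node) {
    if (node$leaf) return()
    acc <<- c(acc, node$var)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  unique(acc)
}

#' @export
print.screenlca_tree <- function(x, ...) {
  show <- function(node, indent, branch) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s%s-> %s (%d/%d)\n", pad, branch, node$label,
                  node$counts[2], node$n))
    } else {
      cat(sprintf("%s%ssplit on %s (n=%d)\n", pad, branch, node$var, node$n))
      show(node$left, indent + 1, "[0] ")
      show(node$right, indent + 1, "[1] ")
    }
  }
  cat(sprintf("Recursive partitioning tree (%s, n=%d):\n",
              if (x$pruned) "pruned" else "unpruned", x$n))
  show(x$root, 0, "")
  invisible(x)
}
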