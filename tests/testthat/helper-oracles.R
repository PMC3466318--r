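# Independent brute-force oracles used across the parsimony and statistics
# tests. These deliberately avoid the package's own algorithms: loss counts
# come from exhaustive subset search, Fitch counts from exhaustive internal
# labelings, permutation p-values from explicit permutation matrices.

# all tips (indices) below each node, computed via ape only
oracle_tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  for (nd in (ntip + 1):(ntip + tree$Nnode)) {
    res[[nd]] <- unlist(ape::prop.part(tree)[nd - ntip])
  }
  # prop.part gives clades for internal nodes in node order
  res
}

# minimal number of loss edges explaining `pres` under a single gain at
# `origin`: exhaustive search over loss-edge subsets of increasing size
brute_dollo_losses <- function(tree, pres, origin) {
  ntip <- length(tree$tip.label)
  below <- oracle_tips_under(tree)
  clade <- below[[origin]]
  stopifnot(any(pres[clade]))
  # edges fully inside the origin clade (child node below origin)
  edges <- which(tree$edge[, 2] %in% setdiff(
    unlist(lapply(seq_along(below), function(i) {
      if (all(below[[i]] %in% clade)) i else NULL
    })), origin))
  absent_target <- setdiff(clade, clade[pres[clade]])
  covers <- lapply(edges, function(e) {
    intersect(below[[tree$edge[e, 2]]], clade)
  })
  check <- function(sel) {
    covered <- unique(unlist(covers[sel]))
    setequal(covered, absent_target)
  }
  if (length(absent_target) == 0) return(0L)
  for (k in 1:length(edges)) {
    for (sel in utils::combn(length(edges), k, simplify = FALSE)) {
      if (check(sel)) return(k)
    }
  }
  stop("no loss subset explains the pattern")
}

# exhaustive Fitch: minimise changes over all internal 0/1 labelings
brute_fitch <- function(tree, pres) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    states <- c(as.integer(pres),
                as.integer(intToBits(mask)[1:nint]))
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# brute-force origin scoring: minimum cost over all candidate origins
brute_origin_costs <- function(tree, pres, costs = c(gain = 1, loss = 1,
                                                     hgt = 1)) {
  below <- oracle_tips_under(tree)
  cands <- which(vapply(below, function(t) any(pres[t]), logical(1)))
  data.frame(
    origin_node = cands,
    cost = vapply(cands, function(nd) {
      nl <- brute_dollo_losses(tree, pres, nd)
      outside <- sum(pres) - sum(pres[below[[nd]]])
      h <- if (outside) costs[["hgt"]] * outside else 0
      costs[["gain"]] + costs[["loss"]] * nl + h
    }, numeric(1)))
}

# all permutations of 1..n as a matrix (rows = permutations)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_matrix(n - 1)
  do.call(rbind, lapply(1:n, function(i) {
    rest <- (1:n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# exact two-sided Spearman permutation p by explicit enumeration
oracle_spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r_obs <- cor(rx, ry)
  pm <- perm_matrix(length(y))
  rs <- apply(pm, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rs) >= abs(r_obs) - 1e-9)
}

# hand-rolled Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# maximal monochromatic subtree sizes by per-clade scan (independent of the
# package's postorder sweep)
brute_cluster_sizes <- function(tree, focal_flags, clade) {
  ntip <- length(tree$tip.label)
  below <- oracle_tips_under(tree)
  clade_tips <- below[[clade]]
  nodes <- which(vapply(below, function(t) {
    all(t %in% clade_tips) && all(focal_flags[t])
  }, logical(1)))
  parent_of <- function(nd) {
    i <- match(nd, tree$edge[, 2])
    if (is.na(i)) NA_integer_ else tree$edge[i, 1]
  }
  maximal <- nodes[vapply(nodes, function(nd) {
    if (nd == clade) return(TRUE)
    p <- parent_of(nd)
    is.na(p) || !(p %in% nodes) || !all(below[[p]] %in% clade_tips)
  }, logical(1))]
  # keep only nodes whose parent is not itself an all-focal node inside clade
  sort(vapply(maximal, function(nd) length(below[[nd]]), integer(1)),
       decreasing = TRUE)
}

root_node_of <- function(tree) length(tree$tip.label) + 1L

# random rooted binary tree with named tips
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_profile <- function(tree, seed, p_present = 0.5) {
  set.seed(seed)
  pres <- runif(length(tree$tip.label)) < p_present
  names(pres) <- tree$tip.label
  pres
}
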