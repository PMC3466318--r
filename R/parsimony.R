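#' Presence/absence profile of an architecture over species-tree leaves
#'
#' @param architecture architecture string the profile refers to.
#' @param presence named logical vector; names must be exactly the leaf
#'   labels of the species tree the profile will be used with.
#' @return A list of class `presence_profile`.
#' @export
presence_profile <- function(architecture, presence) {
  stopifnot(is.logical(presence), !is.null(names(presence)))
  structure(list(architecture = architecture, presence = presence),
            class = "presence_profile")
}

#' Build presence profiles from a census
#'
#' @param census an `arch_census`.
#' @param species all species (tree leaf labels); species absent from the
#'   census get `FALSE` everywhere.
#' @return Named list of [presence_profile()] objects, one per architecture.
#' @export
census_presence_profiles <- function(census, species) {
  archs <- sort(unique(census$architecture))
  out <- lapply(archs, function(a) {
    pres <- vapply(species, function(s) {
      any(census$species_id == s & census$architecture == a & census$count > 0)
    }, logical(1))
    presence_profile(a, setNames(pres, species))
  })
  setNames(out, archs)
}

# validate and align a profile with a tree; returns logical vector indexed by
# tip number
profile_on_tree <- function(tree, profile) {
  pres <- if (inherits(profile, "presence_profile")) profile$presence else profile
  stopifnot(is.logical(pres))
  if (is.null(names(pres))) {
    stopifnot(length(pres) == length(tree$tip.label))
    return(pres)
  }
  miss <- setdiff(tree$tip.label, names(pres))
  if (length(miss)) stop("profile lacks species: ",
                         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  unname(pres[tree$tip.label])
}

#' Count losses under a single-gain (Dollo) origin
#'
#' Under Dollo parsimony the architecture is gained exactly once, on the
#' branch leading to `origin`, and can only be lost thereafter. The minimal
#' number of independent losses explaining the leaf pattern equals the number
#' of maximal all-absent subtrees below the origin: each such subtree is
#' explained by one loss on its stem branch. Under a multifurcation, each
#' all-absent child subtree counts as one loss (unless the whole
#' multifurcating clade is absent, in which case the loss moves to its stem).
#'
#' @param tree a rooted [ape::phylo] species tree.
#' @param profile a [presence_profile()] or named logical vector over the
#'   tree's leaf labels.
#' @param origin origin node: integer node index, tip label, or internal
#'   node label. Defaults to the root.
#' @return A list with `n_absent_descendants` (absent leaves under the
#'   origin) and `n_losses` (minimal independent losses).
#' @export
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' p <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE)
#' dollo_loss_count(tr, p)  # 2 absent, 1 loss (the CD clade)
dollo_loss_count <- function(tree, profile, origin = NULL) {
  pres <- profile_on_tree(tree, profile)
  ntip <- length(tree$tip.label)
  origin <- if (is.null(origin)) root_node(tree) else resolve_node(tree, origin)
  under <- tips_under(tree)[[origin]]
  if (!any(pres[under])) {
    stop("origin node is not ancestral to any present leaf", call. = FALSE)
  }
  ch <- tree_children(tree)
  # all_absent flag per node, postorder
  all_absent <- logical(ntip + tree$Nnode)
  for (nd in tree_postorder(tree)) {
    all_absent[nd] <- if (nd <= ntip) !pres[nd] else all(all_absent[ch[[nd]]])
  }
  # count maximal all-absent subtrees in the clade rooted at `origin`
  n_losses <- 0L
  stack <- origin
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c0 in ch[[nd]]) {
      if (all_absent[c0]) n_losses <- n_losses + 1L
      else stack <- c(stack, c0)
    }
  }
  list(n_absent_descendants = sum(!pres[under]), n_losses = n_losses)
}

#' Fitch small-parsimony change count for a binary character
#'
#' Minimal number of state changes on a rooted tree explaining a binary leaf
#' pattern, with no gain-once constraint. Used as an internal cross-check on
#' the Dollo counts and in tests; multifurcations are handled by the
#' generalised (hard polytomy) Fitch rule via state-count minimisation.
#'
#' @inheritParams dollo_loss_count
#' @return Integer: the minimum number of changes.
#' @export
fitch_changes <- function(tree, profile) {
  pres <- profile_on_tree(tree, profile)
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  # Sankoff dynamic programme with unit costs (exact also on multifurcations)
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(0L, nrow = ntip + tree$Nnode, ncol = 2) # states: absent, present
  for (nd in tree_postorder(tree)) {
    if (nd <= ntip) {
      cost[nd, ] <- if (pres[nd]) c(INF, 0L) else c(0L, INF)
    } else {
      for (s in 1:2) {
        tot <- 0L
        for (c0 in ch[[nd]]) {
          tot <- tot + min(cost[c0, s], min(cost[c0, ]) + 1L)
        }
        cost[nd, s] <- tot
      }
    }
  }
  as.integer(min(cost[root_node(tree), ]))
}

#' Score and rank origin hypotheses for an architecture
#'
#' Every ancestor of at least one present leaf is a candidate origin. A
#' hypothesis places the single gain on the candidate's stem branch; absent
#' leaves inside the candidate's clade are explained by minimal independent
#' losses ([dollo_loss_count()]), and present leaves outside the clade by one
#' horizontal transfer each. Hypothesis cost is
#' `gain + loss * n_losses + hgt * n_recipients`. The returned list is sorted
#' by ascending cost, ties broken by fewer transfer recipients, then by node
#' index. With `hgt = Inf`, the best hypothesis degenerates to the Dollo
#' solution rooted at the MRCA of the present leaves.
#'
#' @inheritParams dollo_loss_count
#' @param costs named numeric vector with elements `gain`, `loss`, `hgt`
#'   (defaults all 1; the relative weighting is a modelling choice).
#' @return A data frame of class `origin_hypotheses` with columns
#'   `origin_node`, `origin_label`, `n_absent_descendants`, `n_losses`,
#'   `n_hgt`, `hgt_recipients` (comma-joined species), `cost`.
#' @export
evaluate_origin_hypotheses <- function(tree, profile,
                                       costs = c(gain = 1, loss = 1, hgt = 1)) {
  pres <- profile_on_tree(tree, profile)
  if (!any(pres)) stop("all-absent profile: no origin to evaluate", call. = FALSE)
  stopifnot(all(c("gain", "loss", "hgt") %in% names(costs)))
  ntip <- length(tree$tip.label)
  tu <- tips_under(tree)
  candidates <- which(vapply(tu, function(t) any(pres[t]), logical(1)))
  rows <- lapply(candidates, function(nd) {
    d <- dollo_loss_count(tree, pres, nd)
    outside <- setdiff(which(pres), tu[[nd]])
    hgt_term <- if (length(outside)) costs[["hgt"]] * length(outside) else 0
    cost <- costs[["gain"]] + costs[["loss"]] * d$n_losses + hgt_term
    data.frame(origin_node = nd,
               origin_label = node_label(tree, nd),
               n_absent_descendants = d$n_absent_descendants,
               n_losses = d$n_losses,
               n_hgt = length(outside),
               hgt_recipients = paste(tree$tip.label[outside], collapse = ","),
               cost = cost,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cost, out$n_hgt, out$origin_node), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("origin_hypotheses", "data.frame")
  out
}

node_label <- function(tree, nd) {
  ntip <- length(tree$tip.label)
  if (nd <= ntip) return(tree$tip.label[nd])
  if (!is.null(tree$node.label) && !is.na(tree$node.label[nd - ntip]) &&
        nzchar(tree$node.label[nd - ntip])) {
    return(tree$node.label[nd - ntip])
  }
  paste0("node", nd)
}

#' Most recent common ancestor of the present leaves
#'
#' @inheritParams dollo_loss_count
#' @return Integer node index.
#' @export
mrca_present <- function(tree, profile) {
  pres <- profile_on_tree(tree, profile)
  ids <- which(pres)
  if (length(ids) == 0) stop("all-absent profile", call. = FALSE)
  if (length(ids) == 1) return(ids)
  ape::getMRCA(tree, ids)
}
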