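#' Principal architecture bipartition of a gene tree
#'
#' Finds the internal edge whose induced tip bipartition best separates the
#' gene tree into two architecture-defined halves — the analogue of the "two
#' main branches" of a family tree split by a single ancestral fusion. The
#' score of an edge is the mean architecture purity of its two sides, where
#' the purity of a side is the frequency of its commonest architecture. Ties
#' are broken in favour of the more balanced split (larger smaller side),
#' then by the lexicographically smallest tip set.
#'
#' @param gtree an `annotated_gene_tree` (see [annotate_gene_tree()]); may be
#'   rooted or unrooted.
#' @return A list with `tips_a`, `tips_b` (protein ids), `arch_a`, `arch_b`
#'   (majority architecture of each side), `purity_a`, `purity_b`, `score`,
#'   and `edge` (the two node indices of the selected edge).
#' @export
principal_bipartition <- function(gtree) {
  stopifnot(inherits(gtree, "annotated_gene_tree"))
  arch <- gtree$tip.annotation$architecture
  if (length(unique(arch)) < 2) {
    stop("all tips share one architecture; no bipartition is meaningful",
         call. = FALSE)
  }
  ntip <- length(gtree$tip.label)
  tu <- tips_under(gtree)
  rootn <- root_node(gtree)
  internal <- gtree$edge[, 2] > ntip
  cand <- which(internal)
  # for a (possibly unrooted-style) phylo, each edge to an internal node
  # induces the bipartition tips_under(child) vs the rest
  purity <- function(idx) {
    tab <- table(arch[idx])
    list(p = max(tab) / length(idx), a = names(tab)[which.max(tab)])
  }
  best <- NULL
  for (e in cand) {
    child <- gtree$edge[e, 2]
    side_a <- tu[[child]]
    side_b <- setdiff(seq_len(ntip), side_a)
    if (length(side_a) < 1 || length(side_b) < 1) next
    pa <- purity(side_a); pb <- purity(side_b)
    score <- (pa$p + pb$p) / 2
    key_tips <- paste(sort(gtree$tip.label[side_a]), collapse = ",")
    rec <- list(score = score, min_side = min(length(side_a), length(side_b)),
                key = key_tips, edge = gtree$edge[e, ], side_a = side_a,
                side_b = side_b, pa = pa, pb = pb)
    if (is.null(best) ||
          score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
             (rec$min_side > best$min_side ||
                (rec$min_side == best$min_side && rec$key < best$key)))) {
      best <- rec
    }
  }
  list(
    tips_a = gtree$tip.annotation$protein_id[best$side_a],
    tips_b = gtree$tip.annotation$protein_id[best$side_b],
    arch_a = best$pa$a, arch_b = best$pb$a,
    purity_a = best$pa$p, purity_b = best$pb$p,
    score = best$score, edge = unname(best$edge)
  )
}

#' Census of monophyletic architecture clusters inside a clade
#'
#' Within a background clade of a gene tree, enumerates the maximal subtrees
#' whose tips all carry the focal architecture. Subtrees of size >= 2 are
#' monophyletic clusters; size-1 subtrees are isolated sequences. This is the
#' machinery behind statements like "N occurrences distributed in k
#' monophyletic groups and m isolated sequences".
#'
#' @param gtree an `annotated_gene_tree`.
#' @param focal focal architecture string.
#' @param clade background clade: node index or label; default the root
#'   (whole tree).
#' @return A list with `n_sequences`, `n_clusters`, `n_singletons`,
#'   `cluster_sizes` (sizes of all maximal focal subtrees, decreasing).
#'   Always `n_sequences == sum(cluster_sizes)` and
#'   `n_clusters + n_singletons == length(cluster_sizes)`.
#' @export
cluster_census <- function(gtree, focal, clade = NULL) {
  stopifnot(inherits(gtree, "annotated_gene_tree"))
  ntip <- length(gtree$tip.label)
  clade <- if (is.null(clade)) root_node(gtree) else resolve_node(gtree, clade)
  is_focal <- gtree$tip.annotation$architecture == focal
  ch <- tree_children(gtree)
  all_focal <- logical(ntip + gtree$Nnode)
  n_tips <- integer(ntip + gtree$Nnode)
  for (nd in tree_postorder(gtree)) {
    if (nd <= ntip) {
      all_focal[nd] <- is_focal[nd]
      n_tips[nd] <- 1L
    } else {
      all_focal[nd] <- length(ch[[nd]]) > 0 && all(all_focal[ch[[nd]]])
      n_tips[nd] <- sum(n_tips[ch[[nd]]])
    }
  }
  sizes <- integer(0)
  if (all_focal[clade]) {
    sizes <- n_tips[clade]
  } else {
    stack <- clade
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (c0 in ch[[nd]]) {
        if (all_focal[c0]) sizes <- c(sizes, n_tips[c0])
        else if (c0 > ntip) stack <- c(stack, c0)
      }
    }
  }
  sizes <- sort(sizes, decreasing = TRUE)
  list(n_sequences = sum(sizes),
       n_clusters = sum(sizes >= 2),
       n_singletons = sum(sizes == 1),
       cluster_sizes = sizes)
}
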