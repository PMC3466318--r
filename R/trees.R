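#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates the input and reports
#' parse failures with the character offset of the first unbalanced
#' parenthesis. Branch lengths and internal node labels are preserved;
#' parse/serialise round trips keep topology, labels and lengths.
#'
#' @param path path to a Newick file, or a literal Newick string ending in
#'   `";"`.
#' @return An [ape::phylo] object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2)n1:0.5,C:3);")
#' tr$tip.label
read_newick <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  depth <- cumsum((strsplit(txt, "")[[1]] == "(") -
                    (strsplit(txt, "")[[1]] == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    off <- if (any(depth < 0)) which(depth < 0)[1] else length(depth)
    stop("unbalanced parentheses in Newick input near character ", off,
         call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("failed to parse Newick input", call. = FALSE)
  }
  tr
}

#' Write a tree to Newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output path; if `NULL` the Newick string is returned.
#' @return The path (invisibly), or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Parse gene-tree tip annotations
#'
#' Gene-tree tips carry a species and an architecture, either embedded in the
#' tip label as `protein|species|architecture` or supplied as a sidecar table
#' with columns `protein_id`, `species_id`, `architecture`.
#'
#' @param tree an [ape::phylo] gene tree.
#' @param annotations optional data frame (or TSV path) with the three
#'   columns above; when `NULL`, labels are split on `"|"`.
#' @return The tree with an added `tip.annotation` data frame (one row per
#'   tip, in tip order: `protein_id`, `species_id`, `architecture`), class
#'   `annotated_gene_tree` prepended.
#' @export
annotate_gene_tree <- function(tree, annotations = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(annotations)) {
    parts <- strsplit(tree$tip.label, "|", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      stop("tip labels are not of the form protein|species|architecture; ",
           "supply a sidecar annotation table", call. = FALSE)
    }
    ann <- data.frame(protein_id = vapply(parts, `[`, "", 1),
                      species_id = vapply(parts, `[`, "", 2),
                      architecture = vapply(parts, `[`, "", 3),
                      stringsAsFactors = FALSE)
  } else {
    if (is.character(annotations) && length(annotations) == 1) {
      annotations <- read.delim(annotations, stringsAsFactors = FALSE,
                                comment.char = "#")
    }
    need <- c("protein_id", "species_id", "architecture")
    miss <- setdiff(need, names(annotations))
    if (length(miss)) stop("annotation table missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    idx <- match(tree$tip.label, annotations$protein_id)
    if (anyNA(idx)) stop("tips without annotation: ",
                         paste(head(tree$tip.label[is.na(idx)], 5),
                               collapse = ", "), call. = FALSE)
    ann <- annotations[idx, need]
    rownames(ann) <- NULL
  }
  tree$tip.annotation <- ann
  class(tree) <- c("annotated_gene_tree", class(tree))
  tree
}

#' Root a tree
#'
#' Algorithms downstream need rooted trees; drawings in comparative studies
#' are often unrooted. Species trees are rooted at an explicit outgroup or at
#' the midpoint; gene trees may additionally be rooted at the principal
#' architecture bipartition (see [principal_bipartition()]).
#'
#' @param tree an [ape::phylo].
#' @param method `"outgroup"`, `"midpoint"`.
#' @param outgroup tip label(s), required for `method = "outgroup"`.
#' @return A rooted [ape::phylo].
#' @export
root_tree <- function(tree, method = c("outgroup", "midpoint"),
                      outgroup = NULL) {
  method <- match.arg(method)
  if (method == "outgroup") {
    if (is.null(outgroup)) stop("outgroup rooting requires `outgroup`",
                                call. = FALSE)
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    unrooted_midpoint(tree)
  }
}

# node-midpoint rooting: root at the node of the longest tip-to-tip path
# nearest its midpoint (the root is placed at a node, not inside an edge;
# adequate here because rooting only orients the parsimony traversals)
unrooted_midpoint <- function(tree) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  ntip <- length(tree$tip.label)
  dt <- ape::dist.nodes(tree)
  tipd <- dt[seq_len(ntip), seq_len(ntip)]
  ij <- which(tipd == max(tipd), arr.ind = TRUE)[1, ]
  half <- tipd[ij[1], ij[2]] / 2
  path <- ape::nodepath(tree, from = ij[1], to = ij[2])
  along <- dt[ij[1], path]
  node <- path[which.min(abs(along - half))]
  if (node <= ntip) node <- path[which.min(abs(along - half)) + 1]
  ape::root(tree, node = node, resolve.root = TRUE)
}

# ---- internal rooted-tree utilities shared by the parsimony code ----

# list of children per node (index = node id); leaves have integer(0)
tree_children <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) ch[[i]] <- integer(0)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

# postorder node sequence (children before parents)
tree_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  c(tr$edge[, 2][!duplicated(tr$edge[, 2])], root_node(tree))
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

# tips (indices) under each node, as a list over all nodes
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  res <- vector("list", ntip + tree$Nnode)
  for (nd in tree_postorder(tree)) {
    if (nd <= ntip) res[[nd]] <- nd
    else res[[nd]] <- sort(unlist(res[ch[[nd]]]))
  }
  res
}

# resolve a node reference (integer index, tip label, or internal node label)
resolve_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1 || node > ntip + tree$Nnode) stop("node index out of range")
    return(node)
  }
  i <- match(node, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(node, tree$node.label)
    if (!is.na(j)) return(ntip + j)
  }
  stop("unknown node: ", node, call. = FALSE)
}
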