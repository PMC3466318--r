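#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact test by the point-probability criterion: with margins
#' fixed, the p-value is the sum of hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (within a small relative tolerance, matching common implementations).
#' Counts are laid out as focal-group-with-term (`a`), focal-group-without
#' (`b`), reference-with (`c`), reference-without (`d`).
#'
#' @param a,b,c,d non-negative integer cell counts; both margins `a + b` and
#'   `c + d` must be positive.
#' @return A list with `odds_ratio` (sample odds ratio `a*d / (b*c)`, may be
#'   `Inf` or `NaN` on zero cells) and `p`.
#' @export
#' @examples
#' fisher_exact(2, 2, 2, 2)$p  # 1
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m1 <- a + b; m2 <- c + d
  if (m1 == 0 || m2 == 0) {
    stop("zero group margin: test undefined", call. = FALSE)
  }
  k <- a + c                       # term-positive margin
  lo <- max(0, k - m2); hi <- min(k, m1)
  support <- lo:hi
  dens <- dhyper(support, m1, m2, k)
  d_obs <- dhyper(a, m1, m2, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  list(odds_ratio = (a * d) / (b * c), p = min(p, 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order preserving, with
#' monotonicity enforced. Delegates to [stats::p.adjust()] (method `"BH"`),
#' which implements exactly this rule.
#'
#' @param pvalues numeric vector in (0, 1]; an empty vector returns an
#'   empty vector.
#' @return Adjusted p-values, same order and length as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

#' Transitive ancestors of every term in a DAG
#'
#' @param dag data frame with columns `child`, `parent` (directed acyclic:
#'   edges point from a term to its more general parent).
#' @return Named list mapping each term to the character vector of all its
#'   (transitive) ancestors.
#' @export
term_ancestors <- function(dag) {
  terms <- unique(c(dag$child, dag$parent))
  parents <- split(dag$parent, dag$child)
  memo <- new.env(parent = emptyenv())
  in_progress <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (!is.null(in_progress[[t]])) {
      stop("term DAG contains a cycle through: ", t, call. = FALSE)
    }
    in_progress[[t]] <- TRUE
    ps <- parents[[t]]
    res <- if (is.null(ps)) character(0) else {
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    }
    rm(list = t, envir = in_progress)
    memo[[t]] <- res
    res
  }
  setNames(lapply(terms, anc), terms)
}

#' Term enrichment between a focal group and a reference group
#'
#' For every term annotated to at least one sequence of either group, builds
#' the 2x2 table (sequences in the focal group with/without the term vs the
#' reference group with/without), applies [fisher_exact()], adjusts across
#' terms with [bh_fdr()], and flags terms whose adjusted p falls below the
#' threshold. Significant terms that are (transitive) ancestors of another
#' significant term are then dropped, so the reported set is the
#' most-specific antichain in the DAG.
#'
#' @param annotations data frame with columns `sequence_id`, `group`,
#'   `term_id` (one row per sequence-term pair).
#' @param group focal group label.
#' @param reference reference group label, or `NULL` (default) for the
#'   complement of the focal group within the dataset.
#' @param dag optional term DAG (`child`, `parent` columns) for the
#'   most-specific filter; `NULL` skips the filter.
#' @param fdr FDR threshold in (0, 1); default 0.05.
#' @param propagate if `TRUE`, every sequence annotated with a term is also
#'   treated as annotated with all the term's ancestors before testing
#'   (default `FALSE`).
#' @return Data frame with columns `term`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`, `fdr_adjusted_p`, `significant`, `most_specific` (significant and
#'   not an ancestor of another significant term), sorted by `p`.
#' @export
enrich_terms <- function(annotations, group, reference = NULL, dag = NULL,
                         fdr = 0.05, propagate = FALSE) {
  stopifnot(fdr > 0, fdr < 1)
  need <- c("sequence_id", "group", "term_id")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!group %in% annotations$group) {
    stop("group label not present in annotations: ", group, call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% annotations$group) {
    stop("reference label not present in annotations: ", reference,
         call. = FALSE)
  }
  ann <- annotations
  if (propagate) {
    if (is.null(dag)) stop("propagate = TRUE requires a dag", call. = FALSE)
    anc <- term_ancestors(dag)
    extra <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
      up <- anc[[ann$term_id[i]]]
      if (is.null(up) || length(up) == 0) return(NULL)
      data.frame(sequence_id = ann$sequence_id[i], group = ann$group[i],
                 term_id = up, stringsAsFactors = FALSE)
    }))
    ann <- unique(rbind(ann[need], extra))
  }
  focal_seqs <- unique(ann$sequence_id[ann$group == group])
  ref_seqs <- if (is.null(reference)) {
    unique(ann$sequence_id[ann$group != group])
  } else {
    unique(ann$sequence_id[ann$group == reference])
  }
  if (length(ref_seqs) == 0) stop("reference group is empty", call. = FALSE)
  in_scope <- ann$sequence_id %in% c(focal_seqs, ref_seqs)
  terms <- sort(unique(ann$term_id[in_scope]))
  n_f <- length(focal_seqs); n_r <- length(ref_seqs)
  rows <- lapply(terms, function(t) {
    with_t <- unique(ann$sequence_id[ann$term_id == t])
    a <- sum(focal_seqs %in% with_t)
    cc <- sum(ref_seqs %in% with_t)
    ft <- fisher_exact(a, n_f - a, cc, n_r - cc)
    data.frame(term = t, a = a, b = n_f - a, c = cc, d = n_r - cc,
               odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_adjusted_p <- bh_fdr(out$p)
  out$significant <- out$fdr_adjusted_p < fdr
  out$most_specific <- out$significant
  if (!is.null(dag) && any(out$significant)) {
    anc <- term_ancestors(dag)
    sig <- out$term[out$significant]
    # a significant term is dropped when it is an ancestor of another
    # significant term
    ancestors_of_sig <- unique(unlist(anc[intersect(sig, names(anc))],
                                      use.names = FALSE))
    out$most_specific <- out$significant & !(out$term %in% ancestors_of_sig)
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
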