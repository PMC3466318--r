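#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' shape of a multi-species regulator-family census: about fifty genomes, a
#' pure-birth (Yule) species tree, per-lineage family sizes spanning roughly
#' one to several tens, and a handful of distinct domain architectures
#' produced by fusion/fission events, with occasional loss, duplication and
#' horizontal transfer.
#'
#' @param seed integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @param n_species number of species-tree leaves (>= 4); default 53.
#' @param birth Yule birth rate for the species tree; default 1.
#' @param rates named per-lineage Poisson event rates per unit branch
#'   length: `fusion`, `fission`, `loss`, `duplication`, `hgt`.
#' @param domain_alphabet pool of non-anchor domain labels a fusion can draw
#'   from; defaults to the nine non-anchor labels of [domain_catalog()].
#' @param anchor anchor domain label; default `"LuxR"`.
#' @param prepend_prob probability that a fused domain lands N-terminal of
#'   the existing architecture (default 0.8, mirroring the predominance of
#'   N-terminal sensor domains).
#' @param eco list of eco-covariate knobs: `slope` and `noise_sd` of the
#'   latent monotone link between family size and the planted ordinal
#'   variable, `n_levels` quantile levels for discretisation, `cat_offset`
#'   and `cat_noise_sd` for the planted categorical split.
#' @param enrichment list of annotation knobs: `term` (planted term id),
#'   `group_freq`, `ref_freq` (planted frequencies), `n_per_group` (cap per
#'   group), `background_freq`.
#' @param decoy_rate expected number (Poisson) of decoy proteins per species
#'   in the emitted hit table (superfamily-class anchor hits and anchor-free
#'   proteins that the census filter must reject).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 53L,
                       birth = 1,
                       rates = c(fusion = 0.015, fission = 0.005, loss = 0.05,
                                 duplication = 0.65, hgt = 0.02),
                       domain_alphabet = setdiff(unique(domain_catalog()$label),
                                                 "LuxR"),
                       anchor = "LuxR",
                       prepend_prob = 0.8,
                       eco = list(slope = 0.2, noise_sd = 0.5, n_levels = 5,
                                  cat_offset = 0.2, cat_noise_sd = 0.5),
                       enrichment = list(term = "T1a", group_freq = 0.9,
                                         ref_freq = 0.1, n_per_group = 50,
                                         background_freq = 0.3),
                       decoy_rate = 1) {
  stopifnot(n_species >= 4, all(rates >= 0),
            all(c("fusion", "fission", "loss", "duplication", "hgt") %in%
                  names(rates)))
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 birth = birth, rates = rates,
                 domain_alphabet = domain_alphabet, anchor = anchor,
                 prepend_prob = prepend_prob, eco = eco,
                 enrichment = enrichment, decoy_rate = decoy_rate),
            class = "sim_config")
}

#' Simulate a Yule species tree
#'
#' Pure-birth tree with `n_species` leaves via [ape::rphylo()], leaves
#' relabelled `sp01`, `sp02`, ... and internal nodes labelled `n<k>`.
#' Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return A rooted ultrametric [ape::phylo].
#' @export
simulate_species_tree <- function(config) {
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_species, birth = config$birth, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  tr$node.label <- sprintf("n%d", seq_len(tr$Nnode) + config$n_species)
  tr
}

#' Simulate architecture evolution along a species tree
#'
#' A single ancestral gene with the bare anchor architecture enters the root
#' and evolves down every branch. Per gene lineage, events arrive as Poisson
#' processes per unit branch length: \emph{fusion} adds a random alphabet
#' domain (N- or C-terminal), \emph{fission} removes one non-anchor domain,
#' \emph{loss} terminates the lineage, \emph{duplication} forks it in place,
#' and \emph{hgt} copies it into a branch alive at the event time (chosen
#' uniformly, excluding the donor). At speciation nodes every lineage is
#' inherited by each daughter branch. The full event log is retained and is
#' replayable: [replay_event_log()] reconstructs the tip repertoires exactly.
#'
#' @param tree rooted species tree with branch lengths (e.g. from
#'   [simulate_species_tree()]).
#' @param config a [sim_config()].
#' @return A list of class `simulated_world`: `config`, `tree`, `repertoire`
#'   (data frame `protein_id`, `species_id`, `architecture`), `event_log`
#'   (data frame, see Details), `gene_tree` (an `annotated_gene_tree`, or
#'   `NULL` when fewer than two genes survive), `census` (the planted
#'   [build_census()] of the repertoire).
#' @details Event-log columns: `event_id`, `type`, `edge` (child-node label
#'   of the species-tree branch), `time`, `lineage`, `new_lineage`, `detail`
#'   (fused/removed domain and side, or HGT recipient branch), `architecture`
#'   (architecture string of the affected/new lineage after the event).
#' @export
simulate_architecture_evolution <- function(tree, config) {
  set.seed(config$seed + 1L)
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  rootn <- root_node(tree)
  edge_child <- tree$edge[, 2]
  edge_parent <- tree$edge[, 1]
  edges_of <- split(seq_len(nrow(tree$edge)), edge_parent)
  rates <- config$rates
  alphabet <- config$domain_alphabet
  anchor <- config$anchor

  # gene-tree node store
  gt <- new.env(parent = emptyenv())
  gt$parent <- integer(0); gt$time <- numeric(0)
  gt$kind <- character(0); gt$label <- character(0)
  new_gnode <- function(parent, time, kind, label = "") {
    gt$parent <- c(gt$parent, parent)
    gt$time <- c(gt$time, time)
    gt$kind <- c(gt$kind, kind)
    gt$label <- c(gt$label, label)
    length(gt$parent)
  }
  root_gnode <- new_gnode(NA_integer_, 0, "root")

  log_rows <- list()
  n_events <- 0L
  add_log <- function(type, edge, time, lineage, new_lineage, detail, arch) {
    n_events <<- n_events + 1L
    log_rows[[n_events]] <<- data.frame(
      event_id = n_events, type = type,
      edge = node_label(tree, edge_child[edge]), time = time,
      lineage = lineage, new_lineage = new_lineage, detail = detail,
      architecture = paste(arch, collapse = "+"), stringsAsFactors = FALSE)
  }

  repertoire <- list()
  species_counter <- setNames(integer(ntip), tree$tip.label)
  dup_counter <- 0L; hgt_counter <- 0L

  # FIFO queue of gene-lineage segments
  queue <- list()
  q_head <- 1L
  push <- function(seg) queue[[length(queue) + 1L]] <<- seg

  for (e in edges_of[[as.character(rootn)]]) {
    push(list(edge = e, t = depths[rootn], arch = anchor,
              lineage = paste0("L1.", node_label(tree, edge_child[e])),
              gparent = root_gnode))
  }

  while (q_head <= length(queue)) {
    seg <- queue[[q_head]]; q_head <- q_head + 1L
    e <- seg$edge; t <- seg$t; arch <- seg$arch
    lineage <- seg$lineage; gparent <- seg$gparent
    t_end <- depths[edge_child[e]]
    alive <- TRUE
    while (alive) {
      can_fiss <- length(arch) > 1
      can_fuse <- length(alphabet) > 0
      lam <- c(fusion = if (can_fuse) rates[["fusion"]] else 0,
               fission = if (can_fiss) rates[["fission"]] else 0,
               loss = rates[["loss"]],
               duplication = rates[["duplication"]],
               hgt = rates[["hgt"]])
      lam_tot <- sum(lam)
      if (lam_tot == 0) break
      wait <- rexp(1, lam_tot)
      te <- t + wait
      if (te >= t_end) break
      type <- sample(names(lam), 1, prob = lam)
      if (type == "fusion") {
        dom <- alphabet[sample.int(length(alphabet), 1)]
        side <- if (runif(1) < config$prepend_prob) "N" else "C"
        arch <- if (side == "N") c(dom, arch) else c(arch, dom)
        add_log("fusion", e, te, lineage, NA, paste0(dom, ":", side), arch)
      } else if (type == "fission") {
        removable <- which(arch != anchor)
        i <- removable[sample.int(length(removable), 1)]
        add_log("fission", e, te, lineage, NA, paste0(arch[i], "@", i),
                arch[-i])
        arch <- arch[-i]
      } else if (type == "loss") {
        add_log("loss", e, te, lineage, NA, "", arch)
        new_gnode(gparent, te, "lost")
        alive <- FALSE
      } else if (type == "duplication") {
        dup_counter <- dup_counter + 1L
        new_lin <- sprintf("%s.d%d", lineage, dup_counter)
        gd <- new_gnode(gparent, te, "duplication")
        add_log("duplication", e, te, lineage, new_lin, "", arch)
        push(list(edge = e, t = te, arch = arch, lineage = new_lin,
                  gparent = gd))
        gparent <- gd
      } else { # hgt
        cand <- which(depths[edge_parent] <= te & depths[edge_child] > te)
        cand <- setdiff(cand, e)
        if (length(cand) > 0) {
          rec <- cand[sample.int(length(cand), 1)]
          hgt_counter <- hgt_counter + 1L
          new_lin <- sprintf("%s.h%d", lineage, hgt_counter)
          gh <- new_gnode(gparent, te, "hgt")
          add_log("hgt", e, te, lineage, new_lin,
                  node_label(tree, edge_child[rec]), arch)
          push(list(edge = rec, t = te, arch = arch, lineage = new_lin,
                    gparent = gh))
          gparent <- gh
        }
      }
      t <- te
    }
    if (!alive) next
    child <- edge_child[e]
    if (child <= ntip) {
      sp <- tree$tip.label[child]
      species_counter[sp] <- species_counter[sp] + 1L
      prot <- sprintf("%s_g%d", sp, species_counter[sp])
      new_gnode(gparent, t_end, "tip",
                paste(prot, sp, paste(arch, collapse = "+"), sep = "|"))
      repertoire[[length(repertoire) + 1L]] <- data.frame(
        protein_id = prot, species_id = sp,
        architecture = paste(arch, collapse = "+"), stringsAsFactors = FALSE)
    } else {
      gs <- new_gnode(gparent, t_end, "speciation")
      for (ce in edges_of[[as.character(child)]]) {
        push(list(edge = ce, t = t_end, arch = arch,
                  lineage = paste0(lineage, ".",
                                   node_label(tree, edge_child[ce])),
                  gparent = gs))
      }
    }
  }

  rep_df <- if (length(repertoire)) do.call(rbind, repertoire) else {
    data.frame(protein_id = character(0), species_id = character(0),
               architecture = character(0), stringsAsFactors = FALSE)
  }
  log_df <- if (n_events) do.call(rbind, log_rows) else {
    data.frame(event_id = integer(0), type = character(0),
               edge = character(0), time = numeric(0), lineage = character(0),
               new_lineage = character(0), detail = character(0),
               architecture = character(0), stringsAsFactors = FALSE)
  }
  gene_tree <- build_gene_tree(gt)
  structure(list(config = config, tree = tree, repertoire = rep_df,
                 event_log = log_df, gene_tree = gene_tree,
                 census = build_census(rep_df)),
            class = "simulated_world")
}

# assemble the recorded gene-lineage nodes into an annotated phylo,
# pruning lost lineages and collapsing unary nodes
build_gene_tree <- function(gt) {
  n <- length(gt$parent)
  if (n == 0) return(NULL)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(n)) {
    p <- gt$parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  alive <- logical(n)
  for (i in rev(seq_len(n))) {  # children always created after parents
    alive[i] <- gt$kind[i] == "tip" || any(alive[children[[i]]])
  }
  if (sum(gt$kind == "tip") < 2) return(NULL)
  rec <- function(node, anc_time) {
    kids <- children[[node]][alive[children[[node]]]]
    if (gt$kind[node] == "tip") {
      return(paste0(gt$label[node], ":",
                    format(gt$time[node] - anc_time, digits = 10)))
    }
    if (length(kids) == 1) return(rec(kids, anc_time))
    inner <- paste(vapply(kids, rec, "", anc_time = gt$time[node]),
                   collapse = ",")
    paste0("(", inner, "):",
           format(gt$time[node] - anc_time, digits = 10))
  }
  root <- 1L
  kids <- children[[root]][alive[children[[root]]]]
  while (length(kids) == 1 && gt$kind[kids] != "tip") {
    root <- kids
    kids <- children[[root]][alive[children[[root]]]]
  }
  if (length(kids) < 2) return(NULL)
  nwk <- paste0("(", paste(vapply(kids, rec, "", anc_time = gt$time[root]),
                           collapse = ","), ");")
  annotate_gene_tree(read_newick(nwk))
}

#' Replay an event log to reconstruct tip repertoires
#'
#' Deterministically re-applies a [simulate_architecture_evolution()] event
#' log to the species tree — inheritance at speciation nodes plus the logged
#' fusion/fission/loss/duplication/HGT events — and returns the implied tip
#' repertoires. Acts as an independent bookkeeping check: for any seed,
#' `replay_event_log(world)` equals `world$repertoire` up to protein
#' numbering (species-architecture counts are identical).
#'
#' @param world a `simulated_world`, or a list with `tree`, `event_log` and
#'   `config` entries.
#' @return Data frame `species_id`, `architecture`, one row per surviving
#'   gene copy.
#' @export
replay_event_log <- function(world) {
  tree <- world$tree; log <- world$event_log
  anchor <- world$config$anchor
  ntip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  rootn <- root_node(tree)
  edge_child <- tree$edge[, 2]
  edge_labels <- vapply(edge_child, function(nd) node_label(tree, nd), "")
  edges_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  # HGT injections per recipient edge
  hgt_rows <- log[log$type == "hgt", , drop = FALSE]
  injections <- split(hgt_rows, match(hgt_rows$detail, edge_labels))
  out <- list()
  process_edge <- function(e, incoming) {
    # incoming: named list lineage -> architecture string
    ev <- log[log$edge == edge_labels[e] & log$type != "hgt", , drop = FALSE]
    donors <- log[log$edge == edge_labels[e] & log$type == "hgt", , drop = FALSE]
    inj <- injections[[as.character(e)]]
    # merge event stream with injections, ordered by time
    stream <- rbind(
      if (nrow(ev)) cbind(ev, what = "event") else NULL,
      if (!is.null(inj) && nrow(inj)) cbind(inj, what = "inject") else NULL)
    lineages <- incoming
    if (!is.null(stream) && nrow(stream)) {
      stream <- stream[order(stream$time, stream$event_id), , drop = FALSE]
      for (i in seq_len(nrow(stream))) {
        row <- stream[i, ]
        if (row$what == "inject") {
          lineages[[row$new_lineage]] <- row$architecture
        } else if (row$type %in% c("fusion", "fission")) {
          lineages[[row$lineage]] <- row$architecture
        } else if (row$type == "loss") {
          lineages[[row$lineage]] <- NULL
        } else if (row$type == "duplication") {
          lineages[[row$new_lineage]] <- row$architecture
        }
      }
    }
    child <- edge_child[e]
    if (child <= ntip) {
      sp <- tree$tip.label[child]
      for (arch in unlist(lineages, use.names = FALSE)) {
        out[[length(out) + 1L]] <<- data.frame(
          species_id = sp, architecture = arch, stringsAsFactors = FALSE)
      }
    } else {
      for (ce in edges_of[[as.character(child)]]) {
        nxt <- lineages
        if (length(nxt)) {
          names(nxt) <- paste0(names(nxt), ".",
                               node_label(tree, edge_child[ce]))
        }
        process_edge(ce, nxt)
      }
    }
  }
  for (e in edges_of[[as.character(rootn)]]) {
    process_edge(e, setNames(list(anchor), paste0("L1.", edge_labels[e])))
  }
  if (length(out) == 0) {
    return(data.frame(species_id = character(0), architecture = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$species_id, res$architecture), , drop = FALSE]
}

#' Emit a domain-hit table for a simulated world
#'
#' One specific-class hit per domain of every gene, with ascending
#' non-overlapping 1-based coordinates, accession looked up from
#' [domain_catalog()]. Optionally injects per-species decoys that the census
#' filter must reject: a protein whose only anchor hit is superfamily-class,
#' and an anchor-free protein with a specific hit to another domain.
#'
#' @param world a `simulated_world`.
#' @param decoys include decoy proteins (default `TRUE`; the expected number
#'   per species is the config's `decoy_rate`).
#' @return A `domain_hits` data frame (same shape as [parse_domain_hits()]
#'   output).
#' @export
emit_domain_hits <- function(world, decoys = TRUE) {
  set.seed(world$config$seed + 4L)
  cat_map <- domain_catalog()
  acc_of <- function(lab) {
    i <- match(lab, cat_map$label)
    ifelse(is.na(i), lab, cat_map$accession[i])
  }
  rows <- list()
  add_protein <- function(prot, sp, labels, classes) {
    n <- length(labels)
    starts <- 10L + (seq_len(n) - 1L) * 110L
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = prot, species_id = sp, domain_acc = acc_of(labels),
      domain_name = labels, hit_class = classes, start = starts,
      end = starts + 90L, evalue = 1e-10, stringsAsFactors = FALSE)
  }
  rep_df <- world$repertoire
  for (i in seq_len(nrow(rep_df))) {
    labels <- strsplit(rep_df$architecture[i], "+", fixed = TRUE)[[1]]
    add_protein(rep_df$protein_id[i], rep_df$species_id[i], labels,
                rep("specific", length(labels)))
  }
  if (decoys && world$config$decoy_rate > 0) {
    alphabet <- world$config$domain_alphabet
    for (sp in world$tree$tip.label) {
      nd <- rpois(1, world$config$decoy_rate)
      for (k in seq_len(nd)) {
        if (runif(1) < 0.5) {
          # anchor present but only as a superfamily-class hit
          add_protein(sprintf("%s_decoySF%d", sp, k), sp,
                      world$config$anchor, "superfamily")
        } else {
          dom <- alphabet[sample.int(length(alphabet), 1)]
          add_protein(sprintf("%s_decoyNA%d", sp, k), sp, dom, "specific")
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("domain_hits", "data.frame")
  out
}

#' Simulate ecological covariates with a planted link to family size
#'
#' Per species: `planted` is a latent `slope * total + N(0, noise_sd)`
#' discretised into `n_levels` ordinal levels by quantiles (emulating the
#' ordinal coding of genome-size-like variables); `null` is an independent
#' uniform ordinal with no link to the family; `category` is a two-level
#' factor (coded 1/2) split on a second latent `cat_offset * total +
#' N(0, cat_noise_sd)` at its median, so group means of the family size
#' differ when `cat_offset > 0` (for Eta recovery) and do not when it is 0.
#'
#' @param world a `simulated_world`.
#' @return Data frame `species_id`, `planted`, `null`, `category`.
#' @export
simulate_eco_covariates <- function(world) {
  set.seed(world$config$seed + 2L)
  eco <- world$config$eco
  sp <- world$tree$tip.label
  totals <- vapply(sp, function(s) {
    sum(world$repertoire$species_id == s)
  }, numeric(1))
  latent <- eco$slope * totals + rnorm(length(sp), 0, eco$noise_sd)
  qs <- quantile(latent, probs = seq(0, 1, length.out = eco$n_levels + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)  # degenerate latents (zero noise, tied totals) collapse levels
  planted <- as.integer(cut(latent, qs, labels = FALSE, include.lowest = TRUE))
  null_var <- sample.int(eco$n_levels, length(sp), replace = TRUE)
  latent2 <- eco$cat_offset * totals + rnorm(length(sp), 0, eco$cat_noise_sd)
  category <- ifelse(latent2 > stats::median(latent2), 2L, 1L)
  data.frame(species_id = sp, planted = planted, null = null_var,
             category = category, stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate an annotation table and toy term DAG with a planted enrichment
#'
#' Builds a three-level DAG (root `R`; mid terms `M1`, `M2`; leaf terms
#' `T1a`, `T1b`, `T2a`, `T2b` under them), assigns sequences to a `focal`
#' and a `reference` group, annotates the planted term at the configured
#' group/reference frequencies and background terms at a shared frequency,
#' and gives every sequence the root term.
#'
#' @param world a `simulated_world`.
#' @return List with `annotations` (data frame `sequence_id`, `group`,
#'   `term_id`) and `dag` (data frame `child`, `parent`).
#' @export
simulate_annotations <- function(world) {
  set.seed(world$config$seed + 3L)
  en <- world$config$enrichment
  dag <- data.frame(
    child = c("M1", "M2", "T1a", "T1b", "T2a", "T2b"),
    parent = c("R", "R", "M1", "M1", "M2", "M2"),
    stringsAsFactors = FALSE)
  n <- en$n_per_group
  seqs <- c(sprintf("focal_s%03d", seq_len(n)),
            sprintf("ref_s%03d", seq_len(n)))
  groups <- rep(c("focal", "reference"), each = n)
  rows <- list(data.frame(sequence_id = seqs, group = groups, term_id = "R",
                          stringsAsFactors = FALSE))
  planted_freq <- ifelse(groups == "focal", en$group_freq, en$ref_freq)
  has_planted <- runif(2 * n) < planted_freq
  if (any(has_planted)) {
    rows[[length(rows) + 1]] <- data.frame(
      sequence_id = seqs[has_planted], group = groups[has_planted],
      term_id = en$term, stringsAsFactors = FALSE)
  }
  for (bg in setdiff(c("T1b", "T2a", "T2b"), en$term)) {
    has_bg <- runif(2 * n) < en$background_freq
    if (any(has_bg)) {
      rows[[length(rows) + 1]] <- data.frame(
        sequence_id = seqs[has_bg], group = groups[has_bg], term_id = bg,
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, rows)
  ann <- ann[order(ann$sequence_id, ann$term_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(annotations = ann, dag = dag)
}

#' Simulate a complete synthetic world
#'
#' Chains [simulate_species_tree()], [simulate_architecture_evolution()],
#' [simulate_eco_covariates()] and [simulate_annotations()] under one seed.
#'
#' @param config a [sim_config()].
#' @return A `simulated_world` with the additional elements `eco` and
#'   `annotations`.
#' @export
simulate_world <- function(config = sim_config()) {
  tree <- simulate_species_tree(config)
  world <- simulate_architecture_evolution(tree, config)
  world$eco <- simulate_eco_covariates(world)
  world$annotations <- simulate_annotations(world)
  world
}

#' Write a simulated world to a directory
#'
#' Writes `species.nwk`, `genetrees/family1.nwk` (when a gene tree exists),
#' `hits.tsv`, `eco.tsv`, `annotations.tsv`, `dag.tsv` and
#' `truth/event_log.tsv` + `truth/census.tsv`.
#'
#' @param world a `simulated_world` from [simulate_world()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genetrees"), recursive = TRUE,
             showWarnings = FALSE)
  write_newick(world$tree, file.path(dir, "species.nwk"))
  if (!is.null(world$gene_tree)) {
    write_newick(world$gene_tree, file.path(dir, "genetrees", "family1.nwk"))
  }
  write_tsv(emit_domain_hits(world), file.path(dir, "hits.tsv"),
            seed = world$config$seed)
  write_tsv(world$eco, file.path(dir, "eco.tsv"), seed = world$config$seed)
  write_tsv(world$annotations$annotations, file.path(dir, "annotations.tsv"),
            seed = world$config$seed)
  write_tsv(world$annotations$dag, file.path(dir, "dag.tsv"),
            seed = world$config$seed)
  write_tsv(world$event_log, file.path(dir, "truth", "event_log.tsv"),
            seed = world$config$seed)
  write_tsv(world$census, file.path(dir, "truth", "census.tsv"),
            seed = world$config$seed)
  invisible(dir)
}

#' Check Dollo identifiability of a loss-only history
#'
#' For a world simulated with only the loss rate positive (single origin at
#' the root, no duplication or transfer), the presence/absence pattern
#' determines the true history exactly when (a) the surviving leaves' MRCA
#' is the root, so the origin cannot be placed lower, and (b) no internal
#' node lost the gene in \emph{all} of its child subtrees independently, so
#' each logged loss maps to its own maximal absent subtree.
#'
#' @param world a `simulated_world` with loss-only rates.
#' @return `TRUE`/`FALSE`.
#' @export
dollo_identifiable <- function(world) {
  tree <- world$tree
  ntip <- length(tree$tip.label)
  present <- tree$tip.label %in% world$repertoire$species_id
  if (!any(present)) return(FALSE)
  names(present) <- tree$tip.label
  if (sum(present) >= 2) {
    if (mrca_present(tree, present) != root_node(tree)) return(FALSE)
  } else {
    return(FALSE)
  }
  losses <- world$event_log[world$event_log$type == "loss", , drop = FALSE]
  if (nrow(losses) == 0) return(TRUE)
  tu <- tips_under(tree)
  loss_nodes <- vapply(losses$edge, function(lab) resolve_node(tree, lab), 0L)
  for (nd in loss_nodes) {
    # the loss edge's sibling subtrees must retain a present descendant
    parent <- tree$edge[match(nd, tree$edge[, 2]), 1]
    sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], nd)
    sib_present <- any(vapply(sibs, function(s) any(present[tu[[s]]]),
                              logical(1)))
    if (!sib_present) return(FALSE)
  }
  TRUE
}
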