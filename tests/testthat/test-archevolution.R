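test_that("dollo loss counting matches direct reasoning on fixed trees", {
  tr <- read_newick("((A,B),(C,D));")
  all_p <- c(A = TRUE, B = TRUE, C = TRUE, D = TRUE)
  expect_equal(dollo_loss_count(tr, all_p),
               list(n_absent_descendants = 0L, n_losses = 0L))

  one_clade <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE)
  expect_equal(dollo_loss_count(tr, one_clade)$n_losses, 1L)

  # caterpillar with three scattered absences: the absent leaves are
  # pairwise non-adjacent, so three independent losses are required
  cat6 <- read_newick("(((((A,B),C),D),E),F);")
  pres <- c(A = TRUE, B = FALSE, C = FALSE, D = TRUE, E = FALSE, F = TRUE)
  d <- dollo_loss_count(cat6, pres)
  expect_equal(d$n_absent_descendants, 3L)
  expect_equal(d$n_losses, brute_dollo_losses(cat6, unname(pres[cat6$tip.label]),
                                              root_node_of(cat6)))
  expect_equal(d$n_losses, 3L)

  expect_error(dollo_loss_count(tr, one_clade, origin = "C"),
               "not ancestral")
})

test_that("dollo, fitch and origin scoring agree with exhaustive oracles", {
  set.seed(42)
  for (n in 4:8) {
    tr <- random_tree(n, seed = n * 100)
    for (rep in 1:8) {
      pres <- random_profile(tr, seed = n * 100 + rep)
      if (!any(pres)) pres[1] <- TRUE
      v <- unname(pres[tr$tip.label])
      root <- length(tr$tip.label) + 1L
      expect_equal(dollo_loss_count(tr, pres)$n_losses,
                   brute_dollo_losses(tr, v, root))
      expect_equal(fitch_changes(tr, pres), brute_fitch(tr, v))
      hy <- evaluate_origin_hypotheses(tr, pres)
      oc <- brute_origin_costs(tr, v)
      expect_equal(hy$cost[1], min(oc$cost))
      # every hypothesis cost matches the oracle for the same origin
      expect_equal(hy$cost, oc$cost[match(hy$origin_node, oc$origin_node)])
    }
  }
})

test_that("fitch agrees with phangorn on random binary profiles", {
  skip_if_not_installed("phangorn")
  for (s in 1:10) {
    tr <- random_tree(8, seed = 7000 + s)
    pres <- random_profile(tr, seed = 7100 + s)
    states <- ifelse(pres[tr$tip.label], "p", "a")
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("a", "p"))
    expect_equal(fitch_changes(tr, pres),
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("origin hypotheses handle singleton, perfect clade and planted HGT", {
  tr <- read_newick("(((A,B),(C,D)),((E,F),(G,H)));")

  single <- setNames(rep(FALSE, 8), tr$tip.label); single["E"] <- TRUE
  hy <- evaluate_origin_hypotheses(tr, single)
  expect_equal(hy$origin_label[1], "E")
  expect_equal(hy$n_losses[1], 0L)
  expect_equal(hy$n_hgt[1], 0L)

  clade <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    tr$tip.label)
  hy <- evaluate_origin_hypotheses(tr, clade)
  expect_equal(hy$cost[1], 1)  # gain only
  expect_equal(hy$n_losses[1], 0L)

  # planted transfer: ABCD clade plus lone recipient G
  hgt <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                  tr$tip.label)
  hy <- evaluate_origin_hypotheses(tr, hgt)
  oc <- brute_origin_costs(tr, unname(hgt[tr$tip.label]))
  expect_equal(hy$cost[1], min(oc$cost))
  best <- hy[1, ]
  expect_equal(best$n_hgt, 1L)
  expect_equal(best$hgt_recipients, "G")
})

test_that("infinite transfer cost degenerates to the Dollo solution at the MRCA", {
  for (s in 1:10) {
    tr <- random_tree(9, seed = 9000 + s)
    pres <- random_profile(tr, seed = 9100 + s)
    if (sum(pres) < 2) next
    hy <- evaluate_origin_hypotheses(tr, pres,
                                     costs = c(gain = 1, loss = 1, hgt = Inf))
    expect_equal(hy$origin_node[1], mrca_present(tr, pres))
    expect_equal(hy$n_hgt[1], 0L)
  }
})

test_that("dollo losses never undercut fitch changes given a root origin", {
  for (s in 1:20) {
    tr <- random_tree(8, seed = 500 + s)
    pres <- random_profile(tr, seed = 600 + s)
    if (!any(pres)) next
    d <- dollo_loss_count(tr, pres)$n_losses
    f <- fitch_changes(tr, pres)
    expect_lte(f, d + 1L)  # gain + losses is one admissible change set
  }
})

test_that("principal bipartition recovers architecture-defined splits", {
  nwk <- "(((a1,a2),(a3,a4)),((b1,b2),(b3,b4)));"
  tr <- read_newick(nwk)
  lab <- function(arch, tip) paste(tip, "sp1", arch, sep = "|")
  pure <- tr
  pure$tip.label <- c(lab("LuxR", paste0("a", 1:4)),
                      lab("REC+LuxR", paste0("b", 1:4)))
  g <- annotate_gene_tree(pure)
  bp <- principal_bipartition(g)
  expect_equal(bp$purity_a, 1)
  expect_equal(bp$purity_b, 1)
  expect_setequal(
    if (bp$arch_a == "LuxR") bp$tips_a else bp$tips_b,
    paste0("a", 1:4))

  # one tip swapped across: the chosen edge must attain the maximum mean
  # purity over an explicit enumeration of all bipartitions
  swapped <- tr
  swapped$tip.label <- c(lab("LuxR", paste0("a", 1:3)), lab("REC+LuxR", "x1"),
                         lab("REC+LuxR", paste0("b", 1:4)))
  g2 <- annotate_gene_tree(swapped)
  bp2 <- principal_bipartition(g2)
  expect_lt(bp2$score, 1)
  arch2 <- g2$tip.annotation$architecture
  below <- oracle_tips_under(g2)
  best_oracle <- max(vapply(which(g2$edge[, 2] > length(g2$tip.label)),
    function(e) {
      a <- below[[g2$edge[e, 2]]]
      b <- setdiff(seq_along(arch2), a)
      mean(c(max(table(arch2[a])) / length(a),
             max(table(arch2[b])) / length(b)))
    }, numeric(1)))
  expect_equal(bp2$score, best_oracle)

  mono <- tr
  mono$tip.label <- lab("LuxR", paste0("t", 1:8))
  expect_error(principal_bipartition(annotate_gene_tree(mono)),
               "no bipartition")
})

test_that("cluster census equals brute-force monochromatic enumeration", {
  for (s in 1:12) {
    set.seed(3000 + s)
    tr <- random_tree(20, seed = 3000 + s)
    archs <- sample(c("focal", "other1", "other2"), 20, replace = TRUE,
                    prob = c(0.4, 0.3, 0.3))
    tr$tip.label <- paste(paste0("g", 1:20), "sp", archs, sep = "|")
    g <- annotate_gene_tree(tr)
    cc <- cluster_census(g, "focal")
    sizes <- brute_cluster_sizes(g, g$tip.annotation$architecture == "focal",
                                 length(g$tip.label) + 1L)
    expect_equal(cc$cluster_sizes, sizes)
    expect_equal(cc$n_sequences, sum(sizes))
    expect_equal(cc$n_clusters + cc$n_singletons, length(sizes))
  }
})

test_that("cluster census trivial cases", {
  tr <- read_newick("((g1|s|A,g2|s|A),(g3|s|B,g4|s|B));")
  g <- annotate_gene_tree(tr)
  expect_equal(cluster_census(g, "Z"),
               list(n_sequences = 0L, n_clusters = 0L, n_singletons = 0L,
                    cluster_sizes = integer(0)))
  cc <- cluster_census(g, "A")
  expect_equal(cc$n_sequences, 2L)
  expect_equal(cc$n_clusters, 1L)
  expect_equal(cc$n_singletons, 0L)
})
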