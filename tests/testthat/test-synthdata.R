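test_that("species tree simulation is shaped and seeded correctly", {
  cfg <- sim_config(seed = 5, n_species = 4)
  tr <- simulate_species_tree(cfg)
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 3)
  expect_identical(write_newick(tr),
                   write_newick(simulate_species_tree(cfg)))
  # different seed, different tree (lengths at minimum)
  tr2 <- simulate_species_tree(sim_config(seed = 6, n_species = 4))
  expect_false(identical(write_newick(tr), write_newick(tr2)))
})

test_that("all-zero rates give one ancestral single-domain gene per species", {
  cfg <- sim_config(seed = 2, n_species = 8,
                    rates = c(fusion = 0, fission = 0, loss = 0,
                              duplication = 0, hgt = 0))
  w <- simulate_world(cfg)
  expect_equal(nrow(w$event_log), 0)
  expect_equal(nrow(w$repertoire), 8)
  expect_true(all(w$repertoire$architecture == "LuxR"))
  expect_setequal(w$repertoire$species_id, w$tree$tip.label)
})

test_that("fusion-only worlds only gain domains and keep one gene per species", {
  cfg <- sim_config(seed = 3, n_species = 10,
                    rates = c(fusion = 0.3, fission = 0, loss = 0,
                              duplication = 0, hgt = 0))
  w <- simulate_world(cfg)
  expect_true(all(w$event_log$type == "fusion"))
  expect_equal(nrow(w$repertoire), 10)
  expect_true(all(vapply(strsplit(w$repertoire$architecture, "+",
                                  fixed = TRUE),
                         function(d) "LuxR" %in% d, logical(1))))
})

test_that("identical configs give identical worlds; replay reproduces tips", {
  cfg <- sim_config(seed = 13, n_species = 12)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$event_log, w2$event_log)
  expect_identical(w1$repertoire, w2$repertoire)
  expect_identical(w1$eco, w2$eco)
  expect_identical(w1$annotations, w2$annotations)

  for (s in c(101, 202, 303, 404)) {
    w <- simulate_world(sim_config(seed = s, n_species = 10))
    replayed <- build_census(replay_event_log(w))
    expect_equal(replayed[c("species_id", "architecture", "count")],
                 w$census[c("species_id", "architecture", "count")],
                 ignore_attr = TRUE)
  }
})

test_that("emitted hit tables respect coordinates and decoys are filtered out", {
  w <- simulate_world(sim_config(seed = 17, n_species = 8))
  hits <- emit_domain_hits(w)
  # within each protein, hits are non-overlapping and ascending
  for (p in unique(hits$protein_id)[1:10]) {
    h <- hits[hits$protein_id == p, ]
    h <- h[order(h$start), ]
    expect_true(all(h$start <= h$end))
    if (nrow(h) > 1) expect_true(all(h$start[-1] > h$end[-nrow(h)]))
  }
  # a two-domain gene puts the N-terminal domain first
  two <- w$repertoire[grepl("\\+LuxR$", w$repertoire$architecture), ]
  if (nrow(two) > 0) {
    h <- hits[hits$protein_id == two$protein_id[1], ]
    doms <- strsplit(two$architecture[1], "+", fixed = TRUE)[[1]]
    expect_equal(h$domain_name[order(h$start)], doms)
  }
  kept <- filter_anchor_proteins(hits)
  expect_false(any(grepl("decoy", kept)))
  expect_setequal(kept, w$repertoire$protein_id)
})

test_that("eco covariates carry the planted structure", {
  # zero noise and per-species levels: the planted variable is a strictly
  # monotone transform of the family size
  cfg <- sim_config(seed = 23, n_species = 20,
                    eco = list(slope = 1, noise_sd = 0, n_levels = 1000,
                               cat_offset = 0.2, cat_noise_sd = 0.5))
  w <- simulate_world(cfg)
  totals <- vapply(w$tree$tip.label,
                   function(s) sum(w$repertoire$species_id == s), numeric(1))
  s <- spearman_rho(totals, w$eco$planted)
  expect_equal(s$r_s, 1)

  # decoupled null variable: small average |r_s| across seeds
  rs <- vapply(1:20, function(s) {
    w <- simulate_world(sim_config(seed = 600 + s, n_species = 25))
    totals <- vapply(w$tree$tip.label,
                     function(sp) sum(w$repertoire$species_id == sp),
                     numeric(1))
    spearman_rho(totals, w$eco$null)$r_s
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 / sqrt(25))
})

test_that("annotation simulation plants a recoverable enrichment", {
  w <- simulate_world(sim_config(seed = 31, n_species = 8))
  ann <- w$annotations
  res <- enrich_terms(ann$annotations, "focal", dag = ann$dag, fdr = 0.05)
  expect_true(res$significant[res$term == w$config$enrichment$term])
  expect_true(res$most_specific[res$term == w$config$enrichment$term])

  # equal planted frequencies: planted term behaves as null
  cfg0 <- sim_config(seed = 32, n_species = 8,
                     enrichment = list(term = "T1a", group_freq = 0.3,
                                       ref_freq = 0.3, n_per_group = 50,
                                       background_freq = 0.3))
  n_sig <- sum(vapply(1:15, function(s) {
    cfg <- cfg0; cfg$seed <- 900 + s
    w0 <- simulate_world(cfg)
    r <- enrich_terms(w0$annotations$annotations, "focal",
                      dag = w0$annotations$dag, fdr = 0.05)
    any(r$significant)
  }, logical(1)))
  expect_lte(n_sig / 15, 0.2)
})

test_that("loss-only histories are recovered when Dollo-identifiable", {
  n_ident <- 0
  for (s in 1:25) {
    cfg <- sim_config(seed = 1200 + s, n_species = 12,
                      rates = c(fusion = 0, fission = 0, loss = 0.25,
                                duplication = 0, hgt = 0))
    w <- simulate_world(cfg)
    if (nrow(w$repertoire) == 0) next
    if (!dollo_identifiable(w)) next
    n_ident <- n_ident + 1
    pres <- setNames(w$tree$tip.label %in% w$repertoire$species_id,
                     w$tree$tip.label)
    # loss-only data are scored under the loss-only (pure Dollo) model
    hy <- evaluate_origin_hypotheses(w$tree, pres,
                                     costs = c(gain = 1, loss = 1, hgt = Inf))
    expect_equal(hy$origin_node[1], root_node_of(w$tree))
    expect_equal(hy$n_losses[1], sum(w$event_log$type == "loss"))
  }
  expect_gte(n_ident, 5)  # the scenario actually exercises the check
})

test_that("world export writes the advertised artifact set", {
  w <- simulate_world(sim_config(seed = 41, n_species = 8))
  dir <- tempfile("world")
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "species.nwk")))
  expect_true(file.exists(file.path(dir, "hits.tsv")))
  expect_true(file.exists(file.path(dir, "eco.tsv")))
  expect_true(file.exists(file.path(dir, "annotations.tsv")))
  expect_true(file.exists(file.path(dir, "dag.tsv")))
  expect_true(file.exists(file.path(dir, "truth", "event_log.tsv")))
  # hit table round-trips through the parser
  hits <- parse_domain_hits(file.path(dir, "hits.tsv"))
  expect_gt(nrow(hits), 0)
})
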