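.sim_tree <- function(ntip = 4, scale = 1) {
  phy <- ape::rtree(ntip)
  phy$edge.length <- phy$edge.length * scale
  phy$node.label <- paste0("n", seq_len(phy$Nnode))
  phy
}

test_that("a null process leaves every karyotype identical to the root", {
  set.seed(1)
  phy <- .sim_tree(5)
  sim <- evolve_karyotypes(phy, root_chromosomes = 5,
                           blocks_per_chromosome = 2,
                           fusion_rate = 0, fission_rate = 0, seed = 4)
  root <- sim$states[["n1"]]
  for (tp in phy$tip.label) expect_identical(sim$states[[tp]], root)
  expect_true(all(sim$counts$fusions == 0) && all(sim$counts$fissions == 0))
})

test_that("event logs replay to the simulated states exactly", {
  set.seed(2)
  for (seed in 1:100) {
    phy <- .sim_tree(4)
    sim <- evolve_karyotypes(phy, root_chromosomes = 6,
                             blocks_per_chromosome = 2,
                             fusion_rate = 1.5, fission_rate = 1.5,
                             seed = seed)
    expect_identical(replay_history(sim), sim$states)
  }
})

test_that("chromosome accounting follows the applied events", {
  phy <- ape::read.tree(text = "(A:10,B:0.001)n1;")
  phy$node.label <- "n1"
  sim <- evolve_karyotypes(phy, root_chromosomes = 12,
                           blocks_per_chromosome = 1,
                           fusion_rate = 0.2, fission_rate = 0, seed = 6)
  nf <- sim$counts$fusions[sim$counts$child == "A"]
  expect_equal(length(sim$states[["A"]]), 12L - nf)
})

test_that("per-branch poisson event counts are calibrated", {
  # 500 replicates of a 10-myr branch at fusion rate 0.5/myr: mean ~ 5
  phy <- ape::read.tree(text = "(A:10,B:0.001)n1;")
  phy$node.label <- "n1"
  counts <- vapply(1:500, function(seed) {
    sim <- evolve_karyotypes(phy, root_chromosomes = 30,
                             blocks_per_chromosome = 1,
                             fusion_rate = 0.5, fission_rate = 0, seed = seed)
    sim$counts$fusions[sim$counts$child == "A"]
  }, numeric(1))
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(5 / 500))
})

test_that("end-to-end counting singles out a burst branch", {
  # two-regime history: one 12-myr internode dwarfs the near-instant rest,
  # so events pile onto it; decomposing each branch's (parent, child) pair
  # must recover the burst branch as the event maximum
  ag <- data.frame(label = c("r", "n2", "A", "B", "C"),
                   age = c(12.2, 0.2, 0, 0, 12), age_se = 0)
  dt <- parse_newick_dated("((A:0.2,B:0.2)n2:12,C:0.2)r;", ag)
  hits <- 0L
  for (seed in 1:10) {
    sim <- evolve_karyotypes(dt, root_chromosomes = 14,
                             blocks_per_chromosome = 2,
                             fusion_rate = 0.6, fission_rate = 0.6,
                             seed = seed, allow_breakpoint_reuse = FALSE)
    bt <- branch_times(dt)
    counted <- vapply(seq_len(nrow(bt)), function(i) {
      anc <- sim$karyotypes[[bt$parent[i]]]
      der <- sim$karyotypes[[bt$child[i]]]
      ec <- count_events(decompose(anc, der))
      ec$fusions + ec$fissions
    }, numeric(1))
    true <- sim$counts$fusions + sim$counts$fissions
    expect_equal(counted, as.numeric(true))  # exact recovery, no reuse
    if (bt$branch[which.max(counted)] == "r->n2") hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("painting emulation censors events monotonically", {
  set.seed(30)
  # threshold 1 is the identity
  k <- make_kary("k", list(c("1", "2", "3"), c("4", "5")))
  expect_identical(emulate_painting(k, 1), k)
  # threshold above every chromosome's block count collapses to one block
  k2 <- emulate_painting(k, 10)
  expect_true(all(vapply(k2$autosomes, function(ch) length(ch$blocks),
                         integer(1)) == 1L))
  # censoring can only hide events
  phy <- .sim_tree(3, scale = 2)
  for (seed in 1:15) {
    sim <- evolve_karyotypes(phy, root_chromosomes = 8,
                             blocks_per_chromosome = 2,
                             fusion_rate = 1, fission_rate = 1, seed = seed)
    root_label <- "n1"
    anc <- sim$karyotypes[[root_label]]
    for (tp in phy$tip.label) {
      der <- sim$karyotypes[[tp]]
      full <- count_events(decompose(anc, der))
      cens <- count_events(decompose(anc, emulate_painting(der, 2)))
      expect_lte(cens$fusions + cens$fissions, full$fusions + full$fissions)
    }
  }
})

test_that("presets and config files load", {
  burst <- sim_preset("burst")
  expect_equal(burst$fusion_rate + burst$fission_rate, 6)
  stasis <- sim_preset("stasis")
  expect_lt(stasis$fusion_rate, 0.1)
})

test_that("simulated histories serialize to plain text", {
  phy <- .sim_tree(3)
  sim <- evolve_karyotypes(phy, root_chromosomes = 4,
                           blocks_per_chromosome = 2,
                           fusion_rate = 0.5, fission_rate = 0.5, seed = 2)
  dir <- tempfile("karyosim")
  paths <- write_karyosim(sim, dir)
  expect_true(all(file.exists(paths)))
  # leaf homology tables parse back to the simulated karyotypes
  for (tp in phy$tip.label) {
    k <- parse_homology_table(file.path(dir, paste0("karyotype_", tp, ".tsv")))
    expect_equal(blocks_of(k[[tp]]), blocks_of(sim$karyotypes[[tp]]))
  }
  unlink(dir, recursive = TRUE)
})
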