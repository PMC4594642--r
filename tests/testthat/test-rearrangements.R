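test_that("fragment decomposition finds maximal ancestral runs", {
  # fused chromosome decomposes at the ancestral chromosome boundary
  anc <- make_kary("anc", list(c("A", "B"), "C"))
  der <- make_kary("der", list(c("A", "B", "C")))
  d <- decompose(anc, der)
  expect_length(d$fragments, 2)
  expect_equal(d$fragments[[1]]$blocks, c("A", "B"))
  expect_equal(d$fragments[[2]]$blocks, "C")

  # split ancestral chromosome: two fragments, split count 2
  d <- decompose(make_kary("anc", list(c("A", "B"))),
                 make_kary("der", list("A", "B")))
  expect_length(d$fragments, 2)
  expect_equal(d$anc_split_counts, 2L)

  # interior excision: [A,C] is not contiguous in [A,B,C]
  d <- decompose(make_kary("anc", list(c("A", "B", "C"))),
                 make_kary("der", list(c("A", "C"), "B")))
  expect_equal(lapply(d$fragments, `[[`, "blocks"), list("A", "C", "B"))
  expect_equal(d$anc_split_counts, 3L)

  # reversed runs stay contiguous (orientation-blind adjacency)
  d <- decompose(make_kary("anc", list(c("A", "B", "C"), "D")),
                 make_kary("der", list(c("D", "C", "B", "A"))))
  expect_length(d$fragments, 2)

  # unknown block names the offender
  expect_error(decompose(make_kary("anc", list("A")),
                         make_kary("der", list("Z"))),
               "Z", class = "karyorate_input_error")
})

test_that("sub-segment labels map onto the untagged ancestral block", {
  anc <- make_kary("anc", list(c("15", "16", "17")))
  # one within-block fission: 16a and 16b end up on different chromosomes
  der <- make_kary("der", list(c("15", "16a"), c("16b", "17")))
  d <- decompose(anc, der)
  ec <- count_events(d)
  expect_equal(ec$fissions, 1L)
  expect_equal(ec$fusions, 0L)
  # adjacent a|b segments of the same block are contiguous
  der2 <- make_kary("der2", list(c("15", "16a", "16b", "17")))
  ec2 <- count_events(decompose(anc, der2))
  expect_equal(c(ec2$fusions, ec2$fissions), c(0L, 0L))
})

test_that("event counts obey the fusion/fission balance", {
  id <- make_kary("k", list(c("A", "B"), "C"))
  ec <- count_events(decompose(id, id))
  expect_equal(c(ec$fusions, ec$fissions), c(0L, 0L))

  ec <- count_events(decompose(make_kary("a", list("A", "B", "C")),
                               make_kary("d", list(c("A", "B", "C")))))
  expect_equal(c(ec$fusions, ec$fissions), c(2L, 0L))

  anc <- make_kary("a", list(c("A", "B"), "C"))
  der <- make_kary("d", list("A", c("B", "C")))
  ec <- count_events(decompose(anc, der))
  expect_equal(c(ec$fusions, ec$fissions), c(1L, 1L))
  # balance: n_derived = n_ancestral + fissions - fusions
  expect_equal(2L, 2L + ec$fissions - ec$fusions)

  # classification partition always holds
  expect_equal(ec$tandem_fusions + ec$robertsonian_fusions +
                 ec$unspecified_fusions, ec$fusions)
})

test_that("fusions classify as robertsonian, tandem or unspecified", {
  # two acrocentrics (centromere at the start terminus) joined
  # centromere-to-centromere into a biarmed chromosome
  anc <- make_kary("anc", list(c("A1", "A2"), c("B1", "B2")),
                   morph = c("A", "A"), cen = c(0L, 0L))
  der <- karyotype("der", list(
    chromosome_model("1", c("A2", "A1", "B1", "B2"), morphology = "M")))
  ec <- count_events(decompose(anc, der))
  expect_equal(ec$fusions, 1L)
  expect_equal(ec$robertsonian_fusions, 1L)

  # telomere-to-telomere (head-to-tail) join: tandem fusion
  der2 <- karyotype("der2", list(
    chromosome_model("1", c("A1", "A2", "B2", "B1"), morphology = "A")))
  ec2 <- count_events(decompose(anc, der2))
  expect_equal(ec2$tandem_fusions, 1L)

  # missing centromere annotation degrades to unspecified
  anc3 <- make_kary("anc", list(c("A1", "A2"), c("B1", "B2")))
  ec3 <- count_events(decompose(anc3, der))
  expect_equal(ec3$unspecified_fusions, 1L)

  # interior breakpoint end: not an ancestral terminus, unspecified
  anc4 <- make_kary("anc", list(c("A1", "A2", "A3"), c("B1", "B2")),
                    morph = c("A", "A"), cen = c(0L, 0L))
  der4 <- karyotype("der4", list(
    chromosome_model("1", c("A3", "A2", "B1", "B2"), morphology = "M"),
    chromosome_model("2", "A1", morphology = "A")))
  ec4 <- count_events(decompose(anc4, der4))
  expect_equal(ec4$fusions, 1L)
  expect_equal(ec4$unspecified_fusions, 1L)
})

test_that("identity decomposition is event-free for random karyotypes", {
  set.seed(21)
  phy <- ape::rtree(4)
  phy$node.label <- paste0("n", 1:3)
  for (seed in 1:10) {
    sim <- evolve_karyotypes(phy, root_chromosomes = 6,
                             blocks_per_chromosome = 2,
                             fusion_rate = 1, fission_rate = 1, seed = seed)
    for (k in sim$karyotypes[phy$tip.label]) {
      ec <- count_events(decompose(k, k))
      expect_equal(c(ec$fusions, ec$fissions), c(0L, 0L))
    }
  }
})

test_that("event counts serialize to TSV", {
  anc <- make_kary("a", list("A", "B"))
  der <- make_kary("d", list(c("A", "B")))
  txt <- write_event_counts(list("a->d" = count_events(decompose(anc, der))))
  expect_match(txt, "a->d\t1\t0\t0\t0\t1")
})
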