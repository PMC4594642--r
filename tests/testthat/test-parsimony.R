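test_that("character matrices collect the union of associations", {
  kA <- make_kary("A", list(c("17", "18")))
  kB <- make_kary("B", list(c("17", "18")))
  m <- build_character_matrix(list(kA, kB))
  expect_equal(colnames(m), "17+18")
  expect_equal(unname(m[, "17+18"]), c(1L, 1L))

  kC <- make_kary("C", list("17", "18"))
  m <- build_character_matrix(list(kA, kC))
  expect_equal(unname(m[, "17+18"]), c(1L, 0L))

  expect_error(build_character_matrix(list()), class = "karyorate_input_error")
  expect_error(build_character_matrix(list(kA, make_kary("A", list("9")))),
               "duplicate", class = "karyorate_input_error")
})

test_that("character matrix exports as TSV and NEXUS-like block", {
  m <- build_character_matrix(list(make_kary("A", list(c("1", "2"))),
                                   make_kary("B", list("1", "2"))))
  tsv <- format_character_matrix(m, "tsv")
  expect_match(tsv, "taxon\t1\\+2")
  expect_match(tsv, "A\t1\nB\t0\n")
  nex <- format_character_matrix(m, "nexus")
  expect_match(nex, "NTAX=2 NCHAR=1")
})

# the subfamily topology used throughout: outgroup MCA, then the
# Phyllostominae clade (TSA,(LOC,MCR))
.subfamily_tree <- function() {
  ape::read.tree(text = "((TSA:3,(LOC:1,MCR:1)N2:2)N1:1,MCA:4)R;")
}

test_that("shared associations are placed at the subfamily ancestor", {
  phy <- .subfamily_tree()
  karyos <- list(make_kary("TSA", list(c("17", "18"))),
                 make_kary("LOC", list(c("17", "18"))),
                 make_kary("MCR", list(c("17", "18"))),
                 make_kary("MCA", list("17", "18")))
  m <- build_character_matrix(karyos)
  fit <- fitch_parsimony(phy, m, outgroup = "MCA")
  expect_equal(fit$scores[["17+18"]], 1L)
  expect_false(fit$homoplasy[["17+18"]])
  # present at the TSA/LOC/MCR ancestor (N1), absent at the root
  expect_equal(fit$node_states["N1", "17+18"], 1L)
  expect_equal(fit$node_states["R", "17+18"], 0L)
  expect_equal(synapomorphies_at(fit, "N1"), "17+18")
  expect_equal(synapomorphies_at(fit, "N2"), character(0))
  expect_error(synapomorphies_at(fit, "TSA"), class = "karyorate_input_error")
})

test_that("constant characters score zero and convergent ones flag homoplasy", {
  phy <- ape::read.tree(text = "((((a:1,b:1)n3:1,c:2)n2:1,d:3)n1:1,e:4)r;")
  m <- matrix(c(1, 1, 1, 1, 1,   # constant
                1, 0, 1, 0, 0),  # present in two non-sister leaves a, c
              nrow = 5, dimnames = list(c("a", "b", "c", "d", "e"),
                                        c("const", "conv")))
  class(m) <- c("character_matrix", class(m))
  fit <- fitch_parsimony(phy, m, outgroup = "e")
  expect_equal(fit$scores[["const"]], 0L)
  expect_true(all(fit$node_states[, "const"] == 1L))
  # constant-present character is synapomorphic nowhere
  for (nd in rownames(fit$node_states))
    expect_false("const" %in% synapomorphies_at(fit, nd))
  expect_equal(fit$scores[["conv"]], 2L)
  expect_true(fit$homoplasy[["conv"]])
})

test_that("fitch scores equal exhaustive enumeration and phangorn", {
  set.seed(42)
  has_phangorn <- requireNamespace("phangorn", quietly = TRUE)
  for (rep in 1:120) {
    ntip <- sample(4:6, 1)
    phy <- ape::rtree(ntip)
    phy$node.label <- paste0("n", seq_len(phy$Nnode))
    states <- stats::setNames(sample(0:1, ntip, TRUE), phy$tip.label)
    if (all(states == states[1])) states[1] <- 1L - states[1]
    m <- matrix(states, ncol = 1, dimnames = list(names(states), "c1"))
    fit <- fitch_parsimony(phy, m, outgroup = phy$tip.label[1])
    expect_equal(unname(fit$scores), fitch_exhaustive(phy, states))
    if (has_phangorn) {
      pd <- phangorn::phyDat(m, type = "USER", levels = c(0, 1))
      expect_equal(unname(fit$scores),
                   as.integer(phangorn::fitch(phy, pd)))
    }
  }
})

test_that("identical inputs give identical assignments", {
  set.seed(9)
  phy <- ape::rtree(6)
  phy$node.label <- paste0("n", seq_len(phy$Nnode))
  m <- matrix(sample(0:1, 6 * 4, TRUE), nrow = 6,
              dimnames = list(phy$tip.label, paste0("c", 1:4)))
  f1 <- fitch_parsimony(phy, m, phy$tip.label[1])
  f2 <- fitch_parsimony(phy, m, phy$tip.label[1])
  expect_identical(f1$node_states, f2$node_states)
  expect_identical(f1$scores, f2$scores)
})

test_that("adding a taxon matching its sister never raises a score", {
  set.seed(13)
  for (rep in 1:40) {
    ntip <- sample(4:6, 1)
    phy <- ape::rtree(ntip)
    phy$node.label <- paste0("n", seq_len(phy$Nnode))
    states <- stats::setNames(sample(0:1, ntip, TRUE), phy$tip.label)
    if (all(states == states[1])) states[1] <- 1L - states[1]
    base <- fitch_exhaustive(phy, states)
    # graft a twin of a random tip as its sister
    victim <- sample(phy$tip.label, 1)
    phy2 <- phy
    where <- which(phy2$tip.label == victim)
    phy2 <- ape::bind.tree(phy2, ape::read.tree(text = "(twin:1);"),
                           where = where)
    phy2$node.label <- paste0("m", seq_len(phy2$Nnode))
    states2 <- c(states, twin = unname(states[victim]))
    expect_lte(fitch_exhaustive(phy2, states2), base)
    m2 <- matrix(states2[phy2$tip.label], ncol = 1,
                 dimnames = list(phy2$tip.label, "c1"))
    fit <- fitch_parsimony(phy2, m2, phy2$tip.label[1])
    expect_equal(unname(fit$scores), fitch_exhaustive(phy2, states2))
  }
})
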