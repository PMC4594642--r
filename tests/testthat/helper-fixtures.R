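# Shared fixtures and independent oracles.  Everything is built in code;
# oracles deliberately avoid the code paths they are used to check.

# quick karyotype from a list of block-label vectors
make_kary <- function(species, chroms, morph = NULL, cen = NULL) {
  autos <- lapply(seq_along(chroms), function(i)
    chromosome_model(as.character(i), chroms[[i]],
                     morphology = if (is.null(morph)) "unspecified" else morph[[i]],
                     centromere_index = if (is.null(cen)) NULL else cen[[i]]))
  karyotype(species, autos)
}

# random dated tree with labelled internal nodes and ultrametric-ish ages
random_dated_tree <- function(ntip) {
  phy <- ape::rtree(ntip)
  phy$node.label <- paste0("n", seq_len(phy$Nnode))
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth
  # jitter tip ages to 0 (extant) while keeping internal ages
  ages[seq_len(ntip)] <- 0
  labels <- c(phy$tip.label, phy$node.label)
  # rtree branch lengths can make an internal age 0; lift all internal ages
  ages[-seq_len(ntip)] <- ages[-seq_len(ntip)] + 0.1
  ses <- stats::runif(length(labels), 0, 0.05)
  ses[seq_len(ntip)] <- 0
  dated_tree(phy, stats::setNames(ages, labels), stats::setNames(ses, labels))
}

# exhaustive-enumeration parsimony oracle: minimum state changes over all
# 0/1 labelings of the internal nodes
fitch_exhaustive <- function(phy, states) {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  node_state <- integer(ntip + nint)
  node_state[seq_len(ntip)] <- states[phy$tip.label]
  best <- Inf
  for (code in 0:(2^nint - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(nint)]
    node_state[(ntip + 1):(ntip + nint)] <- lab
    changes <- sum(node_state[phy$edge[, 1]] != node_state[phy$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# exact Wright-Fisher fixation probability by Markov-chain absorption;
# independent of both simulate_fixation and the diffusion quadrature
exact_wf_fixation <- function(N, s, initial_copies = 1) {
  twoN <- 2L * N
  states <- 0:twoN
  pnext <- function(i) {
    p <- i / twoN; q <- 1 - p
    p * (p + (1 - s) * q) / (1 - 2 * p * q * s)
  }
  P <- t(vapply(states, function(i) stats::dbinom(states, twoN, pnext(i)),
                numeric(twoN + 1)))
  Q <- P[2:twoN, 2:twoN]
  R <- P[2:twoN, twoN + 1]
  sol <- solve(diag(twoN - 1) - Q, R)
  sol[initial_copies]
}

# homology TSV builder
homology_tsv <- function(rows) {
  header <- "species\tchrom_id\tposition\tblock\tarm\tsegment\tcentromere_flag\tmorphology"
  paste(c(header, rows), collapse = "\n")
}
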