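# Synthetic karyotype histories ----------------------------------------------
#
# The generator evolves a root karyotype along a dated tree by sampling
# Poisson numbers of fusions and fissions per branch and applying them
# sequentially.  Every applied event is logged with the exact operands, so
# any node state can be reproduced by replaying the log - the ground truth
# against which the counting module is tested.
#
# Internal state: a list of chromosomes, each a character vector of block
# labels; chromosome list order is the only bookkeeping and every event
# mutates it deterministically (operands removed, products appended), so a
# log replay is RNG-free.

.base_pair <- function(a, b) {
  ba <- parse_block_label(a); bb <- parse_block_label(b)
  la <- block_label(ba$outgroup_chrom, ba$arm, "none")
  lb <- block_label(bb$outgroup_chrom, bb$arm, "none")
  paste(sort(c(la, lb)), collapse = "|")
}

.state_adjacencies <- function(chroms) {
  out <- character(0)
  for (ch in chroms)
    if (length(ch) >= 2L)
      for (i in seq_len(length(ch) - 1L))
        out <- c(out, .base_pair(ch[i], ch[i + 1L]))
  unique(out)
}

.apply_fusion <- function(chroms, i, j, end_i, end_j) {
  a <- chroms[[i]]; b <- chroms[[j]]
  if (end_i == "L") a <- rev(a)
  if (end_j == "R") b <- rev(b)
  fused <- c(a, b)
  chroms[[max(i, j)]] <- NULL; chroms[[min(i, j)]] <- NULL
  c(chroms, list(fused))
}

.apply_fission <- function(chroms, i, junction) {
  ch <- chroms[[i]]
  left <- ch[seq_len(junction)]
  right <- ch[(junction + 1L):length(ch)]
  chroms[[i]] <- NULL
  c(chroms, list(left), list(right))
}

.apply_fission_within <- function(chroms, i, pos) {
  ch <- chroms[[i]]
  p <- parse_block_label(ch[pos])
  la <- block_label(p$outgroup_chrom, p$arm, "a")
  lb <- block_label(p$outgroup_chrom, p$arm, "b")
  left <- c(if (pos > 1L) ch[seq_len(pos - 1L)], la)
  right <- c(lb, if (pos < length(ch)) ch[(pos + 1L):length(ch)])
  chroms[[i]] <- NULL
  c(chroms, list(left), list(right))
}

.sim_state_to_karyotype <- function(chroms, species) {
  autos <- lapply(seq_along(chroms), function(i)
    chromosome_model(sprintf("c%d", i), chroms[[i]]))
  karyotype(species, autos)
}

#' Simulate karyotype evolution along a dated tree
#'
#' Starting from a root karyotype of `root_chromosomes` chromosomes with
#' `blocks_per_chromosome` uniquely labelled blocks each (labels `"1"`,
#' `"2"`, ... in the outgroup naming convention), each branch receives
#' `Poisson(rate * branch time)` fusion and fission events, applied
#' sequentially in a random interleaving.  A fusion joins two uniformly
#' chosen chromosomes at uniformly chosen ends; a fission splits a
#' uniformly chosen eligible chromosome at a uniform junction, falling
#' back to a within-block split (creating `a`/`b` segment labels) when no
#' junction is available.  With `allow_breakpoint_reuse = FALSE` fissions
#' are restricted to junctions already present in the root karyotype and
#' fusions may not recreate any adjacency previously seen on the lineage,
#' which makes the parsimony event counts of [count_events()] exact per
#' branch.  Events that cannot be placed are logged as skips, never
#' errors.
#'
#' @param tree A [dated_tree()] (or rooted `phylo` with labelled nodes and
#'   branch lengths in myr, which is converted internally).
#' @param root_chromosomes Number of root chromosomes (>= 2).
#' @param blocks_per_chromosome Blocks per root chromosome (>= 1).
#' @param fusion_rate,fission_rate Event rates per myr (>= 0).
#' @param allow_breakpoint_reuse Allow events that reuse breakpoints
#'   (default TRUE).
#' @param seed Integer RNG seed.
#' @return Object of class `"karyosim"`: list with `tree`, `states`
#'   (chromosome lists per node label), `karyotypes` ([karyotype()] per
#'   node), `events` (per child-node label: list of event records),
#'   `counts` (data frame branch/child/fusions/fissions of applied
#'   events), `config`.
#' @export
evolve_karyotypes <- function(tree, root_chromosomes,
                              blocks_per_chromosome = 1L,
                              fusion_rate, fission_rate,
                              allow_breakpoint_reuse = TRUE, seed = NULL) {
  if (inherits(tree, "phylo")) {
    ages <- ape::node.depth.edgelength(tree)
    ages <- max(ages) - ages
    labels <- c(tree$tip.label, tree$node.label)
    tree <- dated_tree(tree, stats::setNames(ages, labels))
  }
  stopifnot(inherits(tree, "dated_tree"))
  if (root_chromosomes < 2) stop_input("root_chromosomes must be >= 2")
  if (blocks_per_chromosome < 1) stop_input("blocks_per_chromosome must be >= 1")
  if (fusion_rate < 0 || fission_rate < 0) stop_input("rates must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  nb <- root_chromosomes * blocks_per_chromosome
  root_state <- split(as.character(seq_len(nb)),
                      rep(seq_len(root_chromosomes),
                          each = blocks_per_chromosome))
  root_state <- unname(lapply(root_state, as.character))
  root_adj <- .state_adjacencies(root_state)

  phy <- tree$phy
  ntip <- length(phy$tip.label)
  labels <- c(phy$tip.label, phy$node.label)
  bt <- branch_times(tree)
  root_label <- phy$node.label[1L]

  states <- list(); events <- list(); history <- list()
  states[[root_label]] <- root_state
  history[[root_label]] <- root_adj
  counts <- data.frame(branch = character(0), child = character(0),
                       fusions = integer(0), fissions = integer(0),
                       stringsAsFactors = FALSE)

  for (e in seq_len(nrow(bt))) {
    parent <- bt$parent[e]; child <- bt$child[e]
    chroms <- states[[parent]]
    hist <- history[[parent]]
    t <- bt$time[e]
    nf <- stats::rpois(1L, fusion_rate * t)
    ns <- stats::rpois(1L, fission_rate * t)
    kinds <- c(rep("fusion", nf), rep("fission", ns))
    if (length(kinds) > 1L) kinds <- sample(kinds)
    log <- list()
    n_fus <- 0L; n_fis <- 0L
    for (kind in kinds) {
      if (kind == "fusion") {
        if (length(chroms) < 2L) {
          log[[length(log) + 1L]] <- list(type = "skipped_fusion",
                                          reason = "single chromosome")
          next
        }
        placed <- FALSE
        for (try in seq_len(30L)) {
          ij <- sample.int(length(chroms), 2L)
          end_i <- sample(c("L", "R"), 1L)
          end_j <- sample(c("L", "R"), 1L)
          a <- chroms[[ij[1L]]]; b <- chroms[[ij[2L]]]
          tip_a <- if (end_i == "L") a[1L] else a[length(a)]
          tip_b <- if (end_j == "L") b[1L] else b[length(b)]
          adj <- .base_pair(tip_a, tip_b)
          if (!allow_breakpoint_reuse && adj %in% hist) next
          chroms <- .apply_fusion(chroms, ij[1L], ij[2L], end_i, end_j)
          hist <- union(hist, adj)
          log[[length(log) + 1L]] <- list(type = "fusion", i = ij[1L],
                                          j = ij[2L], end_i = end_i,
                                          end_j = end_j, adjacency = adj)
          n_fus <- n_fus + 1L
          placed <- TRUE
          break
        }
        if (!placed)
          log[[length(log) + 1L]] <- list(type = "skipped_fusion",
                                          reason = "no reusable-free junction")
      } else {
        cand <- list()  # (chrom index, junction index) pairs
        for (ci in seq_along(chroms)) {
          ch <- chroms[[ci]]
          if (length(ch) < 2L) next
          for (jx in seq_len(length(ch) - 1L)) {
            if (!allow_breakpoint_reuse &&
                !(.base_pair(ch[jx], ch[jx + 1L]) %in% root_adj)) next
            cand[[length(cand) + 1L]] <- c(ci, jx)
          }
        }
        if (length(cand)) {
          chosen_ci <- unique(vapply(cand, `[`, numeric(1), 1L))
          ci <- if (length(chosen_ci) == 1L) chosen_ci
                else sample(chosen_ci, 1L)
          jopts <- Filter(function(z) z[1L] == ci, cand)
          jx <- if (length(jopts) == 1L) jopts[[1L]][2L]
                else sample(vapply(jopts, `[`, numeric(1), 2L), 1L)
          chroms <- .apply_fission(chroms, ci, jx)
          log[[length(log) + 1L]] <- list(type = "fission", i = ci,
                                          junction = jx)
          n_fis <- n_fis + 1L
        } else {
          within <- which(vapply(chroms, function(ch)
            length(ch) == 1L &&
              parse_block_label(ch)$segment == "none", logical(1)))
          if (!allow_breakpoint_reuse) {
            # within-block split is always a fresh breakpoint
          }
          if (length(within)) {
            ci <- if (length(within) == 1L) within else sample(within, 1L)
            split_block <- chroms[[ci]][1L]
            chroms <- .apply_fission_within(chroms, ci, 1L)
            # record the fresh intra-block breakpoint so a later fusion
            # cannot silently rejoin the a|b segments
            hist <- union(hist, .base_pair(split_block, split_block))
            log[[length(log) + 1L]] <- list(type = "fission_within", i = ci,
                                            pos = 1L)
            n_fis <- n_fis + 1L
          } else {
            log[[length(log) + 1L]] <- list(type = "skipped_fission",
                                            reason = "no eligible junction or splittable block")
          }
        }
      }
    }
    states[[child]] <- chroms
    history[[child]] <- hist
    events[[child]] <- log
    counts[nrow(counts) + 1L, ] <- list(bt$branch[e], child, n_fus, n_fis)
  }

  karyos <- lapply(names(states), function(lb)
    .sim_state_to_karyotype(states[[lb]], lb))
  names(karyos) <- names(states)
  structure(list(tree = tree, states = states, karyotypes = karyos,
                 events = events, counts = counts,
                 config = list(root_chromosomes = root_chromosomes,
                               blocks_per_chromosome = blocks_per_chromosome,
                               fusion_rate = fusion_rate,
                               fission_rate = fission_rate,
                               allow_breakpoint_reuse = allow_breakpoint_reuse,
                               seed = seed)),
            class = "karyosim")
}

#' Replay a simulated event log from the root
#'
#' Re-applies every logged event from the root state, independently of the
#' stochastic path taken by [evolve_karyotypes()]; the replayed node
#' states must equal the simulated ones exactly (the generator's defining
#' invariant, exercised in the test suite).
#'
#' @param sim A `"karyosim"` object.
#' @return Named list of chromosome-list states per node label.
#' @export
replay_history <- function(sim) {
  stopifnot(inherits(sim, "karyosim"))
  bt <- branch_times(sim$tree)
  root_label <- sim$tree$phy$node.label[1L]
  states <- list()
  states[[root_label]] <- sim$states[[root_label]]
  for (e in seq_len(nrow(bt))) {
    chroms <- states[[bt$parent[e]]]
    for (ev in sim$events[[bt$child[e]]]) {
      chroms <- switch(ev$type,
        fusion = .apply_fusion(chroms, ev$i, ev$j, ev$end_i, ev$end_j),
        fission = .apply_fission(chroms, ev$i, ev$junction),
        fission_within = .apply_fission_within(chroms, ev$i, ev$pos),
        chroms)  # skips are no-ops
    }
    states[[bt$child[e]]] <- chroms
  }
  states
}

#' Degrade a karyotype to painting resolution
#'
#' Cross-species painting misses short homologous segments.  Any maximal
#' run of consecutive blocks sharing the same base label (outgroup
#' chromosome + arm) that is shorter than `min_detectable_blocks` is
#' absorbed into the flanking segment: its blocks fall below resolution
#' and disappear from the map.  The shortest undersized run (leftmost on
#' ties) is removed first and runs are recomputed, until every remaining
#' run is detectable or only one run is left on the chromosome.
#' `min_detectable_blocks = 1` is the identity; a threshold larger than a
#' chromosome's block count collapses it to its last surviving run.
#'
#' @param k A [karyotype()].
#' @param min_detectable_blocks Detection threshold in blocks (>= 1).
#' @return A [karyotype()] satisfying the usual invariants.
#' @export
emulate_painting <- function(k, min_detectable_blocks) {
  stopifnot(inherits(k, "karyotype"))
  if (min_detectable_blocks < 1) stop_input("min_detectable_blocks must be >= 1")
  base_of <- function(lb) {
    p <- parse_block_label(lb)
    block_label(p$outgroup_chrom, p$arm, "none")
  }
  shrink <- function(blocks) {
    repeat {
      bases <- vapply(blocks, base_of, character(1))
      run_id <- cumsum(c(TRUE, bases[-1L] != bases[-length(bases)]))
      lens <- tabulate(run_id)
      if (max(run_id) == 1L || all(lens >= min_detectable_blocks))
        return(blocks)
      short <- which(lens < min_detectable_blocks)
      victim <- short[which.min(lens[short])]
      blocks <- blocks[run_id != victim]
    }
  }
  autos <- lapply(k$autosomes, function(ch)
    chromosome_model(ch$chrom_id, shrink(ch$blocks),
                     morphology = ch$morphology))
  karyotype(k$species, autos, sex_chromosomes = k$sex_chromosomes)
}

#' Ship-with defaults for simulation regimes
#'
#' Two presets bracketing the regimes seen in comparative painting data:
#' `"stasis"` (near-zero rates, long unchanged lineages) and `"burst"`
#' (about 6 events/myr split evenly between fusions and fissions, the
#' tempo of a rapid karyotypic repatterning).  The same key-value files
#' ship under `inst/extdata/presets/`.
#'
#' @param name `"stasis"` or `"burst"`.
#' @return List with `fusion_rate` and `fission_rate` (events/myr).
#' @export
sim_preset <- function(name = c("stasis", "burst")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".cfg"),
                      package = "karyorate")
  cfg <- read_config(path)
  list(fusion_rate = as.numeric(cfg$fusion_rate),
       fission_rate = as.numeric(cfg$fission_rate))
}

#' Read a flat key-value config file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#'
#' @param path File path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop_input("malformed config line: %s", lines[bad][1])
  stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, 1L, FUN.VALUE = character(1)))
}

#' Write a simulated history to plain-text files
#'
#' Emits one homology TSV per leaf (the dialect of
#' [parse_homology_table()]), an event-count TSV, and the input tree as
#' Newick plus an ages TSV.
#'
#' @param sim A `"karyosim"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_karyosim <- function(sim, dir) {
  stopifnot(inherits(sim, "karyosim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  tips <- sim$tree$phy$tip.label
  for (tp in tips) {
    p <- file.path(dir, paste0("karyotype_", tp, ".tsv"))
    write_homology_table(sim$karyotypes[[tp]], p)
    paths <- c(paths, p)
  }
  cp <- file.path(dir, "event_counts.tsv")
  utils::write.table(sim$counts, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wt <- write_newick_dated(sim$tree)
  np <- file.path(dir, "tree.nwk")
  writeLines(wt$newick, np)
  ap <- file.path(dir, "ages.tsv")
  utils::write.table(wt$ages, ap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, cp, np, ap))
}
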