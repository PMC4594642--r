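#' Build a binary association character matrix
#'
#' Columns are the union of syntenic associations observed across the input
#' karyotypes; entry (taxon, association) is 1 when the association is
#' present on that species' autosomes.  By construction every column has at
#' least one 1; all-zero characters cannot arise.
#'
#' @param karyotypes List of [karyotype()] objects (>= 2, unique species).
#' @return Integer matrix with species as rownames and association labels
#'   as colnames, class `"character_matrix"`.
#' @export
build_character_matrix <- function(karyotypes) {
  if (!is.list(karyotypes) || length(karyotypes) < 2L)
    stop_input("need at least two karyotypes")
  sp <- vapply(karyotypes, `[[`, character(1), "species")
  if (anyDuplicated(sp))
    stop_input("duplicate species label: %s", sp[duplicated(sp)][1])
  assoc <- lapply(karyotypes, associations_of)
  chars <- sort(unique(unlist(assoc)))
  m <- matrix(0L, nrow = length(sp), ncol = length(chars),
              dimnames = list(sp, chars))
  for (i in seq_along(sp)) m[i, assoc[[i]]] <- 1L
  structure(m, class = c("character_matrix", class(m)))
}

#' Export a character matrix as TSV or a NEXUS-like block
#'
#' @param m A [build_character_matrix()] result.
#' @param format `"tsv"` (taxa rows x association columns) or `"nexus"`
#'   (plain characters block).
#' @return A single string.
#' @export
format_character_matrix <- function(m, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    header <- paste(c("taxon", colnames(m)), collapse = "\t")
    body <- vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), character(1))
    return(paste0(paste(c(header, body), collapse = "\n"), "\n"))
  }
  body <- vapply(seq_len(nrow(m)), function(i)
    sprintf("    %s  %s", rownames(m)[i], paste(m[i, ], collapse = "")),
    character(1))
  paste0("#NEXUS\nBEGIN CHARACTERS;\n",
         sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;\n", nrow(m), ncol(m)),
         "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\";\n  MATRIX\n",
         paste(body, collapse = "\n"),
         "\n  ;\nEND;\n")
}

# Generalized Fitch down-pass for one binary character on a rooted tree.
# Returns the per-node state sets (coded 1=absent{0}, 2=present{1},
# 3=ambiguous{0,1}) and the minimum change count.  Polytomies are handled
# by the state-count rule (keep states present in the maximal number of
# child sets; add children minus that count to the score).
.fitch_down <- function(phy, states) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  setv <- integer(nn)
  setv[seq_len(ntip)] <- ifelse(states[phy$tip.label] == 1L, 2L, 1L)
  score <- 0L
  po <- ape::reorder.phylo(phy, "postorder")
  children <- split(po$edge[, 2L], po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {
    kids <- children[[as.character(node)]]
    n0 <- sum(setv[kids] %in% c(1L, 3L))
    n1 <- sum(setv[kids] %in% c(2L, 3L))
    # a child with set {0,1} supports either state for free
    amb <- sum(setv[kids] == 3L)
    c0 <- n0; c1 <- n1
    m <- max(c0, c1)
    setv[node] <- if (c0 == m && c1 == m) 3L else if (c0 == m) 1L else 2L
    score <- score + (length(kids) - m)
  }
  list(set = setv, score = score)
}

#' Fitch parsimony for syntenic-association characters
#'
#' Runs an unordered binary Fitch pass per character over the tree topology
#' (node ages are ignored here; they feed the downstream rate step).  The
#' root state, and any interior state left ambiguous, is resolved toward
#' the outgroup's observed state, so all polarity decisions rest on the
#' outgroup.  A character is flagged homoplasious when its minimum change
#' count exceeds 1.
#'
#' @param tree A [dated_tree()] or `ape::phylo` (rooted, labelled nodes).
#' @param matrix A [build_character_matrix()] result; all taxa must be tree
#'   leaves.
#' @param outgroup Leaf label used to polarize states.
#' @return Object of class `"ancestral_assignment"`: list with
#'   `node_states` (internal nodes x characters 0/1 matrix), `scores`
#'   (named integer vector of minimum changes), `homoplasy` (logical),
#'   `leaf_states`, `outgroup`, `tree`.
#' @export
fitch_parsimony <- function(tree, matrix, outgroup) {
  phy <- if (inherits(tree, "dated_tree")) tree$phy else tree
  if (!inherits(phy, "phylo")) stop_input("tree must be a phylo or dated_tree")
  if (!ape::is.rooted(phy)) stop_input("tree must be rooted")
  if (is.null(phy$node.label)) stop_input("internal nodes must be labelled")
  taxa <- rownames(matrix)
  missing_taxa <- setdiff(taxa, phy$tip.label)
  if (length(missing_taxa))
    stop_input("taxa not in tree: %s", paste(missing_taxa, collapse = ", "))
  if (!(outgroup %in% phy$tip.label))
    stop_input("outgroup '%s' is not a tree leaf", outgroup)
  if (!(outgroup %in% taxa))
    stop_input("outgroup '%s' has no character data", outgroup)
  phy <- ape::keep.tip(phy, taxa)
  ntip <- length(phy$tip.label)
  labels <- c(phy$tip.label, phy$node.label)
  root <- ntip + 1L
  chars <- colnames(matrix)
  node_states <- matrix(0L, nrow = phy$Nnode, ncol = length(chars),
                        dimnames = list(phy$node.label, chars))
  scores <- stats::setNames(integer(length(chars)), chars)
  cw <- ape::reorder.phylo(phy, "cladewise")
  for (j in seq_along(chars)) {
    x <- stats::setNames(matrix[, j], rownames(matrix))
    dp <- .fitch_down(phy, x)
    scores[j] <- dp$score
    og <- x[[outgroup]]
    assign <- integer(ntip + phy$Nnode)
    assign[seq_len(ntip)] <- x[phy$tip.label]
    rs <- dp$set[root]
    assign[root] <- if (rs == 3L) og else rs - 1L
    for (e in seq_len(nrow(cw$edge))) {
      p <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]
      if (ch <= ntip) next
      s <- dp$set[ch]
      assign[ch] <- if (s == 3L) {
        # ambiguous: prefer the outgroup (ancestral) state; the parent
        # state is the fallback kept for completeness
        og
      } else s - 1L
    }
    node_states[, j] <- assign[(ntip + 1L):(ntip + phy$Nnode)]
  }
  structure(list(node_states = node_states,
                 scores = scores,
                 homoplasy = scores > 1L,
                 leaf_states = matrix[phy$tip.label, , drop = FALSE],
                 outgroup = outgroup,
                 tree = phy),
            class = "ancestral_assignment")
}

#' Synapomorphies assigned to an internal node
#'
#' Associations assigned present at `node` and absent at its parent; for
#' the root and its direct children the outgroup's observed state is the
#' reference, so gains are polarized exactly as in the painting literature.
#'
#' @param assignment An [fitch_parsimony()] result.
#' @param node Internal node label.
#' @return Character vector of association labels.
#' @export
synapomorphies_at <- function(assignment, node) {
  stopifnot(inherits(assignment, "ancestral_assignment"))
  phy <- assignment$tree
  if (node %in% phy$tip.label) stop_input("'%s' is a leaf, not an internal node", node)
  if (!(node %in% phy$node.label)) stop_input("unknown internal node '%s'", node)
  ntip <- length(phy$tip.label)
  labels <- c(phy$tip.label, phy$node.label)
  num <- ntip + match(node, phy$node.label)
  root <- ntip + 1L
  chars <- colnames(assignment$node_states)
  here <- as.integer(assignment$node_states[node, ])
  parent_num <- phy$edge[phy$edge[, 2L] == num, 1L]
  ref <- if (num == root || (length(parent_num) && parent_num == root)) {
    as.integer(assignment$leaf_states[assignment$outgroup, ])
  } else {
    as.integer(assignment$node_states[labels[parent_num], ])
  }
  chars[here == 1L & ref == 0L]
}
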