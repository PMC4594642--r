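#' Construct a dated tree with node-age standard errors
#'
#' Wraps an `ape` phylo object together with node ages (myr before present)
#' and their standard errors, as produced by a relaxed-clock dating
#' analysis.  Every internal node must be strictly older than each of its
#' children, so every internodal time `parent age - child age` is positive.
#'
#' @param phy A rooted `ape::phylo` with labelled internal nodes.
#' @param ages Named numeric vector of node ages (myr); names are tip and
#'   node labels.  Tips missing from `ages` are taken as extant (age 0).
#' @param ses Named numeric vector of age standard errors (myr); missing
#'   entries default to 0.
#' @return An object of class `"dated_tree"`: a list with elements `phy`,
#'   `ages` and `ses`, both vectors indexed by node number (tips first, as
#'   in `phylo`).
#' @export
dated_tree <- function(phy, ages, ses = numeric(0)) {
  if (!inherits(phy, "phylo")) stop_input("phy must be an ape phylo object")
  if (!ape::is.rooted(phy)) stop_input("tree must be rooted")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (is.null(phy$node.label) || any(!nzchar(phy$node.label)))
    stop_input("every internal node must be labelled")
  if (anyDuplicated(c(phy$tip.label, phy$node.label)))
    stop_input("tip and node labels must be unique")
  labels <- c(phy$tip.label, phy$node.label)
  age <- numeric(ntip + nnode)
  se <- numeric(ntip + nnode)
  missing_internal <- setdiff(phy$node.label, names(ages))
  if (length(missing_internal))
    stop_input("ages table lacks internal node(s): %s",
               paste(missing_internal, collapse = ", "))
  for (i in seq_along(labels)) {
    lb <- labels[i]
    if (lb %in% names(ages)) age[i] <- ages[[lb]]
    if (lb %in% names(ses)) se[i] <- ses[[lb]]
  }
  if (any(se < 0)) stop_input("age standard errors must be >= 0")
  # chronology: every branch must have positive duration
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    if (age[p] <= age[ch])
      stop_input("chronology error: node '%s' (%.4g myr) not older than child '%s' (%.4g myr)",
                 labels[p], age[p], labels[ch], age[ch])
  }
  structure(list(phy = phy, ages = stats::setNames(age, labels),
                 ses = stats::setNames(se, labels)),
            class = "dated_tree")
}

#' Parse a Newick tree plus a node-age table into a dated tree
#'
#' @param newick Newick string or path to a Newick file (rooted, internal
#'   nodes labelled).
#' @param ages A data frame with columns `label`, `age`, `age_se`, or a
#'   path to such a TSV.
#' @return A [dated_tree()].
#' @export
#' @examples
#' ag <- data.frame(label = c("N1", "R"), age = c(1, 2), age_se = c(0.2, 0.3))
#' dt <- parse_newick_dated("((A:1,B:1)N1:1,C:2)R;", ag)
#' branch_times(dt)
parse_newick_dated <- function(newick, ages) {
  stopifnot(is.character(newick), length(newick) == 1L)
  phy <- if (grepl("[();]", newick)) ape::read.tree(text = newick)
         else ape::read.tree(newick)
  if (is.null(phy)) stop_input("could not parse Newick input")
  if (is.character(ages))
    ages <- utils::read.delim(ages, stringsAsFactors = FALSE)
  req <- c("label", "age")
  if (!all(req %in% names(ages)))
    stop_input("ages table needs columns 'label' and 'age'")
  if (!"age_se" %in% names(ages)) ages$age_se <- 0
  dated_tree(phy,
             stats::setNames(ages$age, ages$label),
             stats::setNames(ages$age_se, ages$label))
}

#' Serialize a dated tree
#'
#' @param dt A [dated_tree()].
#' @return A list with elements `newick` (string) and `ages` (data frame
#'   with `label`, `age`, `age_se`), the inverse of [parse_newick_dated()].
#' @export
write_newick_dated <- function(dt) {
  stopifnot(inherits(dt, "dated_tree"))
  list(newick = ape::write.tree(dt$phy),
       ages = data.frame(label = names(dt$ages),
                         age = unname(dt$ages),
                         age_se = unname(dt$ses),
                         stringsAsFactors = FALSE))
}

#' Internodal times of a dated tree
#'
#' One row per branch in preorder (root outwards).  The branch SE combines
#' the two node-age standard errors as `sqrt(se_parent^2 + se_child^2)`
#' (independent-error propagation); supplying a published per-branch SE
#' directly to [branch_rate()] bypasses this choice.
#'
#' @param dt A [dated_tree()].
#' @return Data frame with columns `branch` (`"parent->child"`), `parent`,
#'   `child`, `time` (myr) and `time_se` (myr).
#' @export
branch_times <- function(dt) {
  stopifnot(inherits(dt, "dated_tree"))
  phy <- ape::reorder.phylo(dt$phy, "cladewise")
  labels <- names(dt$ages)
  out <- data.frame(branch = character(0), parent = character(0),
                    child = character(0), time = numeric(0),
                    time_se = numeric(0), stringsAsFactors = FALSE)
  for (e in seq_len(nrow(phy$edge))) {
    p <- labels[phy$edge[e, 1L]]; ch <- labels[phy$edge[e, 2L]]
    out[nrow(out) + 1L, ] <-
      list(paste0(p, "->", ch), p, ch,
           dt$ages[[p]] - dt$ages[[ch]],
           sqrt(dt$ses[[p]]^2 + dt$ses[[ch]]^2))
  }
  out
}
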