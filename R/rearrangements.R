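# Block-interval bookkeeping -------------------------------------------------
#
# Each ancestral block occupies slot [j, j+1) on its chromosome (0-based
# slot j).  A derived block tagged as a fission segment of an untagged
# ancestral block occupies half of that slot: a/x the left half, b/y the
# right half.  Two derived blocks are adjacent in the ancestral karyotype
# exactly when their intervals share an endpoint; adjacency is
# orientation-blind because painting does not resolve orientation.

.anc_index <- function(ancestral) {
  idx <- list()
  for (ci in seq_along(ancestral$autosomes)) {
    blocks <- ancestral$autosomes[[ci]]$blocks
    for (j in seq_along(blocks))
      idx[[blocks[j]]] <- list(chrom = ci, lo = j - 1, hi = j)
  }
  idx
}

.locate_block <- function(label, idx) {
  hit <- idx[[label]]
  if (!is.null(hit)) return(hit)
  p <- parse_block_label(label)
  if (p$segment == "none") return(NULL)
  base <- block_label(p$outgroup_chrom, p$arm, "none")
  hit <- idx[[base]]
  if (is.null(hit)) return(NULL)
  half <- (hit$lo + hit$hi) / 2
  if (p$segment %in% c("a", "x")) list(chrom = hit$chrom, lo = hit$lo, hi = half)
  else list(chrom = hit$chrom, lo = half, hi = hit$hi)
}

#' Decompose a derived karyotype into ancestral fragments
#'
#' Greedy maximal-run decomposition: each derived chromosome is cut into
#' maximal runs of blocks that are contiguous (adjacent, in either order)
#' on a single ancestral chromosome.  Derived fission-segment labels
#' (`"16a"`) are matched against the untagged ancestral block (`"16"`)
#' when no exact ancestral block exists ("sub-segment normalization").
#'
#' @param ancestral,derived [karyotype()] objects; every derived autosomal
#'   block must have an ancestral home.
#' @return Object of class `"fragment_decomposition"`: list with
#'   `fragments` (list of fragment records: `derived_chrom`, `anc_chrom`
#'   indices, `blocks`, `lo`, `hi`, `orient`), `per_derived` (fragment
#'   counts per derived chromosome), `anc_split_counts` (fragments per
#'   ancestral chromosome, 0 when unrepresented), plus the two karyotypes.
#' @export
decompose <- function(ancestral, derived) {
  stopifnot(inherits(ancestral, "karyotype"), inherits(derived, "karyotype"))
  idx <- .anc_index(ancestral)
  fragments <- list()
  per_derived <- integer(length(derived$autosomes))
  for (di in seq_along(derived$autosomes)) {
    blocks <- derived$autosomes[[di]]$blocks
    pos <- lapply(blocks, function(b) {
      h <- .locate_block(b, idx)
      if (is.null(h))
        stop_input("derived block '%s' (species '%s') has no home in ancestral karyotype '%s'",
                   b, derived$species, ancestral$species)
      h
    })
    start <- 1L
    flush <- function(from, to) {
      lo <- min(vapply(pos[from:to], `[[`, numeric(1), "lo"))
      hi <- max(vapply(pos[from:to], `[[`, numeric(1), "hi"))
      orient <- 0L
      if (to > from) {
        orient <- if (pos[[from]]$lo < pos[[to]]$lo) 1L else -1L
      }
      fragments[[length(fragments) + 1L]] <<-
        list(derived_chrom = di, anc_chrom = pos[[from]]$chrom,
             blocks = blocks[from:to], lo = lo, hi = hi, orient = orient)
    }
    if (length(blocks)) {
      for (i in seq_along(blocks)[-1L]) {
        a <- pos[[i - 1L]]; b <- pos[[i]]
        contiguous <- a$chrom == b$chrom && (a$hi == b$lo || b$hi == a$lo)
        if (!contiguous) {
          flush(start, i - 1L)
          start <- i
        }
      }
      flush(start, length(blocks))
    }
    per_derived[di] <- sum(vapply(fragments, function(f)
      f$derived_chrom == di, logical(1)))
  }
  anc_split <- integer(length(ancestral$autosomes))
  for (f in fragments) anc_split[f$anc_chrom] <- anc_split[f$anc_chrom] + 1L
  structure(list(fragments = fragments,
                 per_derived = per_derived,
                 anc_split_counts = anc_split,
                 ancestral = ancestral,
                 derived = derived),
            class = "fragment_decomposition")
}

# classify the ancestral terminus a fragment presents at one of its ends.
# side: "left"/"right" in derived orientation.  Returns "centromeric",
# "telomeric", "interior" (breakpoint end, not an ancestral terminus) or
# "unknown" (no usable centromere annotation / ambiguous orientation).
.fragment_end_type <- function(frag, ancestral, side) {
  anc <- ancestral$autosomes[[frag$anc_chrom]]
  n <- length(anc$blocks)
  terminus_type <- function(edge) {
    if (edge != 0 && edge != n) return("interior")
    if (is.null(anc$centromere_index)) return("unknown")
    cen_at <- anc$centromere_index
    if ((edge == 0 && cen_at == 0L) || (edge == n && cen_at == n))
      "centromeric" else "telomeric"
  }
  if (frag$orient == 1L) {
    terminus_type(if (side == "left") frag$lo else frag$hi)
  } else if (frag$orient == -1L) {
    terminus_type(if (side == "left") frag$hi else frag$lo)
  } else {
    # single-block fragment: orientation unresolved; accept only when both
    # possible readings agree
    t1 <- terminus_type(frag$lo); t2 <- terminus_type(frag$hi)
    if (t1 == t2) t1 else "unknown"
  }
}

#' Classify a fusion junction
#'
#' A junction between two fragments on a derived chromosome is
#' `robertsonian` when both joined fragment ends are centromeric termini of
#' their ancestral chromosomes (centromere at junction index 0 or
#' n_blocks) and the derived chromosome is biarmed; `telomeric_tandem`
#' when both joined ends are telomeric ancestral termini; otherwise
#' `unspecified` (including interior breakpoint ends and any missing
#' centromere or morphology annotation, which degrade gracefully).
#'
#' @param left_frag,right_frag Fragment records from [decompose()],
#'   adjacent on the same derived chromosome (left before right).
#' @param ancestral The ancestral [karyotype()].
#' @param derived_chrom The derived [chromosome_model()] carrying the
#'   junction.
#' @return `"robertsonian"`, `"telomeric_tandem"` or `"unspecified"`.
#' @export
classify_fusion <- function(left_frag, right_frag, ancestral, derived_chrom) {
  e1 <- .fragment_end_type(left_frag, ancestral, "right")
  e2 <- .fragment_end_type(right_frag, ancestral, "left")
  if (e1 == "centromeric" && e2 == "centromeric") {
    biarmed <- derived_chrom$morphology %in% c("M", "SM", "ST", "B")
    if (biarmed) return("robertsonian")
    return("unspecified")
  }
  if (e1 == "telomeric" && e2 == "telomeric") return("telomeric_tandem")
  "unspecified"
}

#' Count fusion and fission events from a fragment decomposition
#'
#' Fusions are junctions between fragments on a derived chromosome
#' (`sum(fragments - 1)` over derived chromosomes); fissions are the extra
#' fragments each ancestral chromosome was split into
#' (`sum(max(splits - 1, 0))`).  When every ancestral chromosome is
#' represented, the balance identity
#' `n_derived = n_ancestral + fissions - fusions` holds.  Each fusion
#' junction is classified via [classify_fusion()].
#'
#' @param d A [decompose()] result.
#' @return Object of class `"event_count"`: list with `fusions`,
#'   `fissions`, `tandem_fusions`, `robertsonian_fusions`,
#'   `unspecified_fusions`.
#' @export
#' @examples
#' anc <- karyotype("anc", list(chromosome_model("1", c("A", "B")),
#'                              chromosome_model("2", "C")))
#' der <- karyotype("der", list(chromosome_model("1", c("A", "B", "C"))))
#' count_events(decompose(anc, der))  # one fusion
count_events <- function(d) {
  stopifnot(inherits(d, "fragment_decomposition"))
  fusions <- sum(pmax(d$per_derived - 1L, 0L))
  fissions <- sum(pmax(d$anc_split_counts - 1L, 0L))
  tandem <- 0L; rb <- 0L; unspec <- 0L
  for (di in seq_along(d$per_derived)) {
    frs <- Filter(function(f) f$derived_chrom == di, d$fragments)
    if (length(frs) < 2L) next
    for (j in seq_len(length(frs) - 1L)) {
      cls <- classify_fusion(frs[[j]], frs[[j + 1L]], d$ancestral,
                             d$derived$autosomes[[di]])
      if (cls == "telomeric_tandem") tandem <- tandem + 1L
      else if (cls == "robertsonian") rb <- rb + 1L
      else unspec <- unspec + 1L
    }
  }
  structure(list(fusions = as.integer(fusions),
                 fissions = as.integer(fissions),
                 tandem_fusions = tandem,
                 robertsonian_fusions = rb,
                 unspecified_fusions = unspec),
            class = "event_count")
}

#' @export
print.event_count <- function(x, ...) {
  cat(sprintf("<event_count> fusions: %d (tandem %d, Rb %d, unspecified %d); fissions: %d\n",
              x$fusions, x$tandem_fusions, x$robertsonian_fusions,
              x$unspecified_fusions, x$fissions))
  invisible(x)
}

#' Serialize per-branch event counts as TSV
#'
#' @param counts Named list of `"event_count"` objects (names are branch
#'   labels).
#' @param file Optional output path.
#' @return TSV string (columns branch, fusions, fissions, tandem,
#'   robertsonian, unspecified), invisibly when written to file.
#' @export
write_event_counts <- function(counts, file = NULL) {
  rows <- vapply(names(counts), function(b) {
    ec <- counts[[b]]
    paste(b, ec$fusions, ec$fissions, ec$tandem_fusions,
          ec$robertsonian_fusions, ec$unspecified_fusions, sep = "\t")
  }, character(1))
  txt <- paste0(paste(c("branch\tfusions\tfissions\ttandem\trobertsonian\tunspecified",
                        rows), collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  cat(txt, file = file)
  invisible(txt)
}
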