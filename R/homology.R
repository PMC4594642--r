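#' Compose a syntenic-block label
#'
#' Blocks detected by cross-species painting are named after the outgroup
#' chromosome they derive from, optionally qualified by the ancestral arm
#' (`p`/`q`) and by a fission-segment tag (`a`, `b`, `x`, `y`) when a block
#' was split with uncertain arm origin.  `block_label()` concatenates the
#' parts (`"2"+"q" -> "2q"`, `"16"+"a" -> "16a"`); [parse_block_label()]
#' inverts it.
#'
#' @param outgroup_chrom Outgroup chromosome label (non-empty character).
#' @param arm `"p"`, `"q"` or `"none"`.
#' @param segment `"a"`, `"b"`, `"x"`, `"y"` or `"none"`.
#' @return A single character label.
#' @export
#' @examples
#' block_label("2", "q")
#' parse_block_label("16a")
block_label <- function(outgroup_chrom, arm = "none", segment = "none") {
  stopifnot(is.character(outgroup_chrom), nzchar(outgroup_chrom))
  arm <- match.arg(arm, c("none", "p", "q"))
  segment <- match.arg(segment, c("none", "a", "b", "x", "y"))
  paste0(outgroup_chrom,
         if (arm != "none") arm else "",
         if (segment != "none") segment else "")
}

#' @rdname block_label
#' @param label A block label such as `"16"`, `"2q"` or `"16a"`.
#' @return For `parse_block_label()`, a list with elements `outgroup_chrom`,
#'   `arm` and `segment`.
#' @export
parse_block_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  segment <- "none"
  arm <- "none"
  rest <- label
  last <- substr(rest, nchar(rest), nchar(rest))
  if (last %in% c("a", "b", "x", "y") && nchar(rest) > 1L) {
    segment <- last
    rest <- substr(rest, 1L, nchar(rest) - 1L)
  }
  last <- substr(rest, nchar(rest), nchar(rest))
  if (last %in% c("p", "q") && nchar(rest) > 1L) {
    arm <- last
    rest <- substr(rest, 1L, nchar(rest) - 1L)
  }
  list(outgroup_chrom = rest, arm = arm, segment = segment)
}

#' Build a chromosome model from painting data
#'
#' A chromosome is an ordered list of syntenic blocks, optionally annotated
#' with a centromere position and a gross morphology class.  The centromere
#' is located at painting resolution: either at a junction between blocks
#' (`centromere_index`, a 0-based junction index in `[0, n_blocks]`, `0`
#' meaning before the first block) or somewhere within block
#' `centromere_within` (0-based block index) when the breakpoint map cannot
#' place it at a junction.
#'
#' @param chrom_id Chromosome identifier within the species karyotype.
#' @param blocks Character vector of block labels, in chromosomal order.
#' @param centromere_index Optional junction index in `[0, length(blocks)]`.
#' @param centromere_within Optional 0-based index of the block containing
#'   the centromere (mutually exclusive with `centromere_index`).
#' @param morphology One of `"A"` (acrocentric), `"SM"`, `"ST"`, `"M"`,
#'   `"B"` (biarmed, unresolved) or `"unspecified"`.
#' @return An object of class `"chromosome_model"`.
#' @export
#' @examples
#' chromosome_model("1", c("17", "18"), morphology = "M", centromere_index = 1)
chromosome_model <- function(chrom_id, blocks, centromere_index = NULL,
                             centromere_within = NULL,
                             morphology = "unspecified") {
  if (length(blocks) < 1L) stop_input("chromosome '%s' has no blocks", chrom_id)
  morphology <- match.arg(morphology,
                          c("unspecified", "A", "SM", "ST", "M", "B"))
  if (!is.null(centromere_index) && !is.null(centromere_within))
    stop_input("chromosome '%s': centromere_index and centromere_within are mutually exclusive",
               chrom_id)
  if (!is.null(centromere_index)) {
    centromere_index <- as.integer(centromere_index)
    if (centromere_index < 0L || centromere_index > length(blocks))
      stop_input("chromosome '%s': centromere_index %d outside [0, %d]",
                 chrom_id, centromere_index, length(blocks))
  }
  if (!is.null(centromere_within)) {
    centromere_within <- as.integer(centromere_within)
    if (centromere_within < 0L || centromere_within >= length(blocks))
      stop_input("chromosome '%s': centromere_within %d outside [0, %d)",
                 chrom_id, centromere_within, length(blocks))
  }
  structure(list(chrom_id = as.character(chrom_id),
                 blocks = as.character(blocks),
                 centromere_index = centromere_index,
                 centromere_within = centromere_within,
                 morphology = morphology),
            class = "chromosome_model")
}

#' Assemble a painting-derived karyotype
#'
#' One representative chromosome per homologous pair.  Autosomal block
#' labels must be unique genome-wide (each painted segment has exactly one
#' home).  Sex chromosomes are carried but excluded from association
#' characters and rearrangement counts, since Y paints are typically
#' unavailable and the X is conserved.
#'
#' @param species Species label.
#' @param autosomes List of [chromosome_model()] objects.
#' @param sex_chromosomes Optional list of [chromosome_model()] objects.
#' @param diploid_number Optional 2n; checked against
#'   `2 * length(autosomes) + 2` when given.
#' @param fundamental_number Optional FN annotation (not checked; see
#'   [compute_fn()]).
#' @return An object of class `"karyotype"`.
#' @export
karyotype <- function(species, autosomes, sex_chromosomes = list(),
                      diploid_number = NULL, fundamental_number = NULL) {
  stopifnot(is.list(autosomes), length(autosomes) >= 1L)
  lab <- unlist(lapply(autosomes, `[[`, "blocks"))
  dup <- lab[duplicated(lab)]
  if (length(dup))
    stop_input("species '%s': block(s) %s appear on more than one autosome",
               species, paste(sQuote(unique(dup)), collapse = ", "))
  if (!is.null(diploid_number) &&
      diploid_number != 2L * length(autosomes) + 2L)
    stop_input("species '%s': diploid_number %d != 2 * %d autosome pairs + 2",
               species, diploid_number, length(autosomes))
  structure(list(species = as.character(species),
                 autosomes = autosomes,
                 sex_chromosomes = sex_chromosomes,
                 diploid_number = diploid_number,
                 fundamental_number = fundamental_number),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %s: %d autosome pair(s), %d sex chromosome(s)\n",
              x$species, length(x$autosomes), length(x$sex_chromosomes)))
  for (ch in x$autosomes)
    cat(sprintf("  %s [%s]: %s\n", ch$chrom_id, ch$morphology,
                paste(ch$blocks, collapse = " | ")))
  invisible(x)
}

#' List the autosomal blocks of a karyotype
#'
#' @param k A [karyotype()].
#' @return Character vector of block labels (order: chromosome by
#'   chromosome).
#' @export
blocks_of <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  unlist(lapply(k$autosomes, `[[`, "blocks"), use.names = FALSE)
}

#' Syntenic associations of a karyotype
#'
#' Every pair of blocks adjacent on the same autosome yields one
#' orientation-blind association character, rendered `"X+Y"` with the
#' lexicographically smaller label first.  A chromosome with m blocks
#' contributes m - 1 associations; sex chromosomes are skipped.
#'
#' @param k A [karyotype()].
#' @return Sorted character vector of association labels.
#' @export
#' @examples
#' k <- karyotype("PA", list(chromosome_model("1", c("17", "18"))))
#' associations_of(k)  # "17+18"
associations_of <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  out <- character(0)
  for (ch in k$autosomes) {
    b <- ch$blocks
    if (length(b) >= 2L) {
      for (i in seq_len(length(b) - 1L)) {
        pr <- sort(c(b[i], b[i + 1L]))
        out <- c(out, paste(pr, collapse = "+"))
      }
    }
  }
  sort(unique(out))
}

#' Fundamental number (arm count) of a karyotype
#'
#' Biarmed morphologies (M, SM, ST, B) contribute two arms, acrocentric (A)
#' one arm, doubled over the homologous pair for autosomes.  Under the
#' `"all_arms"` convention each listed sex chromosome additionally
#' contributes its arms once.
#'
#' @param k A [karyotype()]; every counted chromosome needs a morphology.
#' @param convention `"autosomal_arms"` (default) or `"all_arms"`.
#' @return Integer arm count.
#' @export
compute_fn <- function(k, convention = c("autosomal_arms", "all_arms")) {
  stopifnot(inherits(k, "karyotype"))
  convention <- match.arg(convention)
  arms1 <- function(ch) {
    if (ch$morphology == "unspecified")
      stop_input("species '%s': chromosome '%s' has unspecified morphology; FN cannot be computed",
                 k$species, ch$chrom_id)
    if (ch$morphology == "A") 1L else 2L
  }
  fn <- sum(vapply(k$autosomes, arms1, integer(1))) * 2L
  if (convention == "all_arms" && length(k$sex_chromosomes))
    fn <- fn + sum(vapply(k$sex_chromosomes, arms1, integer(1)))
  as.integer(fn)
}

.sex_chrom_ids <- c("X", "Y", "Z", "W")

#' Read a painting homology table
#'
#' The TSV dialect has header columns `species`, `chrom_id`, `position`,
#' `block`, `arm`, `segment`, `centromere_flag`, `morphology`; `#` lines are
#' comments.  `position` is 0-based and must be consecutive within each
#' chromosome; row order defines block order.  `centromere_flag` per row: 0
#' none, 1 centromere at the junction before this block, 2 within this
#' block, 3 at the junction after this block.  Chromosomes with `chrom_id`
#' in X/Y/Z/W are stored as sex chromosomes.
#'
#' @param input Path to a TSV file, or the table content itself (any string
#'   containing a newline is treated as content).
#' @return List of [karyotype()] objects, one per species, in order of first
#'   appearance.
#' @seealso [write_homology_table()]
#' @export
parse_homology_table <- function(input) {
  stopifnot(is.character(input), length(input) == 1L)
  lines <- if (grepl("\n", input)) strsplit(input, "\n", fixed = TRUE)[[1]]
           else readLines(input)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop_input("homology table is empty")
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  req <- c("species", "chrom_id", "position", "block", "arm", "segment",
           "centromere_flag", "morphology")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_input("homology table lacks column(s): %s",
               paste(missing_cols, collapse = ", "))
  df$position <- suppressWarnings(as.integer(df$position))
  df$centromere_flag <- suppressWarnings(as.integer(df$centromere_flag))
  if (anyNA(df$position)) stop_input("non-integer position value")
  df$.line <- lineno[-1L][seq_len(nrow(df))]  # header consumed first

  norm <- function(x) ifelse(is.na(x) | x == "" | x == "none", "none", x)
  df$arm <- norm(df$arm)
  df$segment <- norm(df$segment)
  df$morphology <- ifelse(is.na(df$morphology) | df$morphology == "",
                          "unspecified", df$morphology)

  out <- list()
  for (sp in unique(df$species)) {
    d <- df[df$species == sp, , drop = FALSE]
    autosomes <- list()
    sexes <- list()
    for (cid in unique(d$chrom_id)) {
      dc <- d[d$chrom_id == cid, , drop = FALSE]
      dc <- dc[order(dc$position), , drop = FALSE]
      expect <- seq_len(nrow(dc)) - 1L
      bad <- which(dc$position != expect)
      if (length(bad))
        stop_input("species '%s' chromosome '%s': positions not consecutive from 0 (line %d)",
                   sp, cid, dc$.line[bad[1]])
      labels <- mapply(block_label, dc$block, dc$arm, dc$segment,
                       USE.NAMES = FALSE)
      cflag <- dc$centromere_flag
      ci <- NULL; cw <- NULL
      hit <- which(cflag != 0L)
      if (length(hit) > 1L)
        stop_input("species '%s' chromosome '%s': more than one centromere flag",
                   sp, cid)
      if (length(hit) == 1L) {
        f <- cflag[hit]
        if (f == 1L) ci <- hit - 1L
        else if (f == 2L) cw <- hit - 1L
        else if (f == 3L) ci <- hit
        else stop_input("species '%s' chromosome '%s': centromere_flag %d not in 0..3",
                        sp, cid, f)
      }
      morph <- unique(dc$morphology)
      if (length(morph) > 1L)
        stop_input("species '%s' chromosome '%s': conflicting morphology tags",
                   sp, cid)
      ch <- chromosome_model(cid, labels, centromere_index = ci,
                             centromere_within = cw, morphology = morph)
      if (toupper(cid) %in% .sex_chrom_ids) sexes[[length(sexes) + 1L]] <- ch
      else autosomes[[length(autosomes) + 1L]] <- ch
    }
    out[[sp]] <- karyotype(sp, autosomes, sex_chromosomes = sexes)
  }
  out
}

#' Write karyotypes back to the homology-table dialect
#'
#' Produces the canonical form of the TSV read by
#' [parse_homology_table()] (round-trip stable).
#'
#' @param karyotypes A list of [karyotype()] objects.
#' @param file Optional path; when `NULL` the table is returned as a string.
#' @return The TSV content, invisibly when written to a file.
#' @export
write_homology_table <- function(karyotypes, file = NULL) {
  if (inherits(karyotypes, "karyotype")) karyotypes <- list(karyotypes)
  rows <- list()
  for (k in karyotypes) {
    for (ch in c(k$autosomes, k$sex_chromosomes)) {
      n <- length(ch$blocks)
      cflag <- integer(n)
      if (!is.null(ch$centromere_within)) {
        cflag[ch$centromere_within + 1L] <- 2L
      } else if (!is.null(ch$centromere_index)) {
        if (ch$centromere_index < n) cflag[ch$centromere_index + 1L] <- 1L
        else cflag[n] <- 3L
      }
      for (i in seq_len(n)) {
        p <- parse_block_label(ch$blocks[i])
        rows[[length(rows) + 1L]] <-
          data.frame(species = k$species, chrom_id = ch$chrom_id,
                     position = i - 1L, block = p$outgroup_chrom,
                     arm = p$arm, segment = p$segment,
                     centromere_flag = cflag[i],
                     morphology = ch$morphology,
                     stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  body <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  txt <- paste(c(paste(names(df), collapse = "\t"), body), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (is.null(file)) return(txt)
  cat(txt, file = file)
  invisible(txt)
}
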