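#' Per-branch rate of chromosomal evolution with divergence-time error
#' bounds
#'
#' The central rate is the number of fixed unique changes divided by the
#' internodal time; the bounds re-evaluate the quotient at `time -/+
#' time_se`.  When the SE reaches or exceeds the time itself, the `t - SE`
#' bound is nonphysical (infinite or negative); it is reported as computed,
#' with `nonphysical = TRUE`, rather than clamped, so that published tables
#' that print such values are reproduced faithfully.
#'
#' @param n_changes Non-negative integer count of fusions + fissions.
#' @param time Internodal time in myr (> 0).
#' @param time_se Standard error of the internodal time in myr (>= 0).
#' @return List of class `"branch_rate"`: `rate_central`,
#'   `rate_at_t_minus_se`, `rate_at_t_plus_se` (changes/myr) and
#'   `nonphysical`.
#' @export
#' @examples
#' branch_rate(39, 6.2324, 2.7562)  # 6.26 / 11.22 / 4.34 changes per myr
branch_rate <- function(n_changes, time, time_se) {
  if (!is.numeric(time) || time <= 0) stop_input("time must be > 0")
  if (n_changes < 0) stop_input("n_changes must be >= 0")
  if (time_se < 0) stop_input("time_se must be >= 0")
  minus <- n_changes / (time - time_se)
  if (n_changes == 0) minus <- 0  # 0 changes: rate is 0 at any time
  structure(list(rate_central = n_changes / time,
                 rate_at_t_minus_se = minus,
                 rate_at_t_plus_se = n_changes / (time + time_se),
                 nonphysical = time_se >= time),
            class = "branch_rate")
}

#' Convert a rate per myr to fixations per generation
#'
#' @param rate_per_myr Changes per million years (>= 0).
#' @param generation_length Generation length in years (>= 0).
#' @return Fixations per generation: `rate_per_myr * 1e-6 *
#'   generation_length`.
#' @export
per_generation_rate <- function(rate_per_myr, generation_length) {
  if (any(rate_per_myr < 0) || any(generation_length < 0))
    stop_input("rate and generation length must be >= 0")
  rate_per_myr * 1e-6 * generation_length
}

#' Per-branch rate table for a dated tree
#'
#' One row per counted branch, in tree preorder.  The Comments column is a
#' narrative annotation, not analysis: `"Evolution"` when the central rate
#' exceeds `evolution_min_rate`, `"Stasis"` when at most
#' `stasis_max_changes` changes occurred, `"variable"` otherwise.
#'
#' @param tree A [dated_tree()].
#' @param counts Named integer vector of change counts keyed by child
#'   tip/node label, or a named list of `"event_count"` objects (fusions +
#'   fissions are summed).
#' @param stasis_max_changes Stasis annotation threshold (default 1).
#' @param evolution_min_rate Evolution annotation threshold in changes/myr
#'   (default 2).
#' @return Data frame with columns `branch`, `parent`, `child`,
#'   `n_changes`, `time`, `time_se`, `rate_at_t_minus_se`, `rate_central`,
#'   `rate_at_t_plus_se`, `nonphysical`, `comment`.
#' @export
rates_table <- function(tree, counts, stasis_max_changes = 1,
                        evolution_min_rate = 2) {
  stopifnot(inherits(tree, "dated_tree"))
  if (is.list(counts) && length(counts) && inherits(counts[[1]], "event_count"))
    counts <- vapply(counts, function(ec) ec$fusions + ec$fissions, integer(1))
  bt <- branch_times(tree)
  unknown <- setdiff(names(counts), bt$child)
  if (length(unknown))
    stop_input("counted branch(es) not in tree: %s",
               paste(unknown, collapse = ", "))
  bt <- bt[bt$child %in% names(counts), , drop = FALSE]
  out <- bt
  out$n_changes <- as.integer(counts[bt$child])
  rr <- lapply(seq_len(nrow(out)), function(i)
    branch_rate(out$n_changes[i], out$time[i], out$time_se[i]))
  out$rate_at_t_minus_se <- vapply(rr, `[[`, numeric(1), "rate_at_t_minus_se")
  out$rate_central <- vapply(rr, `[[`, numeric(1), "rate_central")
  out$rate_at_t_plus_se <- vapply(rr, `[[`, numeric(1), "rate_at_t_plus_se")
  out$nonphysical <- vapply(rr, `[[`, logical(1), "nonphysical")
  out$comment <- ifelse(out$rate_central > evolution_min_rate, "Evolution",
                 ifelse(out$n_changes <= stasis_max_changes, "Stasis",
                        "variable"))
  rownames(out) <- NULL
  out
}

#' Round-half-even display formatting for rate tables
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 4).
#' @return Character vector.
#' @export
format_rate <- function(x, digits = 4) {
  formatC(round(x, digits), format = "f", digits = digits)
}
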