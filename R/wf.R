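#' Forward Wright-Fisher fixation simulation for an underdominant
#' rearrangement
#'
#' Discrete generations in a diploid population of constant size `N`.
#' Genotype fitnesses are `1 : 1-s : 1` (symmetric underdominance).  Each
#' generation the post-selection gamete frequency is
#' `p' = p (p + (1-s) q) / (1 - 2 p q s)` and the next generation is drawn
#' as `Binomial(2N, p')` allele copies.  Replicates run to loss or
#' fixation.  All replicates advance in lock-step from a single seeded
#' generator, so results are bit-reproducible for a given seed.
#'
#' @param N Diploid population size (>= 2).
#' @param s Heterozygote fitness reduction in `[0, 1]`.
#' @param initial_copies Starting allele copies (default 1, a single new
#'   mutant); must be `<= 2N`.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param max_generations Safety cap per replicate (default 1e6).
#' @return Object of class `"fixation_estimate"`: `p_hat` (fixed
#'   fraction), `ci95` (Clopper-Pearson 95\% interval), `mean_sojourn`
#'   (mean generations to absorption), `n_fixed`, `reps`.
#' @export
#' @examples
#' simulate_fixation(N = 25, s = 0, reps = 2000, seed = 1)$p_hat  # ~ 1/50
simulate_fixation <- function(N, s, initial_copies = 1L, reps, seed,
                              max_generations = 1e6) {
  if (N < 2) stop_input("N must be >= 2")
  if (s < 0 || s > 1) stop_input("s must lie in [0, 1]")
  if (initial_copies < 1 || initial_copies > 2 * N)
    stop_input("initial_copies must lie in [1, 2N]")
  if (reps < 1) stop_input("reps must be >= 1")
  set.seed(as.integer(seed))
  twoN <- 2L * as.integer(N)
  count <- rep.int(as.integer(initial_copies), reps)
  absorbed_at <- integer(reps)
  fixed <- logical(reps)
  active <- seq_len(reps)
  gen <- 0L
  while (length(active)) {
    gen <- gen + 1L
    if (gen > max_generations)
      stop_numeric("replicates not absorbed after %g generations", max_generations)
    p <- count[active] / twoN
    q <- 1 - p
    pp <- p * (p + (1 - s) * q) / (1 - 2 * p * q * s)
    count[active] <- stats::rbinom(length(active), twoN, pp)
    done <- count[active] == 0L | count[active] == twoN
    if (any(done)) {
      idx <- active[done]
      absorbed_at[idx] <- gen
      fixed[idx] <- count[idx] == twoN
      active <- active[!done]
    }
  }
  n_fixed <- sum(fixed)
  ci <- c(if (n_fixed == 0) 0 else stats::qbeta(0.025, n_fixed, reps - n_fixed + 1),
          if (n_fixed == reps) 1 else stats::qbeta(0.975, n_fixed + 1, reps - n_fixed))
  structure(list(p_hat = n_fixed / reps,
                 ci95 = ci,
                 mean_sojourn = mean(absorbed_at),
                 n_fixed = n_fixed,
                 reps = as.integer(reps)),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("<fixation_estimate> p_hat = %.5g [%.5g, %.5g] over %d reps; mean sojourn %.1f gen\n",
              x$p_hat, x$ci95[1], x$ci95[2], x$reps, x$mean_sojourn))
  invisible(x)
}

#' Small-deme founder/fecundity fixation experiment
#'
#' An exploratory individual-based model of rearrangement fixation in a
#' tiny deme, deliberately minimal: adults form monogamous pairs (a
#' leftover single does not breed), each pair produces
#' `Poisson(offspring_per_mating)` offspring, each offspring draws one
#' allele from each parent, heterozygous offspring survive viability
#' selection with probability `1 - s`, and survivors are randomly culled
#' to the `founders` cap.  A deme with fewer than two adults is extinct.
#' This is not a reconstruction of any published small-deme model; it
#' probes the qualitative interplay of founder number, underdominance and
#' fecundity.
#'
#' @param founders Deme size cap and starting adult number (>= 2).
#' @param s Heterozygote fitness reduction in `[0, 1]`.
#' @param offspring_per_mating Poisson mean offspring per pair (>= 1).
#' @param reps Number of replicate demes.
#' @param seed Integer RNG seed.
#' @param initial_copies Starting allele copies among the founders
#'   (default 1: one heterozygous founder).
#' @param max_generations Per-replicate generation cap; replicates still
#'   segregating then count as unresolved (neither fixed nor extinct).
#' @return List with `fixation_fraction` (allele fixed while the deme was
#'   alive), `extinction_fraction` (deme fell below two adults at any
#'   point, including after the allele was already lost - demography is
#'   followed to the horizon), `loss_fraction` (deme alive at the horizon
#'   with the allele lost), `unresolved_fraction`, `reps`.
#' @export
deme_fixation_experiment <- function(founders, s, offspring_per_mating,
                                     reps, seed, initial_copies = 1L,
                                     max_generations = 500L) {
  if (founders < 2) stop_input("founders must be >= 2")
  if (offspring_per_mating < 1) stop_input("offspring_per_mating must be >= 1")
  if (s < 0 || s > 1) stop_input("s must lie in [0, 1]")
  if (initial_copies < 1 || initial_copies > 2 * founders)
    stop_input("initial_copies must lie in [1, 2*founders]")
  set.seed(as.integer(seed))
  n_fix <- 0L; n_ext <- 0L; n_loss <- 0L; n_unres <- 0L
  for (r in seq_len(reps)) {
    # genotypes coded by allele copy number 0/1/2
    adults <- integer(founders)
    k <- as.integer(initial_copies)
    i <- 1L
    while (k > 0L) {  # distribute copies as heterozygotes first
      add <- min(k, 1L)
      adults[i] <- adults[i] + add
      k <- k - add
      i <- if (i == founders) 1L else i + 1L
    }
    outcome <- "unresolved"
    allele_fate <- NA_character_
    for (gen in seq_len(max_generations)) {
      n <- length(adults)
      if (n < 2L) { outcome <- "extinct"; break }
      tot <- sum(adults)
      if (is.na(allele_fate)) {
        if (tot == 0L) allele_fate <- "lost"
        if (tot == 2L * n) { outcome <- "fixed"; break }
      }
      npair <- n %/% 2L
      if (!is.na(allele_fate)) {
        # allele absorbed: genotype bookkeeping and selection are moot;
        # keep following the demography so deme extinction is recorded
        noff <- stats::rpois(1L, npair * offspring_per_mating)
        adults <- integer(min(noff, founders))
        next
      }
      ord <- sample.int(n)
      kids <- integer(0)
      for (pr in seq_len(npair)) {
        pa <- adults[ord[2L * pr - 1L]]
        ma <- adults[ord[2L * pr]]
        noff <- stats::rpois(1L, offspring_per_mating)
        if (noff == 0L) next
        g <- stats::rbinom(noff, 1L, pa / 2) + stats::rbinom(noff, 1L, ma / 2)
        het <- g == 1L
        if (s > 0 && any(het))
          g <- g[!het | stats::runif(length(g)) >= s]
        kids <- c(kids, g)
      }
      if (length(kids) > founders)
        kids <- kids[sample.int(length(kids), founders)]
      adults <- kids
    }
    if (outcome == "unresolved") {
      if (length(adults) < 2L) outcome <- "extinct"
      else if (!is.na(allele_fate)) outcome <- "lost"
      else {
        tot <- sum(adults)
        if (tot == 2L * length(adults)) outcome <- "fixed"
        else if (tot == 0L) outcome <- "lost"
      }
    }
    switch(outcome,
           fixed = n_fix <- n_fix + 1L,
           extinct = n_ext <- n_ext + 1L,
           lost = n_loss <- n_loss + 1L,
           unresolved = n_unres <- n_unres + 1L)
  }
  list(fixation_fraction = n_fix / reps,
       extinction_fraction = n_ext / reps,
       loss_fraction = n_loss / reps,
       unresolved_fraction = n_unres / reps,
       reps = as.integer(reps))
}
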