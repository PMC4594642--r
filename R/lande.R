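# Underdominant fixation: diffusion machinery --------------------------------
#
# For a rearrangement with genotype fitnesses 1 : 1-s : 1 (heterozygote
# disadvantage s, both homozygotes equivalent) the diffusion fixation
# probability from initial frequency p0 is
#
#   P(ne, s, p0) = Int_0^p0 exp(4 ne s x (1-x)) dx /
#                  Int_0^1  exp(4 ne s x (1-x)) dx.
#
# The exponent is exactly quadratic, 4 ne s x(1-x) = c - 4 ne s (x-1/2)^2
# with c = ne s * ... , so the full-interval denominator reduces exactly to
# a Gaussian integral, sqrt(pi/a) * erf(sqrt(a)/2) after factoring
# exp(a/4), a = 4 ne s.  The numerator is evaluated by adaptive quadrature
# after rescaling by its maximum so the integrand lies in (0, 1]; the whole
# computation is carried in log space, which keeps the solver stable far
# into the strong-selection regime where P underflows a double.

.erf <- function(z) 2 * stats::pnorm(sqrt(2) * z) - 1

# log of P(ne, s, p0); s > 0
.log_fixation_prob <- function(ne, s, p0, rel_tol = 1e-10) {
  a <- 4 * ne * s
  # numerator: exp(m) * Int_0^p0 exp(-a (x-1/2)^2 - m) dx,
  # m = -a (p0-1/2)^2 puts the rescaled integrand's max at 1 (x = p0)
  m <- -a * (p0 - 0.5)^2
  f <- function(x) exp(a * ((p0 - 0.5)^2 - (x - 0.5)^2))
  qi <- tryCatch(
    stats::integrate(f, 0, p0, rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e)
      stop_numeric("quadrature failed for ne=%g, s=%g, p0=%g: %s",
                   ne, s, p0, conditionMessage(e)))
  if (qi$message != "OK" || !is.finite(qi$value) || qi$value <= 0)
    stop_numeric("quadrature did not converge for ne=%g, s=%g, p0=%g",
                 ne, s, p0)
  log_den_scaled <- 0.5 * (log(pi) - log(a)) + log(.erf(sqrt(a) / 2))
  m + log(qi$value) - log_den_scaled
}

#' Diffusion fixation probability of an underdominant rearrangement
#'
#' Probability that a rearrangement with heterozygote fitness `1 - s`
#' (homozygotes both 1) starting at frequency `p0` eventually fixes in a
#' population of effective size `ne`.  At `s = 0` the neutral identity
#' `P = p0` is returned exactly.  For strong selection (`ne * s` beyond
#' roughly 700) the probability underflows double precision and 0 is
#' returned; use `log = TRUE` there.
#'
#' @param ne Effective population size (>= 2).
#' @param s Heterozygote fitness reduction in `[0, 1]`.
#' @param p0 Initial frequency in (0, 1); defaults to a single new mutant,
#'   `1/(2 ne)`.
#' @param log Return the log probability.
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return Fixation probability (or its log).
#' @export
#' @examples
#' fixation_prob_underdominant(20, 0.1)         # one new mutant copy
#' fixation_prob_underdominant(20, 0, 1 / 40)   # neutral: exactly p0
fixation_prob_underdominant <- function(ne, s, p0 = 1 / (2 * ne),
                                        log = FALSE, rel_tol = 1e-10) {
  if (ne < 2) stop_input("ne must be >= 2")
  if (s < 0 || s > 1) stop_input("s must lie in [0, 1]")
  if (p0 <= 0 || p0 >= 1) stop_input("p0 must lie in (0, 1)")
  if (s == 0) return(if (log) base::log(p0) else p0)
  lp <- .log_fixation_prob(ne, s, p0, rel_tol)
  if (log) lp else exp(lp)
}

#' Per-generation fixation rate of underdominant rearrangements
#'
#' Rate at which new underdominant rearrangements, arising at `u` per
#' gamete per generation, reach fixation:
#' `R = 2 N u * P(ne, s, 1/(2 N))` with census size `N = ne *
#' census_ratio` (the long-term inversion takes `N = ne`).  Strictly
#' decreasing in `ne` for `s > 0`; at `s = 0` it equals `u` exactly (the
#' neutral substitution-rate identity).
#'
#' @param ne Effective population size (>= 2).
#' @param u Chromosomal mutation rate per gamete per generation (0 < u <= 1).
#' @param s Heterozygote fitness reduction in `[0, 1]`.
#' @param census_ratio Census-to-effective size ratio N/Ne (default 1).
#' @param log Return the log rate.
#' @return Fixations per generation (or log thereof).
#' @export
lande_rate <- function(ne, u, s, census_ratio = 1, log = FALSE) {
  if (u <= 0 || u > 1) stop_input("u must lie in (0, 1]")
  if (ne < 2) stop_input("ne must be >= 2")
  n_census <- ne * census_ratio
  if (s == 0) return(if (log) base::log(u) else u)
  lr <- base::log(2 * n_census * u) +
    fixation_prob_underdominant(ne, s, p0 = 1 / (2 * n_census), log = TRUE)
  if (log) lr else exp(lr)
}

#' Strong-selection closed form for the fixation rate
#'
#' Laplace approximation of the diffusion integrals:
#' `R ~ 2 u sqrt(ne s / pi) exp(-ne s) / erf(sqrt(ne s))`, accurate for
#' large `ne * s`; retained as an independent cross-check of the exact
#' quadrature route.
#'
#' @inheritParams lande_rate
#' @return Fixations per generation (or log thereof).
#' @export
lande_rate_closed <- function(ne, u, s, log = FALSE) {
  if (s <= 0) stop_input("closed form requires s > 0")
  c0 <- ne * s
  lr <- base::log(2 * u) + 0.5 * (base::log(c0) - base::log(pi)) - c0 -
    base::log(.erf(sqrt(c0)))
  if (log) lr else exp(lr)
}

#' Solve for the long-term effective population size
#'
#' Inverts the monotone rate equation `lande_rate(ne, u, s) = R_gen` by
#' bisection on `log(ne)` over `[ne_min, ne_max]`.  Because underdominance
#' only ever lowers the fixation rate below the neutral rate `u`, a target
#' rate at or above the rate attainable at `ne_min` admits no solution
#' (`status = "supra_neutral_no_solution"`); a target below the rate at
#' `ne_max` means the population size exceeds the search ceiling
#' (`status = "below_minimum"`).
#'
#' @param R_gen Observed fixation rate per generation (> 0).
#' @param u Chromosomal mutation rate per gamete per generation.
#' @param s Heterozygote fitness reduction (> 0).
#' @param ne_min,ne_max Search bracket (defaults 2 and 1e7).
#' @param rel_tol Relative residual tolerance for `status = "solved"`
#'   (default 1e-6).
#' @param max_iter Bisection iteration cap (default 200).
#' @return Object of class `"ne_solution"`: list with `ne` (NA unless
#'   solved), `status`, `residual` (absolute rate residual at the
#'   solution).
#' @export
#' @examples
#' r <- lande_rate(37.5, 1e-3, 0.3)
#' solve_ne(r, 1e-3, 0.3)$ne  # recovers 37.5
solve_ne <- function(R_gen, u, s, ne_min = 2, ne_max = 1e7,
                     rel_tol = 1e-6, max_iter = 200L) {
  if (R_gen <= 0) stop_input("R_gen must be > 0")
  if (s <= 0) stop_input("s must be > 0 (the neutral model is degenerate: R = u for every ne)")
  if (u <= 0 || u > 1) stop_input("u must lie in (0, 1]")
  logR <- base::log(R_gen)
  f <- function(ne) lande_rate(ne, u, s, log = TRUE) - logR
  f_lo <- f(ne_min)
  if (f_lo <= 0)
    return(structure(list(ne = NA_real_, status = "supra_neutral_no_solution",
                          residual = NA_real_), class = "ne_solution"))
  f_hi <- f(ne_max)
  if (f_hi >= 0)
    return(structure(list(ne = NA_real_, status = "below_minimum",
                          residual = NA_real_), class = "ne_solution"))
  lo <- base::log(ne_min); hi <- base::log(ne_max)
  mid <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(exp(mid))
    if (!is.finite(fm)) stop_numeric("rate evaluation failed at ne=%g", exp(mid))
    if (fm > 0) lo <- mid else hi <- mid
    # stop once the rate residual is far inside tolerance
    if (abs(fm) <= rel_tol * 1e-4 || (hi - lo) < 1e-14) break
  }
  ne_hat <- exp((lo + hi) / 2)
  resid <- abs(lande_rate(ne_hat, u, s) - R_gen)
  if (resid / R_gen > rel_tol)
    stop_numeric("bisection did not reach tolerance at ne=%g (relative residual %g)",
                 ne_hat, resid / R_gen)
  structure(list(ne = ne_hat, status = "solved", residual = resid),
            class = "ne_solution")
}

#' Effective-population-size grid over rates, generation lengths, u and s
#'
#' Cartesian-product sensitivity grid in the style of a published Ne
#' analysis: each per-myr rate is converted to a per-generation rate for
#' each generation length, then inverted with [solve_ne()] for every
#' (u, s) combination.
#'
#' @param rates_myr Numeric vector of branch rates (changes/myr).
#' @param generation_years Numeric vector of generation lengths (years).
#' @param u_values Numeric vector of chromosomal mutation rates.
#' @param s_values Numeric vector of heterozygote fitness reductions.
#' @param ... Passed on to [solve_ne()].
#' @return Data frame with columns `R_myr`, `g_years`, `u`, `s`, `R_gen`,
#'   `ne`, `status`, ordered by the input grids (s fastest).
#' @export
ne_grid <- function(rates_myr, generation_years, u_values, s_values, ...) {
  if (!length(rates_myr) || !length(generation_years) ||
      !length(u_values) || !length(s_values))
    stop_input("all grids must be non-empty")
  g <- expand.grid(s = s_values, u = u_values, g_years = generation_years,
                   R_myr = rates_myr, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("R_myr", "g_years", "u", "s")]
  g$R_gen <- per_generation_rate(g$R_myr, g$g_years)
  sol <- lapply(seq_len(nrow(g)), function(i)
    solve_ne(g$R_gen[i], g$u[i], g$s[i], ...))
  g$ne <- vapply(sol, `[[`, numeric(1), "ne")
  g$status <- vapply(sol, `[[`, character(1), "status")
  rownames(g) <- NULL
  g
}
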