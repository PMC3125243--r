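#' Gaussian relative fitness
#'
#' Survival probability of an individual whose phenotype misses the local
#' resource quality by `delta` trait units, under Gaussian stabilizing
#' selection: `RF = exp(-delta^2 / (2 * omega^2))`. `omega` sets the breadth
#' of the selection function (default 2 trait units); fitness is 1 at a
#' perfect match and decreases monotonically with the mismatch.
#'
#' @param delta non-negative trait mismatch `|quality - phenotype|`
#'   (vectorized).
#' @param omega selection breadth, positive.
#' @return survival probabilities in `(0, 1]`.
#' @export
#' @examples
#' relative_fitness(0)            # 1
#' relative_fitness(2, omega = 2) # exp(-0.5)
relative_fitness <- function(delta, omega = 2) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0)
    stop("`omega` must be a single positive number")
  if (any(delta < 0)) stop("`delta` must be non-negative")
  exp(-delta^2 / (2 * omega^2))
}

#' Viability selection against the local resource quality
#'
#' Each individual survives independently with probability
#' `relative_fitness(|quality - phenotype|, omega)`: it dies when its relative
#' fitness is less than a uniform random number. This stage is where
#' competition acts — the species whose phenotypes track the local optimum
#' more closely loses fewer individuals and gains a numeric advantage.
#'
#' @param phenotypes numeric vector of offspring phenotypes.
#' @param quality local resource quality (scalar or per-individual vector).
#' @param omega selection breadth.
#' @return logical vector: `TRUE` for survivors.
#' @export
viability_cull <- function(phenotypes, quality, omega = 2) {
  n <- length(phenotypes)
  if (!n) return(logical(0))
  rf <- relative_fitness(abs(quality - phenotypes), omega)
  stats::runif(n) < rf
}

#' Enforce the patch carrying capacity
#'
#' If more than `K` individuals (both species pooled) occupy a patch,
#' uniformly random individuals are removed — without regard to species or
#' fitness — until exactly `K` remain; smaller cohorts are untouched. With
#' three patches the regional census is thereby capped at `3 K`.
#'
#' @param n_residents joint number of residents in the patch.
#' @param K carrying capacity, positive.
#' @return logical vector of length `n_residents`: `TRUE` for survivors,
#'   with exactly `min(n_residents, K)` `TRUE` entries.
#' @export
capacity_cull <- function(n_residents, K = 200) {
  if (K <= 0) stop("`K` must be positive")
  keep <- rep(TRUE, n_residents)
  if (n_residents > K)
    keep[sample.int(n_residents, n_residents - K)] <- FALSE
  keep
}

#' Replace the parental generation by its offspring
#'
#' Generations do not overlap: after reproduction all parents are killed, and
#' only the offspring cohort proceeds to selection. A cohort with no offspring
#' (e.g. all patches held singletons) goes locally extinct.
#'
#' @param parents the parental cohort (any object; discarded).
#' @param offspring the offspring cohort.
#' @return `offspring`.
#' @export
kill_parents <- function(parents, offspring) offspring

#' Advance the resource quality of a patch
#'
#' The resource quality (the environmental optimum the trait is selected
#' towards) drifts by `rate` trait units per generation. The default dynamic
#' is a deterministic directional increase; `direction = "decrease"` reverses
#' it and `direction = "random_walk"` takes a step of size `rate` with random
#' sign each generation. Values are reflected into `[0, env_max]`.
#'
#' @param quality current quality (vectorized over patches).
#' @param rate per-generation change, non-negative (vectorized).
#' @param env_max trait-range maximum.
#' @param direction `"increase"`, `"decrease"`, or `"random_walk"`.
#' @return updated quality values.
#' @export
update_resource <- function(quality, rate, env_max = 140,
                            direction = c("increase", "decrease",
                                          "random_walk")) {
  direction <- match.arg(direction)
  step <- switch(direction,
    increase = rate,
    decrease = -rate,
    random_walk = rate * sign(stats::runif(length(quality)) - 0.5))
  q <- quality + step
  # reflect into [0, env_max]
  q <- ifelse(q < 0, -q, q)
  ifelse(q > env_max, 2 * env_max - q, q)
}
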