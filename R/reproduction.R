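#' Draw offspring counts per mating
#'
#' The number of offspring from each mating is Poisson with mean `lambda`
#' (default 1.5).
#'
#' @param n number of matings to draw for.
#' @param lambda mean offspring per mating; must be positive.
#' @return integer vector of non-negative counts.
#' @export
draw_offspring_count <- function(n = 1, lambda = 1.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number")
  stats::rpois(n, lambda)
}

# Source-parent indicator matrix for a batch of recombinations.
# The chromosome has n positions (position 1 = root state, positions 2..n the
# (head, function) pairs). The first position comes from a uniformly chosen
# parent; between consecutive positions the source switches with probability
# r. Returns an n x N 0/1 matrix (0 = parent A, 1 = parent B).
crossover_sources <- function(n, n_off, r) {
  start <- as.integer(stats::runif(n_off) < 0.5)
  if (n == 1L) return(matrix(start, 1L, n_off))
  switches <- matrix(as.integer(stats::runif((n - 1L) * n_off) < r),
                     n - 1L, n_off)
  # column-wise cumulative switch count via one flat cumsum
  cs <- matrix(cumsum(switches), n - 1L, n_off)
  if (n_off > 1L) {
    offs <- c(0, cs[n - 1L, -n_off])
    cs <- cs - rep(offs, each = n - 1L)
  }
  (rbind(0L, cs) + rep(start, each = n)) %% 2L
}

#' Recombine two parental chromosomes
#'
#' Builds an offspring chromosome by the Markov switching rule: the first
#' chromosome position is taken from a uniformly chosen starting parent, and
#' each subsequent position is taken from the same parent as the previous one
#' unless a uniform random number falls below the recombination rate `r`, at
#' which point the source switches. Each non-root position carries that gene's
#' (head, function) pair as one element; the heritable root state travels with
#' the first position, i.e. it is inherited from the starting parent.
#'
#' Both parents must have the same number of genes (same species). Because
#' both parental chromosomes satisfy `heads[i] < i`, any position-wise mixture
#' does too, so recombination preserves acyclicity.
#'
#' @param chrom_a,chrom_b parental `gn_genome`s of equal length, in
#'   construction order.
#' @param r recombination rate in `[0, 1]`.
#' @return an offspring `gn_genome`.
#' @export
recombine <- function(chrom_a, chrom_b, r) {
  stopifnot(inherits(chrom_a, "gn_genome"), inherits(chrom_b, "gn_genome"))
  if (chrom_a$n_genes != chrom_b$n_genes)
    stop("incompatible genomes: chromosome lengths differ")
  if (r < 0 || r > 1) stop("`r` must be in [0, 1]")
  n <- chrom_a$n_genes
  for (g in list(chrom_a, chrom_b))
    if (g$root != 1L || any(g$heads[-1] >= seq(2L, n)))
      stop("recombine() requires genomes in construction order")
  src <- crossover_sources(n, 1L, r)[, 1L]
  heads <- ifelse(src == 0L, chrom_a$heads, chrom_b$heads)
  fns <- ifelse(src == 0L, chrom_a$functions, chrom_b$functions)
  root_state <- if (src[1L] == 0L) chrom_a$root_state else chrom_b$root_state
  genome(heads, fns, root_state)
}

# Vectorized mutation of population chromosome matrices.
# Each of the 2(n-1) mutable elements per genome (head and function of every
# non-root gene) is hit independently with probability mu. A hit function bit
# flips. A hit head entry is resampled uniformly from the earlier-indexed
# genes excluding itself and its current value (all mutations are
# non-synonymous); gene 2 has no alternative head and stays unchanged.
mutate_matrices <- function(heads, funcs, mu) {
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]")
  n1 <- nrow(heads)           # n - 1 rows
  n_ind <- ncol(heads)
  if (mu == 0 || n_ind == 0L) return(list(heads = heads, funcs = funcs))
  fhit <- which(stats::runif(n1 * n_ind) < mu)
  if (length(fhit)) funcs[fhit] <- 1L - funcs[fhit]
  hhit <- which(stats::runif(n1 * n_ind) < mu)
  if (length(hhit)) {
    row <- (hhit - 1L) %% n1 + 1L          # row i corresponds to gene i+1
    n_alt <- row - 1L                      # |{1..i}| - 1 alternatives
    ok <- n_alt > 0L
    hhit <- hhit[ok]; row <- row[ok]; n_alt <- n_alt[ok]
    if (length(hhit)) {
      cur <- heads[hhit]
      u <- 1L + as.integer(floor(stats::runif(length(hhit)) * n_alt))
      heads[hhit] <- u + (u >= cur)
    }
  }
  list(heads = heads, funcs = funcs)
}

#' Mutate a genome
#'
#' Every mutable chromosome element — the head entry and the function bit of
#' each non-root gene, `2(n-1)` elements in all — is independently hit with
#' probability `mu`. A hit function bit flips (activator to repressor or back).
#' A hit head entry is resampled uniformly from the genes added earlier in the
#' construction order, excluding the gene itself and its current head, so
#' every realized mutation is non-synonymous and the network stays an acyclic
#' single-input tree. Gene 2's only legal head is gene 1, so that single
#' element has no non-synonymous alternative and is left unchanged. The
#' heritable root state is not a mutable element.
#'
#' @param g a `gn_genome` in construction order.
#' @param mu per-element mutation rate in `[0, 1]`.
#' @return a mutated `gn_genome`.
#' @export
mutate_genome <- function(g, mu) {
  stopifnot(inherits(g, "gn_genome"))
  if (g$root != 1L || any(g$heads[-1] >= seq(2L, g$n_genes)))
    stop("mutate_genome() requires a genome in construction order")
  m <- mutate_matrices(matrix(g$heads[-1]), matrix(g$functions[-1]), mu)
  genome(c(NA_integer_, m$heads[, 1L]), c(NA_integer_, m$funcs[, 1L]),
         g$root_state)
}

# Mate assignment within one patch: each of m residents acts once as seed
# parent and draws a uniformly random distinct partner (partners reusable).
draw_mates <- function(m) {
  u <- 1L + as.integer(floor(stats::runif(m) * (m - 1L)))
  u + (u >= seq_len(m))
}

# Reproduction for one species across all patches. Residents with at least
# one conspecific patch-mate each seed one mating; offspring counts are
# Poisson(lambda); offspring chromosomes are built by recombination then
# mutation, inherit the starting parent's root state, record the mid-parent
# phenotype, and are placed in the parents' patch.
reproduce_species <- function(pop, lambda, r, mu, env_max) {
  n <- pop$n_genes
  seeds <- integer(0); mates <- integer(0)
  for (p in unique(pop$patch)) {
    idx <- which(pop$patch == p)
    m <- length(idx)
    if (m < 2L) next
    seeds <- c(seeds, idx)
    mates <- c(mates, idx[draw_mates(m)])
  }
  if (!length(seeds)) return(empty_population(n))
  k <- draw_offspring_count(length(seeds), lambda)
  pos <- k > 0L
  a <- rep(seeds[pos], k[pos])
  b <- rep(mates[pos], k[pos])
  n_off <- length(a)
  if (!n_off) return(empty_population(n))

  src <- crossover_sources(n, n_off, r)
  ha <- pop$heads[, a, drop = FALSE]; hb <- pop$heads[, b, drop = FALSE]
  fa <- pop$funcs[, a, drop = FALSE]; fb <- pop$funcs[, b, drop = FALSE]
  pick_b <- src[-1L, , drop = FALSE] == 1L
  ha[pick_b] <- hb[pick_b]
  fa[pick_b] <- fb[pick_b]
  root <- ifelse(src[1L, ] == 0L, pop$root[a], pop$root[b])

  m <- mutate_matrices(ha, fa, mu)
  off <- list(n_genes = n, heads = m$heads, funcs = m$funcs,
              root = as.integer(root), patch = pop$patch[a],
              phen = rep(NA_real_, n_off),
              midpar = (pop$phen[a] + pop$phen[b]) / 2)
  off$phen <- pop_phenotypes(off, env_max)
  off
}

#' Produce the offspring cohort for one patch
#'
#' Residents of one patch (one species) mate at random: each resident seeds a
#' mating with a uniformly drawn distinct conspecific patch-mate, the number
#' of offspring per mating is Poisson(`lambda`), and each offspring genome is
#' built by [recombine()] followed by mutation. Offspring record the
#' mid-parent phenotype and are placed in the parents' patch. A singleton
#' resident produces no offspring.
#'
#' @param residents list of `gn_genome`s resident in one patch.
#' @param patch patch id to place offspring in.
#' @param lambda mean offspring per mating.
#' @param r recombination rate.
#' @param mu per-element mutation rate.
#' @param env_max trait-range maximum.
#' @return a data.frame with one row per offspring (`patch`, `phenotype`,
#'   `midparent`) carrying the offspring `gn_genome`s as the `genome`
#'   list-column.
#' @export
reproduce_patch <- function(residents, patch = 1L, lambda = 1.5, r = 0.05,
                            mu = 1e-4, env_max = 140) {
  if (length(residents) < 2L) {
    out <- data.frame(patch = integer(0), phenotype = numeric(0),
                      midparent = numeric(0))
    out$genome <- list()
    return(out)
  }
  pop <- new_population(residents, rep(as.integer(patch), length(residents)),
                        env_max)
  off <- reproduce_species(pop, lambda, r, mu, env_max)
  out <- data.frame(patch = off$patch, phenotype = off$phen,
                    midparent = off$midpar)
  out$genome <- lapply(seq_len(pop_size(off)), function(j) pop_genome(off, j))
  out
}
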