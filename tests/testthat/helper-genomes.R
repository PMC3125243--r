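# Fixture builders shared across test files.

# A hand-built 13-gene network with five regulatory genes and eight terminal
# genes, four of which evaluate to "on": the worked phenotype example
# (140 / 8 * 4 = 70).
worked_example_genome <- function() {
  #           1   2   3   4   5   6   7   8   9  10  11  12  13
  heads <- c(NA,  1,  1,  2,  3,  4,  4,  5,  5,  2,  2,  3,  3)
  fns   <- c(NA,  1,  0,  1,  1,  1,  0,  1,  0,  1,  0,  1,  0)
  genome(heads, fns, root_state = 1L)
}

# Linear chain of n genes, all the same function bit
chain_genome <- function(n, fn = 1L, root_state = 1L) {
  genome(c(NA, seq_len(n - 1L)), c(NA, rep(fn, n - 1L)), root_state)
}

# Relabel the genes of a genome by a permutation, preserving topology and
# function bits: gene i becomes gene perm[i].
permute_genome <- function(g, perm) {
  n <- g$n_genes
  heads <- integer(n); fns <- integer(n)
  heads[perm] <- ifelse(is.na(g$heads), NA_integer_, perm[g$heads])
  fns[perm] <- g$functions
  genome(heads, fns, g$root_state)
}

# Construction-order genome with fixed topology but distinguishable function
# bits (used to trace recombination sources)
tagged_genome <- function(n, tag) {
  genome(c(NA, seq_len(n - 1L)), c(NA, rep(as.integer(tag), n - 1L)), tag)
}

default_two_species <- function(comp_n = 16, comp_d = 0.05, focal_d = 0.05,
                                comp_mu = 1e-4) {
  list(focal = species_params("focal", d = focal_d, start_patch = 1L),
       competitor = species_params("competitor", n = comp_n, mu = comp_mu,
                                   d = comp_d, start_patch = 2L))
}
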