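# Internal column-wise population representation.
#
# A population of N conspecific individuals with n-gene networks is stored as
# matrices so that reproduction, mutation and state evaluation vectorize over
# individuals:
#   heads  (n-1) x N integer, row i = head of gene i+1 (construction order,
#          so heads[i, j] <= i, guaranteeing acyclicity by index)
#   funcs  (n-1) x N integer function bits, same row convention
#   root   length-N integer heritable root states
#   patch  length-N integer patch ids
#   phen   length-N phenotypes
#   midpar length-N mid-parent phenotypes (NA for founders)

new_population <- function(genomes, patch, env_max = 140) {
  n_ind <- length(genomes)
  stopifnot(length(patch) == n_ind, n_ind >= 1L)
  n <- genomes[[1]]$n_genes
  heads <- matrix(NA_integer_, n - 1L, n_ind)
  funcs <- matrix(NA_integer_, n - 1L, n_ind)
  root <- integer(n_ind)
  for (j in seq_len(n_ind)) {
    g <- genomes[[j]]
    if (g$n_genes != n || g$root != 1L || any(g$heads[-1] >= seq(2L, n)))
      stop("population genomes must share n and be in construction order")
    heads[, j] <- g$heads[-1]
    funcs[, j] <- g$functions[-1]
    root[j] <- g$root_state
  }
  pop <- list(n_genes = n, heads = heads, funcs = funcs, root = root,
              patch = as.integer(patch),
              phen = rep(NA_real_, n_ind), midpar = rep(NA_real_, n_ind))
  pop$phen <- pop_phenotypes(pop, env_max)
  pop
}

empty_population <- function(n_genes) {
  list(n_genes = n_genes,
       heads = matrix(NA_integer_, n_genes - 1L, 0L),
       funcs = matrix(NA_integer_, n_genes - 1L, 0L),
       root = integer(0), patch = integer(0),
       phen = numeric(0), midpar = numeric(0))
}

pop_size <- function(pop) length(pop$patch)

pop_subset <- function(pop, keep) {
  list(n_genes = pop$n_genes,
       heads = pop$heads[, keep, drop = FALSE],
       funcs = pop$funcs[, keep, drop = FALSE],
       root = pop$root[keep], patch = pop$patch[keep],
       phen = pop$phen[keep], midpar = pop$midpar[keep])
}

# Extract individual j as a gn_genome
pop_genome <- function(pop, j) {
  genome(c(NA_integer_, pop$heads[, j]), c(NA_integer_, pop$funcs[, j]),
         pop$root[j])
}

# Boolean states for every individual: n x N matrix. One pass down the
# construction order; each row is a vectorized XNOR over individuals.
pop_states <- function(pop) {
  n <- pop$n_genes
  n_ind <- pop_size(pop)
  states <- matrix(NA_integer_, n, n_ind)
  if (!n_ind) return(states)
  states[1L, ] <- pop$root
  cols <- seq_len(n_ind)
  for (i in seq_len(n - 1L)) {
    up <- states[cbind(pop$heads[i, ], cols)]
    states[i + 1L, ] <- as.integer(up == pop$funcs[i, ])
  }
  states
}

# Phenotypes for every individual: env_max / T * S over terminal genes.
pop_phenotypes <- function(pop, env_max) {
  n <- pop$n_genes
  n_ind <- pop_size(pop)
  if (!n_ind) return(numeric(0))
  states <- pop_states(pop)
  # a gene is terminal for individual j iff it appears in no head entry of j
  has_out <- matrix(FALSE, n, n_ind)
  has_out[cbind(as.vector(pop$heads), rep(seq_len(n_ind), each = n - 1L))] <- TRUE
  terminal <- !has_out
  t_count <- .colSums(terminal, n, n_ind)
  s_count <- .colSums(states * terminal, n, n_ind)
  env_max * s_count / t_count
}

# Founders: independent random genomes for one species in one patch
init_population <- function(n_ind, n_genes, kind, patch, env_max) {
  genomes <- replicate(n_ind, build_topology(n_genes, kind), simplify = FALSE)
  new_population(genomes, rep(as.integer(patch), n_ind), env_max)
}
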