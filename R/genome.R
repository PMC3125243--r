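#' Construct a gene-network genome
#'
#' A genome encodes a single-input Boolean gene network on one chromosome:
#' every gene except the basal-most ("root") gene is regulated by exactly one
#' upstream gene (its *head*), through either an activating or a repressing
#' functional relationship. The root gene carries a heritable binary state.
#' Gene states are fully determined by the root state, the topology and the
#' function bits; the states of all terminal genes (out-degree 0) sum to the
#' quantitative trait (see [phenotype()]).
#'
#' Genes are conventionally stored in construction order (gene 1 is the root
#' and `heads[i] < i`), which is what [build_topology()] produces and what the
#' reproduction operators preserve. Any acyclic single-input labelling is
#' accepted, however: the head relation must form a tree rooted at the unique
#' gene with no regulator.
#'
#' @param heads integer vector of length `n`; `heads[i]` is the index of gene
#'   `i`'s single upstream regulator. Exactly one entry (the root) is `NA`.
#' @param functions integer vector of length `n` of function bits
#'   (1 = activator, 0 = repressor); the root's entry is ignored and stored
#'   as `NA`.
#' @param root_state the heritable binary state (0 or 1) of the root gene.
#' @return an object of class `gn_genome` with elements `n_genes`, `heads`,
#'   `functions`, `root_state`, `root` (index of the root gene).
#' @seealso [build_topology()], [evaluate_states()], [phenotype()]
#' @export
#' @examples
#' g <- genome(heads = c(NA, 1L, 1L), functions = c(NA, 1L, 0L), root_state = 1L)
#' evaluate_states(g)
genome <- function(heads, functions, root_state) {
  heads <- as.integer(heads)
  functions <- as.integer(functions)
  n <- length(heads)
  if (length(functions) != n)
    stop("`heads` and `functions` must have equal length")
  root <- which(is.na(heads))
  if (length(root) != 1L)
    stop("exactly one gene (the root) must have no head")
  functions[root] <- NA_integer_
  g <- structure(
    list(n_genes = n, heads = heads, functions = functions,
         root_state = as.integer(root_state), root = root),
    class = "gn_genome")
  validate_genome(g)
  g
}

#' Validate genome invariants
#'
#' Checks the single-input network invariants: one root, every other gene has
#' exactly one head pointing at an existing gene, no self-regulation, the head
#' relation is acyclic, function bits are binary, and the root state is binary.
#' At least one terminal (out-degree 0) gene always exists in an acyclic
#' single-input network, so that invariant is implied.
#'
#' @param g a `gn_genome`.
#' @return `g`, invisibly; signals an error on any violation.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "gn_genome"))
  n <- g$n_genes
  heads <- g$heads
  root <- g$root
  if (!is.na(heads[root])) stop("root gene must have no head")
  nonroot <- setdiff(seq_len(n), root)
  h <- heads[nonroot]
  if (anyNA(h)) stop("every gene except the root must have a head")
  if (any(h < 1L | h > n)) stop("head index out of range")
  if (any(h == nonroot)) stop("self-regulation is not allowed")
  f <- g$functions[nonroot]
  if (anyNA(f) || any(f != 0L & f != 1L))
    stop("function bits must be 0 (repressor) or 1 (activator)")
  if (is.na(g$root_state) || !(g$root_state %in% c(0L, 1L)))
    stop("root_state must be 0 or 1")
  # acyclicity: walk each gene's regulator chain; it must reach the root in
  # at most n steps
  for (i in nonroot) {
    j <- i; steps <- 0L
    while (!is.na(heads[j])) {
      j <- heads[j]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in head relation")
    }
  }
  invisible(g)
}

#' Build a random or scale-free gene-network topology
#'
#' Genes are added one at a time; each new gene attaches to a single upstream
#' regulator among the genes already present. For `kind = "random"` the head
#' is drawn uniformly; for `kind = "scale_free"` a lottery model is used: the
#' head is drawn with probability proportional to its current out-degree + 1
#' (the +1 lets zero-degree genes acquire their first downstream edge).
#' Preferential attachment makes the out-degree distribution heavy-tailed
#' (approximately power-law), versus approximately Poisson for the uniform
#' rule. Function bits are uniform on {0, 1}; the heritable root state is
#' drawn uniformly unless supplied.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param n number of genes, at least 2.
#' @param kind `"scale_free"` or `"random"`.
#' @param root_state optional fixed root state (0 or 1); drawn uniformly if
#'   `NULL`.
#' @return a `gn_genome` in construction order (gene 1 is the root,
#'   `heads[i] < i`).
#' @export
#' @examples
#' set.seed(1)
#' g <- build_topology(16, "scale_free")
#' out_degrees(g)
build_topology <- function(n, kind = c("scale_free", "random"),
                           root_state = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2")
  heads <- rep(NA_integer_, n)
  if (kind == "random") {
    # head of gene i uniform on 1..(i-1); single runif draw per gene
    heads[2:n] <- 1L + as.integer(floor(stats::runif(n - 1L) * (2:n - 1L)))
  } else {
    outdeg <- integer(n)
    for (i in 2:n) {
      w <- outdeg[seq_len(i - 1L)] + 1
      h <- if (i == 2L) 1L else sample.int(i - 1L, 1L, prob = w)
      heads[i] <- h
      outdeg[h] <- outdeg[h] + 1L
    }
  }
  functions <- c(NA_integer_, as.integer(stats::runif(n - 1L) < 0.5))
  if (is.null(root_state))
    root_state <- as.integer(stats::runif(1L) < 0.5)
  genome(heads, functions, root_state)
}

#' Evaluate the Boolean states of all genes
#'
#' States propagate from the root in one topological pass: a non-root gene is
#' "on" (1) exactly when its head's state equals its function bit — an "on"
#' activator or an "off" repressor switches its target on; an "on" repressor
#' or an "off" activator switches it off (the XNOR of head state and function
#' bit). Because the network is an acyclic single-input tree the assignment is
#' unique and deterministic.
#'
#' @param g a `gn_genome`.
#' @return integer vector of length `n_genes` of states (0/1);
#'   `states[root] == root_state`.
#' @export
evaluate_states <- function(g) {
  stopifnot(inherits(g, "gn_genome"))
  n <- g$n_genes
  heads <- g$heads
  states <- rep(NA_integer_, n)
  states[g$root] <- g$root_state
  pending <- which(is.na(states))
  while (length(pending)) {
    ready <- pending[!is.na(states[heads[pending]])]
    if (!length(ready)) stop("cycle detected: states cannot be resolved")
    states[ready] <- as.integer(states[heads[ready]] == g$functions[ready])
    pending <- pending[is.na(states[pending])]
  }
  states
}

#' Out-degree of every gene
#'
#' Each non-root gene contributes one edge from its head, so the out-degrees
#' always sum to `n_genes - 1`. Genes with out-degree 0 are the *terminal*
#' genes whose states define the phenotype.
#'
#' @param g a `gn_genome`.
#' @return integer vector of out-degrees, one per gene.
#' @export
out_degrees <- function(g) {
  stopifnot(inherits(g, "gn_genome"))
  tabulate(g$heads[!is.na(g$heads)], nbins = g$n_genes)
}

#' Indices of terminal (out-degree 0) genes
#'
#' @param g a `gn_genome`.
#' @return integer vector of gene indices with out-degree 0.
#' @export
terminal_genes <- function(g) which(out_degrees(g) == 0L)

#' Phenotype of a genome
#'
#' The quantitative trait is the number of terminal genes in the "on" state,
#' scaled to the environmental range: `(env_max / T) * S` where `T` is the
#' number of terminal genes and `S` the number of those that are on. The value
#' lies in `[0, env_max]` and, for a fixed topology, takes at most `T + 1`
#' distinct values — smaller networks have coarser trait resolution.
#'
#' @param g a `gn_genome`.
#' @param env_max trait-range maximum (default 140).
#' @return the trait value.
#' @export
#' @examples
#' # a network with 8 terminal genes, 4 of them on, maps to 70 on a 0-140 scale
phenotype <- function(g, env_max = 140) {
  stopifnot(inherits(g, "gn_genome"))
  if (env_max <= 0) stop("`env_max` must be positive")
  term <- terminal_genes(g)
  states <- evaluate_states(g)
  (env_max / length(term)) * sum(states[term])
}

#' @export
print.gn_genome <- function(x, ...) {
  term <- terminal_genes(x)
  cat(sprintf("<gn_genome> %d genes, root = gene %d (state %d), %d terminal\n",
              x$n_genes, x$root, x$root_state, length(term)))
  cat(sprintf("  phenotype (env_max = 140): %.4g\n", phenotype(x)))
  invisible(x)
}

#' Write / read a genome as plain text
#'
#' The chromosome format mirrors the network encoding: a small header with the
#' gene count and heritable root state, then one row per gene giving its head
#' index and function bit (`NA` for the root).
#'
#' @param g a `gn_genome`.
#' @param path file path.
#' @return `write_genome` returns `path` invisibly; `read_genome` returns a
#'   `gn_genome`.
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "gn_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("n %d", g$n_genes),
               sprintf("root_state %d", g$root_state),
               "gene head function"), con)
  utils::write.table(data.frame(gene = seq_len(g$n_genes), head = g$heads,
                         fn = g$functions),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("^n ", "", lines[1]))
  root_state <- as.integer(sub("^root_state ", "", lines[2]))
  tab <- utils::read.table(text = lines[-(1:3)], col.names = c("gene", "head", "fn"))
  tab <- tab[order(tab$gene), ]
  if (nrow(tab) != n) stop("genome file is inconsistent: wrong gene count")
  genome(tab$head, tab$fn, root_state)
}

#' Export a genome in DOT (Graphviz) format
#'
#' Edges run from head (regulator) to target; activating edges are solid,
#' repressing edges dashed; node fill encodes the evaluated state.
#'
#' @param g a `gn_genome`.
#' @return a character vector of DOT lines.
#' @export
genome_dot <- function(g) {
  stopifnot(inherits(g, "gn_genome"))
  states <- evaluate_states(g)
  nodes <- sprintf("  g%d [label=\"%d\", style=filled, fillcolor=%s];",
                   seq_len(g$n_genes), seq_len(g$n_genes),
                   ifelse(states == 1L, "black, fontcolor=white", "white"))
  nr <- setdiff(seq_len(g$n_genes), g$root)
  edges <- sprintf("  g%d -> g%d [style=%s];", g$heads[nr], nr,
                   ifelse(g$functions[nr] == 1L, "solid", "dashed"))
  c("digraph genome {", nodes, edges, "}")
}

#' Convert a genome to an igraph graph
#'
#' Requires the igraph package. Vertex attributes `state` and `terminal` and
#' edge attribute `activator` are attached.
#'
#' @param g a `gn_genome`.
#' @return an `igraph` object.
#' @export
genome_igraph <- function(g) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for genome_igraph()")
  nr <- setdiff(seq_len(g$n_genes), g$root)
  gr <- igraph::graph_from_edgelist(cbind(g$heads[nr], nr), directed = TRUE)
  igraph::V(gr)$state <- evaluate_states(g)
  igraph::V(gr)$terminal <- out_degrees(g) == 0L
  igraph::E(gr)$activator <- g$functions[nr] == 1L
  gr
}
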