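test_that("topology construction yields valid single-input acyclic networks", {
  set.seed(11)
  for (kind in c("random", "scale_free")) {
    for (n in c(2L, 16L, 64L)) {
      g <- build_topology(n, kind)
      expect_s3_class(g, "gn_genome")
      expect_identical(g$root, 1L)
      # n = 2 admits only one topology: gene 2 regulated by gene 1
      if (n == 2) expect_identical(g$heads, c(NA, 1L))
      # one defined edge per non-root gene, summing over out-degrees
      expect_identical(sum(is.na(g$heads)), 1L)
      expect_identical(sum(out_degrees(g)), n - 1L)
      expect_true(length(terminal_genes(g)) >= 1L)
      expect_silent(validate_genome(g))
    }
  }
  expect_error(build_topology(1), "must be an integer >= 2")
})

test_that("state rule matches the functional map on all four cases", {
  # (head state, function) -> target state: the XNOR truth table
  cases <- list(c(1L, 0L, 0L),  # on repressor  -> off
                c(0L, 0L, 1L),  # off repressor -> on
                c(1L, 1L, 1L),  # on activator  -> on
                c(0L, 1L, 0L))  # off activator -> off
  for (cs in cases) {
    g <- genome(c(NA, 1L), c(NA, cs[2]), root_state = cs[1])
    expect_identical(evaluate_states(g), c(cs[1], cs[3]))
  }
})

test_that("activator chains propagate the root state unchanged", {
  g <- chain_genome(5, fn = 1L, root_state = 1L)
  expect_identical(evaluate_states(g), rep(1L, 5))
  g0 <- chain_genome(5, fn = 1L, root_state = 0L)
  expect_identical(evaluate_states(g0), rep(0L, 5))
  # repressor chain alternates
  gr <- chain_genome(4, fn = 0L, root_state = 1L)
  expect_identical(evaluate_states(gr), c(1L, 0L, 1L, 0L))
})

test_that("the worked 13-gene network has 8 terminals, 4 on, phenotype 70", {
  g <- worked_example_genome()
  expect_identical(g$n_genes, 13L)
  expect_length(terminal_genes(g), 8L)
  states <- evaluate_states(g)
  expect_identical(sum(states[terminal_genes(g)]), 4L)
  expect_equal(phenotype(g, env_max = 140), 70)
})

test_that("phenotype spans [0, env_max] and respects the resolution bound", {
  # all terminals off -> 0; all on -> env_max
  g_off <- chain_genome(6, fn = 1L, root_state = 0L)
  expect_equal(phenotype(g_off), 0)
  g_on <- chain_genome(6, fn = 1L, root_state = 1L)
  expect_equal(phenotype(g_on), 140)
  # fixed topology: phenotype lies on the T+1-point grid
  set.seed(21)
  g <- build_topology(16, "scale_free")
  T <- length(terminal_genes(g))
  vals <- replicate(50, {
    g2 <- g
    g2$functions[-1] <- as.integer(runif(15) < 0.5)
    g2$root_state <- as.integer(runif(1) < 0.5)
    phenotype(g2)
  })
  grid_vals <- (140 / T) * 0:T
  expect_true(all(vapply(vals, function(v) min(abs(v - grid_vals)) < 1e-9,
                         logical(1))))
})

test_that("phenotype is invariant under topology-preserving relabeling", {
  set.seed(31)
  for (i in 1:10) {
    g <- build_topology(sample(3:40, 1), sample(c("random", "scale_free"), 1))
    perm <- sample(g$n_genes)
    gp <- permute_genome(g, perm)
    expect_silent(validate_genome(gp))
    expect_equal(phenotype(gp), phenotype(g))
  }
})

test_that("scale-free out-degrees are heavier-tailed than random ones", {
  set.seed(41)
  n <- 256
  reps <- 200
  v_sf <- replicate(reps, var(out_degrees(build_topology(n, "scale_free"))))
  v_rn <- replicate(reps, var(out_degrees(build_topology(n, "random"))))
  tt <- t.test(v_sf, v_rn, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  max_sf <- replicate(50, max(out_degrees(build_topology(n, "scale_free"))))
  max_rn <- replicate(50, max(out_degrees(build_topology(n, "random"))))
  expect_gt(mean(max_sf), mean(max_rn))
})

test_that("invalid genomes are rejected", {
  expect_error(genome(c(NA, 2L), c(NA, 1L), 1L), "self-regulation")
  expect_error(genome(c(2L, 1L), c(1L, 1L), 1L), "root")
  expect_error(genome(c(NA, 3L, 2L), c(NA, 1L, 1L), 1L), "cycle")
  expect_error(genome(c(NA, 1L), c(NA, 2L), 1L), "function bits")
  expect_error(genome(c(NA, 1L), c(NA, 1L), 3L), "root_state")
})

test_that("genome serialization round-trips and exports are well-formed", {
  g <- worked_example_genome()
  path <- withr::local_tempfile(fileext = ".txt")
  write_genome(g, path)
  g2 <- read_genome(path)
  expect_identical(g2$heads, g$heads)
  expect_identical(g2$functions, g$functions)
  expect_identical(g2$root_state, g$root_state)
  dot <- genome_dot(g)
  expect_identical(dot[1], "digraph genome {")
  expect_length(grep("->", dot), 12L)   # one edge per non-root gene
})
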