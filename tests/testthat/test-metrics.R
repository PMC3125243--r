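test_that("mid-parent regression recovers planted heritabilities", {
  set.seed(501)
  # identity transmission: slope 1
  mid <- rnorm(500, 70, 5)
  expect_equal(midparent_heritability(mid, mid), 1)
  # independence: slope 0 within sampling error
  off0 <- rnorm(10000, 70, 5)
  mid0 <- rnorm(10000, 70, 5)
  expect_lt(abs(midparent_heritability(off0, mid0)), 0.03)
  # planted additive model, h2 = 0.5
  h2 <- 0.5
  midp <- rnorm(5000, 70, 6)
  off <- 70 + h2 * (midp - 70) + rnorm(5000, 0, 6 * sqrt(1 - h2^2))
  expect_lt(abs(midparent_heritability(off, midp) - h2), 0.05)
  # degenerate mid-parent variance
  expect_true(is.na(midparent_heritability(rnorm(10), rep(1, 10))))
  expect_error(midparent_heritability(1:5, 1:4), "paired")
})

test_that("heritability is equivariant under affine transformation", {
  set.seed(511)
  mid <- rnorm(200, 70, 4)
  off <- 70 + 0.4 * (mid - 70) + rnorm(200, 0, 2)
  s <- midparent_heritability(off, mid)
  expect_equal(midparent_heritability(3 + 2 * off, 3 + 2 * mid), s)
  expect_equal(midparent_heritability(off, 5 + 0.5 * mid), s / 0.5)
  expect_equal(midparent_heritability(1 - 3 * off, mid), -3 * s)
})

test_that("coexistence and persistence are read off run records", {
  cfg <- sim_config(generations = 25)
  sp <- default_two_species()
  run <- run_simulation(cfg, sp$focal, sp$competitor, seed = 12)
  expect_identical(coexistence(run), TRUE)
  expect_identical(persistence_time(run), 25L)
  sp2 <- default_two_species(comp_n = 256)
  run2 <- run_simulation(cfg, sp2$focal, sp2$competitor, seed = 12)
  expect_identical(coexistence(run2), FALSE)
  expect_identical(persistence_time(run2),
                   unname(attr(run2, "extinction")["competitor"]))
})

test_that("0.9 K metrics follow their definitions on synthetic trajectories", {
  # run pinned at 600 from generation 10 (trajectory index 11)
  traj <- c(rep(100, 10), rep(600, 41))   # generations 0..50
  expect_equal(critical_population(traj), 540)
  expect_identical(time_to_09k(traj, 540), 10L)
  expect_equal(prop_above_09k(traj, 540), 41 / 51)
  # never exceeds: sentinel and zero fraction
  low <- rep(100, 51)
  expect_true(is.na(time_to_09k(low, 540)))
  expect_equal(prop_above_09k(low, 540), 0)
  # threshold is shared: maximum over all supplied runs
  expect_equal(critical_population(traj, low, c(0, 700)), 630)
  expect_error(time_to_09k(traj, 0), "positive")
})

test_that("0.9 K metrics integrate with experiments and contrasts", {
  cfg <- sim_config(generations = 25, canalization_gens = 5)
  design <- data.frame(comp_n = 16L, comp_topology = "scale_free",
                       comp_mu = 1e-4, comp_rec = 0.05, comp_d = 0.05,
                       focal_d = 0.05, landscape = "H3",
                       rate1 = 1e-3, rate2 = 2.5e-4, rate3 = 1e-4,
                       heterogeneity = 3L, stringsAsFactors = FALSE)
  meta <- run_experiment(design, cfg, replicates = 2, master_seed = 31)
  mp <- run_metapopulation(cfg, landscapes = list(H3 = c(1e-3, 2.5e-4, 1e-4)),
                           replicates = 2, master_seed = 32)
  thr <- critical_population(meta, mp)
  expect_gt(thr, 0)
  meta <- add_09k_metrics(meta, thr)
  mp <- add_09k_metrics(mp, thr)
  out <- metapop_contrast(meta$summary, mp$summary)
  expect_identical(nrow(out), nrow(meta$summary))
  expect_true(all(c("d_t09k", "d_prop09k") %in% names(out)))
  # identical arms give differences centred on zero
  self <- metapop_contrast(mp$summary, mp$summary)
  expect_equal(mean(self$d_prop09k), 0)
  bad <- mp$summary; bad$landscape <- "elsewhere"
  expect_error(metapop_contrast(bad, mp$summary), "unmatched")
})

test_that("mismatch is a census-weighted trait-environment gap", {
  cfg <- sim_config(generations = 30, canalization_gens = 5)
  sp <- default_two_species()
  run <- run_simulation(cfg, sp$focal, sp$competitor, seed = 41)
  mm <- mismatch(run)
  expect_gte(mm, 0)
  # manual recomputation over post-canalization rows
  rows <- run$generation >= 6
  num <- 0; den <- 0
  for (s in 1:2) for (p in 1:3) {
    w <- run[rows, sprintf("census_sp%d_p%d", s, p)]
    m <- run[rows, sprintf("mphen_sp%d_p%d", s, p)]
    q <- run[rows, sprintf("quality_p%d", p)]
    ok <- w > 0 & !is.na(m)
    num <- num + sum((w * abs(m - q))[ok]); den <- den + sum(w[ok])
  }
  expect_equal(mm, num / den)
})

test_that("summary models attribute variance to the planted factor", {
  set.seed(531)
  tab <- expand.grid(comp_d = c(0.01, 0.05, 0.1), comp_n = c(16, 64, 256),
                     comp_mu = c(1e-5, 1e-4, 1e-3), heterogeneity = 1:3,
                     rep = 1:2)
  # pure dispersal effect on persistence
  tab$persistence <- 750 - 4000 * tab$comp_d + rnorm(nrow(tab), 0, 10)
  tab$coexist <- runif(nrow(tab)) <
    plogis(2 - 40 * tab$comp_d)   # dispersal lowers coexistence odds
  rep1 <- fit_summary_models(tab)
  pe <- rep1$persistence
  expect_gt(pe$pct_var[pe$term == "comp_d"], 90)
  expect_lt(max(pe$pct_var[pe$term %in% c("comp_n", "comp_mu")]), 5)
  expect_identical(nrow(rep1$coexistence),
                   5L)  # NULL + three mains + interaction
  # null data: near-zero explained variance
  tab$persistence <- rnorm(nrow(tab), 400, 10)
  rep0 <- fit_summary_models(tab)
  expect_lt(sum(rep0$persistence$pct_var[1:3]), 10)
  expect_error(fit_summary_models(tab[, -1]), "lacks columns")
  expect_warning(fit_summary_models(tab[tab$comp_n == 16, ]),
                 "single level")
})
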