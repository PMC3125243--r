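test_that("initialization founds two patches of 100 random individuals", {
  set.seed(401)
  cfg <- sim_config(generations = 50)
  sp <- default_two_species()
  world <- initialize_run(cfg, sp$focal, sp$competitor)
  cen <- netcomm:::world_census(world)$census
  expect_identical(cen[1, ], c(100L, 0L, 0L))
  expect_identical(cen[2, ], c(0L, 100L, 0L))
  expect_equal(world$landscape$quality, rep(70, 3))
  # founding genomes are (essentially) all distinct
  keys <- apply(world$pops[[1]]$heads, 2, paste, collapse = ",")
  expect_gt(length(unique(keys)), 95)
  expect_error(
    initialize_run(cfg, sp$focal,
                   species_params("c", start_patch = 1L)),
    "same patch")
})

test_that("runs are deterministic and respect the carrying capacity", {
  cfg <- sim_config(generations = 40)
  sp <- default_two_species()
  r1 <- run_simulation(cfg, sp$focal, sp$competitor, seed = 99)
  r2 <- run_simulation(cfg, sp$focal, sp$competitor, seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_simulation(cfg, sp$focal, sp$competitor, seed = 100)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
  cen <- as.matrix(r1[grep("^census_", names(r1))])
  patch_tot <- cen[, 1:3] + cen[, 4:6]
  expect_true(all(patch_tot <= 200))
  expect_true(all(rowSums(cen) <= 600))
  expect_lte(max(r1$generation), cfg$generations)
})

test_that("no dispersal occurs during the canalization period", {
  cfg <- sim_config(generations = 30, canalization_gens = 20)
  sp <- default_two_species(comp_d = 0.1, focal_d = 0.1)
  run <- run_simulation(cfg, sp$focal, sp$competitor, seed = 5)
  early <- run$generation <= 20
  # species stay confined to their founding patches while canalizing
  expect_true(all(run$census_sp1_p2[early] == 0))
  expect_true(all(run$census_sp1_p3[early] == 0))
  expect_true(all(run$census_sp2_p1[early] == 0))
  expect_true(all(run$census_sp2_p3[early] == 0))
})

test_that("an empty world is an absorbing fixed point", {
  cfg <- sim_config(generations = 10, canalization_gens = 5)
  world <- initialize_run(cfg, species_params(n0 = 0L),
                          species_params("c", n0 = 0L, start_patch = 2L))
  world <- step_generation(world)
  expect_identical(sum(netcomm:::world_census(world)$census), 0L)
  world <- step_generation(world)
  expect_identical(sum(netcomm:::world_census(world)$census), 0L)
})

test_that("runs stop at the first regional extinction of a tracked species", {
  set.seed(421)
  cfg <- sim_config(generations = 200)
  # a 256-gene competitor cannot establish under these dynamics
  sp <- default_two_species(comp_n = 256)
  run <- run_simulation(cfg, sp$focal, sp$competitor, seed = 17)
  ext <- attr(run, "extinction")
  expect_false(is.na(ext["competitor"]))
  expect_identical(max(run$generation), as.integer(ext["competitor"]))
  expect_identical(coexistence(run), FALSE)
  final <- run[nrow(run), ]
  expect_identical(sum(as.integer(
    final[paste0("census_sp2_p", 1:3)])), 0L)
})

test_that("metapopulation runs track a single species without a stop trigger
           for the absent competitor", {
  cfg <- sim_config(generations = 30)
  run <- run_simulation(cfg, species_params(d = 0.05), competitor = NULL,
                        seed = 3)
  expect_length(attr(run, "species"), 1L)
  expect_true(is.na(coexistence(run)))
  expect_identical(max(run$generation), 30L)
})

test_that("the experiment driver enumerates cells with reproducible seeds", {
  cfg <- sim_config(generations = 15, canalization_gens = 5)
  design <- data.frame(comp_n = 16L, comp_topology = "scale_free",
                       comp_mu = 1e-4, comp_rec = 0.05, comp_d = 0.05,
                       focal_d = 0.05, landscape = "H3",
                       rate1 = 1e-3, rate2 = 2.5e-4, rate3 = 1e-4,
                       heterogeneity = 3L, stringsAsFactors = FALSE)
  e1 <- run_experiment(design, cfg, replicates = 2, master_seed = 7)
  expect_identical(nrow(e1$summary), 2L)
  expect_length(e1$regional, 2L)
  e2 <- run_experiment(design, cfg, replicates = 2, master_seed = 7)
  expect_identical(e1$summary, e2$summary)
  expect_false(e1$summary$seed[1] == e1$summary$seed[2])
  # a 1-cell, 1-replicate design yields a 1-row table
  e3 <- run_experiment(design, cfg, replicates = 1, master_seed = 7)
  expect_identical(nrow(e3$summary), 1L)
})

test_that("the default factorial design has 324 cells; landscapes number 7", {
  d <- default_experiment_design()
  expect_identical(nrow(d), 324L)
  expect_identical(length(unique(d$comp_n)), 3L)
  expect_identical(length(unique(d$comp_d)), 3L)
  expect_setequal(unique(d$heterogeneity), 1:3)
  expect_length(default_landscapes(), 7L)
  # metapopulation arm at default settings: 3 replicates x 7 landscapes
  cfg <- sim_config(generations = 5, canalization_gens = 2)
  mp <- run_metapopulation(cfg, replicates = 1, master_seed = 2,
                           landscapes = default_landscapes()[1:2])
  expect_identical(nrow(mp$summary), 2L)
})
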