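genealogy_cfg <- function(...) {
  simulation_config(
    sampling = data.frame(age_bp = c(-50, 10000), n = c(30, 1)), ...)
}

test_that("a zero mutation rate yields tips identical to the ancestor", {
  sim <- simulate_genealogy(genealogy_cfg(mu_site = 0), seed = 3)
  expect_length(sim$profiles, 31)
  anc <- sim$profiles[["ANC"]]
  diffs <- vapply(sim$profiles[-1], pair_difference, 0, b = anc)
  expect_true(all(diffs == 0))
})

test_that("a fully persistent sample has rho zero regardless of age", {
  sim <- simulate_genealogy(genealogy_cfg(persistent_fraction = 1), seed = 4)
  hg <- haplogroup_sample("M", members = sim$profiles[-1])
  expect_equal(rho_statistic(hg)$rho, 0)
})

test_that("private mutation counts match the Poisson mean mu*L*T", {
  cfg <- simulation_config(
    mu_site = 1.6e-8,
    sampling = data.frame(age_bp = c(-50, 10000), n = c(2000, 1)))
  set.seed(90)
  seeds <- sample.int(2^31 - 1, 200)
  inside <- vapply(seeds, function(s) {
    sim <- simulate_genealogy(cfg, seed = s)
    m <- mean(sim$truth$K)
    m >= 2.54 && m <= 2.77
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})

test_that("mutation demand beyond free sites is rejected", {
  cfg <- simulation_config(
    mu_site = 2e-3,
    sampling = data.frame(age_bp = c(-50, 1000), n = c(50, 1)))
  expect_error(simulate_genealogy(cfg, seed = 1), "free sites")
})

test_that("genealogy draws are reproducible from the seed", {
  cfg <- genealogy_cfg(persistent_fraction = 0.3, divergence = "uniform")
  a <- simulate_genealogy(cfg, seed = 11)
  b <- simulate_genealogy(cfg, seed = 11)
  expect_identical(lapply(a$profiles, `[[`, "variants"),
                   lapply(b$profiles, `[[`, "variants"))
  expect_identical(a$truth$K, b$truth$K)
})

test_that("pairwise diversity of a constant-size coalescent matches theory", {
  # two haploid tips, constant Ne: E[TMRCA] = Ne generations, so
  # E[pairwise differences] = 2 * mu * L * Ne * generation_years
  cfg <- simulation_config(
    mu_site = 1e-7,
    demography = data.frame(time_bp = c(0, 1000), size = c(500, 500)),
    sampling = data.frame(age_bp = c(-50, -50), n = c(1, 1)))
  set.seed(14)
  seeds <- sample.int(2^31 - 1, 4000)
  d <- vapply(seeds, function(s) {
    sim <- simulate_coalescent(cfg, seed = s)
    pair_difference(sim$profiles[[1]], sim$profiles[[2]])
  }, 0)
  expected <- 2 * 1e-7 * 16569 * 500 * 25
  expect_equal(mean(d), expected, tolerance = 0.05)
})

test_that("a single tip coalesces trivially with empty variants", {
  cfg <- simulation_config(
    sampling = data.frame(age_bp = -50, n = 1))
  sim <- simulate_coalescent(cfg, seed = 2)
  expect_length(sim$profiles, 1)
  expect_equal(nrow(sim$profiles[[1]]$variants), 0)
  hg <- haplogroup_sample("M", members = sim$profiles)
  expect_equal(rho_statistic(hg)$rho, 0)
})

test_that("identical seeds give byte-identical fixture files", {
  cfg <- simulation_config(
    sampling = data.frame(age_bp = c(-50, 5000), n = c(6, 3)), seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(simulate_coalescent(cfg), d1)
  write_fixture(simulate_coalescent(cfg), d2)
  for (f in c("sequences.fasta", "metadata.csv", "roots.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("fixtures round-trip through the profile readers", {
  cfg <- simulation_config(
    sampling = data.frame(age_bp = c(-50, 8000), n = c(8, 4)), seed = 33)
  sim <- simulate_coalescent(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  back <- read_profiles(paths[["fasta"]], paths[["metadata"]])
  expect_setequal(names(back), names(sim$profiles))
  for (id in names(back)) {
    expect_setequal(variant_keys(back[[id]]), variant_keys(sim$profiles[[id]]))
  }
  # in-memory and round-tripped pairwise differences agree
  ids <- names(back)[1:4]
  for (i in 1:3) {
    expect_equal(pair_difference(back[[ids[i]]], back[[ids[i + 1]]]),
                 pair_difference(sim$profiles[[ids[i]]],
                                 sim$profiles[[ids[i + 1]]]))
  }
  # truth JSON carries provenance
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 33)
  expect_match(truth$config_hash, "^[0-9a-f]{8}$")

  expect_error(write_fixture(list(profiles = list()), dir), "no profiles")
})

test_that("clade labels partition tips and map onto macrohaplogroups", {
  cfg <- simulation_config(seed = 8)
  sim <- simulate_coalescent(cfg)
  md <- profile_metadata(sim$profiles)
  expect_true(all(md$macrohaplogroup %in% c("M", "N", "R", "L-other")))
  # haplogroup labels start with their clade letter, so prefix matching
  # recovers the clade
  expect_true(all(substr(md$haplogroup, 1, 1) ==
                    substr(sim$truth$clade_labels[sim$truth$tip_clade], 1, 1)))
  expect_equal(sort(unique(sim$truth$tip_clade)),
               seq_along(sim$truth$clade_labels))
})

test_that("truth records the genealogy needed to score estimates", {
  cfg <- genealogy_cfg(mu_site = 1.6e-8)
  sim <- simulate_genealogy(cfg, seed = 5)
  expect_equal(sim$truth$T_anc, 10000)
  expect_equal(sim$truth$expected_K, 1.6e-8 * 16569 * 10000)
  expect_length(sim$truth$K, 30)
  # under ancestral divergence every non-persistent tip spans the full age
  expect_true(all(sim$truth$divergence_times[!sim$truth$persistent] == 10000))
})
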