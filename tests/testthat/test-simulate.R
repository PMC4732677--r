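test_that("configuration invariants are enforced", {
  expect_error(scenario_config(n_sites = 1), "n_sites")
  expect_error(scenario_config(width_range = c(50, 20)), "low < high")
  expect_error(scenario_config(source_sd = -1), "SDs")
  cfg <- scenario_config()
  ap <- cfg$availability_params
  # default curves: decline from 1 at the narrowest to 0 at the widest beach
  w <- cfg$width_range
  expect_equal(ap$mole[["intercept"]] + ap$mole[["slope"]] * w[1], 1)
  expect_equal(ap$mole[["intercept"]] + ap$mole[["slope"]] * w[2], 0)
  expect_equal(ap$coq[["intercept"]] + ap$coq[["slope"]] * w[2], 1)
})

test_that("site grids span the width range and co-vary as morphology dictates", {
  cfg <- scenario_config(n_sites = 16, width_jitter = 0, seed = 3)
  sites <- simulate_sites(cfg)
  expect_equal(nrow(sites), 16L)
  expect_equal(min(sites$width_m), 15.7)
  expect_equal(max(sites$width_m), 106.6)
  # two sites, no jitter: exactly the endpoints
  two <- simulate_sites(scenario_config(n_sites = 2, width_jitter = 0))
  expect_equal(two$width_m, c(15.7, 106.6))
  # narrow = steep & coarse, wide = flat & fine
  expect_lt(cor(sites$width_m, sites$slope_deg), 0)
  expect_lt(cor(sites$width_m, log(sites$grain_mm)), 0)
  expect_true(all(sites$wrack_g >= 0) && all(sites$burrow_density >= 0))
  # same seed, same records
  expect_identical(sites, simulate_sites(cfg))
})

test_that("availability normalizes onto the simplex with a uniform fallback", {
  # flat curves giving scores (2, 1, 1) at every width
  cfg <- scenario_config(
    n_sites = 4, width_jitter = 0, seed = 1,
    availability_params = list(mole = c(intercept = 2, slope = 0),
                               amph = c(center = 40, spread = 1e9, amplitude = 1),
                               coq = c(intercept = 1, slope = 0),
                               predator = c(center = 40, spread = 15, amplitude = 5)))
  tr <- simulate_truth(simulate_sites(cfg), cfg)
  expect_equal(unname(tr$p[1, ]), c(0.5, 0.25, 0.25), tolerance = 1e-9)
  # all-zero availability: uniform diet
  cfg0 <- scenario_config(
    n_sites = 3, seed = 1,
    availability_params = list(mole = c(intercept = 0, slope = 0),
                               amph = c(center = 40, spread = 12, amplitude = 0),
                               coq = c(intercept = 0, slope = 0),
                               predator = c(center = 40, spread = 15, amplitude = 5)))
  tr0 <- simulate_truth(simulate_sites(cfg0), cfg0)
  expect_true(all(abs(tr0$p - 1 / 3) < 1e-12))
  # rising coquina with the others flat: p_coq non-decreasing in width
  cfgm <- scenario_config(
    n_sites = 12, width_jitter = 0, seed = 2,
    availability_params = list(mole = c(intercept = 1, slope = 0),
                               amph = c(center = 40, spread = 1e9, amplitude = 0.5),
                               coq = c(intercept = 0, slope = 0.01),
                               predator = c(center = 40, spread = 15, amplitude = 5)))
  trm <- simulate_truth(simulate_sites(cfgm), cfgm)
  expect_true(all(diff(trm$p[, "coquina"]) >= -1e-12))
  # simplex invariants hold for the default scenario too
  trd <- simulate_truth(simulate_sites(scenario_config(seed = 5)),
                        scenario_config(seed = 5))
  expect_true(all(trd$p >= 0))
  expect_true(all(abs(rowSums(trd$p) - 1) < 1e-12))
})

test_that("zero-noise consumers sit exactly at the mixing model's mean", {
  cfg <- scenario_config(n_sites = 4, source_sd = 0, site_shift_sd = 0,
                         tef_true = c(mean = 2.3, sd = 0),
                         residual_sd = c(d13C = 0, d15N = 0),
                         missing_amphipod = "none", seed = 8)
  sc <- simulate_scenario(cfg)
  taxa <- c("mole_crab", "amphipod", "coquina")
  for (i in seq_len(nrow(sc$sites))) {
    st <- sc$sites$site[i]
    sm <- sc$truth$source_means[sc$truth$source_means$site == st, ]
    sm <- sm[match(taxa, sm$taxon), ]
    p <- sc$truth$p[i, ]
    cons <- sc$consumers[sc$consumers$site == st, ]
    expect_equal(cons$d13C, rep(sum(p * sm$d13C), nrow(cons)))
    expect_equal(cons$d15N, rep(sum(p * (sm$d15N + 2.3)), nrow(cons)))
  }
})

test_that("consumer means converge to the closed form (Monte Carlo)", {
  cfg <- scenario_config(n_sites = 2, n_consumers = c(1000L, 1000L),
                         missing_amphipod = "none", seed = 21)
  sc <- simulate_scenario(cfg)
  st <- sc$sites$site[1]
  sm <- sc$truth$source_means[sc$truth$source_means$site == st, ]
  sm <- sm[match(c("mole_crab", "amphipod", "coquina"), sm$taxon), ]
  p <- sc$truth$p[1, ]
  mu_n <- sum(p * (sm$d15N + cfg$tef_true[[1]]))
  v_n <- sum(p^2 * (cfg$source_sd^2 + cfg$tef_true[[2]]^2)) + cfg$residual_sd[[2]]^2
  x <- sc$consumers$d15N[sc$consumers$site == st]
  expect_lt(abs(mean(x) - mu_n), 3 * sqrt(v_n / length(x)))
})

test_that("identical seeds give byte-identical output files", {
  d1 <- file.path(tempdir(), "scn1"); d2 <- file.path(tempdir(), "scn2")
  write_scenario(simulate_scenario(scenario_config(n_sites = 5, seed = 33)), d1)
  write_scenario(simulate_scenario(scenario_config(n_sites = 5, seed = 33)), d2)
  for (f in c("sites.csv", "signatures.csv", "consumers.csv",
              "wrack_components.csv", "truth_diet.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("low-wrack sites lack amphipod tissue under the auto rule", {
  cfg <- scenario_config(seed = 12)   # auto missing rule, threshold 20 g
  sc <- simulate_scenario(cfg)
  low <- sc$sites$site[sc$sites$wrack_g < cfg$wrack_threshold]
  amph_sites <- unique(sc$signatures$site[sc$signatures$taxon == "amphipod"])
  expect_gt(length(low), 0)   # the default gradient always has dry-wrack beaches
  expect_length(intersect(low, amph_sites), 0)
  # explicit index override
  cfg2 <- scenario_config(n_sites = 5, missing_amphipod = 2, seed = 12)
  sc2 <- simulate_scenario(cfg2)
  expect_false("S02" %in% sc2$signatures$site[sc2$signatures$taxon == "amphipod"])
})
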