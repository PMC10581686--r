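test_that("dispersion_range matches hand-computed haversine values", {
  # single point
  expect_identical(dispersion_range(data.frame(lon = 10, lat = 45)), 0)
  # antipodal equatorial points: half the great circle, pi * R
  d <- dispersion_range(data.frame(lon = c(0, 180), lat = c(0, 0)))
  expect_equal(d, pi * 6371, tolerance = 1e-12)
  expect_equal(signif(d, 7), 20015.09)
  # three equatorial points 1 degree apart:
  # (111.1949 + 222.3898 + 111.1949) / 3 = 148.2599
  d3 <- dispersion_range(data.frame(lon = c(0, 1, 2), lat = c(0, 0, 0)))
  oracle <- mean(6371 * pi / 180 * c(1, 2, 1))
  expect_equal(d3, oracle, tolerance = 1e-10)
  expect_equal(signif(d3, 5), 148.26)
})

test_that("dispersion_range invariances: permutation, rotation, duplicates", {
  set.seed(4)
  pts <- data.frame(lon = runif(12, -170, 170), lat = runif(12, -80, 80))
  d0 <- dispersion_range(pts)
  expect_equal(dispersion_range(pts[sample(12), ]), d0)
  rot <- pts; rot$lon <- ((rot$lon + 57 + 180) %% 360) - 180
  expect_equal(dispersion_range(rot), d0, tolerance = 1e-9)
  # duplicates kept by default: duplicating every point leaves the mean
  # over ordered pairs *different* from the mean over unordered pairs only
  # through the zero self-pairs, so check the documented behaviours directly
  dup <- rbind(pts, pts)
  expect_equal(dispersion_range(dup, dedupe = TRUE), d0)
  expect_lt(dispersion_range(dup), d0)  # zero-distance pairs pull mean down
})

test_that("dispersion_range large-n subsample approximates the exact mean", {
  set.seed(5)
  pts <- data.frame(lon = runif(6000, -10, 10), lat = runif(6000, 40, 50))
  exact_sub <- dispersion_range(pts[1:3000, ])
  est <- dispersion_range(pts, max_exact_points = 5000, n_pairs = 2e5,
                          seed = 7)
  expect_equal(est, exact_sub, tolerance = 0.02)
  # seeded: identical on rerun
  expect_identical(dispersion_range(pts, n_pairs = 2e5, seed = 7), est)
})

test_that("dispersion_range rejects invalid coordinates", {
  expect_error(dispersion_range(data.frame(lon = 0, lat = 91)), "lat")
  expect_error(dispersion_range(data.frame(lon = NA, lat = 0)), "coordinates")
})

test_that("range_centroid: identity, symmetry, antimeridian, degenerate", {
  expect_equal(range_centroid(data.frame(lon = 12, lat = -33)),
               c(lon = 12, lat = -33), tolerance = 1e-10)
  expect_equal(range_centroid(data.frame(lon = c(0, 0), lat = c(10, -10))),
               c(lon = 0, lat = 0), tolerance = 1e-10)
  # straddling the antimeridian: centroid near +-180, never 0
  ctr <- range_centroid(data.frame(lon = c(-179.5, 179.5), lat = c(0, 0)))
  expect_equal(abs(ctr[["lon"]]), 180, tolerance = 1e-8)
  expect_equal(ctr[["lat"]], 0, tolerance = 1e-10)
  expect_error(range_centroid(data.frame(lon = c(0, 180), lat = c(0, 0))),
               "degenerate centroid")
})

test_that("assign_region is a deterministic nearest-cell lookup with Unknown fallback", {
  lookup <- data.frame(lon = c(10, 80, -100), lat = c(50, 20, 40),
                       region = c("Palaearctic", "Oriental", "Nearctic"))
  expect_identical(assign_region(c(11, 51), lookup), "Palaearctic")
  expect_identical(assign_region(c(81, 19), lookup), "Oriental")
  expect_identical(assign_region(c(11, 51), lookup),
                   assign_region(c(11, 51), lookup))
  expect_warning(r <- assign_region(c(0, -60), lookup), "Unknown")
  expect_identical(r, "Unknown")
})

test_that("regroup_iucn reproduces the 9-to-3 mapping and is total/surjective", {
  codes <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD", "NE")
  groups <- regroup_iucn(codes)
  expect_identical(groups,
                   c(rep("Threatened", 5), rep("NonThreatened", 2),
                     rep("Unknown", 2)))
  expect_setequal(unique(groups),
                  c("Threatened", "NonThreatened", "Unknown"))
  expect_error(regroup_iucn("XX"), "XX")
})

test_that("prepare_design transforms, scales and dummy-codes as documented", {
  pf <- make_profiles(n = 200, seed = 21)
  des <- prepare_design(pf, variant = "eq1")
  X <- des$design
  expect_identical(names(X), fixed_terms("eq1"))
  # z-scored continuous columns
  for (cn in grep("^log_", names(X), value = TRUE)) {
    expect_lt(abs(mean(X[[cn]])), 1e-12)
    expect_equal(sd(X[[cn]]), 1, tolerance = 1e-12)
  }
  # log transforms recoverable: log_range is log1p on the raw scale
  tr <- des$transforms$log_range
  expect_equal(X$log_range * tr["scale"] + tr["center"],
               log1p(pf$range_km), ignore_attr = TRUE)
  expect_equal(des$transforms$log_size[["center"]], mean(log(pf$size_mm)))
  # baseline species has all factor dummies zero
  base_rows <- pf$habitat_domain == "multiple" & pf$iucn_group == "Unknown"
  expect_true(any(base_rows))
  dum <- X[base_rows, c("domain_freshwater", "domain_marine",
                        "domain_terrestrial", "iucn_Threatened",
                        "iucn_NonThreatened")]
  expect_true(all(dum == 0))
  # round-trip with stored transform parameters
  des2 <- prepare_design(pf, variant = "eq1", transforms = des$transforms)
  expect_equal(des2$design, des$design)
})

test_that("prepare_design eq2 swaps uniqueness and drops phylogenetic distance", {
  pf <- make_profiles(n = 150, seed = 22)
  des <- prepare_design(pf, variant = "eq2")
  expect_true("log_genus_uniq" %in% names(des$design))
  expect_false("log_phylo_dist" %in% names(des$design))
  expect_false("log_family_uniq" %in% names(des$design))
})

test_that("prepare_design rejects bad inputs", {
  pf <- make_profiles(n = 100, seed = 23)
  pf2 <- pf; pf2$size_mm <- 1          # zero-variance after log
  expect_error(prepare_design(pf2), "zero-variance")
  pf3 <- pf; pf3$habitat_domain[1] <- "lunar"
  expect_error(prepare_design(pf3), "lunar")
  pf4 <- pf; pf4$size_mm[3] <- NA
  expect_error(prepare_design(pf4), "missing values")
})
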