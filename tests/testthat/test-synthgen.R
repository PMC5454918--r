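test_that("generators are bit-reproducible for a fixed seed", {
  m <- nucleus_model(n_clusters = 15L, nucleus_radius_nm = 3000, seed = 211)
  expect_identical(generate_nucleus(m), generate_nucleus(m))

  gm <- repeat_genome_model(c(chr1 = 30000L), n_copies = 5L,
                            substitution_rate = 0.1, seed = 212)
  g1 <- generate_genome(gm); g2 <- generate_genome(gm)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$bed, g2$bed)

  em <- emitter_model(cbind(1500, 1500), frames = 20L, seed = 213)
  expect_identical(generate_stack(em, c(32L, 32L), 100),
                   generate_stack(em, c(32L, 32L), 100))

  expect_identical(generate_dose_series(seed = 214),
                   generate_dose_series(seed = 214))
})

test_that("stacks follow the Bernoulli blinking and Poisson imaging model", {
  # blink probability 1, no background: a blob in every frame at the emitter
  m <- emitter_model(cbind(1600, 1600), blink_prob = 1, background_mean = 0,
                     frames = 30L, seed = 221)
  sim <- generate_stack(m, c(32L, 32L), 100)
  expect_equal(nrow(sim$truth), 30L)
  for (f in sim$frames) {
    expect_gt(sum(f), 0)
    peak <- which(f == max(f), arr.ind = TRUE)[1, ]
    expect_lt(max(abs(peak - c(16, 16))), 3)
  }

  # ON events per emitter concentrate around frames * blink_prob
  m2 <- emitter_model(cbind(c(800, 2400), c(800, 2400)), blink_prob = 0.1,
                      frames = 400L, seed = 222)
  sim2 <- generate_stack(m2, c(32L, 32L), 100)
  per <- table(factor(sim2$truth$emitter, levels = 1:2))
  expect_true(all(abs(per - 40) <= 3 * sqrt(400 * 0.1 * 0.9)))

  expect_error(generate_stack(emitter_model(cbind(1e6, 1e6), seed = 1),
                              c(32L, 32L), 100), "inside the field")
})

test_that("synthetic nuclei plant the configured cluster structure", {
  m <- nucleus_model(n_clusters = 20L, nucleus_radius_nm = 3000, seed = 231)
  nuc <- generate_nucleus(m)
  expect_equal(nrow(nuc$truth$centers), 20L)
  expect_equal(sort(unique(nuc$points$channel)), c("alu", "het"))
  alu_n <- sum(nuc$points$channel == "alu")
  expect_equal(length(nuc$truth$membership), alu_n)
  expect_true(all(nuc$truth$centers$n_points >= 10L))
  # clustered points sit near their planted parent
  mem <- nuc$truth$membership
  alu <- nuc$points[nuc$points$channel == "alu", ]
  sel <- which(mem > 0)
  d <- sqrt((alu$x_nm[sel] - nuc$truth$centers$x_nm[mem[sel]])^2 +
              (alu$y_nm[sel] - nuc$truth$centers$y_nm[mem[sel]])^2)
  expect_lt(mean(d), 4 * 41.2)  # cluster sigma + localization jitter

  # degenerate limit: one tight cluster, no noise
  tiny <- generate_nucleus(nucleus_model(
    n_clusters = 1L, nucleus_radius_nm = 2000, points_per_cluster_min = 10L,
    points_per_cluster_mean = 10, cluster_sigma_nm = 1e-6,
    alu_noise_fraction = 0, loc_precision_nm = 1e-6,
    het_background_per_nm2 = 0, seed = 232))
  a <- tiny$points[tiny$points$channel == "alu", ]
  expect_equal(nrow(a), 10L)
  expect_lt(max(dist(cbind(a$x_nm, a$y_nm))), 1e-3)
})

test_that("heterochromatin is suppressed in the core and elevated in the annulus", {
  # few, well-separated clusters so annuli of different clusters never
  # contaminate each other's shells
  m <- nucleus_model(n_clusters = 5L, nucleus_radius_nm = 5000,
                     het_background_per_nm2 = 8e-4, het_ratio = 3, seed = 241)
  nuc <- generate_nucleus(m)
  het <- nuc$points[nuc$points$channel == "het", ]
  prof <- mean_shell_profile(cbind(nuc$truth$centers$x_nm,
                                   nuc$truth$centers$y_nm),
                             het, shell_width_nm = 10, max_radius_nm = 600)
  core <- prof$shell_outer_nm <= 100
  band <- prof$shell_inner_nm >= 110 & prof$shell_outer_nm <= 290
  outside <- prof$shell_inner_nm >= 350
  expect_equal(sum(prof$count[core]), 0)   # exact exclusion inside the core
  band_mean <- mean(prof$density_per_nm2[band])
  out_mean <- mean(prof$density_per_nm2[outside])
  expect_equal(band_mean / out_mean, 3, tolerance = 0.15)
  expect_equal(out_mean, 8e-4, tolerance = 0.1)
})

test_that("planted repeat copies mutate independently per site", {
  # rate 0: every copy carries the probe exactly once
  g0 <- generate_genome(repeat_genome_model(c(chr1 = 120000L), n_copies = 30L,
                                            seed = 251))
  expect_equal(nrow(scan_kmer(g0$genome, alu_probe(), "forward")), 30L)

  # no copies: background only, empty truth
  ge <- generate_genome(repeat_genome_model(c(chr1 = 20000L), n_copies = 0L,
                                            seed = 252))
  expect_equal(nrow(ge$bed), 0L)
  expect_equal(Biostrings::width(ge$genome), 20000L)

  # rate 0.1: the probe survives in a copy with probability 0.9^17
  g1 <- generate_genome(repeat_genome_model(c(chr1 = 500000L), n_copies = 200L,
                                            substitution_rate = 0.1, seed = 253))
  n_hit <- nrow(scan_kmer(g1$genome, alu_probe(), "forward"))
  expected <- 200 * 0.9^17
  expect_lt(n_hit, 200L)
  expect_lt(abs(n_hit - expected), 3 * sqrt(200 * 0.9^17 * (1 - 0.9^17)) + 3)
})

test_that("dose series follow the quadratic count model", {
  d0 <- generate_dose_series(noise_sigma = 0, n_cells_per_dose = 7L, seed = 261)
  for (D in unique(d0$dose_gy)) {
    cnt <- d0$count[d0$dose_gy == D]
    expect_true(all(cnt == round(3054 * D^2 - 11480 * D + 21390)))
  }

  dn <- generate_dose_series(noise_sigma = 500, n_cells_per_dose = 35L,
                             seed = 262)
  for (D in unique(dn$dose_gy)) {
    mu <- 3054 * D^2 - 11480 * D + 21390
    expect_lt(abs(mean(dn$count[dn$dose_gy == D]) - mu), 3 * 500 / sqrt(35))
  }

  # a model dipping below zero is rejected
  expect_error(generate_dose_series(a = 0, b = -30000, c = 21390,
                                    doses = c(0, 1, 2), seed = 263),
               "positive")
})
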