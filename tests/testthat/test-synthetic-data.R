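test_that("genotype simulation is deterministic given the seed", {
  cfg <- sim_config(n_samples = 50, n_markers = 60, chrom_lengths = rep(1e6, 2),
                    seed = 21)
  gm1 <- simulate_genotypes(cfg)
  gm2 <- simulate_genotypes(cfg)
  expect_identical(gm1$dosages, gm2$dosages)
  expect_identical(gm1$map, gm2$map)
})

test_that("vanishing LD scale gives independence-level adjacent r2", {
  # with L -> 0 adjacent markers are independent; E[r2] ~ 1/n_samples
  vals <- vapply(1:50, function(s) {
    cfg <- sim_config(n_samples = 100, n_markers = 40, chrom_lengths = 2e6,
                      ld_scale_bp = 1, r2_adjacent = 0.9, n_qtl = 5,
                      seed = 1000 + s)
    mean_adjacent_r2(simulate_genotypes(cfg))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1 / 100), 0.01)
})

test_that("calibrated adjacent r2 hits its target", {
  # ~1 kb spacing, decay negligible at this scale; frequency-matched
  # markers so the allele-frequency r^2 bound does not bind
  cfg <- sim_config(n_samples = 1000, n_markers = 200, chrom_lengths = 2e5,
                    r2_adjacent = 0.5, ld_scale_bp = 1e5,
                    maf_range = c(0.3, 0.5), n_qtl = 20, seed = 8)
  gm <- simulate_genotypes(cfg)
  expect_lt(abs(mean_adjacent_r2(gm) - 0.5), 0.1)
})

test_that("LD decays monotonically with distance in binned means", {
  cfg <- sim_config(n_samples = 400, n_markers = 500, chrom_lengths = rep(3e6, 2),
                    seed = 4)
  gm <- simulate_genotypes(cfg)
  curve <- ld_decay(gm, max_dist = 6e4, bin_width = 1e4)
  r2 <- curve$mean_r2[curve$n_pairs > 50]
  expect_true(all(diff(r2) < 0.02))  # non-increasing up to binning noise
})

test_that("phenotype heritability is realised exactly in-sample", {
  cfg <- sim_config(n_samples = 300, n_markers = 200, chrom_lengths = rep(2e6, 2),
                    n_qtl = 20, h2_target = 0.6, seed = 31)
  gm <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(gm, cfg)
  y <- sim$phenotypes$trait
  g <- sim$truth$genetic_values
  expect_equal(var(g) / var(y), 0.6, tolerance = 1e-10)
  expect_equal(sim$truth$realized_h2, 0.6, tolerance = 1e-10)
  expect_true(all(sim$truth$qtl_ids %in% gm$map$id))

  # h2 = 1: phenotype equals the scaled genetic value
  cfg1 <- cfg; cfg1$h2_target <- 1
  sim1 <- simulate_phenotypes(gm, cfg1)
  expect_equal(sim1$phenotypes$trait, sim1$truth$genetic_values, tolerance = 1e-12)

  # h2 = 0: no genetic signal in y
  cfg0 <- cfg; cfg0$h2_target <- 0
  sim0 <- simulate_phenotypes(gm, cfg0)
  g_raw <- as.vector(gm$dosages[, match(sim0$truth$qtl_ids, gm$map$id)] %*%
                       sim0$truth$qtl_effects_raw)
  expect_lt(cor(sim0$phenotypes$trait, g_raw)^2, 0.05)
})

test_that("ordinal traits cut the liability into declared integer codes", {
  cfg <- sim_config(n_samples = 400, n_markers = 100, chrom_lengths = 1e6,
                    n_qtl = 10, h2_target = 0.5, trait_type = "ordinal",
                    ordinal_probs = c(0.1, 0.45, 0.35, 0.1), seed = 12)
  gm <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(gm, cfg)
  y <- sim$phenotypes$trait
  expect_true(all(y %in% 1:4))
  expect_equal(as.vector(table(y)) / 400, c(0.1, 0.45, 0.35, 0.1),
               tolerance = 0.01)
  # higher code = higher liability
  expect_true(all(tapply(sim$truth$liability, y, mean) ==
                    cummax(tapply(sim$truth$liability, y, mean))))
})

test_that("full-sib family mode creates within-family relatedness", {
  cfg <- sim_config(n_samples = 120, n_markers = 400, chrom_lengths = rep(2e6, 2),
                    n_families = 10, seed = 6)
  gm <- simulate_genotypes(cfg)
  fam <- attr(gm, "family")
  G <- build_grm(gm)$matrix
  same <- outer(fam, fam, "==") & upper.tri(G)
  diff_fam <- (!outer(fam, fam, "==")) & upper.tri(G)
  expect_gt(mean(G[same]), mean(G[diff_fam]) + 0.2)
})

test_that("fixture presets re-read cleanly and are seed-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture("mini", d1, seed = 5)
  f2 <- make_fixture("mini", d2, seed = 5)
  gm <- read_vcf(f1$vcf)
  ph <- read_phenotypes(f1$phenotypes)
  expect_equal(nrow(gm$dosages), 120)
  expect_true(all(ph$sample_id %in% rownames(gm$dosages)))
  expect_identical(readLines(f1$vcf), readLines(f2$vcf))
  expect_identical(readLines(f1$phenotypes), readLines(f2$phenotypes))
  # annotation has genes inside and outside +-20 kb of planted QTLs
  genes <- load_gff(f1$gff)
  truth <- jsonlite::read_json(f1$truth, simplifyVector = TRUE)
  qtl <- gm$map[gm$map$id %in% unlist(lapply(truth, `[[`, "qtl_ids")), ]
  dist_to_qtl <- vapply(seq_len(nrow(genes)), function(i) {
    q <- qtl[qtl$chrom == genes$chrom[i], ]
    if (nrow(q) == 0) return(Inf)
    min(pmax(q$pos - genes$end[i], genes$start[i] - q$pos, 0))
  }, numeric(1))
  expect_true(any(dist_to_qtl <= 20000))
  expect_true(any(dist_to_qtl > 20000))
})
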