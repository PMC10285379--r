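test_that("scenario 1 census and family structure follow the design", {
  pop <- small_pop()            # scale 0.1: 5 sires, 50 dams, 100/generation
  cfg <- pop$config
  expect_equal(cfg$n_founders, 55L)
  expect_equal(nrow(pop$ped), 55L + 5L * 100L)
  expect_equal(as.vector(table(pop$ped$generation)),
               c(55L, rep(100L, 5L)))
  # paternal half-sib families of dams_per_sire * 2, maternal full pairs
  for (g in 1:5) {
    gp <- pop$ped[pop$ped$generation == g, ]
    expect_true(all(table(gp$sire) == 20L))
    expect_true(all(table(gp$dam) == 2L))
  }
  # founders have unknown parents; offspring parents are recorded
  expect_true(all(is.na(pop$ped$sire[pop$ped$generation == 0])))
  expect_true(all(!is.na(pop$ped$sire[pop$ped$generation > 0])))
})

test_that("full-sib scenarios produce monogamous pairs", {
  cfg <- scenario_config(2, scale = 0.05, n_hist_generations = 10L)
  gen <- genome_spec(n_chromosomes = 2, markers_per_chromosome = 40)
  pop <- simulate_scenario(cfg, gen, seed = 5)
  for (g in 1:5) {
    gp <- pop$ped[pop$ped$generation == g, ]
    # every sire appears with exactly one dam and vice versa
    pairs <- unique(paste(gp$sire, gp$dam))
    expect_equal(length(pairs), length(unique(gp$sire)))
    expect_equal(length(pairs), length(unique(gp$dam)))
    expect_true(all(table(paste(gp$sire, gp$dam)) == 2L))
  }
})

test_that("every transmitted gamete is a legal recombinant of its parent", {
  pop <- small_pop()
  expect_equal(check_mendelian(pop), 0L)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- scenario_config(1, scale = 0.05, n_hist_generations = 15L)
  gen <- genome_spec(n_chromosomes = 2, markers_per_chromosome = 50)
  a <- simulate_scenario(cfg, gen, seed = 7)
  b <- simulate_scenario(cfg, gen, seed = 7)
  expect_identical(a$ped, b$ped)
  expect_identical(a$hap1, b$hap1)
  c <- simulate_scenario(cfg, gen, seed = 8)
  expect_false(identical(a$hap1, c$hap1))
})

test_that("heterozygosity decays like (1 - 1/(2Ne))^t under drift", {
  # small constant-size population, no expansion, closed-form neutral decay
  t_gen <- 20L
  ne <- 30L
  gen <- genome_spec(n_chromosomes = 3, markers_per_chromosome = 100)
  hets <- vapply(1:20, function(rep) {
    cfg <- scenario_config(2, scale = ne / 1000, n_hist_generations = t_gen)
    pop <- simulate_scenario(cfg, gen, seed = 1000 + rep)
    founders <- pop$ped$generation == 0L
    h1 <- pop$hap1[founders, ]; h2 <- pop$hap2[founders, ]
    p <- (colSums(h1) + colSums(h2)) / (2 * sum(founders))
    mean(2 * p * (1 - p))
  }, numeric(1))
  expected <- 0.5 * (1 - 1 / (2 * ne))^t_gen
  se <- stats::sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 3 * se + 0.002)
})

test_that("one generation of Mendelian sampling drifts frequencies as derived", {
  # monogamous pairs with exactly two offspring transmit two independent
  # gametes per parent, so conditional on the parents
  # Var(p1 - p0) = H/(8 N_par) with H the parental heterozygosity rate
  gen <- genome_spec(n_chromosomes = 3, markers_per_chromosome = 200)
  cfg <- scenario_config(2, scale = 0.025, n_hist_generations = 5L,
                         n_recent_generations = 1L)   # 50 founders, 25 pairs
  pop <- simulate_scenario(cfg, gen, seed = 321)
  f <- pop$ped$generation == 0L
  o <- pop$ped$generation == 1L
  p0 <- colMeans(pop$hap1[f, ] + pop$hap2[f, ]) / 2
  p1 <- colMeans(pop$hap1[o, ] + pop$hap2[o, ]) / 2
  H <- colMeans((pop$hap1[f, ] != pop$hap2[f, ]) * 1)
  expected <- mean(H) / (8 * sum(f))
  expect_equal(stats::var(p1 - p0), expected, tolerance = 0.25)
})

test_that("phenotype construction hits the target heritability", {
  pop <- small_pop()
  ratios <- vapply(1:10, function(r) {
    ph <- simulate_phenotypes(pop, h2 = 0.8, alpha_true = -0.5,
                              n_causal = 150, seed = r)
    stats::var(ph$g_true) / stats::var(ph$y)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.8), 0.03)
})

test_that("the generative scale factor shapes the effect-frequency relation", {
  pop <- small_pop()
  freqs <- colMeans(pop$hap1 + pop$hap2) / 2
  # alpha = -1: rare causal variants get the largest effects
  ph_neg <- simulate_phenotypes(pop, h2 = 0.8, alpha_true = -1,
                                n_causal = 200, seed = 61)
  cz <- attr(ph_neg, "causal")
  maf <- pmin(freqs[cz], 1 - freqs[cz])
  rho_neg <- stats::cor(maf, abs(attr(ph_neg, "gamma")), method = "spearman")
  expect_lt(rho_neg, 0)
  # alpha = 0: effect magnitude independent of frequency
  ph_zero <- simulate_phenotypes(pop, h2 = 0.8, alpha_true = 0,
                                 n_causal = 200, seed = 62)
  cz0 <- attr(ph_zero, "causal")
  maf0 <- pmin(freqs[cz0], 1 - freqs[cz0])
  rho_zero <- stats::cor(maf0, abs(attr(ph_zero, "gamma")),
                         method = "spearman")
  expect_lt(abs(rho_zero), 0.15)
})

test_that("exported datasets round-trip and are byte-identical under a seed", {
  cfg <- scenario_config(1, scale = 0.05, n_hist_generations = 10L)
  gen <- genome_spec(n_chromosomes = 2, markers_per_chromosome = 60)
  pop <- simulate_scenario(cfg, gen, seed = 71)
  phen <- simulate_phenotypes(pop, h2 = 0.5, alpha_true = 0, n_causal = 50,
                              seed = 72)
  d1 <- withr::local_tempdir()
  export_dataset(pop, phen, d1)
  # genotyped subset: the last two generations
  n_geno <- sum(pop$ped$generation %in% 4:5)
  gm_back <- read_plink_raw(file.path(d1, "genotypes.raw"))
  expect_equal(length(gm_back$ids), n_geno)
  expect_equal(gm_back$counts,
               sim_genotypes(pop, generations = 4:5)$counts)
  bed_back <- read_plink_bed(file.path(d1, "genotypes"))
  expect_equal(bed_back$counts, gm_back$counts)
  ped_back <- read_pedigree(file.path(d1, "pedigree.csv"))
  expect_setequal(ped_back$id, pop$ped$id)
  A1 <- build_nrm(ped_back)
  A2 <- build_nrm(sim_pedigree(pop))
  expect_equal(unclass(A1)[pop$ped$id, pop$ped$id],
               unclass(A2)[pop$ped$id, pop$ped$id])
  # determinism of the full export
  d2 <- withr::local_tempdir()
  pop2 <- simulate_scenario(cfg, gen, seed = 71)
  phen2 <- simulate_phenotypes(pop2, h2 = 0.5, alpha_true = 0,
                               n_causal = 50, seed = 72)
  export_dataset(pop2, phen2, d2)
  for (f in c("pedigree.csv", "phenotypes.tsv", "genotypes.raw"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_identical(readBin(file.path(d1, "genotypes.bed"), "raw", 1e6),
                   readBin(file.path(d2, "genotypes.bed"), "raw", 1e6))
})

test_that("impossible designs are rejected", {
  cfg <- scenario_config(2, scale = 0.05, n_hist_generations = 5L)
  cfg$ne <- 10L   # final generation far smaller than the 25 pairs needed
  gen <- genome_spec(n_chromosomes = 1, markers_per_chromosome = 10)
  expect_error(simulate_scenario(cfg, gen, seed = 1), "impossible design")
})
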