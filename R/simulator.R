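#' Genome specification for the forward simulator
#'
#' Defaults mirror the simulation design used throughout the package's
#' validation experiments: 30 chromosomes of 100 cM carrying 300
#' uniformly placed biallelic markers each (9,000 SNPs), all markers
#' starting at allele frequency 0.5, and a symmetric allele-flip mutation
#' rate of 2.8e-8 per locus per meiosis.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_cM genetic length of each chromosome.
#' @param markers_per_chromosome markers per chromosome (uniform random
#'   positions, drawn once per simulation).
#' @param initial_freq starting allele frequency of every marker.
#' @param mutation_rate per-locus per-meiosis allele flip probability.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 30L, chromosome_length_cM = 100,
                        markers_per_chromosome = 300L, initial_freq = 0.5,
                        mutation_rate = 2.8e-8) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 2,
            chromosome_length_cM > 0, initial_freq > 0, initial_freq < 1,
            mutation_rate >= 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_cM = chromosome_length_cM,
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 initial_freq = initial_freq,
                 mutation_rate = mutation_rate),
            class = "genome_spec")
}

#' Scenario configuration for the forward simulator
#'
#' Three stock scenarios differing in historical effective size and
#' recent mating design:
#'
#' * **Scenario 1** (livestock-like): historical population of Ne = 100
#'   (50 males, 50 females) for 95 generations, expanding linearly to
#'   1,000 by generation 100; 50 sires and 500 dams selected as founders;
#'   five recent generations bred with a half-sib design (each sire mated
#'   to 10 dams, 2 offspring per dam -> 1,000 offspring per generation).
#' * **Scenario 2** (human-like): constant Ne = 1,000 for 100 historical
#'   generations; all 1,000 final individuals are founders; five recent
#'   generations of monogamous full-sib matings (500 pairs x 2 offspring).
#' * **Scenario 3**: scenario 1's historical phase, scenario 2's mating
#'   design; 550 founders form 275 disjoint pairs producing 550 offspring
#'   per generation.
#'
#' All counts can be scaled down via `scale` (e.g. `scale = 0.2` gives a
#' scenario-1 design with 10 sires, 100 dams and 200 offspring per
#' generation) — family structure, generation counts and the
#' founder/expansion ratio are preserved.
#'
#' @param scenario 1, 2 or 3.
#' @param scale population scale multiplier in (0, 1] (default 1 = the
#'   full design). Scaling shrinks the recent-phase family counts (and,
#'   for scenario 2, the effective size that doubles as the founder
#'   pool); the historical effective size of scenarios 1 and 3 is a drift
#'   parameter and stays at its designed value.
#' @param n_hist_generations historical generations (default 100).
#' @param n_recent_generations recent (analysis) generations (default 5).
#' @param ne optional override of the historical effective size.
#' @return object of class `scenario_config` with fields used by
#'   [simulate_scenario]: `ne`, `mating` ("half_sib" or "full_sib"),
#'   `n_sires`, `n_dams`, `dams_per_sire`, `offspring_per_dam`,
#'   `expansion_to`, etc.
#' @export
scenario_config <- function(scenario = 1L, scale = 1,
                            n_hist_generations = 100L,
                            n_recent_generations = 5L, ne = NULL) {
  stopifnot(scenario %in% 1:3, scale > 0, scale <= 1)
  sc <- function(x) max(1L, as.integer(round(x * scale)))
  cfg <- switch(as.character(scenario),
    "1" = list(ne = 100L, mating = "half_sib",
               n_sires = sc(50), dams_per_sire = 10L,
               offspring_per_dam = 2L,
               expansion = TRUE),
    "2" = list(ne = sc(1000), mating = "full_sib",
               n_pairs = sc(500), offspring_per_pair = 2L,
               expansion = FALSE),
    "3" = list(ne = 100L, mating = "full_sib",
               n_pairs = sc(275), offspring_per_pair = 2L,
               expansion = TRUE))
  if (!is.null(ne)) cfg$ne <- as.integer(ne)
  cfg$scenario <- as.integer(scenario)
  cfg$scale <- scale
  cfg$n_hist_generations <- as.integer(n_hist_generations)
  cfg$n_recent_generations <- as.integer(n_recent_generations)
  if (cfg$mating == "half_sib") {
    cfg$n_dams <- cfg$n_sires * cfg$dams_per_sire
    cfg$n_founders <- cfg$n_sires + cfg$n_dams
    cfg$offspring_per_gen <- cfg$n_dams * cfg$offspring_per_dam
  } else {
    cfg$n_founders <- 2L * cfg$n_pairs
    cfg$offspring_per_gen <- cfg$n_pairs * cfg$offspring_per_pair
  }
  # expansion target preserves the full-scale founder fraction (550/1000)
  cfg$expansion_to <- if (cfg$expansion)
    max(cfg$ne, as.integer(ceiling(cfg$n_founders / 0.55))) else cfg$ne
  class(cfg) <- "scenario_config"
  cfg
}

# per-interval recombination fractions (Haldane) plus independent
# assortment across chromosomes; interval 1 of each chromosome gets 0.5
# (random choice of starting parental haplotype)
recomb_fractions <- function(map) {
  d <- c(0, diff(map$pos_cM)) / 100   # Morgans
  r <- 0.5 * (1 - exp(-2 * d))
  r[c(TRUE, diff(map$chr) != 0)] <- 0.5
  r
}

# Gametes from parents: H1/H2 are n_parents x L 0/1 matrices, `parent`
# indexes rows. Bernoulli(r) switch points accumulated mod 2 give the
# haplotype source at each locus (equivalent to Poisson/Haldane
# crossovers at marker resolution).
meiosis <- function(H1, H2, parent, r, mutation_rate) {
  N <- length(parent); L <- length(r)
  switches <- matrix(stats::rbinom(N * L, 1L, rep(r, each = N)), N, L)
  state <- t(apply(switches, 1L, cumsum)) %% 2L
  gam <- H1[parent, , drop = FALSE]
  alt <- H2[parent, , drop = FALSE]
  pick <- state == 1L
  gam[pick] <- alt[pick]
  if (mutation_rate > 0) {
    n_mut <- stats::rbinom(1L, N * L, mutation_rate)
    if (n_mut > 0L) {
      at <- sample.int(N * L, n_mut)
      gam[at] <- 1L - gam[at]
    }
  }
  gam
}

# balanced sex vector (exact half males, random placement)
balanced_sexes <- function(n) {
  s <- rep(c("M", "F"), length.out = n)
  sample(s)
}

#' Forward-in-time simulation of a structured population
#'
#' Simulates a neutral biallelic genome through a historical phase
#' (random mating at effective size `ne`, with the scenario-specific
#' expansion in the final five generations) followed by recent
#' generations bred under the configured half-sib or full-sib design.
#' Meiosis uses Haldane (no-interference) recombination, one expected
#' crossover per 100 cM, and symmetric allele-flip mutation. Selection is
#' random throughout.
#'
#' The returned analysis population consists of the founders (pedigree
#' base, parents unknown) and all recent-generation offspring, with both
#' haplotypes retained per individual.
#'
#' @param cfg a [scenario_config].
#' @param genome a [genome_spec].
#' @param seed integer random seed (the simulation is fully reproducible
#'   given `cfg`, `genome` and `seed`).
#' @return object of class `sim_population`: list with `ped` (data.frame
#'   id, sire, dam, sex, generation; generation 0 = founders), `hap1`,
#'   `hap2` (0/1 integer matrices, rows = ped rows; hap1 = paternal
#'   gamete), `map` (chr, pos_cM), `genome`, `config`, `seed`.
#' @export
simulate_scenario <- function(cfg, genome = genome_spec(), seed = 1L) {
  set.seed(as.integer(seed))
  L <- genome$n_chromosomes * genome$markers_per_chromosome
  map <- data.frame(
    chr = rep(seq_len(genome$n_chromosomes),
              each = genome$markers_per_chromosome),
    pos_cM = as.vector(apply(matrix(stats::runif(L, 0,
                 genome$chromosome_length_cM),
                 genome$markers_per_chromosome, genome$n_chromosomes),
                 2L, sort)))
  r <- recomb_fractions(map)
  mu <- genome$mutation_rate

  # --- historical phase ---------------------------------------------------
  n <- cfg$ne
  H1 <- matrix(stats::rbinom(n * L, 1L, genome$initial_freq), n, L)
  H2 <- matrix(stats::rbinom(n * L, 1L, genome$initial_freq), n, L)
  sex <- balanced_sexes(n)
  n_hist <- cfg$n_hist_generations
  sizes <- rep(cfg$ne, n_hist)
  if (cfg$expansion && cfg$expansion_to > cfg$ne) {
    ramp <- round(seq(cfg$ne, cfg$expansion_to, length.out = 6L))[-1L]
    sizes[(n_hist - 4L):n_hist] <- ramp
  }
  for (t in seq_len(n_hist)) {
    n_off <- sizes[t]
    males <- which(sex == "M"); females <- which(sex == "F")
    # independent random parent draws per offspring (multinomial family
    # sizes), so the realized effective size tracks the census size
    sire <- sample(males, n_off, replace = TRUE)
    dam <- sample(females, n_off, replace = TRUE)
    nH1 <- meiosis(H1, H2, sire, r, mu)
    nH2 <- meiosis(H1, H2, dam, r, mu)
    H1 <- nH1; H2 <- nH2
    sex <- balanced_sexes(n_off)
  }

  # --- founder selection --------------------------------------------------
  males <- which(sex == "M"); females <- which(sex == "F")
  if (cfg$mating == "half_sib") {
    need_m <- cfg$n_sires; need_f <- cfg$n_dams
  } else {
    need_m <- cfg$n_pairs; need_f <- cfg$n_pairs
  }
  if (length(males) < need_m || length(females) < need_f)
    stop("impossible design: not enough candidates of each sex ",
         "(have ", length(males), "M/", length(females), "F, need ",
         need_m, "M/", need_f, "F)")
  fm <- sample(males, need_m); ff <- sample(females, need_f)
  keep <- c(fm, ff)
  n_f <- length(keep)
  ped <- data.frame(id = as.character(seq_len(n_f)),
                    sire = NA_character_, dam = NA_character_,
                    sex = c(rep("M", need_m), rep("F", need_f)),
                    generation = 0L, stringsAsFactors = FALSE)
  hap1 <- list(H1[keep, , drop = FALSE])
  hap2 <- list(H2[keep, , drop = FALSE])
  # parent pool for generation 1: founders (rows 1..n_f of analysis pop)
  pool_rows <- seq_len(n_f)      # row indices into the analysis population
  pool_sex <- ped$sex
  pH1 <- hap1[[1L]]; pH2 <- hap2[[1L]]
  next_id <- n_f + 1L

  # --- recent phase -------------------------------------------------------
  all_ped <- list(ped)
  for (g in seq_len(cfg$n_recent_generations)) {
    males <- which(pool_sex == "M"); females <- which(pool_sex == "F")
    if (length(males) < need_m || length(females) < need_f)
      stop("impossible design in recent generation ", g,
           ": not enough parents of each sex")
    sires_loc <- sample(males, need_m)
    dams_loc <- sample(females, need_f)
    if (cfg$mating == "half_sib") {
      dam_of_sire <- rep(sires_loc, each = cfg$dams_per_sire)
      osire <- rep(dam_of_sire, each = cfg$offspring_per_dam)
      odam <- rep(dams_loc, each = cfg$offspring_per_dam)
    } else {
      osire <- rep(sires_loc, each = cfg$offspring_per_pair)
      odam <- rep(dams_loc, each = cfg$offspring_per_pair)
    }
    n_off <- length(osire)
    oH1 <- meiosis(pH1, pH2, osire, r, mu)
    oH2 <- meiosis(pH1, pH2, odam, r, mu)
    gped <- data.frame(
      id = as.character(seq.int(next_id, next_id + n_off - 1L)),
      sire = all_ped_id(all_ped, pool_rows[osire]),
      dam = all_ped_id(all_ped, pool_rows[odam]),
      sex = balanced_sexes(n_off), generation = g,
      stringsAsFactors = FALSE)
    next_id <- next_id + n_off
    all_ped <- c(all_ped, list(gped))
    hap1 <- c(hap1, list(oH1)); hap2 <- c(hap2, list(oH2))
    pool_rows <- seq.int(next_id - n_off, next_id - 1L)
    pool_sex <- gped$sex
    pH1 <- oH1; pH2 <- oH2
  }
  ped <- do.call(rbind, all_ped)
  rownames(ped) <- NULL
  pop <- list(ped = ped,
              hap1 = do.call(rbind, hap1), hap2 = do.call(rbind, hap2),
              map = map, genome = genome, config = cfg,
              seed = as.integer(seed))
  rownames(pop$hap1) <- ped$id; rownames(pop$hap2) <- ped$id
  class(pop) <- "sim_population"
  pop
}

# id lookup by analysis-population row index
all_ped_id <- function(ped_list, rows) {
  ids <- unlist(lapply(ped_list, `[[`, "id"), use.names = FALSE)
  ids[rows]
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population: scenario", x$config$scenario,
      "| n =", nrow(x$ped), "individuals (",
      sum(x$ped$generation == 0L), "founders +",
      x$config$n_recent_generations, "generations ) |",
      ncol(x$hap1), "markers\n")
  invisible(x)
}

#' Extract genotypes from a simulated population
#'
#' @param pop a [simulate_scenario] result.
#' @param generations which generations to keep (default: all). Founders
#'   are generation 0.
#' @param ids alternatively, explicit individual ids.
#' @return a [genotype_matrix] (counts = hap1 + hap2).
#' @export
sim_genotypes <- function(pop, generations = NULL, ids = NULL) {
  if (is.null(ids)) {
    keep <- if (is.null(generations)) rep(TRUE, nrow(pop$ped))
            else pop$ped$generation %in% generations
    ids <- pop$ped$id[keep]
  }
  rows <- match(ids, pop$ped$id)
  if (anyNA(rows)) stop("unknown individual ids requested")
  counts <- pop$hap1[rows, , drop = FALSE] + pop$hap2[rows, , drop = FALSE]
  genotype_matrix(counts, ids = ids,
                  snp_ids = paste0("M", seq_len(ncol(counts))))
}

#' Pedigree of a simulated population
#'
#' Founders appear with unknown parents (the historical phase is the
#' unobserved base population, as in field recording schemes where
#' pedigree depth is limited).
#'
#' @param pop a [simulate_scenario] result.
#' @return a [pedigree] object.
#' @export
sim_pedigree <- function(pop) {
  pedigree(pop$ped$id,
           ifelse(is.na(pop$ped$sire), "0", pop$ped$sire),
           ifelse(is.na(pop$ped$dam), "0", pop$ped$dam),
           generation = pop$ped$generation)
}

#' Simulate phenotypes from causal markers
#'
#' Draws `n_causal` causal loci among the polymorphic markers, raw
#' effects `u ~ N(0, 1)`, and scales each per-locus effect by
#' `[2 p (1 - p)]^alpha_true` — the generative counterpart of the GRM
#' scale factor. The aggregate genetic value is standardized to variance
#' `h2` (and mean 0) and residuals are drawn as `N(0, 1 - h2)`, so the
#' expected phenotypic variance is 1 and the expected heritability is
#' exactly `h2`.
#'
#' @param pop a [simulate_scenario] result.
#' @param h2 target heritability in (0, 1).
#' @param alpha_true generative scale factor linking allele frequency and
#'   per-allele effect size (-0.5 equalizes per-locus variance; 0 makes
#'   effects frequency independent).
#' @param n_causal number of causal markers (default 1,000, capped at the
#'   number of polymorphic markers).
#' @param seed integer seed for effect and residual sampling.
#' @return data.frame with columns `id`, `y`, `g_true`; attributes
#'   `causal` (marker indices), `gamma` (scaled effects), `h2`,
#'   `alpha_true`.
#' @export
simulate_phenotypes <- function(pop, h2 = 0.8, alpha_true = -0.5,
                                n_causal = 1000L, seed = 1L) {
  stopifnot(h2 > 0, h2 < 1)
  set.seed(as.integer(seed))
  counts <- pop$hap1 + pop$hap2
  n <- nrow(counts); L <- ncol(counts)
  p <- colMeans(counts) / 2
  poly <- which(p > 0 & p < 1)
  if (length(poly) < n_causal) {
    message("only ", length(poly), " polymorphic markers; using all as causal")
    n_causal <- length(poly)
  }
  causal <- sort(sample(poly, n_causal))
  u <- stats::rnorm(n_causal)
  gamma <- u * (2 * p[causal] * (1 - p[causal]))^alpha_true
  g <- drop(counts[, causal, drop = FALSE] %*% gamma)
  g <- (g - mean(g)) / stats::sd(g) * sqrt(h2)
  e <- stats::rnorm(n, 0, sqrt(1 - h2))
  out <- data.frame(id = pop$ped$id, y = g + e, g_true = g,
                    stringsAsFactors = FALSE)
  attr(out, "causal") <- causal
  attr(out, "gamma") <- gamma
  attr(out, "h2") <- h2
  attr(out, "alpha_true") <- alpha_true
  out
}

#' Export a simulated dataset to disk
#'
#' Writes the standard analysis files: `pedigree.csv` (id, sire, dam,
#' generation; unknown = 0), `phenotypes.tsv` (id, y), PLINK `.raw` and
#' `.bed/.bim/.fam` genotypes for the genotyped subset, and a
#' `manifest.json` recording the configuration and seeds.
#'
#' @param pop a [simulate_scenario] result.
#' @param phen a [simulate_phenotypes] result.
#' @param dir output directory (created if needed).
#' @param genotyped_generations generations treated as genotyped; default
#'   the last two, matching a scheme where only recent animals are on the
#'   SNP chip.
#' @return invisibly, the manifest list.
#' @export
export_dataset <- function(pop, phen, dir,
                           genotyped_generations = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ngen <- pop$config$n_recent_generations
  if (is.null(genotyped_generations))
    genotyped_generations <- c(ngen - 1L, ngen)
  ped_out <- data.frame(id = pop$ped$id,
                        sire = ifelse(is.na(pop$ped$sire), "0", pop$ped$sire),
                        dam = ifelse(is.na(pop$ped$dam), "0", pop$ped$dam),
                        generation = pop$ped$generation)
  utils::write.table(ped_out, file.path(dir, "pedigree.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(phen[, c("id", "y")], file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- sim_genotypes(pop, generations = genotyped_generations)
  write_plink_raw(gm, file.path(dir, "genotypes.raw"))
  write_plink_bed(gm, file.path(dir, "genotypes"),
                  map = data.frame(chr = pop$map$chr,
                                   pos = round(pop$map$pos_cM * 1e4)))
  manifest <- list(
    scenario = pop$config$scenario, scale = pop$config$scale,
    seed = pop$seed, n_individuals = nrow(pop$ped),
    n_genotyped = length(gm$ids), n_markers = ncol(pop$hap1),
    genotyped_generations = genotyped_generations,
    h2 = attr(phen, "h2"), alpha_true = attr(phen, "alpha_true"),
    files = c("pedigree.csv", "phenotypes.tsv", "genotypes.raw",
              "genotypes.bed", "genotypes.bim", "genotypes.fam"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Check Mendelian consistency of a simulated population
#'
#' Verifies locus-wise that each transmitted gamete of every
#' recent-generation individual matches one of the corresponding parent's
#' two alleles (i.e. is a legal recombinant). Mutations create a small
#' number of legitimate mismatches; the return value counts them.
#'
#' @param pop a [simulate_scenario] result.
#' @return number of mismatching (individual, locus, gamete) entries.
#' @export
check_mendelian <- function(pop) {
  rows <- which(pop$ped$generation > 0L)
  bad <- 0L
  for (i in rows) {
    s <- match(pop$ped$sire[i], pop$ped$id)
    d <- match(pop$ped$dam[i], pop$ped$id)
    bad <- bad +
      sum(pop$hap1[i, ] != pop$hap1[s, ] & pop$hap1[i, ] != pop$hap2[s, ]) +
      sum(pop$hap2[i, ] != pop$hap1[d, ] & pop$hap2[i, ] != pop$hap2[d, ])
  }
  bad
}
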