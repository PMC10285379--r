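# Shared fixtures built in code.

# random multi-generation pedigree: founders plus `n_gen` layers where each
# new individual draws parents from earlier layers (sexes tracked so sire
# and dam are distinct individuals)
random_pedigree <- function(n_founders = 6L, n_gen = 3L, per_gen = 8L,
                            seed = 1L) {
  set.seed(seed)
  id <- as.character(seq_len(n_founders))
  sire <- rep("0", n_founders)
  dam <- rep("0", n_founders)
  sex <- sample(rep(c("M", "F"), length.out = n_founders))
  nxt <- n_founders + 1L
  for (g in seq_len(n_gen)) {
    males <- id[sex == "M"]; females <- id[sex == "F"]
    for (k in seq_len(per_gen)) {
      id <- c(id, as.character(nxt))
      sire <- c(sire, sample(males, 1L))
      dam <- c(dam, sample(females, 1L))
      sex <- c(sex, sample(c("M", "F"), 1L))
      nxt <- nxt + 1L
    }
  }
  list(ped = pedigree(id, sire, dam), sex = sex)
}

# random genotype matrix, guaranteed polymorphic in-sample
random_genotypes <- function(n, L, seed = 1L, maf_min = 0.1) {
  set.seed(seed)
  p <- stats::runif(L, maf_min, 1 - maf_min)
  counts <- vapply(p, function(pk) stats::rbinom(n, 2L, pk), numeric(n))
  mono <- colSums(counts) %in% c(0, 2 * n)
  counts[1L, mono] <- 1
  genotype_matrix(counts, ids = as.character(seq_len(n)))
}

# small simulated scenario-1 population shared across tests (cheap genome)
small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(1, scale = 0.1)    # 5 sires, 100 offspring/gen
      gen <- genome_spec(n_chromosomes = 5, markers_per_chromosome = 120)
      cache <<- simulate_scenario(cfg, gen, seed = 99)
    }
    cache
  }
})
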