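# Shared fixture builders; everything is generated in code.

# One-SNP cluster model with the symmetric textbook geometry:
# AA at (10, 1), BB at (1, 10), AB at (7, 7), axis-aligned covariances.
symmetric_cluster <- function(snp_id = "snp1") {
  data.frame(snp_id = snp_id,
             aa_x = 10, aa_y = 1,
             aa_cxx = 1, aa_cxy = 0, aa_cyy = 0.2,
             ab_x = 7, ab_y = 7,
             ab_cxx = 1, ab_cxy = 0.5, ab_cyy = 1,
             bb_x = 1, bb_y = 10,
             bb_cxx = 0.2, bb_cxy = 0, bb_cyy = 1,
             stringsAsFactors = FALSE)
}

# A small clean synthetic study (noiseless unless asked otherwise).
tiny_study <- function(n_snps = 200, seed = 7, ...) {
  simulate_pool_study(sim_config(
    n_snps = n_snps, n_individuals = 100, n_pools = 2, n_replicates = 3,
    pool_noise_sd = 0, radial_noise_sd = 0, seed = seed, ...))
}

# Genotype panel with LD blocks: SNPs in a block copy a shared pair of
# latent alleles with probability 1 - flip_prob per chromosome copy.
block_ld_genotypes <- function(n_ind, n_blocks, block_size, p = 0.5,
                               flip_prob = 0.05, seed = 1) {
  set.seed(seed)
  n_snps <- n_blocks * block_size
  g <- matrix(0L, n_ind, n_snps)
  for (b in seq_len(n_blocks)) {
    h1 <- rbinom(n_ind, 1, p)
    h2 <- rbinom(n_ind, 1, p)
    for (j in seq_len(block_size)) {
      f1 <- rbinom(n_ind, 1, flip_prob)
      f2 <- rbinom(n_ind, 1, flip_prob)
      g[, (b - 1) * block_size + j] <-
        as.integer(abs(h1 - f1) + abs(h2 - f2))
    }
  }
  g
}
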