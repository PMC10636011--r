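#' Simulate block-LD genotype dosages with variant metadata
#'
#' Draws hard-call allele dosages in {0, 1, 2} for `n_individuals` persons
#' at `n_variants` variants. Linkage disequilibrium is block structured
#' and heterogeneous, as in real genomes: each block of `ld_block_size`
#' variants receives its own latent pairwise correlation drawn uniformly
#' from `[0, 2 * within_block_r]` (capped at 0.95, mean `within_block_r`),
#' shared by the two latent haplotype draws of each person; the latent
#' normals are thresholded at the per-variant allele-frequency quantile so
#' each variant is in Hardy-Weinberg proportions at its drawn MAF. The
#' across-block spread of LD is what gives LD scores enough variation for
#' LD score regression to be well identified on the simulated panel.
#' Imputation INFO scores are drawn in `info_range` so downstream QC
#' filters are exercisable.
#'
#' @param config A [sim_config()].
#' @return A list of class `"fallmr_genotypes"` with elements
#'   * `dosages`: integer matrix, persons x variants, values in {0, 1, 2};
#'   * `variants`: tibble with `variant_id`, `chrom`, `pos`,
#'     `effect_allele`, `other_allele`, `eaf`, `maf`, `info`, `block`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 100, n_variants = 12,
#'                                    ld_block_size = 4, seed = 7))
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_variants
  r <- config$within_block_r
  bs <- max(1L, config$ld_block_size)

  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(maf)
  block <- as.integer((seq_len(m) - 1L) %/% bs + 1L)
  n_blocks <- max(block)
  r_block <- if (r > 0 && bs > 1) {
    pmin(runif(n_blocks, 0, 2 * r), 0.95)
  } else {
    rep(0, n_blocks)
  }
  r_j <- r_block[block]

  # two latent haplotype matrices sharing a per-block common factor
  draw_latent <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (any(r_j > 0)) {
      common <- matrix(rnorm(n * n_blocks), n, n_blocks)
      sweep(common[, block, drop = FALSE], 2, sqrt(r_j), `*`) +
        sweep(z, 2, sqrt(1 - r_j), `*`)
    } else {
      z
    }
  }
  h1 <- draw_latent() < rep(thr, each = n)
  h2 <- draw_latent() < rep(thr, each = n)
  dosages <- matrix(as.integer(h1) + as.integer(h2), n, m)

  # allele pairs; a minority are palindromic (A/T, C/G) so harmonisation
  # ambiguity handling can be exercised
  pairs <- rbind(
    c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
    c("G", "A"), c("C", "A"), c("A", "T"), c("C", "G")
  )
  pick <- sample(nrow(pairs), m, replace = TRUE,
                 prob = c(rep(0.15, 6), 0.05, 0.05))
  variants <- tibble(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chrom = 1L,
    pos = seq_len(m) * 1000L,
    effect_allele = pairs[pick, 1],
    other_allele = pairs[pick, 2],
    eaf = maf,
    maf = maf,
    info = runif(m, config$info_range[1], config$info_range[2]),
    block = block,
    block_r = r_j
  )
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants, config = config),
            class = "fallmr_genotypes")
}
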