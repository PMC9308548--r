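# Shared fixture builders.  Everything is generated in code; nothing is
# stored on disk.

# A small but complete simulation design that runs in well under a second.
small_design <- function(seed = 1L, ...) {
  # sized so that the universe exceeds the largest possible gene-set
  # (200) and carries enough differential genes (~230 of 600, well below
  # the 70% enriched-set composition) to build enriched sets
  args <- list(n_probes = 3000L, n_genes = 600L, n_case = 10L,
               n_control = 8L, frac_diff = 0.1, module_size = 8L,
               n_gene_sets = 20L, enriched_sets = 2L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_design, args)
}

# Hand-written probe annotation rows.
annot_row <- function(probe_id, chrom = "1", snp_distance = 10,
                      maf = 0.2, cross_hyb = 0L, design_type = "II",
                      gene = "GENE1", pos = 100L) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             snp_distance = snp_distance, maf = maf,
             cross_hyb = cross_hyb, design_type = design_type,
             gene = gene, stringsAsFactors = FALSE)
}

# Subnetwork ego-recovery experiment: a scale-free 300-gene target
# subnetwork with a 15-gene planted module whose genes are differential
# (low gene-level p) and co-methylated through a shared latent factor;
# background genes are null.  Returns the module genes and the ego table.
subnet_experiment <- function(seed, n_genes = 300L, module_size = 15L,
                              n_case = 15L, n_control = 15L) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  design <- simulation_design(n_probes = n_genes, n_genes = n_genes,
                              n_case = n_case, n_control = n_control,
                              module_size = module_size,
                              n_seed_genes = 0L, attach_m = 2L,
                              seed = seed)
  truth <- list(diff_genes = genes)
  net <- simulate_network(design, genes, truth)
  module <- net$truth$module_genes

  set.seed(seed + 7000L)
  m <- n_case + n_control
  grp <- c(rep("tumor", n_case), rep("normal", n_control))
  latent <- rnorm(m, 0, 1)
  gene_beta <- matrix(0, n_genes, m,
                      dimnames = list(genes,
                                      sprintf("S%02d", seq_len(m))))
  for (i in seq_len(n_genes)) {
    if (genes[i] %in% module) {
      mu <- ifelse(grp == "tumor", 0.7, 0.4)
      gene_beta[i, ] <- pmin(pmax(mu + 0.08 * latent +
                                    rnorm(m, 0, 0.03), 0.01), 0.99)
    } else {
      gene_beta[i, ] <- pmin(pmax(0.5 + rnorm(m, 0, 0.08), 0.01), 0.99)
    }
  }
  groups <- data.frame(sample_id = colnames(gene_beta), group = grp,
                       stringsAsFactors = FALSE)
  calls <- test_differential(gene_beta, groups)
  node <- data.frame(gene = calls$probe_id, gene_p = calls$p_value,
                     p_i = pmax(-log10(calls$p_value), 1),
                     stringsAsFactors = FALSE)

  subnet <- build_target_subnetwork(net$edges, genes)
  subnet <- gate_by_correlation(subnet, gene_beta)
  subnet <- weight_edges(subnet, node)
  A <- clr_adjacency(methego:::weight_matrix(subnet))
  scores <- rank_ego_genes(A)
  list(module = module, scores = scores, subnet = subnet, A = A,
       gene_beta = gene_beta, node = node)
}
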