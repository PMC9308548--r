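test_that("the generator is deterministic and honors its ground truth", {
  d <- small_design(seed = 11)
  s1 <- simulate_beta_matrix(d)
  s2 <- simulate_beta_matrix(d)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$annot, s2$annot)

  expect_true(all(s1$beta >= 0 & s1$beta <= 1))
  # every probe maps to exactly one gene
  expect_equal(nrow(s1$annot), length(unique(s1$annot$probe_id)))
  expect_false(anyNA(s1$annot$gene))
  # planted counts
  expect_equal(length(s1$truth$diff_probes),
               round(d$frac_diff * d$n_probes))
  expect_equal(length(s1$truth$qc_probes),
               round(d$frac_qc_fail * d$n_probes))
  expect_length(intersect(s1$truth$diff_probes, s1$truth$qc_probes), 0)
})

test_that("frac_diff = 0 yields no planted differential signal", {
  d <- small_design(seed = 12, frac_diff = 0)
  s <- simulate_beta_matrix(d)
  expect_length(s$truth$diff_probes, 0)
  grp <- s$groups$group
  gap <- abs(rowMeans(s$beta[, grp == "tumor"]) -
               rowMeans(s$beta[, grp == "normal"]))
  expect_lt(mean(gap), 0.1)   # sampling noise only
})

test_that("planted effect size is realized at the designed delta", {
  d <- simulation_design(n_probes = 5000, n_genes = 500, n_case = 15,
                         n_control = 15, delta_beta = 0.3, seed = 1)
  s <- simulate_beta_matrix(d)
  grp <- s$groups$group
  dm <- rowMeans(s$beta[, grp == "tumor"]) -
    rowMeans(s$beta[, grp == "normal"])
  dir <- ifelse(s$truth$diff_direction == "hyper", 1, -1)
  realized <- mean(dm[s$truth$diff_probes] * dir)
  # type-II attenuation shrinks the realized shift by the design factor
  # for that probe class; account for the class mix exactly
  ii <- s$annot$design_type[match(s$truth$diff_probes,
                                  s$annot$probe_id)] == "II"
  target <- d$delta_beta * (mean(!ii) + d$typeII_attenuation * mean(ii))
  expect_lt(abs(realized - target), 0.03)
})

test_that("non-differential probes match their beta-distribution targets", {
  d <- simulation_design(n_probes = 6000, n_genes = 600, n_case = 10,
                         n_control = 10, frac_diff = 0, frac_qc_fail = 0,
                         frac_typeII = 0.5, typeII_attenuation = 1,
                         seed = 13)
  s <- simulate_beta_matrix(d)
  # with attenuation 1 both classes are undistorted draws; pool values by
  # rounding each probe's empirical mean to the nearest state
  pm <- rowMeans(s$beta)
  states <- methego:::BETA_STATE_MEANS
  assigned <- states[apply(abs(outer(pm, states, "-")), 1L, which.min)]
  for (m in states) {
    vals <- s$beta[assigned == m, ]
    expect_lt(abs(mean(vals) - m), 0.02)
    expect_lt(abs(var(as.vector(vals)) - m * (1 - m) / (d$dispersion + 1)),
              0.01)
  }
})

test_that("network backbone, planted module and determinism contracts", {
  # Barabasi-Albert with m = 1 over 10 genes and no module: a tree
  d <- simulation_design(n_probes = 10, n_genes = 10, attach_m = 1,
                         module_size = 0, n_seed_genes = 0, seed = 14)
  genes <- sprintf("G%02d", 1:10)
  net <- simulate_network(d, genes, list(diff_genes = genes))
  expect_equal(nrow(net$edges), 9L)

  # planted module of 6 at density 0.6 -> >= ceil(0.6 * 15) = 9 edges
  d2 <- simulation_design(n_probes = 40, n_genes = 40, attach_m = 1,
                          module_size = 6, n_seed_genes = 0, seed = 15)
  genes2 <- sprintf("G%02d", 1:40)
  net2 <- simulate_network(d2, genes2, list(diff_genes = genes2))
  mod <- net2$truth$module_genes
  expect_length(mod, 6L)
  internal <- net2$edges$gene_a %in% mod & net2$edges$gene_b %in% mod
  expect_gte(sum(internal), 9L)
  expect_true(all(net2$edges$confidence >= 400 &
                    net2$edges$confidence <= 1000))

  net2b <- simulate_network(d2, genes2, list(diff_genes = genes2))
  expect_identical(net2$edges, net2b$edges)
})

test_that("gene sets honor the enrichment composition rule", {
  d <- small_design(seed = 16)
  sim <- simulate_beta_matrix(d)
  gs <- simulate_gene_sets(d, sort(unique(sim$annot$gene)), sim$truth)
  expect_length(gs$truth$enriched_sets, d$enriched_sets)
  for (nm in names(gs$sets)) {
    members <- gs$sets[[nm]]
    frac_diff <- mean(members %in% sim$truth$diff_genes)
    if (nm %in% gs$truth$enriched_sets) {
      expect_gte(frac_diff, 0.7 - 1e-9)
    }
    expect_gte(length(members), 15L)
    expect_lte(length(members), 200L)
  }

  # enriched_sets = 0 -> all null draws
  d0 <- small_design(seed = 16, enriched_sets = 0)
  gs0 <- simulate_gene_sets(d0, sort(unique(sim$annot$gene)), sim$truth)
  expect_length(gs0$truth$enriched_sets, 0)
})

test_that("planted QC failures are exactly the probes the filter removes", {
  sim <- simulate_beta_matrix(small_design(seed = 17))
  rep <- filter_probes(sim$annot)
  expect_setequal(rep$removed_ids, sim$truth$qc_probes)
  # truth-differential probes all survive filtering
  expect_true(all(sim$truth$diff_probes %in% rep$kept))
})
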