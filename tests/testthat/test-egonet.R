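test_that("gene-level aggregation and node scores follow the stated rules", {
  beta <- matrix(c(0.2, 0.4, 0.6), 3, 1,
                 dimnames = list(c("cg1", "cg2", "cg3"), "S1"))
  ann <- rbind(annot_row("cg1", gene = "GA"), annot_row("cg2", gene = "GA"),
               annot_row("cg3", gene = "GB"))
  calls <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                      p_value = c(0.01, 0.001, 0.5),
                      stringsAsFactors = FALSE)
  gl <- gene_level_signal(beta, ann, calls)
  expect_equal(gl$gene_beta["GA", "S1"], 0.3)        # unweighted mean
  expect_equal(gl$node$gene_p[gl$node$gene == "GA"], 0.001)  # min rule
  expect_equal(gl$node$p_i[gl$node$gene == "GA"], 3)         # -log10
  expect_equal(gl$node$p_i[gl$node$gene == "GB"], 1)         # floor
})

test_that("target subnetwork keeps only both-endpoint edges", {
  edges <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                      confidence = c(900, 900), stringsAsFactors = FALSE)
  sn <- build_target_subnetwork(edges, c("A", "B"))
  expect_equal(nrow(sn$edges), 1L)
  expect_setequal(sn$nodes, c("A", "B"))
  # a seed gene with no edge into the target set is absent from V
  sn2 <- build_target_subnetwork(edges, c("A", "B"), seed_genes = "Z")
  expect_false("Z" %in% sn2$nodes)
})

test_that("the correlation gate threshold inverts the t quantile", {
  # brute-force search over |r| for the p = 0.05 boundary at m = 38
  m <- 38
  target <- 0.05
  rs <- seq(0.001, 0.999, by = 1e-6)
  tv <- rs * sqrt((m - 2) / (1 - rs^2))
  pv <- 2 * pt(-tv, m - 2)
  brute <- rs[which.min(abs(pv - target))]
  expect_lt(abs(correlation_gate_threshold(m, target) - brute), 1e-5)

  # gating behavior: r = 1 retained, r = 0 gated
  gb <- matrix(c(1, 2, 3, 4,
                 2, 4, 6, 8,
                 4, 3, 5, 1) / 10, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), sprintf("S%d", 1:4)))
  edges <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                      confidence = 900, stringsAsFactors = FALSE)
  sn <- gate_by_correlation(build_target_subnetwork(edges, c("A", "B", "C")),
                            gb)
  expect_false(sn$edges$gated[1L])   # perfectly correlated
  expect_true(abs(sn$edges$r[1L] - 1) < 1e-12)
  # zero-variance gene gates its edges
  gb0 <- gb; gb0["C", ] <- 0.5
  sn0 <- gate_by_correlation(build_target_subnetwork(edges,
                                                     c("A", "B", "C")),
                             gb0)
  expect_true(sn0$edges$gated[2L])
})

test_that("edge weights realize the significance formula in [0,1]", {
  sn <- list(nodes = c("A", "B", "C"),
             edges = data.frame(gene_a = c("A", "B", "A"),
                                gene_b = c("B", "C", "C"),
                                confidence = 900,
                                gated = c(FALSE, FALSE, TRUE),
                                stringsAsFactors = FALSE))
  class(sn) <- "target_subnetwork"
  # log p_i = 2, 4, 4 -> max log = 4
  node <- data.frame(gene = c("A", "B", "C"),
                     p_i = exp(c(2, 4, 4)), stringsAsFactors = FALSE)
  sn <- weight_edges(sn, node)
  expect_equal(sn$edges$weight[1L], 6 / 8)        # (2+4)/(2*4)
  expect_equal(sn$edges$weight[2L], 1)            # both at the maximum
  expect_equal(sn$edges$weight[3L], 0)            # gated
  expect_true(all(sn$edges$weight >= 0 & sn$edges$weight <= 1))

  # all scores at the floor: weights undefined -> 0 with warning
  floor_node <- data.frame(gene = c("A", "B", "C"), p_i = 1)
  expect_warning(snf <- weight_edges(sn, floor_node), "floor")
  expect_true(all(snf$edges$weight == 0))
})

test_that("topology metrics match exhaustive oracles", {
  # triangle: degree 2, closeness 1, betweenness 0, transitivity 1
  tri <- build_target_subnetwork(
    data.frame(gene_a = c("A", "B", "A"), gene_b = c("B", "C", "C"),
               confidence = 900), c("A", "B", "C"))
  tm <- topology_metrics(tri)
  expect_equal(tm$degree, rep(2L, 3))
  expect_equal(tm$closeness, rep(1, 3))
  expect_equal(tm$betweenness, rep(0, 3))
  expect_equal(tm$transitivity, rep(1, 3))

  # path A-B-C: betweenness(B) = 1, betweenness(A) = 0
  path <- build_target_subnetwork(
    data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
               confidence = 900), c("A", "B", "C"))
  tmp <- topology_metrics(path)
  expect_equal(tmp$betweenness[tmp$gene == "B"], 1)
  expect_equal(tmp$betweenness[tmp$gene == "A"], 0)

  # random graphs with <= 8 nodes vs brute-force path enumeration
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n)
    nodes <- sprintf("N%d", seq_len(n))
    idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L) next   # edgeless draw: nothing to compare
    edges <- data.frame(gene_a = nodes[idx[, 1]],
                        gene_b = nodes[idx[, 2]],
                        confidence = rep(900, nrow(idx)),
                        stringsAsFactors = FALSE)
    sn <- build_target_subnetwork(edges, nodes)
    sn$nodes <- nodes   # keep isolated nodes for the oracle comparison
    tm <- topology_metrics(sn)
    ord <- match(nodes, tm$gene)
    expect_equal(tm$degree[ord], rowSums(adj))
    expect_equal(tm$closeness[ord], unname(oracle_closeness(adj)),
                 tolerance = 1e-12)
    expect_equal(tm$betweenness[ord], oracle_betweenness(adj),
                 tolerance = 1e-12)
    expect_equal(tm$transitivity[ord], oracle_transitivity_local(adj),
                 tolerance = 1e-12)
  }
})

test_that("CLR adjacency matches hand arithmetic and its invariances", {
  W <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.4,
                0.8, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  A <- clr_adjacency(W)
  # hand-computed: row A mu=0.5 sd=sqrt(0.18); z_A(AB)=0 (negative)
  z <- function(w, mu, sd) max(0, (w - mu) / sd)
  sdv <- function(v) sd(v)
  zA_B <- z(0.2, 0.5, sdv(c(0.2, 0.8)))
  zB_A <- z(0.2, 0.3, sdv(c(0.2, 0.4)))
  expect_equal(A["A", "B"], sqrt(zA_B^2 + zB_A^2), tolerance = 1e-12)
  zA_C <- z(0.8, 0.5, sdv(c(0.2, 0.8)))
  zC_A <- z(0.8, 0.6, sdv(c(0.8, 0.4)))
  expect_equal(A["A", "C"], sqrt(zA_C^2 + zC_A^2), tolerance = 1e-12)
  expect_true(isSymmetric(A))
  expect_true(all(A >= 0))
  expect_equal(diag(A), c(A = 0, B = 0, C = 0))

  # constant W -> zero matrix
  Wc <- matrix(0.3, 3, 3); diag(Wc) <- 0
  expect_true(all(clr_adjacency(Wc) == 0))

  # location invariance: adding a constant off-diagonal changes nothing
  W2 <- W + 0.1; diag(W2) <- 0
  expect_equal(clr_adjacency(W2), A, tolerance = 1e-12)
  expect_error(clr_adjacency(W[1:2, 1:2]), "3 nodes")
})

test_that("ego ranking selects ceil(30%) and is permutation equivariant", {
  set.seed(52)
  n <- 10
  W <- matrix(runif(n * n), n); W <- (W + t(W)) / 2; diag(W) <- 0
  dimnames(W) <- list(sprintf("G%02d", 1:n), sprintf("G%02d", 1:n))
  A <- clr_adjacency(W)
  sc <- rank_ego_genes(A)
  expect_equal(sum(sc$is_ego), 3L)            # ceil(0.3 * 10)
  expect_equal(mean(sc$g_i), 0, tolerance = 1e-12)
  expect_equal(sd(sc$g_i), 1, tolerance = 1e-12)

  # a dominant hub ranks first
  W2 <- W * 0.01
  W2[1, ] <- 0.99; W2[, 1] <- 0.99; diag(W2) <- 0
  sc2 <- rank_ego_genes(clr_adjacency(W2))
  expect_equal(sc2$gene[1L], "G01")

  # permutation equivariance of the ego set
  perm <- sample(n)
  Ap <- A[perm, perm]
  scp <- rank_ego_genes(Ap)
  expect_setequal(scp$gene[scp$is_ego], sc$gene[sc$is_ego])
})

test_that("weights are monotone in endpoint significance", {
  sn <- list(nodes = c("A", "B", "C"),
             edges = data.frame(gene_a = "A", gene_b = "B",
                                confidence = 900, gated = FALSE,
                                stringsAsFactors = FALSE))
  class(sn) <- "target_subnetwork"
  w_at <- function(pa) {
    node <- data.frame(gene = c("A", "B", "C"), p_i = c(pa, 2, 10))
    weight_edges(sn, node)$edges$weight
  }
  ws <- vapply(c(1, 2, 4, 8, 10), w_at, numeric(1L))
  expect_true(all(diff(ws) > 0))
  expect_true(all(ws >= 0 & ws <= 1))
})
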