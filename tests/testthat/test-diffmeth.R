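two_group_matrix <- function(values_case, values_ctrl) {
  # values_*: list of per-probe numeric vectors (same probe order)
  n1 <- length(values_case[[1L]]); n0 <- length(values_ctrl[[1L]])
  mat <- t(mapply(c, values_case, values_ctrl))
  rownames(mat) <- names(values_case)
  colnames(mat) <- c(sprintf("T%02d", seq_len(n1)),
                     sprintf("N%02d", seq_len(n0)))
  groups <- data.frame(sample_id = colnames(mat),
                       group = c(rep("tumor", n1), rep("normal", n0)),
                       stringsAsFactors = FALSE)
  list(beta = mat, groups = groups)
}

test_that("test_differential matches the Welch oracle and its contracts", {
  fx <- two_group_matrix(
    list(p1 = c(0.8, 0.8, 0.8), p2 = c(0.70, 0.75, 0.80),
         p3 = c(0.5, 0.6, 0.7)),
    list(p1 = c(0.6, 0.6, 0.6), p2 = c(0.50, 0.55, 0.60),
         p3 = c(0.5, 0.6, 0.7)))
  calls <- test_differential(fx$beta, fx$groups)

  # exact means and direction
  expect_equal(calls$A[1L], 0.2)
  expect_equal(calls$direction[1L], "hyper")
  expect_equal(calls$methylation_score[1L], 80)
  # degenerate equal-variance-zero probe
  expect_true(calls$degenerate[1L])
  expect_equal(calls$p_value[1L], 0)      # zero variance, unequal means

  # identical case/control values -> A = 0, p = 1, flagged
  expect_equal(calls$A[3L], 0)
  expect_equal(calls$p_value[3L], 1)
  expect_true(calls$degenerate[3L])

  # Welch formula oracle to 1e-10
  o <- oracle_welch(c(0.70, 0.75, 0.80), c(0.50, 0.55, 0.60))
  expect_equal(calls$t_stat[2L], o$t, tolerance = 1e-10)
  expect_equal(calls$p_value[2L], o$p, tolerance = 1e-10)

  # random matrices agree with stats::t.test (independent implementation)
  set.seed(31)
  for (rep in 1:5) {
    n1 <- sample(3:9, 1); n0 <- sample(3:9, 1)
    m <- matrix(runif(20 * (n1 + n0)), 20,
                dimnames = list(sprintf("cg%02d", 1:20),
                                c(sprintf("T%02d", 1:n1),
                                  sprintf("N%02d", 1:n0))))
    g <- data.frame(sample_id = colnames(m),
                    group = c(rep("tumor", n1), rep("normal", n0)))
    calls <- test_differential(m, g)
    for (i in c(1, 10, 20)) {
      tt <- t.test(m[i, 1:n1], m[i, n1 + (1:n0)])
      expect_equal(calls$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(calls$p_value[i], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("bh_adjust equals the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))

  set.seed(32)
  for (n in c(1, 7, 100, 1000)) {
    p <- runif(n)
    q <- bh_adjust(p)
    expect_lt(max(abs(q - oracle_bh(p))), 1e-12)
    expect_lt(max(abs(q - p.adjust(p, "BH"))), 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))   # monotone in p
  }
})

test_that("stage-1 and stage-2 thresholds act as published", {
  cfg <- pipeline_config()
  calls <- data.frame(
    probe_id = sprintf("cg%d", 1:3),
    mean_case = c(0.6, 0.6, 0.6), mean_control = c(0.54, 0.56, 0.3),
    A = c(0.06, 0.04, 0.30), t_stat = c(4, 4, 8),
    p_value = c(0.04, 0.04, 1e-5), q_value = c(0.2, 0.2, 1e-3),
    methylation_score = c(60, 60, 60),
    direction = "hyper", degenerate = FALSE, stringsAsFactors = FALSE)
  s1 <- stage1_select(calls, cfg)
  expect_setequal(s1$probe_id, c("cg1", "cg3"))   # cg2: A below threshold

  # six hand-written stage-2 rows: one failing each criterion + one pass
  base <- data.frame(probe_id = sprintf("r%d", 1:6),
                     methylation_score = c(60, 40, 60, 60, 60, 60),
                     p_value = c(1e-4, 1e-4, 1e-2, 1e-4, 1e-4, 1e-4),
                     t_stat = c(5, 5, 5, 2, 5, 5),
                     A = c(0.20, 0.20, 0.20, 0.20, 0.10, 0.20),
                     q_value = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2),
                     stringsAsFactors = FALSE)
  s2 <- stage2_refine(base, cfg)
  expect_equal(s2$probe_id, "r1")
  expect_equal(unname(attr(s2, "attrition")), c(1L, 1L, 1L, 1L, 1L))

  # boundary: A = 0.17 passes (>=), score = 50 fails (strict >)
  edge <- base[1, ]
  edge$A <- 0.17
  expect_equal(nrow(stage2_refine(edge, cfg)), 1L)
  edge$methylation_score <- 50
  expect_equal(nrow(stage2_refine(edge, cfg)), 0L)
})

test_that("stage-2 output is a subset of stage-1 on simulated calls", {
  sim <- simulate_beta_matrix(small_design(seed = 33))
  calls <- test_differential(sim$beta, sim$groups)
  s1 <- stage1_select(calls)
  s2 <- stage2_refine(s1)
  expect_true(all(s2$probe_id %in% s1$probe_id))
  expect_equal(sum(calls$direction %in% c("hyper", "hypo")), nrow(calls))
})

test_that("UPGMA clustering matches hand-computed merge heights", {
  # three samples on a line at 0, 0.05, 0.55 in each of two probes
  v <- c(0, 0.05, 0.55)
  beta <- rbind(cg1 = v, cg2 = v)
  colnames(beta) <- c("A", "B", "C")
  groups <- data.frame(sample_id = c("A", "B", "C"),
                       group = c("g1", "g1", "g2"))
  res <- cluster_samples(beta, groups)
  d_ab <- sqrt(2) * 0.05
  d_ac <- sqrt(2) * 0.55
  d_bc <- sqrt(2) * 0.50
  expect_equal(res$hclust$height, c(d_ab, mean(c(d_ac, d_bc))),
               tolerance = 1e-12)
  expect_equal(res$ari, 1)
  expect_error(cluster_samples(beta[1, , drop = FALSE], groups),
               ">= 2 probes")
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  set.seed(34)
  null_ari <- replicate(20, {
    adjusted_rand_index(sample(rep(1:2, 10)), rep(1:2, each = 10))
  })
  expect_lt(max(abs(null_ari)), 0.5)
  expect_lt(abs(mean(null_ari)), 0.15)
})
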