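#' Per-probe differential methylation tests
#'
#' For every probe: group means, `A` (absolute difference in mean beta),
#' a two-sided two-sample t-test (Welch by default, pooled variances with
#' `config$t_var = "pooled"`), the methylation score
#' (`100 * max(mean_case, mean_control)`), the direction (hyper when the
#' case mean exceeds the control mean), and Benjamini-Hochberg q-values
#' across all tested probes.  A probe with zero variance in both groups
#' and equal means gets p = 1 and is flagged `degenerate`.
#'
#' @param beta probes x samples matrix.
#' @param groups data.frame with `sample_id`, `group`; `case_level`
#'   defaults to `"tumor"` if present, else the first level.
#' @param config a [pipeline_config()].
#' @param case_level which group label is the case group.
#' @return data.frame of per-probe calls (`probe_id`, `mean_case`,
#'   `mean_control`, `A`, `t_stat`, `p_value`, `q_value`,
#'   `methylation_score`, `direction`, `degenerate`).
#' @export
test_differential <- function(beta, groups, config = pipeline_config(),
                              case_level = NULL) {
  stopifnot(all(colnames(beta) %in% groups$sample_id))
  grp <- groups$group[match(colnames(beta), groups$sample_id)]
  levels <- unique(grp)
  if (length(levels) != 2L) stop("exactly two groups required", call. = FALSE)
  if (is.null(case_level)) {
    case_level <- if ("tumor" %in% levels) "tumor" else levels[1L]
  }
  case <- beta[, grp == case_level, drop = FALSE]
  ctrl <- beta[, grp != case_level, drop = FALSE]
  n1 <- ncol(case); n0 <- ncol(ctrl)
  if (n1 < 2L || n0 < 2L) stop("need >= 2 samples per group", call. = FALSE)

  m1 <- rowMeans(case); m0 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1L)
  v0 <- rowSums((ctrl - m0)^2) / (n0 - 1L)
  if (config$t_var == "welch") {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep(n1 + n0 - 2L, length(m1))
  }
  tt <- (m1 - m0) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  novar <- se2 == 0
  # zero variance in both groups: equal means -> p = 1; unequal -> p = 0
  p[novar & m1 == m0] <- 1
  tt[novar & m1 == m0] <- 0
  p[novar & m1 != m0] <- 0
  tt[novar & m1 != m0] <- sign(m1 - m0)[novar & m1 != m0] * Inf
  degenerate <- novar | m1 == m0   # no usable signal either way

  data.frame(
    probe_id = rownames(beta),
    mean_case = m1, mean_control = m0,
    A = abs(m1 - m0),
    t_stat = tt, p_value = p, q_value = bh_adjust(p),
    methylation_score = 100 * pmax(m1, m0),
    direction = ifelse(m1 > m0, "hyper", "hypo"),
    degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * n / j`, clipped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  n <- length(p_values)
  if (n == 0L) return(numeric(0L))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  o <- order(p_values, decreasing = TRUE)
  ranked <- p_values[o] * n / seq(n, 1L)
  q <- pmin(cummin(ranked), 1)[order(o)]
  q
}

#' Stage-1 differential selection
#'
#' Keeps probes with `p_value < stage1_p` and `A > stage1_delta`.
#'
#' @param calls output of [test_differential()].
#' @param config a [pipeline_config()].
#' @return the calls data.frame restricted to the stage-1 set, with a
#'   `stage1_pass` column added to the full table in attribute `"flags"`.
#' @export
stage1_select <- function(calls, config = pipeline_config()) {
  pass <- calls$p_value < config$stage1_p & calls$A > config$stage1_delta
  out <- calls[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- nrow(calls)
  out
}

#' Stage-2 refinement of the differential set
#'
#' Within the stage-1 set, keeps probes with methylation score
#' `> stage2_score`, `p_value < stage2_p`, `|t| > stage2_tstat`,
#' `A >= stage2_delta` and `q_value < stage2_q`.  Per-criterion attrition
#' counts (probes failing each criterion within the stage-1 set) are
#' attached as attribute `"attrition"`.
#'
#' @param stage1 output of [stage1_select()].
#' @param config a [pipeline_config()].
#' @return the final differential calls data.frame (possibly 0 rows).
#' @export
stage2_refine <- function(stage1, config = pipeline_config()) {
  crit <- cbind(
    score = stage1$methylation_score > config$stage2_score,
    p = stage1$p_value < config$stage2_p,
    t = abs(stage1$t_stat) > config$stage2_tstat,
    A = stage1$A >= config$stage2_delta,
    q = stage1$q_value < config$stage2_q)
  pass <- rowSums(crit) == ncol(crit)
  out <- stage1[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "attrition") <- colSums(!crit)
  out
}

#' Hierarchical clustering of samples on the differential probes
#'
#' Agglomerative clustering of the sample columns with Euclidean distance
#' and average linkage (UPGMA), cut into two clusters at the last merge;
#' agreement with the known groups is summarized by the adjusted Rand
#' index.
#'
#' @param beta probes x samples matrix restricted to the final CpGs
#'   (>= 2 probes, >= 3 samples).
#' @param groups data.frame with `sample_id`, `group`.
#' @return list of class `cluster_result`: `hclust` (the merge tree),
#'   `labels` (named two-cluster assignment), `ari`.
#' @export
cluster_samples <- function(beta, groups) {
  if (nrow(beta) < 2L || ncol(beta) < 3L) {
    stop("clustering needs >= 2 probes and >= 3 samples", call. = FALSE)
  }
  d <- stats::dist(t(beta), method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = 2L)
  truth <- groups$group[match(colnames(beta), groups$sample_id)]
  out <- list(hclust = hc, labels = labels,
              ari = adjusted_rand_index(labels, truth))
  class(out) <- "cluster_result"
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param x,y partition labels (same length).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
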