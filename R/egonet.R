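#' Gene-level methylation signal and node significance
#'
#' Bridges CpG-level calls to the gene network: per sample, a gene's
#' methylation is the unweighted mean beta over its surviving probes; the
#' gene-level differential p-value is the minimum probe p-value, and the
#' node score is `p_i = max(-log10(gene_p), 1)`.  The floor at 1 keeps
#' `log p_i >= 0` so the edge-weight formula lands in \[0, 1\].
#'
#' @param beta probes x samples matrix (filtered/normalized).
#' @param annot probe annotation (`probe_id`, `gene`).
#' @param calls per-probe calls from [test_differential()] (restricted to
#'   the probes of `beta` or a superset).
#' @return list: `gene_beta` (genes x samples matrix), `node` (data.frame
#'   `gene`, `gene_p`, `p_i`).
#' @export
gene_level_signal <- function(beta, annot, calls) {
  gene <- annot$gene[match(rownames(beta), annot$probe_id)]
  if (anyNA(gene)) stop("beta matrix probes missing from annotation",
                        call. = FALSE)
  gl <- sort(unique(gene))
  gidx <- match(gene, gl)
  gene_beta <- rowsum(beta, gidx) /
    as.vector(table(factor(gidx, levels = seq_along(gl))))
  rownames(gene_beta) <- gl

  p <- calls$p_value[match(rownames(beta), calls$probe_id)]
  if (anyNA(p)) stop("calls missing for some probes", call. = FALSE)
  gene_p <- tapply(p, factor(gene, levels = gl), min)
  node <- data.frame(gene = gl, gene_p = as.numeric(gene_p),
                     p_i = pmax(-log10(as.numeric(gene_p)), 1),
                     stringsAsFactors = FALSE)
  list(gene_beta = gene_beta, node = node)
}

#' Build the target subnetwork
#'
#' Restricts the interaction edge list to edges whose *both* endpoints
#' belong to the target set (differential genes plus the susceptibility
#' seed genes); genes with no surviving edge are dropped from the node
#' set.
#'
#' @param edges edge data.frame (`gene_a`, `gene_b`, `confidence`).
#' @param diff_genes character vector of differential genes.
#' @param seed_genes character vector of susceptibility genes.
#' @return list of class `target_subnetwork`: `nodes`, `edges`
#'   (data.frame), `diff_genes`, `seed_genes`.
#' @export
build_target_subnetwork <- function(edges, diff_genes,
                                    seed_genes = character()) {
  target <- union(diff_genes, seed_genes)
  keep <- edges$gene_a %in% target & edges$gene_b %in% target
  sub <- edges[keep, , drop = FALSE]
  rownames(sub) <- NULL
  out <- list(nodes = sort(unique(c(sub$gene_a, sub$gene_b))),
              edges = sub, diff_genes = diff_genes,
              seed_genes = seed_genes)
  class(out) <- "target_subnetwork"
  out
}

#' Correlation gate for subnetwork edges
#'
#' Per edge, the Pearson correlation of the two genes' methylation
#' profiles across all samples and its two-sided p-value via
#' `t = r * sqrt((m-2) / (1-r^2))`.  The gate threshold `delta` is the
#' |r| whose p-value equals `config$delta_corr_p` at the sample count m,
#' obtained by inverting the t quantile in closed form:
#' `delta = t_c / sqrt(m - 2 + t_c^2)` with
#' `t_c = qt(1 - p/2, m - 2)`.  Edges with `|r| < delta` are marked
#' `gated` (their weight will be 0); an edge touching a zero-variance
#' gene is gated and flagged.
#'
#' @param subnet a `target_subnetwork`.
#' @param gene_beta genes x samples matrix from [gene_level_signal()].
#' @param config a [pipeline_config()].
#' @return the subnetwork with per-edge `r`, `p_r`, `gated` columns and
#'   a `delta` element.
#' @export
gate_by_correlation <- function(subnet, gene_beta,
                                config = pipeline_config()) {
  m <- ncol(gene_beta)
  if (m < 4L) stop("need >= 4 samples for the correlation gate",
                   call. = FALSE)
  missing <- setdiff(subnet$nodes, rownames(gene_beta))
  if (length(missing)) {
    stop("gene matrix missing subnetwork genes: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  delta <- correlation_gate_threshold(m, config$delta_corr_p)
  e <- subnet$edges
  if (nrow(e)) {
    xa <- gene_beta[e$gene_a, , drop = FALSE]
    xb <- gene_beta[e$gene_b, , drop = FALSE]
    sa <- apply(xa, 1L, stats::sd)
    sb <- apply(xb, 1L, stats::sd)
    r <- rep(NA_real_, nrow(e))
    ok <- sa > 0 & sb > 0
    if (any(ok)) {
      r[ok] <- vapply(which(ok), function(i) {
        stats::cor(xa[i, ], xb[i, ])
      }, numeric(1L))
    }
    r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tv <- r_cl * sqrt((m - 2) / (1 - r_cl^2))
    p_r <- 2 * stats::pt(-abs(tv), m - 2)
    e$r <- r
    e$p_r <- p_r
    e$gated <- is.na(r) | abs(r) < delta
  } else {
    e$r <- numeric(0L); e$p_r <- numeric(0L); e$gated <- logical(0L)
  }
  subnet$edges <- e
  subnet$delta <- delta
  subnet$n_samples <- m
  subnet
}

#' @rdname gate_by_correlation
#' @param m sample count.
#' @param p two-sided p-value defining the gate.
#' @export
correlation_gate_threshold <- function(m, p = 0.05) {
  tc <- stats::qt(1 - p / 2, df = m - 2)
  tc / sqrt(m - 2 + tc^2)
}

#' Significance edge weights
#'
#' For every retained (ungated) edge,
#' `w_ij = (log p_i + log p_j) / (2 * max over v in V of log p_v)`,
#' natural log (the base cancels in the ratio); gated edges get weight 0.
#' Because every node score satisfies `p_i >= 1`, the weights lie in
#' \[0, 1\], reaching 1 only when both endpoints attain the maximum.
#' When all node scores sit at the floor (max log = 0) the ratio is
#' undefined; all weights are set to 0 with a warning.
#'
#' @param subnet gated `target_subnetwork` from [gate_by_correlation()].
#' @param node node-significance data.frame (`gene`, `p_i`) from
#'   [gene_level_signal()].
#' @return the subnetwork with a per-edge `weight` column and a
#'   `node_score` element (named `p_i` over the node set).
#' @export
weight_edges <- function(subnet, node) {
  p_i <- node$p_i[match(subnet$nodes, node$gene)]
  if (anyNA(p_i)) stop("node scores missing for some subnetwork genes",
                       call. = FALSE)
  names(p_i) <- subnet$nodes
  lp <- log(p_i)
  mx <- max(lp)
  e <- subnet$edges
  if (mx <= 0) {
    warning("all node scores at the floor; edge weights set to 0",
            call. = FALSE)
    e$weight <- rep(0, nrow(e))
  } else {
    w <- (lp[e$gene_a] + lp[e$gene_b]) / (2 * mx)
    w[e$gated] <- 0
    e$weight <- unname(w)
  }
  subnet$edges <- e
  subnet$node_score <- p_i
  subnet
}

#' Node topology metrics of the target subnetwork
#'
#' Computed on the ungated, unweighted graph: degree; closeness
#' `(reachable - 1) / sum of shortest-path lengths` within the node's
#' component (0 for isolated nodes); betweenness (unnormalized sum over
#' pairs of the fraction of shortest paths through the node); local
#' transitivity (clustering coefficient; 0 when degree < 2).
#'
#' @param subnet a `target_subnetwork`.
#' @return data.frame `gene`, `degree`, `closeness`, `betweenness`,
#'   `transitivity`.
#' @export
topology_metrics <- function(subnet) {
  g <- igraph::graph_from_data_frame(
    subnet$edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = subnet$nodes))
  deg <- igraph::degree(g)
  dm <- igraph::distances(g)
  closeness <- apply(dm, 1L, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (!length(reach)) 0 else length(reach) / sum(reach)
  })
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  trans <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
             closeness = as.numeric(closeness),
             betweenness = as.numeric(btw),
             transitivity = as.numeric(trans),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Context-likelihood-of-relatedness adjacency
#'
#' Given a symmetric edge-weight matrix W (zero diagonal), each entry is
#' z-scored against its row's off-diagonal background:
#' `z_i(ij) = max(0, (W_ij - mu_i) / sigma_i)` (0 when `sigma_i = 0`),
#' and the adjacency combines the two endpoint scores:
#' `A_ij = sqrt(z_i(ij)^2 + z_j(ij)^2)`.  A is symmetric, non-negative,
#' zero-diagonal, and invariant to adding a constant to all of W.
#'
#' @param W symmetric numeric matrix with zero diagonal, |V| >= 3.
#' @return the CLR adjacency matrix, same dimnames.
#' @export
clr_adjacency <- function(W) {
  n <- nrow(W)
  if (n < 3L) stop("CLR needs at least 3 nodes", call. = FALSE)
  stopifnot(isTRUE(all.equal(W, t(W))), all(diag(W) == 0))
  off <- W
  diag(off) <- NA_real_
  mu <- rowMeans(off, na.rm = TRUE)
  sg <- apply(off, 1L, stats::sd, na.rm = TRUE)
  Z <- (W - mu) / sg        # row-wise standardization (recycles by column)
  Z[sg == 0, ] <- 0
  Z[Z < 0] <- 0
  diag(Z) <- 0
  A <- sqrt(Z^2 + t(Z)^2)
  dimnames(A) <- dimnames(W)
  A
}

# Dense symmetric weight matrix over the subnetwork nodes.
weight_matrix <- function(subnet) {
  n <- length(subnet$nodes)
  W <- matrix(0, n, n, dimnames = list(subnet$nodes, subnet$nodes))
  e <- subnet$edges
  if (nrow(e)) {
    ia <- match(e$gene_a, subnet$nodes)
    ib <- match(e$gene_b, subnet$nodes)
    W[cbind(ia, ib)] <- e$weight
    W[cbind(ib, ia)] <- e$weight
  }
  W
}

#' Rank ego genes by standardized CLR row strength
#'
#' Node strength `r_i = sum_j A_ij` is standardized to
#' `g_i = (r_i - mean(r)) / sd(r)` and genes are sorted by descending
#' `g_i` (ties broken lexicographically by gene ID).  The top
#' `ceil(ego_top_fraction * |V|)` genes are flagged as ego genes; genes
#' tied with the boundary value are all included.  When `sd(r) = 0` all
#' `g_i = 0` and ranking falls back to gene ID with a warning.
#'
#' @param A CLR adjacency matrix from [clr_adjacency()].
#' @param config a [pipeline_config()].
#' @param topology optional data.frame from [topology_metrics()] to merge
#'   into the output.
#' @return data.frame `gene`, `r_i`, `g_i`, `rank`, `is_ego` (plus the
#'   topology columns when supplied), sorted by rank.
#' @export
rank_ego_genes <- function(A, config = pipeline_config(),
                           topology = NULL) {
  r <- rowSums(A)
  sdr <- stats::sd(r)
  if (is.na(sdr) || sdr == 0) {
    warning("constant CLR row strengths; ranking by gene ID", call. = FALSE)
    g <- rep(0, length(r))
  } else {
    g <- (r - mean(r)) / sdr
  }
  ord <- order(-g, names(r))
  out <- data.frame(gene = names(r)[ord], r_i = unname(r[ord]),
                    g_i = unname(g[ord]), rank = seq_along(r),
                    stringsAsFactors = FALSE)
  n_ego <- ceiling(config$ego_top_fraction * nrow(out))
  out$is_ego <- out$rank <= n_ego
  if (n_ego >= 1L && n_ego < nrow(out)) {
    boundary <- out$g_i[n_ego]
    out$is_ego[out$g_i == boundary] <- TRUE   # include boundary ties
  }
  if (!is.null(topology)) {
    out <- merge(out, topology, by = "gene", sort = FALSE)
    out <- out[order(out$rank), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Full ego-network analysis
#'
#' Convenience wrapper running the whole module: gene-level signal,
#' target-subnetwork construction, correlation gating, edge weighting,
#' topology metrics, CLR and ego ranking.
#'
#' @param beta filtered/normalized probes x samples matrix.
#' @param annot probe annotation.
#' @param calls per-probe calls from [test_differential()].
#' @param diff_genes final differential gene list.
#' @param edges full interaction edge list.
#' @param config a [pipeline_config()].
#' @return list: `subnet` (weighted subnetwork), `gene_beta`, `node`,
#'   `A` (CLR adjacency), `scores` (ego table) — or a list with
#'   `status = "empty_subnetwork"` when no edge survives.
#' @export
egonet_analysis <- function(beta, annot, calls, diff_genes, edges,
                            config = pipeline_config()) {
  gl <- gene_level_signal(beta, annot, calls)
  subnet <- build_target_subnetwork(edges, diff_genes, config$seed_genes)
  if (!length(subnet$nodes)) {
    return(list(status = "empty_subnetwork", subnet = subnet))
  }
  subnet <- gate_by_correlation(subnet, gl$gene_beta, config)
  subnet <- weight_edges(subnet, gl$node)
  topo <- topology_metrics(subnet)
  if (length(subnet$nodes) < 3L) {
    return(list(status = "subnetwork_too_small", subnet = subnet,
                gene_beta = gl$gene_beta, node = gl$node,
                topology = topo))
  }
  A <- clr_adjacency(weight_matrix(subnet))
  scores <- rank_ego_genes(A, config, topology = topo)
  list(status = "ok", subnet = subnet, gene_beta = gl$gene_beta,
       node = gl$node, A = A, scores = scores)
}
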