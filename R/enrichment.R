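#' Fisher's-exact (hypergeometric) gene-set over-representation
#'
#' One-sided over-representation test per set: with universe size N,
#' K differential genes, a set of size n (after intersecting with the
#' universe) and overlap x, the p-value is the upper hypergeometric tail
#' `P(X >= x)`, computed in log-stable form.  P-values are BH-adjusted
#' across all tested sets and rows are sorted by ascending FDR (ties by
#' p-value then set name).  Sets with no members in the universe are
#' skipped with a warning.
#'
#' @param diff_genes character vector of differential genes (subset of
#'   `universe`).
#' @param universe character vector: all testable genes (by default the
#'   genes carrying at least one QC-surviving probe).
#' @param gene_sets named list of character vectors.
#' @param config a [pipeline_config()].
#' @return data.frame with columns `set`, `set_size`, `n_diff`,
#'   `overlap`, `p_value`, `fdr`, `significant`.
#' @export
fisher_enrich <- function(diff_genes, universe, gene_sets,
                          config = pipeline_config()) {
  universe <- unique(universe)
  diff_genes <- unique(diff_genes)
  if (!all(diff_genes %in% universe)) {
    stop("diff_genes must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  K <- length(diff_genes)
  sizes <- integer(0L); overlaps <- integer(0L); names_kept <- character(0L)
  for (nm in names(gene_sets)) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    if (!length(members)) {
      warning("gene set '", nm, "' has no members in the universe; skipped",
              call. = FALSE)
      next
    }
    sizes <- c(sizes, length(members))
    overlaps <- c(overlaps, length(intersect(members, diff_genes)))
    names_kept <- c(names_kept, nm)
  }
  if (!length(names_kept)) {
    return(data.frame(set = character(), set_size = integer(),
                      n_diff = integer(), overlap = integer(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  p <- hyper_tail_p(overlaps, K, N, sizes)
  fdr <- bh_adjust(p)
  out <- data.frame(set = names_kept, set_size = sizes, n_diff = K,
                    overlap = overlaps, p_value = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < config$enrich_fdr &
    out$overlap > config$enrich_min_count
  out <- out[order(out$fdr, out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Upper-tail hypergeometric P(X >= x) with X ~ Hyper(N, K, n),
# log-stable via phyper.
hyper_tail_p <- function(x, K, N, n) {
  p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Apply the enrichment significance thresholds
#'
#' Keeps rows with `fdr < enrich_fdr` (default 0.01) and
#' `overlap > enrich_min_count` (default 10, strict).
#'
#' @param rows output of [fisher_enrich()].
#' @param config a [pipeline_config()].
#' @return the significant subset, same ordering.
#' @export
apply_significance <- function(rows, config = pipeline_config()) {
  keep <- rows$fdr < config$enrich_fdr &
    rows$overlap > config$enrich_min_count
  out <- rows[keep, , drop = FALSE]
  out$significant <- TRUE
  rownames(out) <- NULL
  out
}
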