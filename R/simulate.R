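#' Simulation design for the synthetic beta-value study
#'
#' The generator emulates a tumor/normal methylation-array study: per-probe
#' beta values are drawn from beta distributions parameterized by a state
#' mean (unmethylated ~0.1, hemimethylated ~0.5, methylated ~0.85) and a
#' precision (`dispersion`); a planted fraction of probes is differential
#' with a case-group mean shift of `delta_beta`; design-class-II probes are
#' compressed toward 0.5 by `typeII_attenuation` (the distortion that
#' beta-mixture quantile normalization must undo); a fraction of probes is
#' planted to fail exactly one quality-control criterion each (SNP
#' proximity, low MAF, cross-hybridization, sex chromosome), never
#' overlapping the differential probes.  Defaults mirror the emulated study
#' shape at desk scale: 29 case / 9 control samples, 20000 probes over
#' 2000 genes in contiguous blocks.
#'
#' @param n_probes,n_genes probe and gene counts; probes map to genes in
#'   contiguous blocks of `n_probes / n_genes`.
#' @param n_case,n_control samples per group (>= 2 each).
#' @param frac_diff fraction of probes planted differential (may be 0).
#' @param frac_hyper fraction of differential probes hypermethylated in
#'   the case group.
#' @param delta_beta planted case-minus-control mean shift, beta units.
#' @param dispersion beta-distribution precision s; shapes are
#'   `a = m*s`, `b = (1-m)*s`.
#' @param frac_typeII fraction of probes on design class II.
#' @param typeII_attenuation compression factor in (0,1]; class-II values
#'   are mapped `x <- 0.5 + typeII_attenuation * (x - 0.5)`.
#' @param frac_qc_fail fraction of probes planted to fail QC, split evenly
#'   across the four removal criteria.
#' @param n_seed_genes number of susceptibility stand-in genes.
#' @param module_size planted disease-module size (genes, drawn from the
#'   differential genes).
#' @param attach_m preferential-attachment edges per added node.
#' @param n_gene_sets,enriched_sets gene-set collection size and how many
#'   sets are enriched for differential genes.
#' @param seed integer master seed for the generator.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_probes = 20000L, n_genes = 2000L,
                              n_case = 29L, n_control = 9L,
                              frac_diff = 0.05, frac_hyper = 0.8,
                              delta_beta = 0.3, dispersion = 30,
                              frac_typeII = 0.7, typeII_attenuation = 0.8,
                              frac_qc_fail = 0.10,
                              n_seed_genes = 4L, module_size = 15L,
                              attach_m = 2L,
                              n_gene_sets = 50L, enriched_sets = 3L,
                              seed = 1L) {
  d <- list(n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
            n_case = as.integer(n_case), n_control = as.integer(n_control),
            frac_diff = frac_diff, frac_hyper = frac_hyper,
            delta_beta = delta_beta, dispersion = dispersion,
            frac_typeII = frac_typeII,
            typeII_attenuation = typeII_attenuation,
            frac_qc_fail = frac_qc_fail,
            n_seed_genes = as.integer(n_seed_genes),
            module_size = as.integer(module_size),
            attach_m = as.integer(attach_m),
            n_gene_sets = as.integer(n_gene_sets),
            enriched_sets = as.integer(enriched_sets),
            seed = as.integer(seed))
  stopifnot(d$n_probes >= d$n_genes, d$n_genes >= 1L,
            d$n_case >= 2L, d$n_control >= 2L,
            d$frac_diff >= 0, d$frac_diff < 1,
            d$frac_hyper >= 0, d$frac_hyper <= 1,
            d$delta_beta > 0, d$delta_beta < 1,
            d$dispersion > 0,
            d$frac_typeII > 0, d$frac_typeII < 1,
            d$typeII_attenuation > 0, d$typeII_attenuation <= 1,
            d$frac_qc_fail >= 0, d$frac_qc_fail < 1,
            d$attach_m >= 1L, d$module_size >= 0L, d$n_seed_genes >= 0L,
            d$module_size + d$n_seed_genes <= d$n_genes,
            d$n_gene_sets >= d$enriched_sets, d$enriched_sets >= 0L)
  class(d) <- "simulation_design"
  d
}

# State means of the unmethylated / hemimethylated / methylated components.
BETA_STATE_MEANS <- c(low = 0.1, mid = 0.5, high = 0.85)

#' Simulate a beta-value matrix with annotation and ground truth
#'
#' Differential probes draw their base state from the states that leave
#' headroom for the full `delta_beta` shift in the assigned direction
#' (hyper: low/mid; hypo: mid/high), so the planted effect is not eroded
#' by the \[0.02, 0.98\] mean clamp.  Planted QC failures each violate
#' exactly one criterion and never overlap the differential probes, so
#' the QC filter recovers them exactly.
#'
#' @param design a [simulation_design()].
#' @return list with elements `beta` (matrix), `annot` (data.frame),
#'   `groups` (data.frame sample_id/group), `truth` (list: `diff_probes`,
#'   `diff_direction`, `probe_gene`, `diff_genes`, `qc_probes`,
#'   `qc_criterion`).
#' @export
simulate_beta_matrix <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  set.seed(stage_seed(d$seed, 1L))

  probes <- sprintf("cg%06d", seq_len(d$n_probes))
  genes <- sprintf("G%05d", seq_len(d$n_genes))
  block <- ceiling(d$n_probes / d$n_genes)
  probe_gene <- genes[pmin(((seq_len(d$n_probes) - 1L) %/% block) + 1L,
                           d$n_genes)]
  gene_chrom <- sample(as.character(1:22), d$n_genes, replace = TRUE)
  chrom <- gene_chrom[match(probe_gene, genes)]

  n_qc <- round(d$frac_qc_fail * d$n_probes)
  n_diff <- round(d$frac_diff * d$n_probes)
  if (n_qc + n_diff > d$n_probes) {
    stop("frac_qc_fail + frac_diff exceed the probe budget", call. = FALSE)
  }
  qc_idx <- if (n_qc > 0) sort(sample.int(d$n_probes, n_qc)) else integer()
  rest <- setdiff(seq_len(d$n_probes), qc_idx)
  diff_idx <- if (n_diff > 0) sort(sample(rest, n_diff)) else integer()

  # annotation defaults: every criterion passing
  snp_distance <- sample(3:500, d$n_probes, replace = TRUE)
  maf <- stats::runif(d$n_probes, 0.05, 0.5)
  cross_hyb <- integer(d$n_probes)
  qc_criterion <- rep(NA_character_, d$n_probes)
  if (n_qc > 0) {
    crit <- rep(c("snp_proximity", "low_maf", "cross_hyb", "sex_chromosome"),
                length.out = n_qc)
    qc_criterion[qc_idx] <- crit
    snp_fail <- qc_idx[crit == "snp_proximity"]
    snp_distance[snp_fail] <- sample(0:2, length(snp_fail), replace = TRUE)
    maf_fail <- qc_idx[crit == "low_maf"]
    maf[maf_fail] <- stats::runif(length(maf_fail), 0.005, 0.0499)
    cross_hyb[qc_idx[crit == "cross_hyb"]] <- 1L
    sex_fail <- qc_idx[crit == "sex_chromosome"]
    chrom[sex_fail] <- sample(c("X", "Y"), length(sex_fail), replace = TRUE)
  }

  # per-probe base state mean; differential probes re-drawn with headroom
  state <- sample(BETA_STATE_MEANS, d$n_probes, replace = TRUE)
  direction <- rep(NA_character_, d$n_probes)
  if (n_diff > 0) {
    n_hyper <- round(d$frac_hyper * n_diff)
    dirs <- sample(c(rep("hyper", n_hyper), rep("hypo", n_diff - n_hyper)))
    direction[diff_idx] <- dirs
    hyper_states <- BETA_STATE_MEANS[c("low", "mid")]
    hypo_states <- BETA_STATE_MEANS[c("mid", "high")]
    is_hyper <- diff_idx[dirs == "hyper"]
    is_hypo <- diff_idx[dirs == "hypo"]
    state[is_hyper] <- sample(hyper_states, length(is_hyper), replace = TRUE)
    state[is_hypo] <- sample(hypo_states, length(is_hypo), replace = TRUE)
  }
  mean_control <- state
  mean_case <- state
  if (n_diff > 0) {
    shift <- ifelse(direction[diff_idx] == "hyper", d$delta_beta,
                    -d$delta_beta)
    mean_case[diff_idx] <- pmin(pmax(state[diff_idx] + shift, 0.02), 0.98)
  }

  s <- d$dispersion
  n_samples <- d$n_case + d$n_control
  sample_ids <- c(sprintf("T%02d", seq_len(d$n_case)),
                  sprintf("N%02d", seq_len(d$n_control)))
  group <- c(rep("tumor", d$n_case), rep("normal", d$n_control))
  beta <- matrix(NA_real_, d$n_probes, n_samples,
                 dimnames = list(probes, sample_ids))
  for (j in seq_len(n_samples)) {
    m <- if (group[j] == "tumor") mean_case else mean_control
    beta[, j] <- stats::rbeta(d$n_probes, m * s, (1 - m) * s)
  }

  design_type <- rep("I", d$n_probes)
  ii <- sample.int(d$n_probes, round(d$frac_typeII * d$n_probes))
  design_type[ii] <- "II"
  beta[ii, ] <- 0.5 + d$typeII_attenuation * (beta[ii, ] - 0.5)

  annot <- data.frame(
    probe_id = probes, chrom = chrom,
    pos = seq_len(d$n_probes) * 100L,
    snp_distance = snp_distance, maf = maf, cross_hyb = cross_hyb,
    design_type = design_type, gene = probe_gene,
    stringsAsFactors = FALSE)

  truth <- list(
    diff_probes = probes[diff_idx],
    diff_direction = stats::setNames(direction[diff_idx], probes[diff_idx]),
    probe_gene = stats::setNames(probe_gene, probes),
    diff_genes = sort(unique(probe_gene[diff_idx])),
    qc_probes = probes[qc_idx],
    qc_criterion = stats::setNames(qc_criterion[qc_idx], probes[qc_idx]))

  list(beta = beta, annot = annot,
       groups = data.frame(sample_id = sample_ids, group = group,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a scale-free interaction network with a planted module
#'
#' A preferential-attachment (Barabasi-Albert) backbone over the gene
#' universe, plus a planted module — `module_size` genes drawn from the
#' truth-differential genes together with `n_seed_genes` susceptibility
#' stand-ins (drawn from non-differential genes) — wired to at least 60%
#' internal edge density.  Confidence scores are sampled in \[400, 1000\].
#'
#' @param design a [simulation_design()].
#' @param gene_universe character vector of gene IDs.
#' @param truth ground-truth list from [simulate_beta_matrix()].
#' @return list with `edges` (data.frame gene_a/gene_b/confidence) and
#'   `truth` (the input truth augmented with `module_genes`, `seed_genes`).
#' @export
simulate_network <- function(design, gene_universe, truth) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  set.seed(stage_seed(d$seed, 2L))
  n <- length(gene_universe)
  stopifnot(d$module_size + d$n_seed_genes <= n)

  g <- igraph::sample_pa(n, power = 1, m = d$attach_m, directed = FALSE)
  perm <- sample(gene_universe)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(gene_a = perm[el[, 1L]], gene_b = perm[el[, 2L]],
                      stringsAsFactors = FALSE)

  diff_pool <- intersect(truth$diff_genes, gene_universe)
  if (d$module_size > length(diff_pool)) {
    stop("not enough differential genes to plant the module", call. = FALSE)
  }
  module <- if (d$module_size > 0) sort(sample(diff_pool, d$module_size))
            else character()
  nondiff <- setdiff(gene_universe, truth$diff_genes)
  seed_genes <- if (d$n_seed_genes > 0) {
    pool <- if (length(nondiff) >= d$n_seed_genes) nondiff
            else gene_universe
    sort(sample(pool, d$n_seed_genes))
  } else character()

  mod_all <- union(module, seed_genes)
  if (length(mod_all) >= 2L) {
    pairs <- utils::combn(sort(mod_all), 2L)
    need <- ceiling(0.6 * ncol(pairs))
    key <- paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b), sep = "\r")
    pkey <- paste(pairs[1L, ], pairs[2L, ], sep = "\r")
    present <- pkey %in% key
    missing <- which(!present)
    extra <- need - sum(present)
    if (extra > 0) {
      add <- sample(missing, extra)
      edges <- rbind(edges,
                     data.frame(gene_a = pairs[1L, add],
                                gene_b = pairs[2L, add],
                                stringsAsFactors = FALSE))
    }
  }
  edges$confidence <- sample(400:1000, nrow(edges), replace = TRUE)
  edges <- dedup_edges(edges)

  truth$module_genes <- module
  truth$seed_genes <- seed_genes
  list(edges = edges, truth = truth)
}

#' Simulate gene-set collections
#'
#' Enriched sets draw at least 70% of their members from the
#' truth-differential genes; null sets draw uniformly from the universe.
#' Set sizes are uniform on \[15, 200\].
#'
#' @inheritParams simulate_network
#' @return list with `sets` (named list), `descriptions`, and `truth`
#'   augmented with `enriched_sets`.
#' @export
simulate_gene_sets <- function(design, gene_universe, truth) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  set.seed(stage_seed(d$seed, 3L))
  if (d$n_gene_sets == 0L) {
    truth$enriched_sets <- character()
    return(list(sets = list(), descriptions = character(), truth = truth))
  }
  sizes <- sample(15:200, d$n_gene_sets, replace = TRUE)
  if (max(sizes) > length(gene_universe)) {
    stop("gene universe smaller than the largest gene-set size",
         call. = FALSE)
  }
  diff_pool <- intersect(truth$diff_genes, gene_universe)
  sets <- vector("list", d$n_gene_sets)
  names(sets) <- sprintf("SET%03d", seq_len(d$n_gene_sets))
  enriched <- names(sets)[seq_len(d$enriched_sets)]
  for (i in seq_len(d$n_gene_sets)) {
    sz <- sizes[i]
    if (names(sets)[i] %in% enriched) {
      k <- ceiling(0.7 * sz)
      if (k > length(diff_pool)) {
        stop("not enough differential genes to build an enriched set",
             call. = FALSE)
      }
      core <- sample(diff_pool, k)
      rest <- sample(setdiff(gene_universe, core), sz - k)
      sets[[i]] <- sample(c(core, rest))
    } else {
      sets[[i]] <- sample(gene_universe, sz)
    }
  }
  truth$enriched_sets <- enriched
  desc <- ifelse(names(sets) %in% enriched, "planted_enriched", "null")
  list(sets = sets, descriptions = desc, truth = truth)
}

#' Simulate the complete synthetic study and optionally write it to disk
#'
#' Runs the three generators in sequence and, when `out_dir` is given,
#' writes `beta.tsv`, `annot.tsv`, `groups.tsv`, `edges.tsv`, `sets.gmt`
#' and `truth.tsv`.
#'
#' @param design a [simulation_design()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `beta`, `annot`, `groups`, `edges`, `sets`, `truth`.
#' @export
simulate_dataset <- function(design, out_dir = NULL) {
  sim <- simulate_beta_matrix(design)
  net <- simulate_network(design, sort(unique(sim$annot$gene)), sim$truth)
  gs <- simulate_gene_sets(design, sort(unique(sim$annot$gene)), net$truth)
  out <- list(beta = sim$beta, annot = sim$annot, groups = sim$groups,
              edges = net$edges, sets = gs$sets, truth = gs$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_beta_matrix(out$beta, file.path(out_dir, "beta.tsv"))
    write_result_table(out$annot, file.path(out_dir, "annot.tsv"))
    write_result_table(out$groups, file.path(out_dir, "groups.tsv"))
    write_network_edges(out$edges, file.path(out_dir, "edges.tsv"))
    write_gene_sets(out$sets, file.path(out_dir, "sets.gmt"),
                    gs$descriptions)
    write_truth(out$truth, file.path(out_dir, "truth.tsv"))
  }
  out
}

# Long-format truth table: one row per (category, id, value).
write_truth <- function(truth, path) {
  rows <- rbind(
    data.frame(category = "diff_probe", id = truth$diff_probes,
               value = unname(truth$diff_direction),
               stringsAsFactors = FALSE),
    data.frame(category = "qc_probe", id = truth$qc_probes,
               value = unname(truth$qc_criterion),
               stringsAsFactors = FALSE),
    data.frame(category = "diff_gene", id = truth$diff_genes, value = ".",
               stringsAsFactors = FALSE),
    data.frame(category = "module_gene",
               id = truth$module_genes %||% character(), value = ".",
               stringsAsFactors = FALSE),
    data.frame(category = "seed_gene",
               id = truth$seed_genes %||% character(), value = ".",
               stringsAsFactors = FALSE),
    data.frame(category = "enriched_set",
               id = truth$enriched_sets %||% character(), value = ".",
               stringsAsFactors = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
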