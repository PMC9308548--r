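#' Read a beta-value matrix from TSV
#'
#' The file has probe IDs in the first column, sample IDs in the header,
#' and a numeric body of methylation fractions.  Values must lie in
#' \[0, 1\]; missing values are written as `"."`.
#'
#' @param path TSV file path.
#' @return Numeric matrix, probes x samples, with dimnames.
#' @export
read_beta_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = ".", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("beta matrix needs a probe column and >= 1 sample",
                           call. = FALSE)
  probes <- as.character(tab[[1L]])
  dup <- probes[duplicated(probes)]
  if (length(dup)) {
    stop("duplicate probe ID(s) in beta matrix: ",
         paste(utils::head(unique(dup), 5L), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- probes
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("beta value %g outside [0,1] at probe '%s', sample '%s'",
                 mat[i, j], probes[i], colnames(mat)[j]), call. = FALSE)
  }
  mat
}

#' @rdname read_beta_matrix
#' @param beta probes x samples numeric matrix with dimnames.
#' @param digits decimals written (default 6).
#' @export
write_beta_matrix <- function(beta, path, digits = 6L) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  body <- formatC(beta, format = "f", digits = digits)
  body[is.na(beta)] <- "."
  tab <- cbind(probe_id = rownames(beta), as.data.frame(body))
  colnames(tab) <- c("probe_id", colnames(beta))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Required columns: `probe_id`, `chrom`, `pos`, `snp_distance`, `maf`,
#' `cross_hyb`, `design_type`, `gene`.  `design_type` must be `"I"` or
#' `"II"`; `maf` must lie in \[0, 0.5\]; chromosome tokens are normalized
#' (leading `"chr"` stripped, so `chrX` and `X` are equivalent).
#'
#' @param path TSV file path.
#' @return A data.frame with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = ".", stringsAsFactors = FALSE)
  required <- c("probe_id", "chrom", "pos", "snp_distance", "maf",
                "cross_hyb", "design_type", "gene")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols)) {
    stop("probe annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$probe_id)) {
    stop("duplicate probe IDs in annotation", call. = FALSE)
  }
  tab$chrom <- normalize_chrom(tab$chrom)
  if (!all(tab$design_type %in% c("I", "II"))) {
    stop("design_type must be 'I' or 'II'", call. = FALSE)
  }
  bad <- which(!is.na(tab$maf) & (tab$maf < 0 | tab$maf > 0.5))
  if (length(bad)) {
    stop(sprintf("MAF outside [0, 0.5] for probe '%s' (%g)",
                 tab$probe_id[bad[1L]], tab$maf[bad[1L]]), call. = FALSE)
  }
  tab[required]
}

normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  toupper(x)
}

#' Read a sample-group table
#'
#' Two tab-separated columns: `sample_id` and `group` (e.g. tumor/normal).
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_group_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(tab))) {
    stop("group table needs columns sample_id, group", call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample IDs", call. = FALSE)
  tab[c("sample_id", "group")]
}

#' Read a gene-gene interaction edge list
#'
#' STRING-style TSV with columns `gene_a`, `gene_b`, `confidence`
#' (0-1000).  Edges are undirected: `(a,b)` and `(b,a)` are collapsed to
#' one record (keeping the highest confidence); self-loops are dropped
#' with a warning.
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_a`, `gene_b`, `confidence`,
#'   one row per unique unordered pair, `gene_a < gene_b` lexically.
#' @export
read_network_edges <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "confidence") %in% colnames(tab))) {
    stop("edge list needs columns gene_a, gene_b, confidence", call. = FALSE)
  }
  if (!is.numeric(tab$confidence)) {
    stop("edge confidence must be numeric", call. = FALSE)
  }
  dedup_edges(tab)
}

# Canonicalize an edge table: drop self loops (warning), order endpoints,
# collapse duplicates keeping the maximum confidence.
dedup_edges <- function(tab) {
  self <- tab$gene_a == tab$gene_b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped from edge list", call. = FALSE)
    tab <- tab[!self, , drop = FALSE]
  }
  a <- pmin(tab$gene_a, tab$gene_b)
  b <- pmax(tab$gene_a, tab$gene_b)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -tab$confidence)
  keep <- !duplicated(key[ord])
  out <- data.frame(gene_a = a[ord][keep], gene_b = b[ord][keep],
                    confidence = tab$confidence[ord][keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname read_network_edges
#' @param edges edge data.frame as returned by `read_network_edges`.
#' @export
write_network_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> members...`.
#' Duplicate members within a line are stored once; empty sets and
#' duplicate set names are rejected.
#'
#' @param path GMT file path.
#' @return For `read_gene_sets`, a named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    name <- fields[1L]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("GMT line %d defines an empty set '%s'", i, name),
           call. = FALSE)
    }
    if (name %in% names(sets)) {
      stop("duplicate gene-set name: ", name, call. = FALSE)
    }
    sets[[name]] <- members
  }
  sets
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Generic result-table writer: TSV, "." for NA, 6 significant-stable
# decimals for doubles.
write_result_table <- function(tab, path, digits = 6L) {
  out <- tab
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      col <- formatC(out[[j]], format = "g", digits = 10)
      col[is.na(out[[j]])] <- "."
      out[[j]] <- col
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
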