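#' Probe quality-control filter cascade
#'
#' Removes a probe when any of the four criteria holds: (i) SNP within 2
#' bases of the CpG (`snp_distance <= 2`); (ii) low minor allele frequency
#' (`maf < 0.05`, the rule exactly as published — note that this direction
#' inverts the usual convention of removing *common* variants; switch with
#' `config$maf_rule = "conventional"` to remove `maf >= 0.05`);
#' (iii) cross-hybridizing probe; (iv) probe on a sex chromosome.
#' Removal is the union of the criteria; the per-criterion counts in the
#' report attribute each removed probe to its first matching criterion in
#' the order (i)-(iv).  Probes with missing `snp_distance` or `maf` are
#' kept (QC never silently drops unannotated probes) and counted in
#' `n_missing_annotation`.
#'
#' @param annot probe annotation data.frame
#'   (see [read_probe_annotation()]).
#' @param config a [pipeline_config()].
#' @return list of class `filter_report`: `n_input`, `removed` (named
#'   counts: snp_proximity, low_maf, cross_hyb, sex_chromosome),
#'   `kept` (probe IDs), `removed_ids`, `n_missing_annotation`.
#' @export
filter_probes <- function(annot, config = pipeline_config()) {
  snp_fail <- !is.na(annot$snp_distance) & annot$snp_distance <= 2
  maf_fail <- if (config$maf_rule == "as_printed") {
    !is.na(annot$maf) & annot$maf < 0.05
  } else {
    !is.na(annot$maf) & annot$maf >= 0.05
  }
  cross_fail <- !is.na(annot$cross_hyb) & annot$cross_hyb != 0
  sex_fail <- normalize_chrom(annot$chrom) %in% c("X", "Y")

  removed <- snp_fail | maf_fail | cross_fail | sex_fail
  first <- rep(NA_character_, nrow(annot))
  first[sex_fail] <- "sex_chromosome"
  first[cross_fail] <- "cross_hyb"
  first[maf_fail] <- "low_maf"
  first[snp_fail] <- "snp_proximity"

  counts <- c(snp_proximity = sum(first == "snp_proximity", na.rm = TRUE),
              low_maf = sum(first == "low_maf", na.rm = TRUE),
              cross_hyb = sum(first == "cross_hyb", na.rm = TRUE),
              sex_chromosome = sum(first == "sex_chromosome", na.rm = TRUE))
  out <- list(n_input = nrow(annot),
              removed = counts,
              kept = annot$probe_id[!removed],
              removed_ids = annot$probe_id[removed],
              n_missing_annotation = sum(is.na(annot$snp_distance) |
                                           is.na(annot$maf)))
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe QC filter report\n")
  cat("  input probes:", x$n_input, "\n")
  for (k in names(x$removed)) cat(sprintf("  removed (%s): %d\n", k,
                                          x$removed[[k]]))
  cat("  kept:", length(x$kept), "\n")
  invisible(x)
}

BETA_CLIP <- 1e-6

#' Fit a beta-mixture model by EM
#'
#' Fits a k-component beta mixture to values in (0,1) (values are clipped
#' to `[1e-6, 1 - 1e-6]` first).  Initialization is deterministic:
#' component means at the 10th/50th/90th percentiles (k = 3; evenly spaced
#' quantiles otherwise), equal weights, precision 10.  The M-step
#' maximizes each component's weighted beta log-likelihood through its
#' sufficient statistics (weighted means of log x and log(1-x)),
#' warm-started at the previous parameters, so the log-likelihood never
#' decreases.  Convergence: log-likelihood gain < 1e-6 or 500 iterations.
#' A component whose weight collapses below 1e-4 triggers a refit with
#' k - 1 components, flagged in the result.
#'
#' @param values numeric vector, length >= 50 for a stable fit.
#' @param k number of components (default 3: unmethylated /
#'   hemimethylated / methylated).
#' @return list of class `beta_mixture_fit`: `a`, `b`, `pi` (ascending
#'   component means), `loglik` (trace), `iterations`, `k`, `degenerate`.
#' @export
fit_beta_mixture <- function(values, k = 3L) {
  x <- pmin(pmax(values[!is.na(values)], BETA_CLIP), 1 - BETA_CLIP)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values to fit a mixture", call. = FALSE)
  if (stats::sd(x) < 1e-10) {
    # all values (numerically) identical: single-component fallback
    m <- mean(x)
    fit <- list(a = m * 100, b = (1 - m) * 100, pi = 1,
                loglik = NA_real_, iterations = 0L, k = 1L,
                degenerate = TRUE)
    class(fit) <- "beta_mixture_fit"
    return(fit)
  }
  fit <- em_beta_mixture(x, k)
  while (fit$collapsed && fit$k > 1L) {
    fit <- em_beta_mixture(x, fit$k - 1L)
    fit$degenerate <- TRUE
  }
  fit$degenerate <- isTRUE(fit$degenerate)
  fit$collapsed <- NULL
  class(fit) <- "beta_mixture_fit"
  fit
}

em_beta_mixture <- function(x, k, max_iter = 500L, tol = 1e-6) {
  n <- length(x)
  qs <- if (k == 3L) c(0.10, 0.50, 0.90) else seq(0.1, 0.9,
                                                  length.out = k)
  m0 <- pmin(pmax(stats::quantile(x, qs, names = FALSE), 0.02), 0.98)
  s0 <- 10
  a <- m0 * s0
  b <- (1 - m0) * s0
  pi_k <- rep(1 / k, k)
  lx <- log(x)
  l1x <- log1p(-x)
  ll_trace <- numeric(0L)
  ll_old <- -Inf
  collapsed <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: log responsibilities
    logd <- vapply(seq_len(k), function(j) {
      stats::dbeta(x, a[j], b[j], log = TRUE) + log(pi_k[j])
    }, numeric(n))
    logd <- matrix(logd, nrow = n)
    mx <- logd[, 1L]
    for (j in seq_len(k)[-1L]) mx <- pmax(mx, logd[, j])
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    w <- colSums(resp)
    pi_new <- w / n
    if (any(pi_new < 1e-4)) { collapsed <- TRUE; break }
    # M-step via sufficient statistics, warm start at current params
    for (j in seq_len(k)) {
      slx <- sum(resp[, j] * lx) / w[j]
      sl1x <- sum(resp[, j] * l1x) / w[j]
      ab <- beta_wmle(a[j], b[j], slx, sl1x)
      a[j] <- ab[1L]; b[j] <- ab[2L]
    }
    pi_k <- pi_new
    if (iter >= max_iter || (is.finite(ll_old) && ll - ll_old < tol)) break
    ll_old <- ll
  }
  ord <- order(a / (a + b))
  list(a = a[ord], b = b[ord], pi = pi_k[ord], loglik = ll_trace,
       iterations = iter, k = k, collapsed = collapsed)
}

# Weighted beta MLE from sufficient statistics (mean log x, mean
# log(1-x)), by damped Newton on (log a, log b) warm-started at the
# previous parameters.  Backtracking only accepts improving steps, so
# the surrounding EM is a generalized EM with a non-decreasing
# log-likelihood.
beta_wmle <- function(a, b, slx, sl1x, max_newton = 25L, tol = 1e-10) {
  ll <- function(a, b) (a - 1) * slx + (b - 1) * sl1x - lbeta(a, b)
  cur <- ll(a, b)
  for (it in seq_len(max_newton)) {
    dab <- digamma(a + b)
    g <- c(a * (slx - digamma(a) + dab), b * (sl1x - digamma(b) + dab))
    tab <- trigamma(a + b)
    # Hessian of ll in (log a, log b)
    h11 <- g[1L] + a * a * (tab - trigamma(a))
    h22 <- g[2L] + b * b * (tab - trigamma(b))
    h12 <- a * b * tab
    det <- h11 * h22 - h12 * h12
    step <- if (is.finite(det) && det > 0 && h11 < 0) {
      # Newton direction for a negative-definite Hessian
      c(-(h22 * g[1L] - h12 * g[2L]), -(h11 * g[2L] - h12 * g[1L])) / det
    } else {
      g * 0.1   # gradient ascent fallback
    }
    improved <- FALSE
    for (half in 0:20) {
      an <- a * exp(step[1L] / 2^half)
      bn <- b * exp(step[2L] / 2^half)
      if (is.finite(an) && is.finite(bn) && an > 1e-8 && bn > 1e-8) {
        new <- ll(an, bn)
        if (is.finite(new) && new >= cur) {
          improved <- new > cur + tol
          a <- an; b <- bn; cur <- new
          break
        }
      }
    }
    if (!improved) break
  }
  c(a, b)
}

# Map class-II values onto the class-I mixture component-wise:
# hard-assign each value to its max-responsibility class-II component,
# then quantile-map u = F_II,k(x), x' = Finv_I,k(u).  Components are
# matched by ascending-mean rank; if the fits ended with different k
# (degenerate collapse), ranks are matched proportionally.
bmiq_map <- function(x, fit_from, fit_to) {
  kf <- fit_from$k
  kt <- fit_to$k
  xc <- pmin(pmax(x, BETA_CLIP), 1 - BETA_CLIP)
  logd <- vapply(seq_len(kf), function(j) {
    stats::dbeta(xc, fit_from$a[j], fit_from$b[j], log = TRUE) +
      log(fit_from$pi[j])
  }, numeric(length(xc)))
  comp <- max.col(matrix(logd, nrow = length(xc)), ties.method = "first")
  target <- if (kf == kt) seq_len(kf) else
    pmax(1L, pmin(kt, round((seq_len(kf) - 0.5) * kt / kf + 0.5)))
  out <- numeric(length(x))
  for (j in seq_len(kf)) {
    sel <- comp == j
    if (!any(sel)) next
    u <- stats::pbeta(xc[sel], fit_from$a[j], fit_from$b[j])
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    out[sel] <- stats::qbeta(u, fit_to$a[target[j]], fit_to$b[target[j]])
  }
  pmin(pmax(out, 0), 1)
}

#' Beta-mixture quantile normalization of design-class-II probes
#'
#' Per sample: fit 3-component beta mixtures separately to the class-I and
#' class-II probe values, hard-assign each class-II value to its
#' maximum-responsibility class-II component, and map it through the
#' matched class-I component's distribution
#' (`u = F_II,k(beta)`, `beta' = F_I,k^{-1}(u)`).  Class-I values are
#' never altered.  The map is a monotone CDF/quantile composition within
#' each (sample, component), so value order is preserved there, and the
#' output stays in \[0, 1\].
#'
#' @param beta probes x samples matrix.
#' @param annot probe annotation with `probe_id`, `design_type`.
#' @param min_per_class minimum probes per design class required to fit;
#'   below it the sample is skipped with a warning.
#' @param fit_subsample cap on the number of values used to *fit* each
#'   mixture (deterministic thinning); all values are still transformed.
#' @return matrix of the same shape, class-II values normalized.
#' @export
normalize_typeII <- function(beta, annot, min_per_class = 50L,
                             fit_subsample = 5000L) {
  idx <- match(rownames(beta), annot$probe_id)
  if (anyNA(idx)) stop("beta matrix contains probes absent from annotation",
                       call. = FALSE)
  type <- annot$design_type[idx]
  i1 <- which(type == "I")
  i2 <- which(type == "II")
  if (length(i1) < min_per_class || length(i2) < min_per_class) {
    warning("a design class has fewer than ", min_per_class,
            " probes; normalization skipped", call. = FALSE)
    return(beta)
  }
  thin <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= fit_subsample) return(v)
    v[round(seq(1L, length(v), length.out = fit_subsample))]
  }
  out <- beta
  for (j in seq_len(ncol(beta))) {
    f1 <- fit_beta_mixture(thin(beta[i1, j]))
    f2 <- fit_beta_mixture(thin(beta[i2, j]))
    ok <- !is.na(beta[i2, j])
    out[i2[ok], j] <- bmiq_map(beta[i2[ok], j], f2, f1)
  }
  out
}
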