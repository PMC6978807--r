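# Expression-level stages: detection filtering, TMM normalization, log-CPM,
# PCA, differential abundance, abundance ranking, set overlaps and cell-type
# attribution.

lib_sizes_of <- function(counts, lib_sizes = NULL) {
  if (!is.null(lib_sizes)) return(lib_sizes[colnames(counts)])
  if (inherits(counts, "mir_quantification")) return(counts$lib_sizes)
  colSums(counts)
}

counts_of <- function(counts) {
  if (inherits(counts, "mir_quantification")) counts$counts else counts
}

#' Counts per million on raw library sizes
#'
#' @param counts miRNA x sample matrix or `mir_quantification`.
#' @param lib_sizes optional per-sample library sizes (default: attached
#'   sizes, else column sums).
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  ls <- lib_sizes_of(counts, lib_sizes)
  m <- counts_of(counts)
  sweep(m, 2, ls, "/") * 1e6
}

#' Detection filter: CPM threshold in a minimum number of samples
#'
#' A miRNA is considered expressed if its CPM (computed on raw, pre-TMM
#' library sizes) reaches `cpm_threshold` in at least `min_samples` samples.
#'
#' @inheritParams cpm
#' @param cpm_threshold CPM detection threshold (default 1, i.e. log-CPM 0).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 6).
#' @return the filtered count matrix (library sizes carried in attribute
#'   `lib_sizes`).
#' @export
detection_filter <- function(counts, cpm_threshold = 1, min_samples = 6L,
                             lib_sizes = NULL) {
  ls <- lib_sizes_of(counts, lib_sizes)
  m <- counts_of(counts)
  if (min_samples > ncol(m))
    stop("min_samples exceeds the number of samples")
  if (any(ls <= 0)) stop("library sizes must be positive")
  keep <- rowSums(cpm(m, ls) >= cpm_threshold) >= min_samples
  out <- m[keep, , drop = FALSE]
  attr(out, "lib_sizes") <- ls
  out
}

#' TMM normalization factors
#'
#' Scaling factors by the trimmed mean of M-values: the reference sample is
#' the one whose upper-quartile count fraction is closest to the mean of
#' those; per sample, gene-wise M (log2 ratio of count fractions versus the
#' reference) and A (mean log2 abundance) are computed over genes nonzero in
#' both, the extreme 30% of M and 5% of A are trimmed, and the factor is two
#' to the precision-weighted mean of the remaining M-values, with weights the
#' inverse asymptotic binomial variances.  Factors are rescaled to geometric
#' mean 1.
#'
#' @inheritParams cpm
#' @param trim_M,trim_A two-sided trim fractions for M and A.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05,
                        lib_sizes = NULL) {
  m <- counts_of(counts)
  ls <- lib_sizes_of(counts, lib_sizes)
  if (ncol(m) < 2L) stop("TMM needs at least two samples")
  if (any(colSums(m) == 0)) stop("a sample has no counts")
  uq <- apply(m, 2, function(x) quantile(x, 0.75)) / ls
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j)
    tmm_pair(m[, j], m[, ref], ls[j], ls[ref], trim_M, trim_A), numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

# One TMM factor: sample obs against reference ref.
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) stop("sample shares no expressed genes with the reference")
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  f <- 2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  if (!is.finite(f)) 1 else f
}

#' log2 counts per million with TMM-effective library sizes
#'
#' log2((count + prior) / (library_size * factor + 2 * prior) * 1e6).
#'
#' @inheritParams cpm
#' @param factors TMM factors from [tmm_factors()] (default: all 1).
#' @param prior_count pseudo-count added to each count.
#' @return list of class `mir_norm`: `log_cpm` matrix, `tmm_factors`,
#'   `lib_sizes`, `prior_count`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5,
                    lib_sizes = NULL) {
  m <- counts_of(counts)
  ls <- lib_sizes_of(counts, lib_sizes)
  if (is.null(factors)) factors <- setNames(rep(1, ncol(m)), colnames(m))
  eff <- ls * factors[colnames(m)]
  lc <- log2(sweep(m + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
  structure(list(log_cpm = lc, tmm_factors = factors, lib_sizes = ls,
                 prior_count = prior_count), class = "mir_norm")
}

norm_matrix <- function(x) if (inherits(x, "mir_norm")) x$log_cpm else x

#' PCA of samples on row-centered log-CPM
#'
#' @param normalized a `mir_norm` or log-CPM matrix (miRNA x sample).
#' @param n_components number of components to return.
#' @return list: `coordinates` (sample x PC tibble), `variance_explained`
#'   (fractions), `sdev`.
#' @export
pca_samples <- function(normalized, n_components = 5L) {
  lc <- norm_matrix(normalized)
  if (ncol(lc) < 3L) stop("PCA needs at least three samples")
  centered <- lc - rowMeans(lc)
  if (all(abs(centered) < 1e-12)) {
    k <- min(n_components, ncol(lc))
    coord <- as.data.frame(matrix(0, ncol(lc), k))
    names(coord) <- paste0("PC", seq_len(k))
    coord <- dplyr::mutate(as_tibble(coord), sample_id = colnames(lc),
                           .before = 1)
    return(list(coordinates = coord, variance_explained = rep(0, k),
                sdev = rep(0, k)))
  }
  p <- prcomp(t(centered), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  ve <- p$sdev^2 / sum(p$sdev^2)
  coord <- as_tibble(as.data.frame(p$x[, seq_len(k), drop = FALSE]))
  coord <- dplyr::mutate(coord, sample_id = colnames(lc), .before = 1)
  list(coordinates = coord, variance_explained = ve[seq_len(k)],
       sdev = p$sdev[seq_len(k)])
}

# Welch t-test returning (p, stat); handles degenerate zero-variance cases:
# both groups constant and equal -> p = 1; constant but unequal -> smallest
# positive double, flagged downstream by the caller via p attribute.
welch_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(c(NA_real_, NA_real_))
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(c(1, 0))
    return(c(.Machine$double.xmin, Inf))
  }
  se2 <- vx / length(x) + vy / length(y)
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  c(2 * pt(-abs(stat), df), stat)
}

#' Differential abundance between groups at one timepoint
#'
#' Per miRNA, a two-sided Welch (unequal-variance) t-test on log-CPM between
#' the two contrast groups; log2 fold-change is the difference of group
#' means.  The primary "differential" flag uses the unadjusted p < alpha
#' rule; a BH-adjusted flag is also reported.
#'
#' @param normalized a `mir_norm` or log-CPM matrix.
#' @param design a `sample_design` covering the matrix columns.
#' @param contrast character(2): (numerator group, denominator group),
#'   e.g. `c("KA", "control")`.
#' @param timepoint restrict to one timepoint (NULL = all samples).
#' @param method restrict to one isolation method (NULL = all).
#' @param alpha unadjusted significance threshold (default 0.05).
#' @return tibble: mature_id, log2fc, p_value, q_value, differential,
#'   differential_bh, comparison.
#' @export
differential_expression <- function(normalized, design,
                                    contrast = c("KA", "control"),
                                    timepoint = NULL, method = NULL,
                                    alpha = 0.05) {
  lc <- norm_matrix(normalized)
  design <- validate_design(design)
  d <- design[design$sample_id %in% colnames(lc), ]
  if (!is.null(timepoint)) d <- d[d$timepoint %in% timepoint, ]
  if (!is.null(method)) d <- d[d$method %in% method, ]
  g1 <- d$sample_id[d$group == contrast[1]]
  g2 <- d$sample_id[d$group == contrast[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each side of the contrast needs at least two samples")
  x1 <- lc[, g1, drop = FALSE]
  x2 <- lc[, g2, drop = FALSE]
  res <- t(vapply(seq_len(nrow(lc)),
                  function(i) welch_p(x1[i, ], x2[i, ]), numeric(2)))
  lab <- paste0(contrast[1], "-vs-", contrast[2],
                if (!is.null(timepoint)) paste0("@", paste(timepoint, collapse = "+")),
                if (!is.null(method)) paste0("/", paste(method, collapse = "+")))
  tibble(mature_id = rownames(lc),
         log2fc = unname(rowMeans(x1) - rowMeans(x2)),
         t_stat = res[, 2],
         p_value = res[, 1],
         q_value = p.adjust(res[, 1], "BH"),
         differential = res[, 1] < alpha,
         differential_bh = p.adjust(res[, 1], "BH") < alpha,
         zero_variance = res[, 2] %in% c(0, Inf) & res[, 1] < 1,
         comparison = lab)
}

#' Rank miRNAs by mean abundance; flag the top set common to all samples
#'
#' @param normalized a `mir_norm` or log-CPM matrix.
#' @param counts the (filtered) count matrix used for detection.
#' @param top_n size of the head of the ranking to inspect.
#' @param cpm_threshold per-sample detection threshold used for the
#'   "common to all samples" flag.
#' @param lib_sizes optional library sizes for the detection CPM.
#' @return tibble ranked by mean log-CPM: mature_id, mean_log_cpm, rank,
#'   in_top, common (detected in every sample among the top_n).
#' @export
abundance_ranking <- function(normalized, counts, top_n = 20L,
                              cpm_threshold = 1, lib_sizes = NULL) {
  lc <- norm_matrix(normalized)
  if (top_n > nrow(lc)) {
    warning("top_n exceeds the number of miRNAs; returning all")
    top_n <- nrow(lc)
  }
  detected <- cpm(counts_of(counts), lib_sizes_of(counts, lib_sizes)) >=
    cpm_threshold
  mean_lc <- rowMeans(lc)
  ord <- order(-mean_lc)
  tb <- tibble(mature_id = rownames(lc)[ord],
               mean_log_cpm = mean_lc[ord],
               rank = seq_along(ord))
  tb$in_top <- tb$rank <= top_n
  everywhere <- rowSums(detected) == ncol(detected)
  tb$common <- tb$in_top & everywhere[match(tb$mature_id, rownames(detected))]
  tb
}

#' Two-set overlap (Venn partition)
#'
#' @param set_a,set_b character vectors of mature ids.
#' @return list: counts `only_a`, `common`, `only_b` and the membership
#'   vectors.
#' @export
set_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  common <- intersect(set_a, set_b)
  list(only_a = length(setdiff(set_a, common)),
       common = length(common),
       only_b = length(setdiff(set_b, common)),
       members = list(only_a = setdiff(set_a, common), common = common,
                      only_b = setdiff(set_b, common)))
}

#' Attribute miRNAs to cell types via marker reference lists
#'
#' Each miRNA is labeled with every list containing it; the exclusive
#' summary counts single-membership miRNAs per list, multi-membership ones
#' as "ambiguous" and absent ones as "unassigned".
#'
#' @param mirnas character vector of mature ids.
#' @param reference_lists list of reference lists as returned by
#'   [read_reference_list()] (or any named list of character vectors).
#' @return list: `assignments` tibble (mature_id, lists, n_lists, label) and
#'   `summary` named counts.
#' @export
attribute_cell_types <- function(mirnas, reference_lists) {
  mirnas <- unique(mirnas)
  sets <- lapply(reference_lists, function(l)
    if (is.list(l)) l$members else l)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(reference_lists, function(l)
      if (is.list(l)) l$list_id else stop("unnamed reference list"),
      character(1))
  membership <- vapply(sets, function(s) mirnas %in% s,
                       logical(length(mirnas)))
  membership <- matrix(membership, nrow = length(mirnas),
                       dimnames = list(mirnas, names(sets)))
  n_lists <- rowSums(membership)
  label <- ifelse(n_lists == 0L, "unassigned",
                  ifelse(n_lists > 1L, "ambiguous",
                         colnames(membership)[max.col(membership,
                                                      ties.method = "first")]))
  counts <- c(table(factor(label,
                           levels = c(colnames(membership), "ambiguous",
                                      "unassigned"))))
  list(assignments = tibble(
    mature_id = mirnas,
    lists = unname(apply(membership, 1, function(z)
      paste(colnames(membership)[z], collapse = ","))),
    n_lists = unname(as.integer(n_lists)),
    label = unname(label)),
    summary = counts)
}
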