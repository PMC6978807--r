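# Editing-site detection with a binomial sequencing-error null model.
#
# For each (sample, miRNA, mature position, substitution) the modification
# read count k is tested against Binomial(n, p_err), where n is the miRNA's
# total read count in that sample and p_err the expected per-base miscall
# rate (0.01, the Phred-20 error probability).  P-values are BH-adjusted
# within each sample; significant modifications replicated in at least two
# samples of a (group, timepoint) cell within one isolation method become
# edited sites.  Editing levels are k/n; group differences are tested by
# Welch t-tests with BH adjustment across sites.

#' Upper-tail binomial probability P(X >= k)
#'
#' Exact survival-function formulation, numerically stable for large n.
#'
#' @param k observed modification read count(s).
#' @param n total read count(s).
#' @param p_err null miscall probability.
#' @return P(X >= k) with X ~ Binomial(n, p_err); 1 when k = 0.
#' @export
binomial_tail <- function(k, n, p_err = 0.01) {
  if (any(k < 0 | n < 0 | k > n)) stop("need 0 <= k <= n")
  if (any(p_err <= 0 | p_err >= 1)) stop("need 0 < p_err < 1")
  pbinom(k - 1, n, p_err, lower.tail = FALSE)
}

#' Phred quality score to error probability
#'
#' @param q Phred score(s); Q20 corresponds to 0.01.
#' @return 10^(-q/10).
#' @export
phred_to_error <- function(q) 10^(-q / 10)

#' Test every observed modification against the sequencing-error null
#'
#' Per sample: miRNAs with total read count below `min_count` are dropped;
#' each remaining (miRNA, position, substitution) entry of the modification
#' table is tested with [binomial_tail()]; p-values are BH-adjusted within
#' the sample (optionally pooled across samples) and flagged at `fdr`.
#'
#' @param modifications long tibble (sample_id, mature_id, position, ref_nt,
#'   obs_nt, count) as produced by [quantify_samples()].
#' @param counts miRNA x sample count matrix (or `mir_quantification`).
#' @param min_count minimum miRNA read count for a sample to be testable.
#' @param p_err null miscall probability.
#' @param fdr BH threshold for calling a modification significant.
#' @param scope `"per_sample"` (default) adjusts within each sample;
#'   `"pooled"` adjusts across all samples at once.
#' @return tibble of modification tests: sample_id, mature_id, position,
#'   substitution, k, n, p_value, q_value, significant.
#' @export
call_sample_modifications <- function(modifications, counts, min_count = 10L,
                                      p_err = 0.01, fdr = 0.05,
                                      scope = c("per_sample", "pooled")) {
  scope <- match.arg(scope)
  m <- counts_of(counts)
  mods <- as_tibble(modifications)
  if (!nrow(mods)) {
    return(tibble(sample_id = character(), mature_id = character(),
                  position = integer(), substitution = character(),
                  k = integer(), n = integer(), p_value = numeric(),
                  q_value = numeric(), significant = logical()))
  }
  idx <- cbind(match(mods$mature_id, rownames(m)),
               match(mods$sample_id, colnames(m)))
  if (anyNA(idx))
    stop("modification entry without a matching count (unknown miRNA or sample)")
  mods$n <- as.integer(m[idx])
  if (any(mods$count > mods$n))
    stop("modification count exceeds the miRNA read count")
  mods <- mods[mods$n >= min_count, , drop = FALSE]
  out <- tibble(sample_id = mods$sample_id,
                mature_id = mods$mature_id,
                position = as.integer(mods$position),
                substitution = paste0(mods$ref_nt, ">", mods$obs_nt),
                k = as.integer(mods$count),
                n = mods$n)
  out$p_value <- binomial_tail(out$k, out$n, p_err)
  out$q_value <- if (scope == "per_sample") {
    stats::ave(out$p_value, out$sample_id,
               FUN = function(p) p.adjust(p, "BH"))
  } else p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < fdr
  out
}

#' Replication filter: keep sites significant in enough samples of one cell
#'
#' A (miRNA, position, substitution) site is kept if, within at least one
#' isolation method, it is significant in at least `min_samples` samples of
#' at least one (group, timepoint) cell.  The stricter reading — replication
#' required in every (group, timepoint) cell of some method — is available
#' via `rule = "all_cells"`.
#'
#' @param tests output of [call_sample_modifications()].
#' @param design a `sample_design` covering all flagged samples.
#' @param min_samples replication threshold per cell (default 2).
#' @param rule `"any_cell"` (default) or `"all_cells"`.
#' @return tibble of candidate sites: mature_id, position, substitution,
#'   plus per-(method, group, timepoint) significant-sample counts in
#'   `cell_counts` (a nested tibble attribute-free long summary is returned
#'   in `$cells`).
#' @export
replication_filter <- function(tests, design, min_samples = 2L,
                               rule = c("any_cell", "all_cells")) {
  rule <- match.arg(rule)
  design <- validate_design(design)
  sig <- tests[tests$significant, , drop = FALSE]
  empty <- tibble(mature_id = character(), position = integer(),
                  substitution = character())
  if (!nrow(sig)) return(structure(empty, cells = tibble()))
  missing <- setdiff(sig$sample_id, design$sample_id)
  if (length(missing))
    stop("flagged sample(s) absent from design: ",
         paste(missing, collapse = ", "))
  sig <- dplyr::left_join(sig, design, by = "sample_id")
  cells <- dplyr::summarise(
    dplyr::group_by(sig, .data$mature_id, .data$position,
                    .data$substitution, .data$method, .data$group,
                    .data$timepoint),
    n_significant = dplyr::n(), .groups = "drop")
  per_method <- dplyr::summarise(
    dplyr::group_by(cells, .data$mature_id, .data$position,
                    .data$substitution, .data$method),
    max_cell = max(.data$n_significant),
    n_cells_replicated = sum(.data$n_significant >= min_samples),
    .groups = "drop")
  n_cells_total <- nrow(unique(design[, c("group", "timepoint")]))
  keep <- if (rule == "any_cell") {
    per_method$max_cell >= min_samples
  } else {
    per_method$n_cells_replicated >= n_cells_total
  }
  sites <- unique(per_method[keep, c("mature_id", "position",
                                     "substitution")])
  sites <- dplyr::arrange(sites, .data$mature_id, .data$position)
  structure(sites, cells = cells)
}

#' Per-sample editing levels for candidate sites
#'
#' The editing level is k / n: the read count of the non-reference
#' modification over the miRNA's total read count in that sample.  Samples
#' where the miRNA has fewer than `min_count` reads get a missing level;
#' samples with enough reads but no modified reads get level 0.
#'
#' @param sites tibble with mature_id, position, substitution (e.g. from
#'   [replication_filter()]).
#' @param modifications long modification table from [quantify_samples()].
#' @param counts count matrix or `mir_quantification`.
#' @param min_count minimum read count for a defined level.
#' @return long tibble: mature_id, position, substitution, sample_id, k, n,
#'   level.
#' @export
editing_levels <- function(sites, modifications, counts, min_count = 10L) {
  m <- counts_of(counts)
  if (!nrow(sites)) {
    return(tibble(mature_id = character(), position = integer(),
                  substitution = character(), sample_id = character(),
                  k = integer(), n = integer(), level = numeric()))
  }
  grid <- tidyr::crossing(sites[, c("mature_id", "position", "substitution")],
                          sample_id = colnames(m))
  mods <- as_tibble(modifications)
  mods$substitution <- paste0(mods$ref_nt, ">", mods$obs_nt)
  grid <- dplyr::left_join(
    grid,
    mods[, c("sample_id", "mature_id", "position", "substitution", "count")],
    by = c("sample_id", "mature_id", "position", "substitution"))
  grid$k <- ifelse(is.na(grid$count), 0L, grid$count)
  grid$count <- NULL
  grid$n <- as.integer(m[cbind(match(grid$mature_id, rownames(m)),
                               match(grid$sample_id, colnames(m)))])
  grid$level <- ifelse(grid$n >= min_count, grid$k / grid$n, NA_real_)
  grid
}

#' Summarise editing levels per (group, timepoint)
#'
#' Median and interquartile range of the per-sample levels, the style of a
#' boxplot panel.
#'
#' @param levels output of [editing_levels()].
#' @param design a `sample_design`.
#' @return tibble with median_level, iqr_level, n_samples per site and cell.
#' @export
summarise_editing <- function(levels, design) {
  design <- validate_design(design)
  x <- dplyr::left_join(levels, design, by = "sample_id")
  dplyr::summarise(
    dplyr::group_by(x, .data$mature_id, .data$position, .data$substitution,
                    .data$group, .data$timepoint),
    median_level = median(.data$level, na.rm = TRUE),
    iqr_level = IQR(.data$level, na.rm = TRUE),
    n_samples = sum(!is.na(.data$level)), .groups = "drop")
}

#' Differential editing between groups at each timepoint
#'
#' Unpaired two-sided Welch t-tests on per-sample editing levels, BH
#' adjustment across sites within each timepoint contrast.
#'
#' @param levels output of [editing_levels()].
#' @param design a `sample_design`.
#' @param contrast character(2): (group 1, group 2).
#' @param fdr significance threshold on BH-adjusted p-values.
#' @return tibble: site columns, timepoint, mean levels per group, diff_p,
#'   diff_q, significant, n per side; sites with fewer than two defined
#'   levels on a side carry NA p-values.
#' @export
differential_editing <- function(levels, design,
                                 contrast = c("KA", "control"), fdr = 0.05) {
  design <- validate_design(design)
  x <- dplyr::left_join(levels, design, by = "sample_id")
  x <- x[x$group %in% contrast, , drop = FALSE]
  res <- dplyr::summarise(
    dplyr::group_by(x, .data$mature_id, .data$position, .data$substitution,
                    .data$timepoint),
    mean_level_1 = mean(.data$level[.data$group == contrast[1]], na.rm = TRUE),
    mean_level_2 = mean(.data$level[.data$group == contrast[2]], na.rm = TRUE),
    n_1 = sum(!is.na(.data$level[.data$group == contrast[1]])),
    n_2 = sum(!is.na(.data$level[.data$group == contrast[2]])),
    diff_p = welch_p(.data$level[.data$group == contrast[1] &
                                   !is.na(.data$level)],
                     .data$level[.data$group == contrast[2] &
                                   !is.na(.data$level)])[1],
    .groups = "drop")
  insufficient <- res$n_1 < 2L | res$n_2 < 2L
  if (any(insufficient))
    message(sum(insufficient),
            " site-timepoint combination(s) skipped: fewer than two levels per side")
  res$diff_q <- stats::ave(res$diff_p, res$timepoint,
                           FUN = function(p) p.adjust(p, "BH"))
  res$significant <- !is.na(res$diff_q) & res$diff_q < fdr
  res
}

#' Binomial seed-enrichment test
#'
#' Are edited sites concentrated in seed regions more than expected from the
#' seed's share of the mature length?  Upper-tail binomial test of
#' `n_in_seed` successes in `n_sites` trials at success probability
#' `seed_fraction`.
#'
#' @param n_sites total edited sites.
#' @param n_in_seed sites falling in seed regions.
#' @param seed_fraction expected fraction (default 1/3, roughly the seed's
#'   share of a mature miRNA; see [seed_fraction_of()] for a per-reference
#'   value).
#' @return the upper-tail p-value.
#' @export
seed_enrichment <- function(n_sites, n_in_seed, seed_fraction = 1 / 3) {
  stopifnot(n_in_seed >= 0, n_in_seed <= n_sites,
            seed_fraction > 0, seed_fraction <= 1)
  if (seed_fraction == 1) return(1)
  binomial_tail(n_in_seed, n_sites, seed_fraction)
}

#' Mean seed share of the mature length across a reference
#'
#' @param ref a `mirna_reference`.
#' @return mean of (seed length / mature length).
#' @export
seed_fraction_of <- function(ref) {
  mean((ref$seed_end - ref$seed_start + 1) /
         (ref$mature_end - ref$mature_start + 1))
}

#' Trinucleotide context of edited sites
#'
#' Per site, the (preceding, edited, following) nucleotides read off the
#' mature sequence, plus an aggregate position-frequency table of the three
#' positions (suitable for logo rendering).  Sites at the first or last
#' mature position get a one-sided context with the absent flank reported as
#' NA.
#'
#' @param sites tibble with mature_id, position, substitution.
#' @param reference a `mirna_reference`.
#' @return list: `contexts` tibble (site columns + preceding, edited,
#'   following) and `pfm` (3 x 4 count matrix over A/C/G/U).
#' @export
motif_context <- function(sites, reference) {
  reference <- validate_reference(reference)
  mats <- mature_seq(reference)
  if (!all(sites$mature_id %in% names(mats)))
    stop("site miRNA absent from reference")
  seqs <- unname(mats[sites$mature_id])
  L <- nchar(seqs)
  pos <- as.integer(sites$position)
  if (any(pos < 1L | pos > L)) stop("site position outside mature sequence")
  edited <- substr(seqs, pos, pos)
  ref_nt <- sub(">.*$", "", sites$substitution)
  if (any(edited != ref_nt))
    stop("substitution reference nucleotide disagrees with the mature sequence")
  preceding <- ifelse(pos > 1L, substr(seqs, pos - 1L, pos - 1L), NA)
  following <- ifelse(pos < L, substr(seqs, pos + 1L, pos + 1L), NA)
  ctx <- dplyr::mutate(as_tibble(sites),
                       preceding = preceding, edited = edited,
                       following = following)
  pfm <- rbind(
    preceding = table(factor(preceding, levels = RNA_ALPHABET)),
    edited = table(factor(edited, levels = RNA_ALPHABET)),
    following = table(factor(following, levels = RNA_ALPHABET)))
  list(contexts = ctx, pfm = pfm)
}

#' Restrict sites to one substitution class and an optional whitelist
#'
#' The ADAR case is the default: inosine reads as G, so A-to-I editing
#' appears as A>G.  A whitelist (e.g. bona fide miRNA genes) drops sites on
#' miRNAs outside it.
#'
#' @param sites tibble with mature_id, position, substitution.
#' @param substitution substitution to keep (default "A>G").
#' @param whitelist optional character vector (or [read_reference_list()]
#'   result) of allowed mature ids.
#' @return filtered sites tibble.
#' @export
restrict_sites <- function(sites, substitution = "A>G", whitelist = NULL) {
  out <- sites[sites$substitution == substitution, , drop = FALSE]
  if (!is.null(whitelist)) {
    wl <- if (is.list(whitelist)) whitelist$members else whitelist
    if (!length(wl)) {
      warning("empty whitelist: all sites dropped")
      return(out[0, , drop = FALSE])
    }
    out <- out[out$mature_id %in% wl, , drop = FALSE]
  }
  out
}

#' Annotate candidate sites with seed membership
#'
#' @param sites tibble with mature_id, position.
#' @param reference a `mirna_reference`.
#' @return `sites` with a logical `in_seed` column.
#' @export
annotate_seed <- function(sites, reference) {
  sites$in_seed <- if (nrow(sites))
    in_seed(reference, sites$mature_id, sites$position) else logical()
  sites
}
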