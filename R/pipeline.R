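# End-to-end orchestration: simulate -> quantify -> expression -> editing,
# with a bundled desk-scale fixture mirroring the study design (three
# replicate libraries per {control, KA} x {24 h, 2 wk} cell, isolated by
# ultracentrifugation and by precipitation kit).

#' Generate a random miRNA reference
#'
#' Random hairpins with an embedded mature window; mature sequences are
#' pairwise-distinct so ungapped assignment is unambiguous at desk scale.
#'
#' @param n_mirnas number of miRNA genes.
#' @param seed integer seed.
#' @param mature_length range of mature lengths to sample from.
#' @param flank range of flank lengths on each side of the mature window.
#' @return a `mirna_reference`.
#' @export
generate_reference <- function(n_mirnas = 50L, seed = 1L,
                               mature_length = 20:23, flank = 6:12) {
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  withr::with_seed(seed, {
    repeat {
      mlen <- resample(mature_length, n_mirnas)
      mats <- vapply(mlen, function(L)
        paste(sample(RNA_ALPHABET, L, replace = TRUE), collapse = ""),
        character(1))
      if (!anyDuplicated(mats)) break
    }
    lflank <- resample(flank, n_mirnas)
    rflank <- resample(flank, n_mirnas)
    hp <- vapply(seq_len(n_mirnas), function(i) paste0(
      paste(sample(RNA_ALPHABET, lflank[i], replace = TRUE), collapse = ""),
      mats[i],
      paste(sample(RNA_ALPHABET, rflank[i], replace = TRUE), collapse = "")),
      character(1))
    mirna_reference(
      gene_id = sprintf("syn-mir-%03d", seq_len(n_mirnas)),
      hairpin_seq = hp,
      mature_id = sprintf("syn-miR-%03d-3p", seq_len(n_mirnas)),
      mature_start = lflank + 1L,
      mature_end = lflank + mlen)
  })
}

#' Build the bundled toy fixture
#'
#' A 50-miRNA reference and the full factorial design (3 replicates x
#' {control, KA} x {24h, 2wk} x {UC, kit} = 24 libraries), with three
#' planted A>G edits — one in a seed region, one outside, one differential
#' between groups — and four planted differentially expressed miRNAs
#' (two up, two down, 4-fold).
#'
#' @param seed integer seed driving reference, abundances and libraries.
#' @param n_mirnas reference size.
#' @param library_size_mean expected reads per library.
#' @param out_dir if non-NULL, reference/design/FASTQ/truth files are
#'   written there.
#' @return list: `reference`, `design`, `config`, `truth` (planted edits and
#'   DE), and if simulated here, nothing else — pass to [run_pipeline()].
#' @export
make_fixture <- function(seed = 1L, n_mirnas = 50L,
                         library_size_mean = 5e4, out_dir = NULL) {
  reference <- generate_reference(n_mirnas, seed = seed)
  design <- simulate_design(3L)
  mats <- mature_seq(reference)

  withr::with_seed(seed + 2L, {
    abundances <- setNames(rlnorm(n_mirnas, 0, 1.5), reference$mature_id)
    rich <- names(sort(abundances, decreasing = TRUE))
    # pick edit hosts among the most abundant miRNAs so levels are
    # well-estimated at desk-scale depth
    pos_of <- function(id, window) {
      s <- mats[[id]]
      hits <- which(strsplit(s, "")[[1]] == "A")
      hits <- intersect(hits, window)
      if (length(hits)) hits[1] else NA_integer_
    }
    seed_host <- non_seed_host <- diff_host <- NULL
    seed_pos <- non_seed_pos <- diff_pos <- NA_integer_
    for (id in rich) {
      L <- nchar(mats[[id]])
      if (is.null(seed_host) && !is.na(p <- pos_of(id, 2:8))) {
        seed_host <- id; seed_pos <- p
      } else if (is.null(non_seed_host) &&
                 !is.na(p <- pos_of(id, 9:(L - 1L)))) {
        non_seed_host <- id; non_seed_pos <- p
      } else if (is.null(diff_host) && !is.na(p <- pos_of(id, 2:(L - 1L)))) {
        diff_host <- id; diff_pos <- p
      }
      if (!is.null(seed_host) && !is.null(non_seed_host) &&
          !is.null(diff_host)) break
    }
    if (is.null(seed_host) || is.null(non_seed_host) || is.null(diff_host))
      stop("fixture reference lacks adenosines in the required windows")
    edits <- dplyr::bind_rows(
      planted_edit(design, seed_host, seed_pos, level = 0.30),
      planted_edit(design, non_seed_host, non_seed_pos, level = 0.40),
      planted_edit(design, diff_host, diff_pos,
                   level = c(control = 0.05, KA = 0.50)))
    de_hosts <- setdiff(rich, c(seed_host, non_seed_host, diff_host))[1:4]
    de <- tibble(mature_id = de_hosts,
                 log2fc = c(2, 2, -2, -2),
                 timepoint = c("24h", "2wk", "24h", "2wk"))
  })

  config <- simulation_config(design, seed = seed,
                              library_size_mean = library_size_mean,
                              planted_edits = edits, planted_de = de,
                              abundances = abundances)
  truth <- list(
    edits = unique(edits[, c("mature_id", "position", "from_nt", "to_nt")]),
    differential_edit = tibble(mature_id = diff_host, position = diff_pos),
    seed_edit = tibble(mature_id = seed_host, position = seed_pos),
    de = de)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reference(reference, file.path(out_dir, "reference.fa"),
                    file.path(out_dir, "reference.tsv"))
    write.table(design, file.path(out_dir, "design.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(reference = reference, design = design, config = config,
       truth = truth)
}

#' Run the full pipeline on a reference + simulation config
#'
#' Simulates libraries (unless reads are supplied), quantifies them,
#' applies the expression stages (detection filter at CPM >= 1 in >= 6
#' samples, TMM, log-CPM, PCA, Welch differential abundance per timepoint),
#' and the editing stages (binomial error-model tests at p_err, BH within
#' sample, replication filter, A>G restriction, seed and motif annotation,
#' differential-editing tests).
#'
#' @param reference a `mirna_reference`.
#' @param config a `sim_config` (its design drives all contrasts).
#' @param reads optional named list of per-sample read vectors or FASTQ
#'   paths; when NULL, libraries are simulated from `config`.
#' @param params list of stage parameters overriding the defaults
#'   (`cpm_threshold`, `min_detect_samples`, `min_count`, `p_err`, `fdr`,
#'   `min_rep_samples`, `max_mismatches`, `start_slack`, `alpha`).
#' @param out_dir if non-NULL, all stage outputs and a `run_report.json`
#'   are written there.
#' @return list with elements `quant`, `filtered`, `norm`, `pca`, `de`,
#'   `ranking`, `overlap`, `tests`, `sites`, `levels`, `diff_editing`,
#'   `motif`, `seed_enrichment_p`, `truth_reads`.
#' @export
run_pipeline <- function(reference, config, reads = NULL, params = list(),
                         out_dir = NULL) {
  p <- utils::modifyList(list(
    cpm_threshold = 1, min_detect_samples = 6L, min_count = 10L,
    p_err = 0.01, fdr = 0.05, min_rep_samples = 2L,
    max_mismatches = 2L, start_slack = 2L, alpha = 0.05,
    prior_count = 0.5), params)
  design <- config$design

  truth <- NULL
  if (is.null(reads)) {
    sim <- simulate_counts(config, reference)
    truth <- emit_reads(sim, config, reference)
    reads <- truth$reads
  }
  quant <- quantify_samples(reads, reference,
                            max_mismatches = p$max_mismatches,
                            start_slack = p$start_slack)

  filtered <- detection_filter(quant, cpm_threshold = p$cpm_threshold,
                               min_samples = p$min_detect_samples)
  factors <- tmm_factors(filtered,
                         lib_sizes = attr(filtered, "lib_sizes"))
  norm <- log_cpm(filtered, factors, prior_count = p$prior_count,
                  lib_sizes = attr(filtered, "lib_sizes"))
  pca <- pca_samples(norm)
  timepoints <- unique(design$timepoint)
  de <- dplyr::bind_rows(lapply(timepoints, function(tp)
    differential_expression(norm, design, timepoint = tp, alpha = p$alpha)))
  ranking <- abundance_ranking(norm, filtered, top_n = 20L,
                               cpm_threshold = p$cpm_threshold,
                               lib_sizes = attr(filtered, "lib_sizes"))

  # per-method detected sets, as in the UC / kit comparison
  methods <- unique(design$method)
  overlap <- NULL
  if (length(methods) == 2L) {
    det <- lapply(methods, function(me) {
      smp <- design$sample_id[design$method == me]
      ms <- min(p$min_detect_samples, length(smp))
      rownames(detection_filter(quant$counts[, smp, drop = FALSE],
                                cpm_threshold = p$cpm_threshold,
                                min_samples = ms,
                                lib_sizes = quant$lib_sizes[smp]))
    })
    overlap <- set_overlap(det[[1]], det[[2]])
  }

  tests <- call_sample_modifications(quant$modifications, quant,
                                     min_count = p$min_count,
                                     p_err = p$p_err, fdr = p$fdr)
  sites <- replication_filter(tests, design,
                              min_samples = p$min_rep_samples)
  sites <- restrict_sites(sites, "A>G")
  sites <- annotate_seed(sites, reference)
  levels <- editing_levels(sites, quant$modifications, quant,
                           min_count = p$min_count)
  diff_ed <- differential_editing(levels, design, fdr = p$fdr)
  motif <- if (nrow(sites)) motif_context(sites, reference) else NULL
  seed_p <- if (nrow(sites))
    seed_enrichment(nrow(sites), sum(sites$in_seed)) else NA_real_

  report <- list(quant = quant, filtered = filtered, tmm_factors = factors,
                 norm = norm, pca = pca, de = de, ranking = ranking,
                 overlap = overlap, tests = tests, sites = sites,
                 levels = levels, diff_editing = diff_ed, motif = motif,
                 seed_enrichment_p = seed_p, truth_reads = truth,
                 params = p)
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_quantification(report$quant, out_dir)
  wr <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  nm <- cbind(mature_id = rownames(report$norm$log_cpm),
              as.data.frame(report$norm$log_cpm))
  wr(nm, "normalized.tsv")
  wr(report$de, "de_results.tsv")
  wr(report$pca$coordinates, "pca.tsv")
  wr(report$ranking, "ranking.tsv")
  wr(report$tests, "modification_tests.tsv")
  wr(report$sites, "edited_sites.tsv")
  wr(report$levels, "editing_levels.tsv")
  wr(report$diff_editing, "differential_editing.tsv")
  if (!is.null(report$motif)) {
    pfm <- cbind(flank = rownames(report$motif$pfm),
                 as.data.frame(unclass(report$motif$pfm)))
    wr(pfm, "motif_pfm.tsv")
  }
  summary <- list(
    n_detected = nrow(report$filtered),
    tmm_factors = as.list(report$tmm_factors),
    n_de = if (nrow(report$de)) sum(report$de$differential) else 0L,
    overlap = if (!is.null(report$overlap))
      report$overlap[c("only_a", "common", "only_b")] else NULL,
    n_edited_sites = nrow(report$sites),
    n_seed_sites = if (nrow(report$sites)) sum(report$sites$in_seed) else 0L,
    seed_enrichment_p = report$seed_enrichment_p,
    n_diff_edited = if (nrow(report$diff_editing))
      sum(report$diff_editing$significant) else 0L,
    params = report$params)
  jsonlite::write_json(summary, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
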