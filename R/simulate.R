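# Small-RNA library simulator.
#
# Emulates the statistical structure the downstream analysis assumes:
# log-normal relative miRNA abundances shared across samples, mild per-sample
# biological noise, negative-binomial library sizes, multinomial read counts,
# planted fold-changes in the treated group, planted A>G (or any) editing at
# chosen mature positions and levels, and independent per-base sequencing
# miscalls at a fixed rate (default 0.01, i.e. Phred 20).  Every run is fully
# reproducible from the config seed and emits ground truth for all planted
# signals.

#' Build a simulation configuration
#'
#' @param design a `sample_design` tibble (see [simulate_design()]).
#' @param seed integer seed; all randomness of the simulation derives from it.
#' @param library_size_mean expected reads per library.
#' @param library_size_dispersion negative-binomial size parameter of the
#'   library-size distribution (larger = tighter).
#' @param abundance_logmean,abundance_logsd natural-log-space parameters of
#'   the per-miRNA relative abundance distribution (drawn once per miRNA and
#'   shared across samples).
#' @param sample_logsd natural-log SD of per-sample, per-miRNA biological
#'   noise multipliers (0.2 approximates replicate variability of pooled
#'   libraries; 0 disables it).
#' @param per_base_error probability that any sequenced base is miscalled,
#'   uniformly to one of the other three nucleotides.
#' @param planted_edits tibble with columns `mature_id`, `position`,
#'   `from_nt`, `to_nt`, `group`, `timepoint`, `level` — the editing level of
#'   that site in samples of that (group, timepoint) cell. See
#'   [planted_edit()].
#' @param planted_de tibble with columns `mature_id`, `log2fc`, `timepoint`:
#'   the fold-change applied to KA-group samples at that timepoint (use
#'   `timepoint = NA` for all timepoints).
#' @param de_group the design group receiving the planted fold-changes.
#' @param abundances optional named numeric vector of fixed relative
#'   abundances (one per reference miRNA), bypassing the log-normal draw.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(design,
                              seed = 1L,
                              library_size_mean = 2e5,
                              library_size_dispersion = 20,
                              abundance_logmean = 0,
                              abundance_logsd = 1.5,
                              sample_logsd = 0.2,
                              per_base_error = 0.01,
                              planted_edits = NULL,
                              planted_de = NULL,
                              de_group = "KA",
                              abundances = NULL) {
  design <- validate_design(design)
  stopifnot(per_base_error >= 0, per_base_error < 0.25,
            library_size_mean > 0, abundance_logsd >= 0, sample_logsd >= 0)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > .Machine$integer.max - 10L)
    stop("seed must be a (not too large) integer")
  if (!is.null(planted_edits)) {
    planted_edits <- as_tibble(planted_edits)
    stopifnot(all(c("mature_id", "position", "from_nt", "to_nt",
                    "group", "timepoint", "level") %in% names(planted_edits)))
    if (any(planted_edits$level < 0 | planted_edits$level > 1))
      stop("editing levels must lie in [0, 1]")
  }
  if (!is.null(planted_de)) {
    planted_de <- as_tibble(planted_de)
    stopifnot(all(c("mature_id", "log2fc", "timepoint") %in% names(planted_de)))
  }
  structure(list(design = design, seed = seed,
                 library_size_mean = library_size_mean,
                 library_size_dispersion = library_size_dispersion,
                 abundance_logmean = abundance_logmean,
                 abundance_logsd = abundance_logsd,
                 sample_logsd = sample_logsd,
                 per_base_error = per_base_error,
                 planted_edits = planted_edits,
                 planted_de = planted_de,
                 de_group = de_group,
                 abundances = abundances),
            class = "sim_config")
}

#' Expand a planted edit to every (group, timepoint) cell
#'
#' Convenience constructor: one editing event at a single level in all cells
#' (the no-differential-editing null), or at two levels to create
#' differential-editing truth.
#'
#' @param design a `sample_design`.
#' @param mature_id,position,from_nt,to_nt the site (mature coordinates).
#' @param level editing level for all cells, or a named vector
#'   `c(control = ..., KA = ...)` of per-group levels.
#' @return tibble in the `planted_edits` format of [simulation_config()].
#' @export
planted_edit <- function(design, mature_id, position, from_nt = "A",
                         to_nt = "G", level = 0.3) {
  cells <- unique(design[, c("group", "timepoint")])
  lev <- if (length(level) == 1L) rep(level, nrow(cells)) else {
    if (is.null(names(level))) stop("multi-valued level must be named by group")
    unname(level[cells$group])
  }
  tibble(mature_id = mature_id, position = as.integer(position),
         from_nt = from_nt, to_nt = to_nt,
         group = cells$group, timepoint = cells$timepoint, level = lev)
}

#' Build the study's factorial sample design
#'
#' Replicated libraries across {control, KA} x {24h, 2wk} x {UC, kit}.
#'
#' @param n_replicates biological replicates per cell (default 3).
#' @param groups,timepoints,methods factor levels.
#' @return a `sample_design` tibble.
#' @export
simulate_design <- function(n_replicates = 3L,
                            groups = c("control", "KA"),
                            timepoints = c("24h", "2wk"),
                            methods = c("UC", "kit")) {
  g <- expand.grid(replicate = seq_len(n_replicates), group = groups,
                   timepoint = timepoints, method = methods,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$group, g$timepoint, g$method,
                         g$replicate)
  validate_design(as_tibble(g[, c("sample_id", "group", "timepoint",
                                  "method", "replicate")]))
}

#' Simulate the true count matrix
#'
#' Relative abundances are drawn log-normal once per miRNA; planted
#' fold-changes multiply the abundance in treated samples at the stated
#' timepoint; per-sample biological noise multiplies each abundance; library
#' sizes are negative-binomial; counts are multinomial given the library
#' size.
#'
#' @param config a `sim_config`.
#' @param reference a `mirna_reference`.
#' @return list with `counts` (integer matrix, miRNA x sample), `lib_sizes`,
#'   `proportions` (expected per-sample proportions), and `true_de` (tibble of
#'   planted differential miRNAs).
#' @export
simulate_counts <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  reference <- validate_reference(reference)
  design <- config$design
  if (!is.null(config$planted_de)) {
    missing <- setdiff(config$planted_de$mature_id, reference$mature_id)
    if (length(missing))
      stop("planted_de names absent from reference: ",
           paste(missing, collapse = ", "))
  }
  withr::with_seed(config$seed, {
    n_mir <- nrow(reference)
    n_smp <- nrow(design)
    base <- if (!is.null(config$abundances)) {
      if (!all(reference$mature_id %in% names(config$abundances)))
        stop("fixed abundances must cover every reference miRNA")
      unname(config$abundances[reference$mature_id])
    } else {
      rlnorm(n_mir, config$abundance_logmean, config$abundance_logsd)
    }
    expected <- matrix(base, n_mir, n_smp,
                       dimnames = list(reference$mature_id, design$sample_id))
    if (!is.null(config$planted_de)) {
      for (r in seq_len(nrow(config$planted_de))) {
        pd <- config$planted_de[r, ]
        hit <- design$group == config$de_group &
          (is.na(pd$timepoint) | design$timepoint == pd$timepoint)
        i <- match(pd$mature_id, reference$mature_id)
        expected[i, hit] <- expected[i, hit] * 2^pd$log2fc
      }
    }
    if (config$sample_logsd > 0) {
      expected <- expected * matrix(rlnorm(n_mir * n_smp, 0, config$sample_logsd),
                                    n_mir, n_smp)
    }
    props <- sweep(expected, 2, colSums(expected), "/")
    lib <- rnbinom(n_smp, size = config$library_size_dispersion,
                   mu = config$library_size_mean)
    lib <- pmax(lib, 1L)
    counts <- matrix(0L, n_mir, n_smp,
                     dimnames = dimnames(expected))
    for (j in seq_len(n_smp))
      counts[, j] <- rmultinom(1, lib[j], props[, j])[, 1]
    true_de <- if (is.null(config$planted_de)) {
      tibble(mature_id = character(), timepoint = character(),
             log2fc = numeric(), direction = character())
    } else {
      tibble(mature_id = config$planted_de$mature_id,
             timepoint = config$planted_de$timepoint,
             log2fc = config$planted_de$log2fc,
             direction = ifelse(config$planted_de$log2fc >= 0, "up", "down"))
    }
    list(counts = counts, lib_sizes = setNames(as.numeric(lib),
                                               design$sample_id),
         proportions = props, true_de = true_de)
  })
}

#' Emit reads for each library
#'
#' Every read is the full mature sequence.  For a planted edit at level e in
#' a sample's (group, timepoint) cell, a Binomial(n, e) number of that
#' miRNA's reads carry the substitution before sequencing error; every base
#' is then independently miscalled with probability `per_base_error`,
#' uniformly to the other three nucleotides.  FASTQ qualities are constant
#' Phred 20.
#'
#' @param sim result of [simulate_counts()].
#' @param config the same `sim_config`.
#' @param reference the same `mirna_reference`.
#' @param out_dir if non-NULL, one FASTQ per sample plus ground-truth TSVs
#'   are written there.
#' @return list with `reads` (per-sample character vectors of read
#'   sequences), `true_counts`, `true_edits` (realized per-sample edited-read
#'   counts and fractions), and `config`.
#' @export
emit_reads <- function(sim, config, reference, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  reference <- validate_reference(reference)
  mats <- mature_seq(reference)
  design <- config$design
  pe <- config$planted_edits
  if (!is.null(pe)) {
    i <- match(pe$mature_id, reference$mature_id)
    if (anyNA(i)) stop("planted_edits names absent from reference")
    mlen <- reference$mature_end[i] - reference$mature_start[i] + 1L
    if (any(pe$position < 1L | pe$position > mlen))
      stop("planted edit position outside its mature sequence")
    ref_nt <- substr(mats[i], pe$position, pe$position)
    if (any(ref_nt != rna_string(pe$from_nt)))
      stop("planted edit from_nt does not match the reference nucleotide")
  }
  counts <- sim$counts
  reads <- vector("list", nrow(design))
  names(reads) <- design$sample_id
  true_edits <- vector("list", nrow(design))

  withr::with_seed(config$seed + 1L, {
    for (j in seq_len(nrow(design))) {
      smp <- design[j, ]
      n_per <- setNames(counts[, j], rownames(counts))
      rd <- rep(mats[rownames(counts)], times = n_per)
      # planted edits, before sequencing error
      edits_j <- tibble(mature_id = character(), position = integer(),
                        from_nt = character(), to_nt = character(),
                        k_true = integer(), n_true = integer())
      if (!is.null(pe)) {
        pe_j <- pe[pe$group == smp$group & pe$timepoint == smp$timepoint, ]
        if (nrow(pe_j)) {
          offset <- c(0L, cumsum(n_per))[match(pe_j$mature_id,
                                               rownames(counts))]
          for (r in seq_len(nrow(pe_j))) {
            n_i <- n_per[[pe_j$mature_id[r]]]
            k <- rbinom(1, n_i, pe_j$level[r])
            if (k > 0) {
              idx <- offset[r] + sample.int(n_i, k)
              rd <- substitute_bases_cpp(rd, idx,
                                         rep(pe_j$position[r], k),
                                         rep(rna_string(pe_j$to_nt[r]), k))
            }
            edits_j <- dplyr::bind_rows(edits_j, tibble(
              mature_id = pe_j$mature_id[r], position = pe_j$position[r],
              from_nt = pe_j$from_nt[r], to_nt = pe_j$to_nt[r],
              k_true = as.integer(k), n_true = as.integer(n_i)))
          }
        }
      }
      # sequencing miscalls: uniform over the other three nucleotides
      if (config$per_base_error > 0 && length(rd)) {
        lens <- nchar(rd)
        total <- sum(lens)
        n_mis <- rbinom(1, total, config$per_base_error)
        if (n_mis > 0) {
          flat <- sort(sample.int(total, n_mis))
          ends <- cumsum(lens)
          read_i <- findInterval(flat - 1L, ends) + 1L
          pos_i <- flat - c(0L, ends)[read_i]
          old <- substr(rd[read_i], pos_i, pos_i)
          alt <- matrix(c("C", "G", "U",  "A", "G", "U",
                          "A", "C", "U",  "A", "C", "G"),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(RNA_ALPHABET, NULL))
          new <- alt[cbind(match(old, RNA_ALPHABET),
                           sample.int(3L, n_mis, replace = TRUE))]
          rd <- substitute_bases_cpp(rd, read_i, pos_i, new)
        }
      }
      reads[[j]] <- unname(rd)
      true_edits[[j]] <- dplyr::mutate(edits_j, sample_id = smp$sample_id,
                                       level_true = ifelse(.data$n_true > 0,
                                                           .data$k_true / .data$n_true, NA_real_))
    }
  })

  true_edits <- dplyr::bind_rows(true_edits)
  out <- list(reads = reads,
              true_counts = counts,
              lib_sizes = sim$lib_sizes,
              true_edits = true_edits,
              true_de = sim$true_de,
              config = config)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

#' Write simulated libraries to disk
#'
#' One FASTQ per sample (constant Phred-20 qualities) plus ground-truth TSVs
#' (`true_counts.tsv`, `true_edits.tsv`, `true_de.tsv`).
#'
#' @param sim_reads result of [emit_reads()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim_reads, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (s in names(sim_reads$reads)) {
    rd <- sim_reads$reads[[s]]
    p <- file.path(out_dir, paste0(s, ".fastq"))
    qual <- vapply(nchar(rd), function(L)
      paste(rep("5", L), collapse = ""), character(1))  # '5' = Phred 20
    writeLines(paste0("@", s, ":", seq_along(rd), "\n", rd, "\n+\n", qual), p)
    paths <- c(paths, p)
  }
  tc <- as.data.frame(sim_reads$true_counts)
  tc <- cbind(mature_id = rownames(sim_reads$true_counts), tc)
  write.table(tc, file.path(out_dir, "true_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim_reads$true_edits, file.path(out_dir, "true_edits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim_reads$true_de, file.path(out_dir, "true_de.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
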