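# Read-to-miRNA assignment and per-position modification counting.
#
# A deliberately transparent stand-in for a web quantifier: ungapped matching
# of each read against every hairpin with the read 5' end within a small
# slack of an annotated mature start, a mismatch budget, discard-on-tie
# across genes, and exclusion of terminal mismatch runs (3' non-templated
# additions and their 5' mirror) from internal modifications.

#' Assign reads to mature miRNAs on hairpin references
#'
#' @param reads character vector of read sequences (RNA or DNA alphabet), or
#'   a FASTA/FASTQ path.
#' @param reference a `mirna_reference`.
#' @param max_mismatches mismatch budget per placement.
#' @param start_slack maximal distance (nt) between the read 5' end and an
#'   annotated mature start.
#' @param min_read_length reads shorter than this are tallied as too short.
#' @return tibble with one row per read: `read`, `mature_id` (NA if
#'   unassigned), `gene_id`, `offset` (0-based on hairpin), `n_mismatch`,
#'   `status` (assigned / ambiguous / unassigned / too_short).
#' @export
assign_reads <- function(reads, reference, max_mismatches = 2L,
                         start_slack = 2L, min_read_length = 16L) {
  reference <- validate_reference(reference)
  reads <- read_sequences(reads)
  m <- match_reads_cpp(reads, reference$hairpin_seq,
                       reference$mature_start,
                       match(reference$gene_id, unique(reference$gene_id)),
                       as.integer(max_mismatches), as.integer(start_slack),
                       as.integer(min_read_length))
  status <- ifelse(m$too_short, "too_short",
                   ifelse(m$ambiguous, "ambiguous",
                          ifelse(is.na(m$ref_row), "unassigned", "assigned")))
  tibble(read = reads,
         mature_id = reference$mature_id[m$ref_row],
         gene_id = reference$gene_id[m$ref_row],
         offset = m$offset,
         n_mismatch = m$n_mismatch,
         status = status)
}

read_sequences <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", x, ignore.case = TRUE))
      "fastq" else "fasta"
    x <- as.character(Biostrings::readBStringSet(x, format = fmt))
  }
  rna_string(unname(x))
}

#' Quantify one library: counts and internal modifications
#'
#' Identical reads are collapsed before matching, so runtime scales with the
#' number of distinct sequences.  Mismatch positions are reported in mature
#' coordinates; maximal runs of contiguous mismatches touching the read 3'
#' end are classified as 3' additions (5' runs analogously) and excluded
#' from internal modifications, as are mismatches falling outside the mature
#' window.
#'
#' @inheritParams assign_reads
#' @return list with `counts` (named integer vector over all mature_ids),
#'   `modifications` (tibble: mature_id, position, ref_nt, obs_nt, count),
#'   and `log` (total / assigned / unassigned / ambiguous / too_short read
#'   tallies, and `three_prime_additions` read count).
#' @export
quantify_sample <- function(reads, reference, max_mismatches = 2L,
                            start_slack = 2L, min_read_length = 16L) {
  reference <- validate_reference(reference)
  reads <- read_sequences(reads)
  counts <- setNames(integer(nrow(reference)), reference$mature_id)
  mods <- tibble(mature_id = character(), position = integer(),
                 ref_nt = character(), obs_nt = character(),
                 count = integer())
  if (!length(reads)) {
    warning("no reads in input; returning an empty column")
    return(list(counts = counts, modifications = mods,
                log = list(total = 0L, assigned = 0L, unassigned = 0L,
                           ambiguous = 0L, too_short = 0L,
                           three_prime_additions = 0L)))
  }
  tab <- table(reads)
  uniq <- names(tab)
  mult <- as.integer(tab)
  asg <- assign_reads(uniq, reference, max_mismatches, start_slack,
                      min_read_length)

  ok <- asg$status == "assigned"
  cnt <- tapply(mult[ok], asg$mature_id[ok], sum)
  counts[names(cnt)] <- as.integer(cnt)

  three_prime <- 0L
  with_mm <- which(ok & asg$n_mismatch > 0L)
  if (length(with_mm)) {
    ref_row <- match(asg$mature_id[with_mm], reference$mature_id)
    pos_list <- mismatch_positions_cpp(uniq[with_mm], reference$hairpin_seq,
                                       ref_row, asg$offset[with_mm])
    n_mm <- length(with_mm)
    posL <- refL <- vector("list", n_mm)
    for (t in seq_len(n_mm)) {
      i <- with_mm[t]
      pos <- pos_list[[t]]                       # 1-based on the read
      L <- nchar(uniq[i])
      # trim maximal contiguous terminal mismatch runs (5' and 3')
      is_mm <- logical(L); is_mm[pos] <- TRUE
      lead <- 0L; while (lead < L && is_mm[lead + 1L]) lead <- lead + 1L
      trail <- 0L; while (trail < L - lead && is_mm[L - trail]) trail <- trail + 1L
      if (trail > 0L) three_prime <- three_prime + mult[i]
      posL[[t]] <- pos[pos > lead & pos <= L - trail]
    }
    take <- rep.int(seq_len(n_mm), lengths(posL))  # one row per internal mm
    if (length(take)) {
      read_pos <- unlist(posL, use.names = FALSE)
      i <- with_mm[take]
      r <- ref_row[take]
      hp_pos <- asg$offset[i] + read_pos           # 1-based hairpin coordinate
      mat_pos <- hp_pos - reference$mature_start[r] + 1L
      mlen <- reference$mature_end[r] - reference$mature_start[r] + 1L
      keep <- mat_pos >= 1L & mat_pos <= mlen
      acc <- tibble(
        mature_id = asg$mature_id[i][keep],
        position = mat_pos[keep],
        ref_nt = substr(reference$hairpin_seq[r][keep],
                        hp_pos[keep], hp_pos[keep]),
        obs_nt = substr(uniq[i][keep], read_pos[keep], read_pos[keep]),
        count = mult[i][keep])
      if (nrow(acc)) {
        mods <- dplyr::summarise(
          dplyr::group_by(acc, .data$mature_id, .data$position,
                          .data$ref_nt, .data$obs_nt),
          count = sum(.data$count), .groups = "drop")
        mods <- dplyr::arrange(mods, .data$mature_id, .data$position,
                               .data$obs_nt)
      }
    }
  }
  list(counts = counts,
       modifications = mods,
       log = list(total = sum(mult),
                  assigned = sum(mult[ok]),
                  unassigned = sum(mult[asg$status == "unassigned"]),
                  ambiguous = sum(mult[asg$status == "ambiguous"]),
                  too_short = sum(mult[asg$status == "too_short"]),
                  three_prime_additions = three_prime))
}

#' Quantify a set of libraries into a count matrix and modification table
#'
#' @param read_sets named list of per-sample read vectors (or file paths);
#'   names are sample ids.
#' @inheritParams assign_reads
#' @param lib_sizes optional named vector of library sizes; defaults to the
#'   total number of input reads per sample.
#' @return list of class `mir_quantification`: `counts` (miRNA x sample
#'   integer matrix), `lib_sizes`, `modifications` (long tibble with
#'   sample_id), `logs`.
#' @export
quantify_samples <- function(read_sets, reference, max_mismatches = 2L,
                             start_slack = 2L, min_read_length = 16L,
                             lib_sizes = NULL) {
  reference <- validate_reference(reference)
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  cols <- lapply(read_sets, quantify_sample, reference = reference,
                 max_mismatches = max_mismatches, start_slack = start_slack,
                 min_read_length = min_read_length)
  counts <- vapply(cols, `[[`, integer(nrow(reference)), "counts")
  rownames(counts) <- reference$mature_id
  mods <- dplyr::bind_rows(lapply(names(cols), function(s)
    dplyr::mutate(cols[[s]]$modifications, sample_id = s, .before = 1)))
  logs <- lapply(cols, `[[`, "log")
  if (is.null(lib_sizes))
    lib_sizes <- vapply(logs, function(l) as.numeric(l$total), numeric(1))
  structure(list(counts = counts, lib_sizes = lib_sizes,
                 modifications = mods, logs = logs),
            class = "mir_quantification")
}

#' Write quantification outputs as TSV
#'
#' @param quant a `mir_quantification`.
#' @param out_dir output directory.
#' @export
write_quantification <- function(quant, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cm <- cbind(mature_id = rownames(quant$counts),
              as.data.frame(quant$counts))
  write.table(cm, file.path(out_dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(quant$modifications, file.path(out_dir, "modifications.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_df <- do.call(rbind, lapply(names(quant$logs), function(s)
    data.frame(sample_id = s, quant$logs[[s]])))
  write.table(log_df, file.path(out_dir, "quantify_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
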