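# miRNA reference model: one row per mature miRNA annotated on its hairpin.
# Coordinates are 1-based inclusive; hairpin coordinates locate the mature
# window, seed coordinates are relative to the mature strand (position 1 =
# 5' nucleotide of the mature sequence).  The internal alphabet is RNA (U);
# DNA input (T) is converted on read.

RNA_ALPHABET <- c("A", "C", "G", "U")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside A/C/G/U is an error.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over \{A, C, G, U\}.
#' @export
rna_string <- function(x) {
  out <- chartr("T", "U", toupper(x))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("non-ACGU/T character in sequence(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  out
}

#' Construct a validated miRNA reference table
#'
#' @param gene_id hairpin (gene) identifiers.
#' @param hairpin_seq hairpin sequences (RNA or DNA alphabet).
#' @param mature_id mature miRNA identifiers.
#' @param mature_start,mature_end 1-based inclusive mature window on the
#'   hairpin.
#' @param seed_start,seed_end 1-based inclusive seed window on the mature
#'   sequence (defaults 2 and 8).
#' @return a tibble of class `mirna_reference` with one row per mature miRNA.
#' @export
mirna_reference <- function(gene_id, hairpin_seq, mature_id,
                            mature_start, mature_end,
                            seed_start = 2L, seed_end = 8L) {
  ref <- tibble(
    gene_id = as.character(gene_id),
    hairpin_seq = rna_string(hairpin_seq),
    mature_id = as.character(mature_id),
    mature_start = as.integer(mature_start),
    mature_end = as.integer(mature_end),
    seed_start = as.integer(rep_len(seed_start, length(gene_id))),
    seed_end = as.integer(rep_len(seed_end, length(gene_id)))
  )
  validate_reference(ref)
}

#' @export
validate_reference <- function(ref) {
  stopifnot(is.data.frame(ref), nrow(ref) > 0)
  if (anyDuplicated(ref$mature_id))
    stop("duplicated mature_id in reference")
  hlen <- nchar(ref$hairpin_seq)
  mlen <- ref$mature_end - ref$mature_start + 1L
  bad <- which(ref$mature_start < 1L | ref$mature_end > hlen |
                 ref$mature_start > ref$mature_end)
  if (length(bad))
    stop("mature window out of hairpin bounds for: ",
         paste(ref$mature_id[bad], collapse = ", "))
  bad <- which(mlen < 16L | mlen > 28L)
  if (length(bad))
    stop("mature length outside [16, 28] for: ",
         paste(ref$mature_id[bad], collapse = ", "))
  bad <- which(ref$seed_start < 1L | ref$seed_end > mlen |
                 ref$seed_start > ref$seed_end)
  if (length(bad))
    stop("seed window outside mature sequence for: ",
         paste(ref$mature_id[bad], collapse = ", "))
  class(ref) <- unique(c("mirna_reference", class(ref)))
  ref
}

#' Read a miRNA reference from a hairpin FASTA plus an annotation TSV
#'
#' The annotation must have a header row with columns `gene_id`, `mature_id`,
#' `mature_start`, `mature_end` and optionally `seed_start`, `seed_end`.
#' Every annotation row must name a FASTA record; FASTA records without any
#' annotation row are an error (they would silently absorb reads).
#'
#' @param fasta_path hairpin FASTA (RNA or DNA alphabet).
#' @param annotation_path TSV as described above.
#' @return a `mirna_reference` tibble.
#' @export
read_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- read.delim(annotation_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_id", "mature_id", "mature_start", "mature_end")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  missing_seq <- setdiff(ann$gene_id, ids)
  if (length(missing_seq))
    stop("annotation names absent from FASTA: ",
         paste(missing_seq, collapse = ", "))
  orphan <- setdiff(ids, ann$gene_id)
  if (length(orphan))
    stop("FASTA records without annotation: ", paste(orphan, collapse = ", "))
  mirna_reference(
    gene_id = ann$gene_id,
    hairpin_seq = as.character(seqs[match(ann$gene_id, ids)]),
    mature_id = ann$mature_id,
    mature_start = ann$mature_start,
    mature_end = ann$mature_end,
    seed_start = ann$seed_start %||% 2L,
    seed_end = ann$seed_end %||% 8L
  )
}

#' Write a miRNA reference back to FASTA + annotation TSV
#'
#' Inverse of [read_reference()]: sequences are written in the RNA alphabet,
#' coordinates byte-for-byte as read.
#'
#' @param ref a `mirna_reference`.
#' @param fasta_path,annotation_path output paths.
#' @export
write_reference <- function(ref, fasta_path, annotation_path) {
  hp <- ref[!duplicated(ref$gene_id), c("gene_id", "hairpin_seq")]
  writeLines(paste0(">", hp$gene_id, "\n", hp$hairpin_seq), fasta_path)
  write.table(ref[, c("gene_id", "mature_id", "mature_start", "mature_end",
                      "seed_start", "seed_end")],
              annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ref)
}

#' Extract mature sequences
#'
#' @param ref a `mirna_reference`.
#' @return named character vector (names = mature_id) of mature sequences.
#' @export
mature_seq <- function(ref) {
  setNames(substr(ref$hairpin_seq, ref$mature_start, ref$mature_end),
           ref$mature_id)
}

#' Is a mature-coordinate position inside the seed region?
#'
#' Positions are 1-based on the mature strand; the default seed window is
#' 2--8 inclusive.
#'
#' @param ref a `mirna_reference`.
#' @param mature_id mature identifier(s), recycled against `position`.
#' @param position 1-based mature coordinate(s).
#' @return logical vector.
#' @export
in_seed <- function(ref, mature_id, position) {
  n <- max(length(mature_id), length(position))
  mature_id <- rep_len(mature_id, n)
  position <- rep_len(as.integer(position), n)
  i <- match(mature_id, ref$mature_id)
  if (anyNA(i))
    stop("unknown mature_id: ",
         paste(unique(mature_id[is.na(i)]), collapse = ", "))
  mlen <- ref$mature_end[i] - ref$mature_start[i] + 1L
  if (any(position < 1L | position > mlen))
    stop("position outside the mature sequence")
  position >= ref$seed_start[i] & position <= ref$seed_end[i]
}

#' Read a sample design table
#'
#' TSV with header columns `sample_id`, `group`, `timepoint`, `method` and
#' optionally `replicate`. Factors are kept as character; `group` is the
#' biological contrast (e.g. control vs KA), `method` the isolation batch
#' factor (UC vs kit).
#'
#' @param path TSV path.
#' @return tibble of class `sample_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  comment.char = "#")
  validate_design(as_tibble(d))
}

#' @export
validate_design <- function(design) {
  need <- c("sample_id", "group", "timepoint", "method")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design")
  if (!"replicate" %in% names(design)) {
    design$replicate <- stats::ave(seq_len(nrow(design)),
                                   design$group, design$timepoint,
                                   design$method, FUN = seq_along)
  }
  class(design) <- unique(c("sample_design", class(design)))
  design
}

#' Read a reference list (one mature_id per line, '#' comments allowed)
#'
#' @param path file path.
#' @param list_id label for the list (defaults to the file stem).
#' @return list with elements `list_id` and `members` (character set).
#' @export
read_reference_list <- function(path, list_id = NULL) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- unique(x[nzchar(x)])
  if (!length(x)) stop("reference list is empty: ", path)
  list(list_id = list_id %||% tools::file_path_sans_ext(basename(path)),
       members = x)
}
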