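#' Read a FASTA file into a transcript tibble
#'
#' Transcript sets are represented throughout the package as a tibble with one
#' row per transcript: `transcript_id` and an uppercase nucleotide `sequence`.
#' Record order in the file is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `transcript_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  transcript_tibble(ids, toupper(as.character(set)))
}

#' Construct and validate a transcript tibble
#'
#' @param transcript_id Character vector of unique, non-empty ids.
#' @param sequence Character vector of nucleotide sequences (IUPAC alphabet).
#' @return A tibble with columns `transcript_id`, `sequence`, `length`.
#' @export
transcript_tibble <- function(transcript_id, sequence) {
  transcript_id <- as.character(transcript_id)
  sequence <- toupper(as.character(sequence))
  if (any(is.na(transcript_id) | transcript_id == "")) {
    abort("transcript ids must be non-empty")
  }
  dup <- transcript_id[duplicated(transcript_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate id ", dup[[1]]))
  }
  empty <- transcript_id[!nzchar(sequence)]
  if (length(empty) > 0) {
    abort(paste0("empty sequence for record ", empty[[1]]))
  }
  bad <- grepl("[^ACGTURYSWKMBDHVN]", sequence)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in record ", transcript_id[bad][[1]]))
  }
  tibble(
    transcript_id = transcript_id,
    sequence = sequence,
    length = nchar(sequence)
  )
}

#' Write a transcript tibble to FASTA
#'
#' @param transcripts Tibble with `transcript_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::DNAStringSet(setNames(
    transcripts$sequence, transcripts$transcript_id
  ))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

blast_cols <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "query_start", "query_end",
  "subject_start", "subject_end", "evalue", "bit_score"
)

#' Read a 12-column tabular BLAST hit file
#'
#' Expects the classic 12-column tab-separated dialect (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score; 1-based inclusive coordinates).
#' Extra trailing columns are tolerated and ignored. All rows are retained
#' untouched; a `db` label column is attached.
#'
#' @param path Path to the tabular hit file.
#' @param db_label Label naming the database the hits came from
#'   (e.g. `"nr"`, `"swissprot"`, `"rfam"`, `"mirbase"`, `"noncode"`).
#' @return A tibble with the 12 standard columns plus `db`.
#' @export
read_blast_tab <- function(path, db_label) {
  if (!file.exists(path)) abort(paste0("hit file not found: ", path))
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) {
    out <- tibble(
      query_id = character(), subject_id = character(),
      percent_identity = numeric(), alignment_length = integer(),
      mismatches = integer(), gap_opens = integer(),
      query_start = integer(), query_end = integer(),
      subject_start = integer(), subject_end = integer(),
      evalue = numeric(), bit_score = numeric(), db = character()
    )
    return(out)
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 12L)
  if (length(short) > 0) {
    abort(paste0("line ", short[[1]], ": fewer than 12 tab-separated columns"))
  }
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(grab(i)))
    bad <- which(is.na(x))
    if (length(bad) > 0) {
      abort(paste0("line ", bad[[1]], ": non-numeric ", what))
    }
    x
  }
  hits <- tibble(
    query_id = grab(1), subject_id = grab(2),
    percent_identity = num(3, "percent identity"),
    alignment_length = as.integer(num(4, "alignment length")),
    mismatches = as.integer(num(5, "mismatch count")),
    gap_opens = as.integer(num(6, "gap open count")),
    query_start = as.integer(num(7, "query start")),
    query_end = as.integer(num(8, "query end")),
    subject_start = as.integer(num(9, "subject start")),
    subject_end = as.integer(num(10, "subject end")),
    evalue = num(11, "evalue"),
    bit_score = num(12, "bit score"),
    db = as.character(db_label)
  )
  if (any(hits$evalue < 0)) abort("negative evalue in hit table")
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    abort("percent identity outside [0, 100]")
  }
  hits
}

#' Filter a hit table on E-value and identity
#'
#' Both comparisons are strict, matching the conventions used across the
#' pipeline: a hit is kept iff `evalue < max_evalue` and
#' `percent_identity > min_identity`.
#'
#' @param hits Hit tibble as returned by [read_blast_tab()].
#' @param max_evalue Strict upper bound on E-value.
#' @param min_identity Strict lower bound on percent identity (0-100 scale);
#'   default 0 keeps every identity.
#' @return The subset of rows passing both thresholds.
#' @export
filter_hits <- function(hits, max_evalue, min_identity = 0) {
  stopifnot(is.finite(max_evalue), is.finite(min_identity))
  filter(hits, .data$evalue < max_evalue, .data$percent_identity > min_identity)
}

#' Read an FPKM expression matrix and its library design
#'
#' The expression file is a TSV whose first column is the gene id and whose
#' remaining columns are libraries; the design file is a TSV with columns
#' `library_id`, `condition`, `replicate`. Conditions keep the order of their
#' first appearance in the design unless `condition_order` is given.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @param condition_order Optional character vector fixing condition order.
#' @return A list with elements `expr` (tibble, `gene_id` + library columns)
#'   and `design` (tibble `library_id`, `condition`, `replicate`).
#' @export
read_expression <- function(path, design_path, condition_order = NULL) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  names(expr)[1] <- "gene_id"
  expr$gene_id <- as.character(expr$gene_id)
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              library_id = readr::col_character(),
                              condition = readr::col_character(),
                              replicate = readr::col_integer()
                            ))
  design <- order_design(design, condition_order)
  validate_expression(expr, design)
  list(expr = expr, design = design)
}

order_design <- function(design, condition_order = NULL) {
  if (!all(c("library_id", "condition", "replicate") %in% names(design))) {
    abort("design must have columns library_id, condition, replicate")
  }
  if (is.null(condition_order)) condition_order <- unique(design$condition)
  missing_cond <- setdiff(design$condition, condition_order)
  if (length(missing_cond) > 0) {
    abort(paste0("condition not in condition_order: ", missing_cond[[1]]))
  }
  design$condition <- factor(design$condition, levels = condition_order)
  design <- arrange(design, .data$condition, .data$replicate)
  design$condition <- as.character(design$condition)
  attr(design, "condition_order") <- condition_order
  design
}

#' Validate an expression tibble against a design
#'
#' @param expr Expression tibble (`gene_id` + one numeric column per library).
#' @param design Design tibble (`library_id`, `condition`, `replicate`).
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr, design) {
  libs <- setdiff(names(expr), "gene_id")
  missing_lib <- setdiff(libs, design$library_id)
  if (length(missing_lib) > 0) {
    abort(paste0("library missing from design: ", missing_lib[[1]]))
  }
  unused <- setdiff(design$library_id, libs)
  if (length(unused) > 0) {
    abort(paste0("design library absent from matrix: ", unused[[1]]))
  }
  if (anyDuplicated(design$library_id)) abort("duplicate library in design")
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene id in matrix")
  vals <- as.matrix(expr[libs])
  if (nrow(expr) > 0 && !is.numeric(vals)) {
    abort("expression values must be numeric")
  }
  if (anyNA(vals)) abort("missing expression values")
  if (any(vals < 0)) abort("negative FPKM values are not allowed")
  invisible(expr)
}

#' Condition order of a design
#'
#' @param design Design tibble.
#' @return Character vector of conditions in course order.
#' @export
condition_levels <- function(design) {
  ord <- attr(design, "condition_order")
  if (is.null(ord)) ord <- unique(design$condition)
  ord
}

# genes x libraries numeric matrix, libraries in design order
expr_matrix <- function(expr, design = NULL) {
  libs <- if (is.null(design)) setdiff(names(expr), "gene_id") else design$library_id
  m <- as.matrix(expr[libs])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

#' Per-condition mean expression
#'
#' Averages replicate libraries within each condition (arithmetic mean of
#' FPKM), returning one column per condition in course order.
#'
#' @param expr Expression tibble.
#' @param design Design tibble.
#' @return Tibble with `gene_id` and one numeric column per condition.
#' @export
condition_means <- function(expr, design) {
  validate_expression(expr, design)
  m <- expr_matrix(expr, design)
  conds <- condition_levels(design)
  out <- lapply(conds, function(cc) {
    libs <- design$library_id[design$condition == cc]
    unname(rowMeans(m[, libs, drop = FALSE]))
  })
  names(out) <- conds
  tibble(gene_id = expr$gene_id, !!!out)
}
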