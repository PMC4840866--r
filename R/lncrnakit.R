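STOP_CODONS <- c("TAA", "TAG", "TGA")

revcomp <- function(seq) {
  x <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

frame_codons <- function(seq, offset) {
  n <- nchar(seq)
  if (n - offset < 3) return(character(0))
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

# longest ATG..stop stretch (aa, stop excluded) in one codon vector;
# codons containing ambiguity codes block ORFs and never count toward them
longest_orf_in_frame <- function(codons) {
  if (length(codons) == 0) return(0L)
  valid <- !grepl("[^ACGT]", codons)
  is_stop <- codons %in% STOP_CODONS
  starts <- which(codons == "ATG")
  if (length(starts) == 0) return(0L)
  blockers <- which(is_stop | !valid)
  if (length(blockers) == 0) return(0L)
  nxt <- findInterval(starts, blockers) + 1L
  ok <- nxt <= length(blockers)
  if (!any(ok)) return(0L)
  starts <- starts[ok]
  stop_pos <- blockers[nxt[ok]]
  lens <- ifelse(is_stop[stop_pos], stop_pos - starts, 0L)
  max(lens, 0L)
}

#' Longest open reading frame over six frames
#'
#' Length in amino acids (stop codon excluded) of the longest ATG-initiated,
#' in-frame-stop-terminated open reading frame over the three forward and
#' three reverse-complement frames. ORFs running off the transcript end are
#' not counted, and codons containing ambiguity codes (including N) are never
#' part of an ORF.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Integer vector of amino-acid lengths (0 when no ORF exists).
#' @export
longest_orf <- function(sequence) {
  sequence <- toupper(sequence)
  rc <- revcomp(sequence)
  vapply(seq_along(sequence), function(i) {
    best <- 0L
    for (s in c(sequence[[i]], rc[[i]])) {
      for (off in 0:2) {
        best <- max(best, longest_orf_in_frame(frame_codons(s, off)))
      }
    }
    best
  }, integer(1))
}

#' Positional nucleotide-bias statistic
#'
#' A simplified Fickett-style statistic: for each base, the asymmetry of its
#' occupancy across the three codon positions of the forward strand is
#' combined with its overall content. Values fall in (0, 1); coding-like
#' periodic sequences score higher than compositionally uniform ones. Used
#' only as a small graded component of [cnci_like_score()].
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Numeric vector in (0, 1).
#' @export
fickett_statistic <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    keep <- chars %in% c("A", "C", "G", "T")
    chars <- chars[keep]
    n <- length(chars)
    if (n < 3) return(0.5)
    pos <- (seq_len(n) - 1L) %% 3L
    asym <- vapply(c("A", "C", "G", "T"), function(b) {
      cnt <- tabulate(pos[chars == b] + 1L, nbins = 3L)
      max(cnt) / (min(cnt) + 1)
    }, numeric(1))
    content <- vapply(c("A", "C", "G", "T"), function(b) mean(chars == b),
                      numeric(1))
    raw <- mean(asym / (asym + 1.5)) + 0.25 * (max(content) - min(content))
    1 / (1 + exp(-4 * (raw - 0.5)))
  }, numeric(1), USE.NAMES = FALSE)
}

orf_coverage <- function(orf_aa, length) {
  pmin(1, 3 * (orf_aa + 1) / pmax(length, 1))
}

#' Intrinsic coding-potential score (negative = noncoding)
#'
#' A deterministic, alignment-free coding-potential score whose decision
#' boundary sits at 0. The sign is carried by the size of the longest
#' six-frame ORF relative to the 100-amino-acid convention used by the lncRNA
#' cascade; ORF coverage of the transcript and the positional-bias statistic
#' grade the magnitude multiplicatively (factors bounded in \[0.85, 1.15\])
#' so they can never flip the boundary. Transcripts whose longest ORF is at
#' most 100 aa always score below 0.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Numeric vector of scores; `< 0` is called noncoding.
#' @export
cnci_like_score <- function(sequence) {
  orf_aa <- longest_orf(sequence)
  cov <- orf_coverage(orf_aa, nchar(sequence))
  fick <- fickett_statistic(sequence)
  base <- 4 * log2((orf_aa + 1) / 101.5)
  mult <- 1 + 0.2 * (cov - 0.5) + 0.1 * (fick - 0.5)
  base * pmin(pmax(mult, 0.85), 1.15)
}

#' Evidence-aware coding-potential score (below -1 = noncoding)
#'
#' Combines ORF quality with protein-database hit evidence. The intrinsic
#' part mirrors [cnci_like_score()] but is shifted so the noncoding decision
#' boundary sits at -1; any protein hit passing the E-value filter forces the
#' score to at least 0 (the transcript is retained as coding regardless of
#' its ORF structure).
#'
#' @param sequence Character vector of nucleotide sequences.
#' @param protein_hits Optional hit tibble ([read_blast_tab()]) of protein-
#'   database hits for these transcripts; matched by position through
#'   `transcript_id`.
#' @param transcript_id Ids aligning `sequence` to `protein_hits$query_id`.
#' @param max_evalue E-value filter applied to hits before they count as
#'   evidence.
#' @return Numeric vector of scores; `< -1` is called noncoding.
#' @export
cpc_like_score <- function(sequence, protein_hits = NULL,
                           transcript_id = NULL, max_evalue = 1e-5) {
  orf_aa <- longest_orf(sequence)
  cov <- orf_coverage(orf_aa, nchar(sequence))
  mult <- pmin(pmax(1 + 0.3 * (cov - 0.5), 0.85), 1.15)
  score <- 3 * log2((orf_aa + 1) / 101.5) * mult - 1
  if (!is.null(protein_hits) && nrow(protein_hits) > 0) {
    if (is.null(transcript_id)) {
      abort("transcript_id is required when protein_hits are supplied")
    }
    evidenced <- unique(protein_hits$query_id[protein_hits$evalue < max_evalue])
    has_hit <- transcript_id %in% evidenced
    score[has_hit] <- pmax(score[has_hit], 0)
  }
  score
}

CASCADE_STAGES <- c("annotation", "length", "coding_potential", "orf", "triage")

#' Run the lncRNA identification cascade
#'
#' Applies the five-stage filter cascade to a de novo transcript set:
#' \enumerate{
#'   \item \strong{annotation} — transcripts with any protein-database hit at
#'     `evalue < protein_evalue` are removed as `annotated_coding`;
#'   \item \strong{length} — transcripts shorter than `min_len` nt are removed
#'     as `too_short`;
#'   \item \strong{coding potential} — only transcripts called noncoding by
#'     both channels (intrinsic score `< 0` and evidence-aware score `< -1`)
#'     survive; the rest are `coding_potential`;
#'   \item \strong{ORF} — transcripts whose longest six-frame ORF exceeds
#'     `max_orf_aa` amino acids are removed as `orf_coding`;
#'   \item \strong{triage} — survivors are compared against structural-ncRNA
#'     hits filtered at (`evalue < ncrna_evalue`, identity `> ncrna_identity`):
#'     a miRNA-family hit (miRBase, or an Rfam family whose subject id names a
#'     miRNA) makes the transcript `pri_miRNA`; any other Rfam hit makes it
#'     `other_ncRNA`; a known-lncRNA database (NONCODE) hit makes it
#'     `lncRNA_known`; no qualifying hit leaves it `lncRNA_novel`.
#' }
#' Triage precedence is miRNA family, then other Rfam, then NONCODE.
#'
#' @param transcripts Transcript tibble ([read_fasta()]).
#' @param protein_hits Protein-database hit tibble (may be empty or `NULL`).
#' @param ncrna_hits Structural-ncRNA hit tibble with `db` among
#'   `"mirbase"`, `"rfam"`, `"noncode"` (may be empty or `NULL`).
#' @param min_len Minimum transcript length in nt (default 200).
#' @param max_orf_aa Maximum ORF length in aa for a noncoding call
#'   (default 100).
#' @param protein_evalue E-value threshold for annotation evidence.
#' @param ncrna_evalue,ncrna_identity Thresholds for stage-5 triage hits.
#' @param cnci_scores,cpc_scores Optional externally computed score tables:
#'   named numeric vectors (or two-column data frames `transcript_id`,
#'   `score`) that replace the built-in scorers.
#' @return An object of class `lnc_cascade`: a list with `verdicts` (one row
#'   per transcript: `transcript_id`, `final_class`, scores, `longest_orf_aa`,
#'   `length`), `stage_counts` (survivors after each stage), and `trace`
#'   (per-transcript per-stage decisions with evidence).
#' @export
run_cascade <- function(transcripts, protein_hits = NULL, ncrna_hits = NULL,
                        min_len = 200, max_orf_aa = 100,
                        protein_evalue = 1e-5,
                        ncrna_evalue = 1e-5, ncrna_identity = 90,
                        cnci_scores = NULL, cpc_scores = NULL) {
  ids <- transcripts$transcript_id
  check_hit_ids <- function(hits, what) {
    if (is.null(hits) || nrow(hits) == 0) return(NULL)
    orphan <- setdiff(unique(hits$query_id), ids)
    if (length(orphan) > 0) {
      warn(paste0(length(orphan), " ", what,
                  " hit(s) reference transcripts absent from the set; ignored"))
      hits <- filter(hits, .data$query_id %in% ids)
    }
    hits
  }
  protein_hits <- check_hit_ids(protein_hits, "protein")
  ncrna_hits <- check_hit_ids(ncrna_hits, "ncRNA")

  n <- length(ids)
  final_class <- rep(NA_character_, n)
  trace <- vector("list", 5L)

  # stage 1: protein annotation
  annotated <- if (!is.null(protein_hits) && nrow(protein_hits) > 0) {
    unique(protein_hits$query_id[protein_hits$evalue < protein_evalue])
  } else character(0)
  removed <- ids %in% annotated
  final_class[removed] <- "annotated_coding"
  alive <- !removed
  trace[[1]] <- tibble(
    transcript_id = ids, stage = "annotation",
    decision = as.character(ifelse(removed, "removed", "pass")),
    evidence = as.character(ifelse(removed,
                      paste0("protein hit with E < ", format(protein_evalue)),
                      "no qualifying protein hit"))
  )

  # stage 2: length
  len <- transcripts$length
  removed <- alive & len < min_len
  final_class[removed] <- "too_short"
  trace[[2]] <- tibble(
    transcript_id = ids[alive], stage = "length",
    decision = as.character(ifelse(removed[alive], "removed", "pass")),
    evidence = paste0(len[alive], " nt vs minimum ", min_len)
  )
  alive <- alive & !removed

  # stage 3: dual coding-potential filter
  resolve_scores <- function(ext, builtin) {
    if (is.null(ext)) return(builtin)
    if (is.data.frame(ext)) ext <- setNames(ext[[2]], ext[[1]])
    miss <- setdiff(ids[alive], names(ext))
    if (length(miss) > 0) {
      abort(paste0("external score missing for transcript ", miss[[1]]))
    }
    as.numeric(ext[ids])
  }
  cnci <- rep(NA_real_, n)
  cpc <- rep(NA_real_, n)
  if (any(alive)) {
    cnci[alive] <- cnci_like_score(transcripts$sequence[alive])
    cpc[alive] <- cpc_like_score(transcripts$sequence[alive],
                                 protein_hits = protein_hits,
                                 transcript_id = ids[alive],
                                 max_evalue = protein_evalue)
  }
  if (!is.null(cnci_scores)) cnci <- resolve_scores(cnci_scores, cnci)
  if (!is.null(cpc_scores)) cpc <- resolve_scores(cpc_scores, cpc)
  noncoding <- alive & cnci < 0 & cpc < -1
  removed <- alive & !noncoding
  final_class[removed] <- "coding_potential"
  trace[[3]] <- tibble(
    transcript_id = ids[alive], stage = "coding_potential",
    decision = as.character(ifelse(removed[alive], "removed", "pass")),
    evidence = sprintf("intrinsic %.3f (cut 0), evidence-aware %.3f (cut -1)",
                       cnci[alive], cpc[alive])
  )
  alive <- alive & !removed

  # stage 4: ORF size
  orf_aa <- rep(NA_integer_, n)
  orf_aa[alive] <- longest_orf(transcripts$sequence[alive])
  removed <- alive & orf_aa > max_orf_aa
  final_class[removed] <- "orf_coding"
  trace[[4]] <- tibble(
    transcript_id = ids[alive], stage = "orf",
    decision = as.character(ifelse(removed[alive], "removed", "pass")),
    evidence = paste0(orf_aa[alive], " aa vs maximum ", max_orf_aa)
  )
  alive <- alive & !removed

  # stage 5: structural-ncRNA triage
  triage_db <- rep("none", n)
  if (!is.null(ncrna_hits) && nrow(ncrna_hits) > 0) {
    qualifying <- filter_hits(ncrna_hits, ncrna_evalue, ncrna_identity)
    is_mirna <- qualifying$db == "mirbase" |
      (qualifying$db == "rfam" &
         grepl("mir|let-7", qualifying$subject_id, ignore.case = TRUE))
    mirna_ids <- unique(qualifying$query_id[is_mirna])
    rfam_ids <- unique(qualifying$query_id[qualifying$db == "rfam" & !is_mirna])
    noncode_ids <- unique(qualifying$query_id[qualifying$db == "noncode"])
    triage_db[ids %in% noncode_ids] <- "noncode"
    triage_db[ids %in% rfam_ids] <- "rfam_other"
    triage_db[ids %in% mirna_ids] <- "mirna"
  }
  cls <- c(mirna = "pri_miRNA", rfam_other = "other_ncRNA",
           noncode = "lncRNA_known", none = "lncRNA_novel")
  final_class[alive] <- unname(cls[triage_db[alive]])
  trace[[5]] <- tibble(
    transcript_id = ids[alive], stage = "triage",
    decision = unname(cls[triage_db[alive]]),
    evidence = paste0("qualifying ncRNA evidence: ", triage_db[alive])
  )

  verdicts <- tibble(
    transcript_id = ids,
    final_class = final_class,
    cnci_score = cnci,
    cpc_score = cpc,
    longest_orf_aa = orf_aa,
    length = len
  )
  stage_counts <- tibble(
    stage = c("input", CASCADE_STAGES),
    survivors = c(n, vapply(trace, function(tr) {
      sum(!tr$decision %in% c("removed"))
    }, integer(1)))
  )
  stage_counts$removed <- c(0L, -diff(stage_counts$survivors))
  structure(
    list(verdicts = verdicts, stage_counts = stage_counts,
         trace = bind_rows(trace)),
    class = "lnc_cascade"
  )
}

#' @export
print.lnc_cascade <- function(x, ...) {
  cat("lncRNA identification cascade:", nrow(x$verdicts), "transcripts\n")
  print(x$stage_counts)
  print(count(x$verdicts, .data$final_class))
  invisible(x)
}

#' @rdname run_cascade
#' @param x,object An `lnc_cascade` object.
#' @param ... Unused.
#' @export
tidy.lnc_cascade <- function(x, ...) x$verdicts

#' @rdname run_cascade
#' @export
glance.lnc_cascade <- function(x, ...) {
  v <- x$verdicts
  tibble(
    n_input = nrow(v),
    n_lncRNA = sum(v$final_class %in% c("lncRNA_known", "lncRNA_novel")),
    n_novel = sum(v$final_class == "lncRNA_novel"),
    n_known = sum(v$final_class == "lncRNA_known"),
    n_pri_miRNA = sum(v$final_class == "pri_miRNA"),
    n_other_ncRNA = sum(v$final_class == "other_ncRNA"),
    n_removed = sum(!v$final_class %in%
                      c("lncRNA_known", "lncRNA_novel", "pri_miRNA",
                        "other_ncRNA"))
  )
}

#' @rdname run_cascade
#' @export
autoplot.lnc_cascade <- function(object, ...) {
  counts <- count(object$verdicts, .data$final_class)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$final_class, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "lncRNA cascade verdicts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
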