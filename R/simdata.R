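# All generators take an explicit integer seed and restore the caller's RNG
# state, so a single dataset-level seed can drive the whole suite through
# documented sub-seeding (see simulate_dataset).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

SIM_CLASSES <- c("coding", "lncRNA", "pri_miRNA", "other_ncRNA", "short_nc")

random_nt <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

NONSTOP_CODONS <- {
  all64 <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0
  ))
  setdiff(all64, STOP_CODONS)
}

# coding transcript: UTR5 + ATG + (orf_aa - 1) non-stop codons + stop + UTR3,
# with the planted ORF covering > 80 % of the transcript
make_coding_seq <- function(orf_aa, coverage) {
  orf <- paste0("ATG",
                paste(sample(NONSTOP_CODONS, orf_aa - 1, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1))
  orf_nt <- nchar(orf)
  total <- max(orf_nt + 6L, round(orf_nt / coverage))
  utr5 <- sample.int(total - orf_nt - 1L, 1)
  paste0(random_nt(utr5), orf, random_nt(total - orf_nt - utr5))
}

# noncoding transcript: rejection-sample random sequence until every
# six-frame ORF is at most max_orf aa (keeps base composition unbiased)
make_noncoding_seq <- function(len, max_orf = 100L) {
  repeat {
    s <- random_nt(len)
    if (longest_orf(s) <= max_orf) return(s)
  }
}

#' Simulate a transcript set with planted coding/noncoding classes
#'
#' Generates transcripts of five classes: `coding` (an embedded ATG..stop ORF
#' longer than 100 codons spanning more than 80 percent of the transcript),
#' `lncRNA`, `pri_miRNA` and `other_ncRNA` (at least 200 nt with every
#' six-frame ORF at most 100 aa, enforced by rejection sampling), and
#' `short_nc` (shorter than 200 nt). Output is byte-identical under a fixed
#' seed.
#'
#' @param n_by_class Named integer vector of transcript counts; names among
#'   `r paste(SIM_CLASSES, collapse = ", ")`.
#' @param length_range Length range (nt) for the long noncoding classes; the
#'   lower bound is raised to 200 for them. Must allow coding transcripts of
#'   at least ~340 nt when coding transcripts are requested.
#' @param seed Integer seed.
#' @return List with `transcripts` (tibble as from [read_fasta()]) and
#'   `truth` (tibble `transcript_id`, `class`).
#' @export
simulate_transcripts <- function(n_by_class, length_range = c(200, 1500),
                                 seed = 1) {
  bad <- setdiff(names(n_by_class), SIM_CLASSES)
  if (length(bad) > 0) abort(paste0("unknown transcript class: ", bad[[1]]))
  if (any(n_by_class < 0)) abort("class counts must be non-negative")
  if (length_range[1] < 50) abort("length_range minimum must be >= 50")
  n_by_class <- n_by_class[n_by_class > 0]
  if ("coding" %in% names(n_by_class) && length_range[2] < 340) {
    abort("length_range too short for coding transcripts (need >= 340 nt)")
  }
  with_seed(seed, {
    classes <- rep(names(n_by_class), as.integer(n_by_class))
    seqs <- vapply(classes, function(cl) {
      switch(cl,
        coding = {
          max_aa <- floor(0.9 * length_range[2] / 3) - 2L
          make_coding_seq(sample(110:min(300, max_aa), 1), runif(1, 0.82, 0.92))
        },
        short_nc = make_noncoding_seq(sample(50:199, 1)),
        make_noncoding_seq(
          sample(max(200, length_range[1]):max(200, length_range[2]), 1)
        )
      )
    }, character(1), USE.NAMES = FALSE)
    ids <- sprintf("SIM%05d", seq_along(classes))
    list(
      transcripts = transcript_tibble(ids, seqs),
      truth = tibble(transcript_id = ids, class = classes)
    )
  })
}

sim_hit_row <- function(query, subject, db, evalue, identity, qlen) {
  alen <- max(30L, round(qlen * runif(1, 0.3, 0.9)))
  tibble(
    query_id = query, subject_id = subject,
    percent_identity = round(identity, 2),
    alignment_length = alen,
    mismatches = as.integer(round(alen * (100 - identity) / 100)),
    gap_opens = sample(0:2, 1),
    query_start = 1L, query_end = alen,
    subject_start = 1L, subject_end = alen,
    evalue = evalue, bit_score = round(runif(1, 50, 400), 1),
    db = db
  )
}

#' Simulate database-hit evidence consistent with planted classes
#'
#' Coding transcripts receive protein-database hits passing the E-value
#' filter; pri-miRNA transcripts receive miRNA-family hits (miRBase/Rfam)
#' passing both E-value and identity filters; other structural ncRNAs receive
#' non-miRNA Rfam hits; a configurable fraction of lncRNAs receive
#' known-lncRNA (NONCODE) hits and the rest hit nothing.
#'
#' @param truth Truth tibble from [simulate_transcripts()]; a `length` column
#'   is optional (default 500 nt is assumed for alignment bookkeeping).
#' @param seed Integer seed.
#' @param known_fraction Fraction of lncRNAs given a NONCODE hit
#'   (default 0.031, the regime of a largely novel lncRNA catalogue).
#' @return List with `hits` (tibble in [read_blast_tab()] layout) and `truth`
#'   (input truth with a logical `noncode_known` column added for lncRNAs).
#' @export
simulate_hits <- function(truth, seed = 1, known_fraction = 0.031) {
  stopifnot(known_fraction >= 0, known_fraction <= 1)
  with_seed(seed, {
    qlen <- if ("length" %in% names(truth)) truth$length else
      rep(500L, nrow(truth))
    known <- rep(NA, nrow(truth))
    is_lnc <- truth$class == "lncRNA"
    known[is_lnc] <- runif(sum(is_lnc)) < known_fraction
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      id <- truth$transcript_id[[i]]
      rows[[length(rows) + 1L]] <- switch(truth$class[[i]],
        coding = {
          n_hits <- sample(1:3, 1)
          bind_rows(lapply(seq_len(n_hits), function(j) {
            sim_hit_row(id, sprintf("PROT%05d", sample.int(99999, 1)),
                        sample(c("nr", "swissprot"), 1),
                        10^runif(1, -60, -6), runif(1, 60, 99), qlen[[i]])
          }))
        },
        pri_miRNA = sim_hit_row(
          id, sprintf("mir-%03d", sample.int(999, 1)),
          sample(c("mirbase", "rfam"), 1),
          10^runif(1, -30, -6), runif(1, 90.5, 99.5), qlen[[i]]
        ),
        other_ncRNA = sim_hit_row(
          id, sprintf("RF%05d_tRNA", sample.int(99999, 1)), "rfam",
          10^runif(1, -30, -6), runif(1, 90.5, 99.5), qlen[[i]]
        ),
        lncRNA = if (isTRUE(known[[i]])) {
          sim_hit_row(id, sprintf("NONHSAT%06d", sample.int(999999, 1)),
                      "noncode", 10^runif(1, -30, -6), runif(1, 90.5, 99.5),
                      qlen[[i]])
        } else NULL,
        NULL
      )
    }
    truth$noncode_known <- known
    list(hits = bind_rows(rows), truth = truth)
  })
}

#' Default 5-condition, 3-replicate library design
#'
#' Conditions follow the temperature course 25, 4, 0, -4, 44 degrees C
#' (labels `T25`, `T4`, `T0`, `TM4`, `T44`), three replicate libraries each.
#'
#' @param conditions Condition labels in course order.
#' @param n_reps Replicates per condition.
#' @return Design tibble (`library_id`, `condition`, `replicate`).
#' @export
default_design <- function(conditions = c("T25", "T4", "T0", "TM4", "T44"),
                           n_reps = 3) {
  design <- tibble(
    library_id = paste0(rep(conditions, each = n_reps), "_R",
                        rep(seq_len(n_reps), length(conditions))),
    condition = rep(conditions, each = n_reps),
    replicate = rep(seq_len(n_reps), length(conditions))
  )
  order_design(design, conditions)
}

# latent log2 profiles for planted coexpression pairs are rejection-sampled
# to stay mutually separated (|cor| <= 0.8) so recovery at |PCC| > 0.95 is a
# property of the construction, not of the draw
sample_latent <- function(n_cond, existing, max_cor = 0.8, floor_log2 = 2,
                          ceil_log2 = 9) {
  repeat {
    z <- runif(n_cond, floor_log2, ceil_log2)
    if (stats::sd(z) < 0.5) next
    ok <- all(vapply(existing, function(e) abs(cor(z, e)) <= max_cor,
                     logical(1)))
    if (ok) return(z)
  }
}

#' Simulate a replicated FPKM matrix with planted truth
#'
#' Draws per-gene per-condition mean FPKM and multiplies by log-normal
#' replicate noise (`value = mean * exp(N(0, noise_sd))`). Planted structure:
#' \itemize{
#'   \item \strong{DE genes} (`de_spec`: tibble `condition`, `fc`, `n`) have
#'     the named treatment mean at `fc` times their control-condition
#'     baseline (baselines at least 20 FPKM so a pseudocount of 1 cannot
#'     erode the planted fold change);
#'   \item \strong{pattern genes} (`pattern_spec`: tibble `pattern`, `n`)
#'     have adjacent cold-course mean ratios realizing each U/D/M letter
#'     (U drawn in \[3, 4\], D in \[0.25, 0.33\], M in \[0.9, 1.15\], kept
#'     away from the 2x and 0.5x decision boundaries);
#'   \item \strong{coexpression pairs} (`coexpr_spec`: tibble `sign`, `n`)
#'     are source/target gene pairs sharing a latent condition profile, the
#'     target's `log2(FPKM + 1)` an increasing (sign `"positive"`) or
#'     decreasing (sign `"negative"`) affine image of the source's, so the
#'     planted correlation is exactly +1 or -1 at zero noise;
#'   \item remaining genes are background with condition-flat means.
#' }
#'
#' @param design Design tibble (default [default_design()]); at least two
#'   replicates per condition are required for downstream DE testing.
#' @param n_genes Total gene count (must cover all planted genes).
#' @param de_spec,pattern_spec,coexpr_spec Planting specifications (see
#'   above); `NULL` plants nothing of that kind.
#' @param noise_sd Standard deviation of log replicate noise (>= 0).
#' @param seed Integer seed.
#' @param control Control condition for DE planting (default: first
#'   condition of the design).
#' @param course Ordered conditions of the pattern course (default: first
#'   four conditions).
#' @return List with `expr` (tibble `gene_id` + library columns), `design`,
#'   and `truth` (list of tibbles `genes`, `de`, `patterns`, `coexpr`).
#' @export
simulate_expression <- function(design = default_design(), n_genes = 1000,
                                de_spec = NULL, pattern_spec = NULL,
                                coexpr_spec = NULL, noise_sd = 0.1,
                                seed = 1, control = NULL, course = NULL) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  conds <- condition_levels(design)
  if (is.null(control)) control <- conds[[1]]
  if (is.null(course)) course <- conds[seq_len(min(4, length(conds)))]
  n_de <- if (is.null(de_spec)) 0L else sum(de_spec$n)
  n_pat <- if (is.null(pattern_spec)) 0L else sum(pattern_spec$n)
  n_coex <- if (is.null(coexpr_spec)) 0L else 2L * sum(coexpr_spec$n)
  if (n_de + n_pat + n_coex > n_genes) {
    abort("n_genes too small for the requested planted structure")
  }
  with_seed(seed, {
    ids <- sprintf("G%05d", seq_len(n_genes))
    means <- matrix(0, n_genes, length(conds),
                    dimnames = list(ids, conds))
    role <- rep("background", n_genes)
    nxt <- 1L

    de_truth <- NULL
    if (n_de > 0) {
      rows <- list()
      for (r in seq_len(nrow(de_spec))) {
        for (j in seq_len(de_spec$n[[r]])) {
          b <- runif(1, 20, 200)
          means[nxt, ] <- b
          means[nxt, de_spec$condition[[r]]] <- b * de_spec$fc[[r]]
          role[nxt] <- "de"
          rows[[length(rows) + 1L]] <- tibble(
            gene_id = ids[[nxt]], condition = de_spec$condition[[r]],
            fc = de_spec$fc[[r]],
            direction = if (de_spec$fc[[r]] >= 1) "up" else "down"
          )
          nxt <- nxt + 1L
        }
      }
      de_truth <- bind_rows(rows)
    }

    pattern_truth <- NULL
    if (n_pat > 0) {
      ratio_for <- function(letter) switch(letter,
        U = runif(1, 3, 4), D = runif(1, 0.25, 0.33), M = runif(1, 0.9, 1.15))
      rows <- list()
      for (r in seq_len(nrow(pattern_spec))) {
        letters_r <- strsplit(pattern_spec$pattern[[r]], "", fixed = TRUE)[[1]]
        if (length(letters_r) != length(course) - 1 ||
            !all(letters_r %in% c("U", "D", "M"))) {
          abort(paste0("invalid planted pattern: ", pattern_spec$pattern[[r]]))
        }
        for (j in seq_len(pattern_spec$n[[r]])) {
          start <- runif(1, 100, 500)
          prof <- Reduce(function(v, l) v * ratio_for(l), letters_r,
                         init = start, accumulate = TRUE)
          means[nxt, ] <- start
          means[nxt, course] <- prof
          role[nxt] <- "pattern"
          rows[[length(rows) + 1L]] <- tibble(
            gene_id = ids[[nxt]], pattern = pattern_spec$pattern[[r]]
          )
          nxt <- nxt + 1L
        }
      }
      pattern_truth <- bind_rows(rows)
    }

    coexpr_truth <- NULL
    if (n_coex > 0) {
      latents <- list()
      rows <- list()
      for (r in seq_len(nrow(coexpr_spec))) {
        for (j in seq_len(coexpr_spec$n[[r]])) {
          z <- sample_latent(length(conds), latents)
          latents[[length(latents) + 1L]] <- z
          src <- nxt; tgt <- nxt + 1L
          means[src, ] <- 2^z - 1
          if (coexpr_spec$sign[[r]] == "positive") {
            means[tgt, ] <- 2^(0.8 * z + 1) - 1
          } else {
            means[tgt, ] <- 2^(10 - z) - 1
          }
          role[src] <- "coexpr_source"; role[tgt] <- "coexpr_target"
          rows[[length(rows) + 1L]] <- tibble(
            source = ids[[src]], target = ids[[tgt]],
            sign = coexpr_spec$sign[[r]],
            planted_pcc = if (coexpr_spec$sign[[r]] == "positive") 1 else -1
          )
          nxt <- nxt + 2L
        }
      }
      coexpr_truth <- bind_rows(rows)
    }

    if (nxt <= n_genes) {
      n_bg <- n_genes - nxt + 1L
      means[nxt:n_genes, ] <- rlnorm(n_bg, meanlog = log(20), sdlog = 1)
    }

    vals <- matrix(0, n_genes, nrow(design),
                   dimnames = list(ids, design$library_id))
    for (k in seq_len(nrow(design))) {
      mu <- means[, design$condition[[k]]]
      noise <- if (noise_sd > 0) exp(rnorm(n_genes, 0, noise_sd)) else 1
      vals[, k] <- mu * noise
    }
    expr <- tibble(gene_id = ids, as_tibble(vals))
    truth <- list(
      genes = tibble(gene_id = ids, role = role),
      de = de_truth, patterns = pattern_truth, coexpr = coexpr_truth
    )
    list(expr = expr, design = design, truth = truth)
  })
}

#' Simulate a complete linked dataset from one seed
#'
#' Convenience wrapper deriving sub-seeds (`seed`, `seed + 1`, `seed + 2`)
#' for [simulate_transcripts()], [simulate_hits()] and
#' [simulate_expression()].
#'
#' @param seed Integer master seed.
#' @param n_by_class,length_range Passed to [simulate_transcripts()].
#' @param known_fraction Passed to [simulate_hits()].
#' @param design,n_genes,de_spec,pattern_spec,coexpr_spec,noise_sd Passed to
#'   [simulate_expression()].
#' @return List with `transcripts`, `hits`, `truth` (transcript truth),
#'   `expr`, `design`, `expr_truth`.
#' @export
simulate_dataset <- function(seed = 1,
                             n_by_class = c(coding = 50, lncRNA = 50,
                                            pri_miRNA = 10, other_ncRNA = 10,
                                            short_nc = 20),
                             length_range = c(200, 1500),
                             known_fraction = 0.031,
                             design = default_design(), n_genes = 500,
                             de_spec = NULL, pattern_spec = NULL,
                             coexpr_spec = NULL, noise_sd = 0.1) {
  tx <- simulate_transcripts(n_by_class, length_range, seed = seed)
  tx_truth <- mutate(tx$truth, length = tx$transcripts$length)
  hits <- simulate_hits(tx_truth, seed = seed + 1,
                        known_fraction = known_fraction)
  ex <- simulate_expression(design, n_genes, de_spec, pattern_spec,
                            coexpr_spec, noise_sd, seed = seed + 2)
  list(transcripts = tx$transcripts, hits = hits$hits, truth = hits$truth,
       expr = ex$expr, design = ex$design, expr_truth = ex$truth)
}
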