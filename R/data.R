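#' Ten stress-responsive genes differential across a five-temperature course
#'
#' Published per-condition FPKM of ten non-heading Chinese cabbage genes
#' that were called differentially expressed under every temperature
#' treatment (4, 0, -4 and 44 degrees C) against the 25 degrees C control,
#' together with their reported regulation direction and functional
#' annotation. Used as the worked example for the pseudocounted fold-change
#' classification rule: applying [deg_direction()] with `q = 1` to these
#' values reproduces the `regulation` column gene by gene.
#'
#' @return Tibble with columns `gene_id`, `T25`, `T4`, `T0`, `TM4`, `T44`,
#'   `regulation`, `annotation`.
#' @export
nhcc_deg10 <- function() {
  readr::read_tsv(
    system.file("extdata", "nhcc_deg10.tsv", package = "lnckit",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' Seventeen cold-responsive transcription-factor records
#'
#' Published log2 expression ratios and differential probabilities
#' (q-values in the noise-dominance sense, not FDR) of seventeen
#' transcription-factor transcripts of non-heading Chinese cabbage in the
#' three cold comparisons (4, 0 and -4 degrees C versus the 25 degrees C
#' control), with their Pfam family assignments. Every record satisfies the
#' differential-expression criterion (|log2 ratio| >= 1 and q > 0.8) in all
#' three comparisons.
#'
#' @return Tibble with columns `unigene_id`, `pfam_id`, `tf_family`,
#'   `pfam_evalue`, and `log2_*` / `q_*` pairs for `T4`, `T0`, `TM4`.
#' @export
nhcc_tf17 <- function() {
  readr::read_tsv(
    system.file("extdata", "nhcc_tf17.tsv", package = "lnckit",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}
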