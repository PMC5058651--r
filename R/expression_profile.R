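#' Summarize gene-family alteration from a differential-expression table
#'
#' A family gene counts as up-regulated when its adjusted p-value is below
#' `padj_cutoff` with positive log2 fold change (above `min_abs_log2fc` in
#' magnitude), down-regulated likewise with negative fold change; family
#' genes absent from the table are unaltered.  The altered percentage is
#' rounded half-up to one decimal.  Invariant to table row order and to
#' non-family filler genes.
#'
#' @param de data.frame with columns `gene`, `log2fc`, `padj`; gene symbols
#'   must be unique.
#' @param family_genes character vector of family symbols (unique,
#'   non-empty).
#' @param padj_cutoff adjusted-p significance cutoff (default 0.05).
#' @param min_abs_log2fc minimal absolute log2 fold change (default 0, i.e.
#'   no magnitude requirement).
#' @param family_name label for the summary (default "SLC").
#' @param top_n length of the ranked top up/down lists (default 5).
#' @return an object of class `family_alteration_summary`: a list with
#'   `family_name`, `n_family`, `n_up`, `n_down`, `n_altered`,
#'   `pct_altered`, `top_up`, `top_down`.
#' @export
family_alteration_summary <- function(de, family_genes, padj_cutoff = 0.05,
                                      min_abs_log2fc = 0,
                                      family_name = "SLC", top_n = 5) {
  if (!length(family_genes)) stop_input("family_genes must be non-empty")
  if (anyDuplicated(family_genes)) stop_input("family_genes must be unique")
  if (anyDuplicated(de$gene)) stop_input("duplicate gene symbols in DE table")
  if (any(de$padj < 0 | de$padj > 1, na.rm = TRUE))
    stop_input("padj values must lie in [0, 1]")
  fam <- de[de$gene %in% family_genes, , drop = FALSE]
  sig <- !is.na(fam$padj) & fam$padj < padj_cutoff &
    abs(fam$log2fc) > min_abs_log2fc
  up <- sig & fam$log2fc > 0
  down <- sig & fam$log2fc < 0
  n_family <- length(family_genes)
  n_up <- sum(up)
  n_down <- sum(down)
  rank_top <- function(sel) {
    g <- fam[sel, , drop = FALSE]
    g <- g[order(-abs(g$log2fc), g$gene), , drop = FALSE]
    utils::head(g$gene, top_n)
  }
  structure(list(family_name = family_name, n_family = n_family,
                 n_up = n_up, n_down = n_down, n_altered = n_up + n_down,
                 pct_altered = round_half_up(100 * (n_up + n_down) / n_family, 1),
                 top_up = rank_top(up), top_down = rank_top(down)),
            class = "family_alteration_summary")
}

#' @export
print.family_alteration_summary <- function(x, ...) {
  cat(sprintf("%s family: %d/%d altered (%.1f%%): %d up, %d down\n",
              x$family_name, x$n_altered, x$n_family, x$pct_altered,
              x$n_up, x$n_down))
  if (length(x$top_up)) cat("top up:  ", paste(x$top_up, collapse = ", "), "\n")
  if (length(x$top_down)) cat("top down:", paste(x$top_down, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of samples with marker up-regulation
#'
#' Counts samples whose per-sample log2 fold change (tumor vs matched
#' non-tumor) exceeds `min_log2fc`.
#'
#' @param log2fc named numeric vector, or data.frame with `sample_id` and
#'   `log2fc` columns.
#' @param min_log2fc threshold above which a sample counts as up-regulated
#'   (default 0).
#' @return list `n_up`, `n_total`, `pct` (one-decimal, half-up).
#' @export
#' @examples
#' per_sample_up_fraction(c(2.1, 1.4, 3.0, 0.8, -0.5))  # 4 of 5, 80%
per_sample_up_fraction <- function(log2fc, min_log2fc = 0) {
  if (is.data.frame(log2fc)) log2fc <- log2fc$log2fc
  if (!length(log2fc)) stop_input("need at least one sample")
  n_up <- sum(log2fc > min_log2fc)
  list(n_up = n_up, n_total = length(log2fc),
       pct = round_half_up(100 * n_up / length(log2fc), 1))
}

#' Bin an IHC percent-positive score
#'
#' The conventional scoring bins are low (2-20% positive cells) and high
#' (80-100% positive cells); the gaps are filled with explicit `negative`
#' (< 2%) and `intermediate` (> 20% and < 80%) bins so that every value in
#' `[0, 100]` classifies.
#'
#' @param pct_positive percent positive cells, in `[0, 100]` (vectorized).
#' @return character vector in `negative` / `low` / `intermediate` / `high`.
#' @export
#' @examples
#' classify_ihc(c(90, 10, 50))
classify_ihc <- function(pct_positive) {
  if (any(is.na(pct_positive)) || any(pct_positive < 0 | pct_positive > 100))
    stop_input("pct_positive must lie in [0, 100]")
  ifelse(pct_positive < 2, "negative",
         ifelse(pct_positive <= 20, "low",
                ifelse(pct_positive < 80, "intermediate", "high")))
}

#' Cohort fraction of IHC-high cases
#'
#' @param scores data.frame with a `bin` column (from [classify_ihc()]) or a
#'   `pct_positive` column to be binned, or a bare character vector of bins.
#' @return list `n_high`, `n_total`, `pct` (one-decimal, half-up).
#' @export
ihc_cohort_fraction <- function(scores) {
  bins <- if (is.character(scores)) scores
  else if ("bin" %in% names(scores)) scores$bin
  else classify_ihc(scores$pct_positive)
  if (!length(bins)) stop_input("need at least one score")
  n_high <- sum(bins == "high")
  list(n_high = n_high, n_total = length(bins),
       pct = round_half_up(100 * n_high / length(bins), 1))
}
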