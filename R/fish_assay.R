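#' FISH target/reference probe ratio
#'
#' Ratio of the average number of target-gene probe signals per nucleus to
#' the average number of reference (centromeric) probe signals per nucleus.
#' Invariant to cell order and to duplicating the full cell list.
#'
#' @param cells data.frame with integer columns `n_target`, `n_reference`
#'   (one row per evaluated nucleus).
#' @return the ratio (non-negative real).
#' @export
#' @examples
#' fish_ratio(data.frame(n_target = rep(1:2, each = 100),
#'                       n_reference = 2))  # 0.75
fish_ratio <- function(cells) {
  if (!all(c("n_target", "n_reference") %in% names(cells)))
    stop_input("cells must have columns n_target and n_reference")
  if (nrow(cells) < 1) stop_input("fish_ratio: need at least one cell")
  if (any(cells$n_target < 0) || any(cells$n_reference < 0))
    stop_input("probe counts must be non-negative")
  mref <- mean(cells$n_reference)
  if (mref == 0)
    stop_input("assay failure: all reference probe counts are zero")
  mean(cells$n_target) / mref
}

#' Classify a FISH ratio into gene-loss bins
#'
#' A ratio above `no_loss_min` means no loss; between `homo_max` and
#' `no_loss_min` (both boundaries inclusive) a heterozygous loss; below
#' `homo_max` a biallelic (homozygous) loss.  Defaults are the conventional
#' 0.75 / 0.5 cut-offs; the two boundary values themselves classify as
#' heterozygous loss.  The three bins partition `[0, Inf)`.
#'
#' @param ratio non-negative FISH ratio (vectorized).
#' @param no_loss_min upper het bin edge (default 0.75).
#' @param homo_max lower het bin edge (default 0.5).
#' @return character vector in `no_loss` / `het_loss` / `homo_loss`.
#' @export
#' @examples
#' classify_fish(c(1, 0.6, 0.2))
classify_fish <- function(ratio, no_loss_min = 0.75, homo_max = 0.5) {
  if (any(is.na(ratio)) || any(ratio < 0))
    stop_input("ratio must be non-negative")
  ifelse(ratio > no_loss_min, "no_loss",
         ifelse(ratio >= homo_max, "het_loss", "homo_loss"))
}

#' Evaluate one FISH case
#'
#' Computes the probe ratio and the loss call for one case.  Cases with
#' fewer than `min_cells` evaluated nuclei are still computed but flagged
#' sub-threshold, with a warning.
#'
#' @param sample_id case identifier.
#' @param cells per-nucleus counts (see [fish_ratio()]).
#' @param min_cells evaluated-nuclei threshold below which the result is
#'   flagged (default 200).
#' @param no_loss_min,homo_max bin edges, see [classify_fish()].
#' @return one-row data.frame: `sample_id`, `n_cells`, `ratio`, `call`,
#'   `sub_threshold`.
#' @export
evaluate_fish_case <- function(sample_id, cells, min_cells = 200,
                               no_loss_min = 0.75, homo_max = 0.5) {
  if (nrow(cells) == 0) stop_input("empty cell list for case %s", sample_id)
  r <- fish_ratio(cells)
  flag <- nrow(cells) < min_cells
  if (flag)
    warning(sprintf("case %s: only %d cells evaluated (< %d)",
                    sample_id, nrow(cells), min_cells), call. = FALSE)
  data.frame(sample_id = sample_id, n_cells = nrow(cells), ratio = r,
             call = classify_fish(r, no_loss_min, homo_max),
             sub_threshold = flag, stringsAsFactors = FALSE)
}

#' Evaluate every case in a long per-cell FISH table
#'
#' @param fish long data.frame (`sample_id`, `cell_index`, `n_target`,
#'   `n_reference`).
#' @param ... passed to [evaluate_fish_case()].
#' @return data.frame with one row per case, ordered by `sample_id`.
#' @export
evaluate_fish_table <- function(fish, ...) {
  ids <- sort(unique(fish$sample_id))
  out <- do.call(rbind, lapply(ids, function(s) {
    evaluate_fish_case(s, fish[fish$sample_id == s, , drop = FALSE], ...)
  }))
  rownames(out) <- NULL
  out
}
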