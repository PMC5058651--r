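#' Integrate multi-assay evidence into a final gene status for one sample
#'
#' Combines array copy-number status, FISH status and sequencing evidence (a
#' truncating SNV together with LOH at the locus) into one call.  Any assay
#' reporting the deeper loss wins: the final status is the maximum over an
#' ordered severity scale `no_loss < het_loss < homo_loss`, where a
#' truncating SNV under LOH counts as biallelic inactivation.  Discordance
#' in the opposite direction (one assay deep loss, another no loss) still
#' resolves to the deeper loss but is noted for review.
#'
#' @param array_status,fish_status one of `no_loss`, `het_loss`,
#'   `homo_loss`, `not_assayed`.
#' @param truncating_snv logical: truncating (nonsense/frameshift) SNV at
#'   the locus; `NA` when the sample was not sequenced.
#' @param loh_at_locus logical: LOH over the locus; `NA` if unknown.
#' @return list with `final_status` and `evidence_note`.
#' @export
#' @examples
#' integrate_sample("no_loss", "homo_loss")                     # FISH wins
#' integrate_sample("not_assayed", "no_loss", TRUE, TRUE)       # SNV + LOH
integrate_sample <- function(array_status = "not_assayed",
                             fish_status = "not_assayed",
                             truncating_snv = FALSE,
                             loh_at_locus = FALSE) {
  states <- c("no_loss", "het_loss", "homo_loss", "not_assayed")
  if (!(array_status %in% states) || !(fish_status %in% states))
    stop_input("statuses must be one of %s", paste(states, collapse = ", "))
  snv_hit <- isTRUE(truncating_snv) && isTRUE(loh_at_locus)
  snv_assayed <- !is.na(truncating_snv)
  assayed <- c(array = array_status != "not_assayed",
               fish = fish_status != "not_assayed",
               snv = snv_assayed)
  if (!any(assayed))
    stop_input("no evidence source assayed for this sample")

  sev <- c(no_loss = 0L, het_loss = 1L, homo_loss = 2L)
  score <- c(array = if (assayed[["array"]]) sev[[array_status]] else -1L,
             fish = if (assayed[["fish"]]) sev[[fish_status]] else -1L,
             snv = if (snv_hit) 2L else if (snv_assayed) 0L else -1L)
  final <- max(score)
  final_status <- names(sev)[final + 1L]

  drivers <- names(score)[score == final & score >= 0L]
  lab <- function(src) switch(src,
    array = paste0("array:", array_status),
    fish = paste0("fish:", fish_status),
    snv = if (snv_hit) "snv+loh:biallelic" else "snv:none")
  note <- paste(vapply(drivers, lab, ""), collapse = ",")
  discord <- final == 2L &&
    ((assayed[["array"]] && array_status == "no_loss") ||
     (assayed[["fish"]] && fish_status == "no_loss"))
  if (discord) note <- paste0(note, ";discordant_no_loss_assay")
  list(final_status = final_status, evidence_note = note)
}

#' Integrate an evidence table over a cohort
#'
#' Row-wise [integrate_sample()] over a per-sample evidence data.frame.
#'
#' @param evidence data.frame with columns `sample_id`, `array_status`,
#'   `fish_status`, `truncating_snv`, `loh_at_locus` (and optionally
#'   `gene`).
#' @return the input plus `final_status` and `evidence_note` columns.
#' @export
integrate_gene_status <- function(evidence) {
  need <- c("sample_id", "array_status", "fish_status",
            "truncating_snv", "loh_at_locus")
  miss <- setdiff(need, names(evidence))
  if (length(miss))
    stop_input("evidence table lacks columns: %s", paste(miss, collapse = ", "))
  res <- lapply(seq_len(nrow(evidence)), function(i)
    integrate_sample(evidence$array_status[i], evidence$fish_status[i],
                     evidence$truncating_snv[i], evidence$loh_at_locus[i]))
  evidence$final_status <- vapply(res, `[[`, "", "final_status")
  evidence$evidence_note <- vapply(res, `[[`, "", "evidence_note")
  evidence
}

#' Cohort frequencies of integrated gene loss
#'
#' Counts final statuses across the cohort and reports percentages rounded
#' half-up to one decimal.
#'
#' @param statuses data.frame with `sample_id` and `final_status` (one row
#'   per sample; duplicated sample ids are an error).
#' @return one-row data.frame: `n_samples`, `n_homo`, `n_het`, `n_no_loss`,
#'   `pct_homo`, `pct_het`, `pct_no_loss`, `pct_any_loss`.
#' @export
#' @examples
#' x <- data.frame(sample_id = paste0("S", 1:16),
#'                 final_status = rep(c("homo_loss", "het_loss", "no_loss"),
#'                                    c(8, 2, 6)))
#' cohort_frequencies(x)  # 50.0 / 12.5 / 62.5
cohort_frequencies <- function(statuses) {
  if (nrow(statuses) == 0) stop_input("empty status table")
  if (anyDuplicated(statuses$sample_id))
    stop_input("duplicate sample_id in status table")
  n <- nrow(statuses)
  n_homo <- sum(statuses$final_status == "homo_loss")
  n_het <- sum(statuses$final_status == "het_loss")
  n_no <- sum(statuses$final_status == "no_loss")
  if (n_homo + n_het + n_no != n)
    stop_input("final_status values outside no_loss/het_loss/homo_loss")
  data.frame(n_samples = n, n_homo = n_homo, n_het = n_het, n_no_loss = n_no,
             pct_homo = round_half_up(100 * n_homo / n, 1),
             pct_het = round_half_up(100 * n_het / n, 1),
             pct_no_loss = round_half_up(100 * n_no / n, 1),
             pct_any_loss = round_half_up(100 * (n_homo + n_het) / n, 1))
}

#' Published per-sample CDKN2A evidence for the 16-case cohort
#'
#' The assay-level evidence tabulated for the 16 collecting duct carcinoma
#' cases: biallelic deletions detected by SNP array in CDC1/2/4, a
#' FISH-only biallelic loss in CDC6, a FISH heterozygous loss in CDC3, a
#' nonsense mutation under LOH in CDC5, FISH calls for the nine FFPE-only
#' cases, and no-loss results for the remainder.  This is the worked-example
#' input whose integration yields 8/16 homozygous (50.0%), 2/16
#' heterozygous (12.5%) and 62.5% any loss.
#'
#' @return data.frame `sample_id`, `gene`, `array_status`, `fish_status`,
#'   `truncating_snv`, `loh_at_locus`.
#' @export
cdkn2a_evidence <- function() {
  s <- paste0("CDC", 1:16)
  array_status <- rep("not_assayed", 16)
  array_status[c(1, 2, 4)] <- "homo_loss"
  array_status[c(5, 7)] <- "no_loss"
  fish_status <- rep("no_loss", 16)
  fish_status[c(1, 2, 4, 6, 8, 9, 10)] <- "homo_loss"
  fish_status[c(3, 11)] <- "het_loss"
  truncating <- rep(FALSE, 16)
  truncating[5] <- TRUE
  loh <- rep(FALSE, 16)
  loh[c(1, 2, 4, 5)] <- TRUE
  data.frame(sample_id = s, gene = "CDKN2A", array_status = array_status,
             fish_status = fish_status, truncating_snv = truncating,
             loh_at_locus = loh, stringsAsFactors = FALSE)
}
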