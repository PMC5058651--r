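#' @name io
#' @title Tab-separated readers and writers
#'
#' @description
#' All exchange formats are plain TSV.  The variant candidate table uses the
#' uppercase column convention `SAMPLE, CHROM, POS, REF, ALT, CLASS,
#' CONTEXT, T_REF_FWD, T_REF_REV, T_ALT_FWD, T_ALT_REV, N_REF_FWD,
#' N_REF_REV, N_ALT_FWD, N_ALT_REV, CONSEQUENCE, GENE`; segment files follow
#' the SEG convention (`sample, chrom, start, end, logR`) with an extra
#' `loh` column.  Segment and gene coordinates are 1-based inclusive
#' internally; BED input (0-based half-open) is converted on read.
NULL

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

variant_cols <- c(sample_id = "SAMPLE", chrom = "CHROM", pos = "POS",
                  ref = "REF", alt = "ALT", variant_class = "CLASS",
                  context = "CONTEXT",
                  t_ref_fwd = "T_REF_FWD", t_ref_rev = "T_REF_REV",
                  t_alt_fwd = "T_ALT_FWD", t_alt_rev = "T_ALT_REV",
                  n_ref_fwd = "N_REF_FWD", n_ref_rev = "N_REF_REV",
                  n_alt_fwd = "N_ALT_FWD", n_alt_rev = "N_ALT_REV",
                  consequence = "CONSEQUENCE", gene = "GENE")

#' @rdname io
#' @param candidates candidate table in the internal (lowercase) schema.
#' @param path file path.
#' @export
write_variant_table <- function(candidates, path) {
  out <- candidates[, names(variant_cols)[names(variant_cols) %in% names(candidates)],
                    drop = FALSE]
  names(out) <- variant_cols[names(out)]
  write_tsv_file(out, path)
}

#' @rdname io
#' @export
read_variant_table <- function(path) {
  df <- read_tsv_file(path)
  inv <- stats::setNames(names(variant_cols), variant_cols)
  hit <- names(df) %in% names(inv)
  names(df)[hit] <- inv[names(df)[hit]]
  miss <- setdiff(setdiff(names(variant_cols), c("consequence", "gene")), names(df))
  if (length(miss))
    stop_input("variant table %s lacks columns: %s", path,
               paste(variant_cols[miss], collapse = ", "))
  df
}

#' @rdname io
#' @param segments segment data.frame (`sample_id`, `chrom`, `start`,
#'   `end`, `logR`, `loh`).
#' @export
write_seg <- function(segments, path) {
  out <- segments[, c("sample_id", "chrom", "start", "end", "logR", "loh")]
  names(out) <- c("sample", "chrom", "start", "end", "logR", "loh")
  write_tsv_file(out, path)
}

#' @rdname io
#' @export
read_seg <- function(path) {
  df <- read_tsv_file(path)
  names(df) <- tolower(names(df))
  if ("logr" %in% names(df)) names(df)[names(df) == "logr"] <- "logR"
  if ("sample" %in% names(df)) names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "chrom", "start", "end", "logR")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("SEG file %s lacks columns: %s", path, paste(miss, collapse = ", "))
  if (!"loh" %in% names(df)) df$loh <- FALSE
  df$loh <- as.logical(df$loh)
  if (any(df$start > df$end)) stop_input("SEG file %s has start > end", path)
  df[, c("sample_id", "chrom", "start", "end", "logR", "loh")]
}

#' @rdname io
#' @details `read_gene_bed()` reads gene intervals from BED (via
#'   rtracklayer, so 0-based half-open coordinates become 1-based
#'   inclusive); the BED name field supplies the gene symbol.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name %||% paste0("gene", seq_along(gr))
  data.frame(gene = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' @rdname io
#' @param genes gene interval data.frame (1-based inclusive).
#' @export
write_gene_bed <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param df any plain table (FISH per-cell counts, DE records, IHC scores,
#'   verdicts, ...).
#' @export
write_table_tsv <- function(df, path) write_tsv_file(df, path)

#' @rdname io
#' @export
read_table_tsv <- function(path) read_tsv_file(path)
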