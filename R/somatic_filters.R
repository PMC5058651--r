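#' Stranded allele counts
#'
#' Container for the read evidence at one site in one sample: reference and
#' alternative allele read counts on the forward and reverse strands.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev non-negative integer read counts.
#' @return an object of class `stranded_counts` (a named list).
#' @export
#' @examples
#' stranded_counts(ref_fwd = 20, ref_rev = 22, alt_fwd = 8, alt_rev = 7)
stranded_counts <- function(ref_fwd = 0, ref_rev = 0, alt_fwd = 0, alt_rev = 0) {
  x <- list(ref_fwd = ref_fwd, ref_rev = ref_rev,
            alt_fwd = alt_fwd, alt_rev = alt_rev)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stop_input("stranded_counts: '%s' must be a single non-negative integer", nm)
    x[[nm]] <- as.integer(v)
  }
  structure(x, class = "stranded_counts")
}

as_stranded <- function(x) {
  if (inherits(x, "stranded_counts")) return(x)
  nms <- c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  if (is.numeric(x) && length(x) == 4 && is.null(names(x)))
    return(stranded_counts(x[1], x[2], x[3], x[4]))
  if (!all(nms %in% names(x)))
    stop_input("expected stranded counts with fields %s", paste(nms, collapse = ", "))
  stranded_counts(x[["ref_fwd"]], x[["ref_rev"]], x[["alt_fwd"]], x[["alt_rev"]])
}

alt_total <- function(x) x$alt_fwd + x$alt_rev
depth_of <- function(x) x$ref_fwd + x$ref_rev + x$alt_fwd + x$alt_rev

#' Filtering parameters for somatic candidate variants
#'
#' Thresholds for the five post-caller filters.  The filter criteria
#' (alternative allele absent in the matched normal; alt reads significantly
#' enriched in tumor by a one-sided Fisher exact test; mutant allele seen on
#' both strands; no homopolymer run at the variant position; indel support
#' confirmed by realignment against the mutant template) are fixed, but each
#' numeric cut-off is configurable here.
#'
#' @param fisher_alpha significance level for the one-sided Fisher test
#'   (default 0.05).
#' @param max_normal_alt_reads maximum alt reads tolerated in the normal for
#'   the "absent in normal" criterion (default 0, i.e. strictly absent).
#' @param min_alt_per_strand minimum alt reads required on each strand
#'   (default 1).
#' @param homopolymer_min_run minimal single-base run length considered a
#'   homopolymer (default 5).
#' @param homopolymer_max_dist maximal distance (bases) between the run and
#'   the variant position for the run to disqualify it (default 1, i.e.
#'   touching or immediately adjacent).
#' @param indel_min_tumor_support minimum tumor reads supporting the mutant
#'   template after realignment (default 2).
#' @param indel_max_normal_support maximum normal reads supporting the mutant
#'   template after realignment (default 0).
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(fisher_alpha = 0.05,
                          max_normal_alt_reads = 0,
                          min_alt_per_strand = 1,
                          homopolymer_min_run = 5,
                          homopolymer_max_dist = 1,
                          indel_min_tumor_support = 2,
                          indel_max_normal_support = 0) {
  if (fisher_alpha <= 0 || fisher_alpha >= 1)
    stop_input("fisher_alpha must lie in (0, 1)")
  if (homopolymer_min_run < 2)
    stop_input("homopolymer_min_run must be >= 2")
  if (max_normal_alt_reads < 0 || min_alt_per_strand < 0 ||
      indel_min_tumor_support < 0 || indel_max_normal_support < 0)
    stop_input("count thresholds must be non-negative")
  structure(list(fisher_alpha = fisher_alpha,
                 max_normal_alt_reads = as.integer(max_normal_alt_reads),
                 min_alt_per_strand = as.integer(min_alt_per_strand),
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 homopolymer_max_dist = as.integer(homopolymer_max_dist),
                 indel_min_tumor_support = as.integer(indel_min_tumor_support),
                 indel_max_normal_support = as.integer(indel_max_normal_support)),
            class = "filter_params")
}

#' One-sided Fisher exact p-value for tumor alt-allele enrichment (vector form)
#'
#' Exact p-value that the alt-allele fraction in the tumor is higher than in
#' the matched normal, conditioning on the margins of the 2x2 table
#' `[(tumor alt, tumor ref), (normal alt, normal ref)]`.  The p-value is the
#' upper tail of the hypergeometric distribution at the observed tumor alt
#' count.  All four arguments are recycled to a common length, so the whole
#' candidate table can be scored in one call.
#'
#' @param alt_tumor,ref_tumor alt and ref read counts in tumor.
#' @param alt_normal,ref_normal alt and ref read counts in normal.
#' @return numeric vector of p-values in `[0, 1]`.
#' @seealso [fisher_tumor_enrichment()] for the single-candidate interface on
#'   stranded counts.
#' @export
#' @examples
#' fisher_p_greater(10, 10, 0, 20)
fisher_p_greater <- function(alt_tumor, ref_tumor, alt_normal, ref_normal) {
  n <- max(length(alt_tumor), length(ref_tumor),
           length(alt_normal), length(ref_normal))
  at <- rep_len(alt_tumor, n); rt <- rep_len(ref_tumor, n)
  an <- rep_len(alt_normal, n); rn <- rep_len(ref_normal, n)
  if (any(is.na(c(at, rt, an, rn))) || any(c(at, rt, an, rn) < 0))
    stop_input("read counts must be non-negative and non-missing")
  td <- at + rt
  nd <- an + rn
  if (any(td < 1) || any(nd < 1))
    stop_input("Fisher enrichment test requires depth >= 1 in both tumor and normal")
  K <- at + an          # total alt reads across both samples
  N <- td + nd          # total depth
  # P(X >= alt_tumor) with X ~ Hypergeom(white = K, black = N - K, drawn = td)
  stats::phyper(at - 1, K, N - K, td, lower.tail = FALSE)
}

#' One-sided Fisher exact test for tumor alt enrichment
#'
#' @param tumor,normal stranded allele counts ([stranded_counts()] objects or
#'   anything coercible: a named list/vector with fields `ref_fwd`, `ref_rev`,
#'   `alt_fwd`, `alt_rev`).  Strands are collapsed before testing.
#' @return the one-sided p-value (alt enriched in tumor).
#' @export
#' @examples
#' fisher_tumor_enrichment(stranded_counts(20, 20, 5, 5),
#'                         stranded_counts(25, 25, 0, 0))
fisher_tumor_enrichment <- function(tumor, normal) {
  tumor <- as_stranded(tumor)
  normal <- as_stranded(normal)
  fisher_p_greater(alt_total(tumor), tumor$ref_fwd + tumor$ref_rev,
                   alt_total(normal), normal$ref_fwd + normal$ref_rev)
}

#' Is the alternative allele (effectively) absent in the matched normal?
#'
#' @param normal stranded allele counts for the normal sample.
#' @param params [filter_params()].
#' @return `TRUE` iff total normal alt reads `<= max_normal_alt_reads`.
#' @export
check_normal_absence <- function(normal, params = filter_params()) {
  alt_total(as_stranded(normal)) <= params$max_normal_alt_reads
}

#' Is the mutant allele present on both strand orientations?
#'
#' @param tumor stranded allele counts for the tumor sample.
#' @param params [filter_params()].
#' @return `TRUE` iff both strands carry at least `min_alt_per_strand` alt
#'   reads.
#' @export
check_orientation <- function(tumor, params = filter_params()) {
  tumor <- as_stranded(tumor)
  tumor$alt_fwd >= params$min_alt_per_strand &&
    tumor$alt_rev >= params$min_alt_per_strand
}

#' Detect a homopolymer run at the variant position
#'
#' Sequencing errors concentrate in and next to single-base runs, so
#' candidates whose reference context carries a long run at (or within
#' `homopolymer_max_dist` of) the variant position are flagged.  The context
#' string must have odd length with the variant at its centre.
#'
#' @param context reference context (A/C/G/T/N), odd length, variant at the
#'   centre position.
#' @param params [filter_params()]; uses `homopolymer_min_run` and
#'   `homopolymer_max_dist`.
#' @return `TRUE` if a disqualifying homopolymer is present (i.e. the
#'   candidate FAILS the homopolymer criterion).
#' @export
#' @examples
#' detect_homopolymer("CGTAAAAATGC")  # 5-A run under the centre -> TRUE
#' detect_homopolymer("ACGTACGTACG")  # no run -> FALSE
detect_homopolymer <- function(context, params = filter_params()) {
  if (length(context) != 1 || is.na(context) || nchar(context) %% 2 != 1)
    stop_input("context must be a single string of odd length")
  cs <- chars(toupper(context))
  if (!all(cs %in% c("A", "C", "G", "T", "N")))
    stop_input("context contains characters outside A/C/G/T/N")
  centre <- (length(cs) + 1L) / 2L
  r <- rle(cs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- r$lengths >= params$homopolymer_min_run
  if (!any(long)) return(FALSE)
  d <- params$homopolymer_max_dist
  any(starts[long] - d <= centre & ends[long] + d >= centre)
}

#' Count reads supporting the mutant allele by realignment at an indel site
#'
#' Rebuilds the local haplotype by substituting the alternative allele for the
#' reference allele inside the reference window, then scores every read
#' (tumor and normal) ungapped against both templates at its stated offset.
#' On the mutant template, a read that starts to the right of the indel start
#' has its offset shifted by the net indel length.  A read supports the
#' mutant allele iff its mismatch count against the mutant template is
#' strictly lower than against the reference template; ties count as
#' non-supporting.
#'
#' @param reads data.frame with columns `sample` (`"tumor"`/`"normal"`),
#'   `seq` (read bases) and `offset` (0-based start of the read relative to
#'   the window start, in reference coordinates).
#' @param ref_allele,alt_allele the indel alleles, VCF style (e.g. ref `"A"`,
#'   alt `"ATT"` for an insertion).
#' @param window reference subsequence around the indel site.
#' @param site 1-based position within `window` at which `ref_allele` starts.
#' @return named integer vector `c(tumor_support = , normal_support = )`.
#' @export
realign_indel_support <- function(reads, ref_allele, alt_allele, window, site) {
  req <- c("sample", "seq", "offset")
  if (!all(req %in% names(reads)))
    stop_input("reads must have columns %s", paste(req, collapse = ", "))
  if (site < 1 || site + nchar(ref_allele) - 1 > nchar(window))
    stop_input("window does not contain the indel site")
  mut <- paste0(substr(window, 1, site - 1), alt_allele,
                substr(window, site + nchar(ref_allele), nchar(window)))
  delta <- nchar(alt_allele) - nchar(ref_allele)

  mismatches <- function(read, off, tmpl) {
    # off is the 0-based start of the read on tmpl; ungapped comparison over
    # the overlapping stretch only
    start_t <- off + 1L
    end_t <- off + nchar(read)
    s <- max(1L, start_t)
    e <- min(nchar(tmpl), end_t)
    if (e < s) return(Inf)  # no overlap with this template interpretation
    a <- chars(substr(tmpl, s, e))
    b <- chars(substr(read, s - start_t + 1L, e - start_t + 1L))
    sum(a != b)
  }

  support <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    off <- reads$offset[i]
    rd <- reads$seq[i]
    mm_ref <- mismatches(rd, off, window)
    off_mut <- if (off + 1L > site) off + delta else off
    mm_mut <- mismatches(rd, off_mut, mut)
    if (is.infinite(mm_ref) && is.infinite(mm_mut)) {
      message(sprintf("read %d overlaps neither template; counted as non-supporting", i))
      support[i] <- FALSE
    } else {
      support[i] <- mm_mut < mm_ref
    }
  }
  c(tumor_support = sum(support[reads$sample == "tumor"]),
    normal_support = sum(support[reads$sample == "normal"]))
}

candidate_key <- function(sample_id, chrom, pos) paste(sample_id, chrom, pos, sep = ":")

#' Apply the somatic filter chain to a candidate table
#'
#' Evaluates, per candidate: (1) alt allele absent in the matched normal;
#' (2) one-sided Fisher exact enrichment of alt reads in tumor; (3) mutant
#' allele present on both strands; (4) no homopolymer run at the variant
#' position; and, for indels only, (5) realignment support against the mutant
#' template.  A candidate is called somatic iff all applicable filters pass.
#'
#' @param candidates data.frame in the candidate-table schema (see
#'   [simulate_variants()] / [read_variant_table()]): columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_class`, `context`, `consequence`,
#'   and the eight stranded count columns `t_ref_fwd` ... `n_alt_rev`.
#' @param params [filter_params()].
#' @param indel_reads for candidates with `variant_class != "snv"`, a named
#'   list keyed by `"sample_id:chrom:pos"`; each element a list with fields
#'   `reads` (see [realign_indel_support()]), `window` and `site`.
#' @return data.frame of verdicts: the identifying candidate columns plus
#'   `pass_normal_absence`, `fisher_p`, `pass_fisher`, `pass_orientation`,
#'   `pass_homopolymer`, `pass_realignment` (vacuously `TRUE` for SNVs) and
#'   `is_somatic`.
#' @export
apply_somatic_filters <- function(candidates, params = filter_params(),
                                  indel_reads = NULL) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
            "context", "t_ref_fwd", "t_ref_rev", "t_alt_fwd", "t_alt_rev",
            "n_ref_fwd", "n_ref_rev", "n_alt_fwd", "n_alt_rev")
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop_input("candidate table lacks columns: %s", paste(miss, collapse = ", "))
  n <- nrow(candidates)
  if (n == 0) {
    out <- candidates[, intersect(c(need[1:6], "consequence", "gene"), names(candidates)), drop = FALSE]
    out$pass_normal_absence <- logical(0); out$fisher_p <- numeric(0)
    out$pass_fisher <- logical(0); out$pass_orientation <- logical(0)
    out$pass_homopolymer <- logical(0); out$pass_realignment <- logical(0)
    out$is_somatic <- logical(0)
    return(out)
  }

  t_alt <- candidates$t_alt_fwd + candidates$t_alt_rev
  t_ref <- candidates$t_ref_fwd + candidates$t_ref_rev
  n_alt <- candidates$n_alt_fwd + candidates$n_alt_rev
  n_ref <- candidates$n_ref_fwd + candidates$n_ref_rev

  pass_normal <- n_alt <= params$max_normal_alt_reads
  fisher_p <- fisher_p_greater(t_alt, t_ref, n_alt, n_ref)
  pass_fisher <- fisher_p < params$fisher_alpha
  pass_orient <- candidates$t_alt_fwd >= params$min_alt_per_strand &
    candidates$t_alt_rev >= params$min_alt_per_strand
  hp <- vapply(candidates$context, detect_homopolymer, logical(1),
               params = params, USE.NAMES = FALSE)
  pass_homopolymer <- !hp

  pass_realign <- rep(TRUE, n)
  is_indel <- candidates$variant_class != "snv"
  if (any(is_indel)) {
    keys <- candidate_key(candidates$sample_id, candidates$chrom, candidates$pos)
    for (i in which(is_indel)) {
      ir <- indel_reads[[keys[i]]]
      if (is.null(ir))
        stop_input("indel candidate %s has no read set for realignment", keys[i])
      sup <- realign_indel_support(ir$reads, candidates$ref[i], candidates$alt[i],
                                   ir$window, ir$site)
      pass_realign[i] <- sup[["tumor_support"]] >= params$indel_min_tumor_support &&
        sup[["normal_support"]] <= params$indel_max_normal_support
    }
  }

  keep <- intersect(c("sample_id", "chrom", "pos", "ref", "alt",
                      "variant_class", "consequence", "gene"), names(candidates))
  out <- candidates[, keep, drop = FALSE]
  out$pass_normal_absence <- pass_normal
  out$fisher_p <- fisher_p
  out$pass_fisher <- pass_fisher
  out$pass_orientation <- pass_orient
  out$pass_homopolymer <- pass_homopolymer
  out$pass_realignment <- pass_realign
  out$is_somatic <- pass_normal & pass_fisher & pass_orient &
    pass_homopolymer & pass_realign
  rownames(out) <- NULL
  out
}

#' Tally somatic calls by predicted consequence
#'
#' @param verdicts output of [apply_somatic_filters()]; a `consequence`
#'   column is expected (missing/NA labels are counted as `"other"`).
#' @return data.frame with columns `consequence` and `n`, one row per label
#'   in `missense`, `nonsense`, `frameshift`, `protein_deletion`, `other`,
#'   plus a `total` attribute equal to the number of somatic calls.
#' @export
summarize_calls <- function(verdicts) {
  labs <- c("missense", "nonsense", "frameshift", "protein_deletion", "other")
  cons <- if ("consequence" %in% names(verdicts)) verdicts$consequence else
    rep(NA_character_, nrow(verdicts))
  cons[is.na(cons) | !(cons %in% labs)] <- "other"
  keep <- verdicts$is_somatic
  counts <- vapply(labs, function(l) sum(keep & cons == l), integer(1))
  out <- data.frame(consequence = labs, n = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(counts)
  out
}
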