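#' Configuration for the synthetic tumor/normal cohort generator
#'
#' Builds and validates the single configuration object consumed by all
#' generators ([simulate_variants()], [simulate_segments()],
#' [simulate_fish()], [simulate_de_table()], [simulate_ihc()],
#' [simulate_marker_lfc()]).  Defaults encode a 16-sample collecting duct
#' carcinoma cohort with the mix of CDKN2A alterations reported for this
#' tumor type (three array-detected biallelic deletions, one FISH-only
#' biallelic deletion, two heterozygous losses, one nonsense mutation under
#' copy-neutral LOH) and a solute-carrier expression profile with 41
#' up-regulated and 95 down-regulated family members of 300.
#'
#' @param n_samples cohort size.
#' @param n_somatic_sites,n_germline_sites,n_artifact_sites numbers of
#'   simulated variant candidate sites per class.
#' @param tumor_depth,normal_depth read depth at each site.
#' @param somatic_vaf variant allele fraction of somatic (and strand-artifact)
#'   sites, in (0, 1].
#' @param strand_bias_prob probability that an artifact site is a
#'   single-strand artifact (otherwise it is a homopolymer-context artifact).
#' @param homopolymer_len length of the single-base run embedded at
#'   homopolymer-artifact sites (>= 5 so the default filter fires).
#' @param seq_error_rate per-read probability of an alt call in the normal
#'   (and of noise alt reads generally); default 0 gives the clean mode in
#'   which downstream truth recovery is exact.
#' @param context_k half-width of the reference context string; contexts have
#'   length `2 * context_k + 1`.
#' @param genes data.frame of gene intervals (`gene`, `chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @param cn_truth data.frame (`sample_id`, `gene`, `state`, `loh`): true
#'   copy state per array-assayed sample (`state` one of `no_loss`,
#'   `het_loss`, `homo_loss`; `NA` = sample not array-assayed); `loh` logical
#'   (permits copy-neutral LOH with `state = "no_loss"`).
#' @param cn_sd standard deviation of simulated segment logR around its
#'   state centre (0, -0.7, -2.0 for no/het/homo loss).
#' @param fish_truth data.frame (`sample_id`, `state`): true FISH state per
#'   case.
#' @param fish_noise per-count probability that a probe signal is misread by
#'   one (dropped or gained), in `[0, 0.5)`.
#' @param fish_normal_fraction fraction of evaluated nuclei that are
#'   admixed non-neoplastic (diploid) cells, in `[0, 1)`.
#' @param snv_truth data.frame (`sample_id`, `gene`): samples carrying a
#'   truncating (nonsense) somatic SNV in the gene.
#' @param de_family_up,de_family_down number of family genes that are
#'   significantly up-/down-regulated.
#' @param family_size size of the gene family.
#' @param de_filler_up,de_filler_down,de_filler_null non-family filler genes
#'   (significant up, significant down, non-significant).
#' @param ihc_high,ihc_low numbers of IHC cases scored high (80-100% positive
#'   cells) and low (2-20%).
#' @param marker_up,marker_total per-sample marker log2 fold changes: how
#'   many of how many samples are up-regulated.
#' @param seed master seed; each generator derives its own substream from it
#'   so growing one generator's output does not shift another's.
#' @return validated `sim_config` object (a list).
#' @export
sim_config <- function(n_samples = 16,
                       n_somatic_sites = 200,
                       n_germline_sites = 200,
                       n_artifact_sites = 100,
                       tumor_depth = 100,
                       normal_depth = 100,
                       somatic_vaf = 0.3,
                       strand_bias_prob = 0.5,
                       homopolymer_len = 6,
                       seq_error_rate = 0,
                       context_k = 10,
                       genes = demo_genes(),
                       cn_truth = demo_cn_truth(),
                       cn_sd = 0.1,
                       fish_truth = demo_fish_truth(),
                       fish_noise = 0.05,
                       fish_normal_fraction = 0.2,
                       snv_truth = demo_snv_truth(),
                       de_family_up = 41,
                       de_family_down = 95,
                       family_size = 300,
                       de_filler_up = 2838,
                       de_filler_down = 1856,
                       de_filler_null = 1000,
                       ihc_high = 12,
                       ihc_low = 3,
                       marker_up = 4,
                       marker_total = 5,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_samples", "n_somatic_sites", "n_germline_sites",
              "n_artifact_sites", "de_family_up", "de_family_down",
              "family_size", "de_filler_up", "de_filler_down",
              "de_filler_null", "ihc_high", "ihc_low", "marker_up",
              "marker_total", "context_k", "homopolymer_len")
  for (nm in counts)
    if (cfg[[nm]] < 0 || cfg[[nm]] != round(cfg[[nm]]))
      stop_input("sim_config: '%s' must be a non-negative integer", nm)
  if (tumor_depth < 1 || normal_depth < 1)
    stop_input("sim_config: read depths must be positive")
  if (somatic_vaf <= 0 || somatic_vaf > 1)
    stop_input("sim_config: somatic_vaf must lie in (0, 1]")
  for (nm in c("strand_bias_prob", "seq_error_rate"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop_input("sim_config: '%s' must lie in [0, 1]", nm)
  if (fish_noise < 0 || fish_noise >= 0.5)
    stop_input("sim_config: fish_noise must lie in [0, 0.5)")
  if (fish_normal_fraction < 0 || fish_normal_fraction >= 1)
    stop_input("sim_config: fish_normal_fraction must lie in [0, 1)")
  if (de_family_up + de_family_down > family_size)
    stop_input("sim_config: de_family_up + de_family_down exceeds family_size")
  if (marker_up > marker_total)
    stop_input("sim_config: marker_up exceeds marker_total")
  if (homopolymer_len > 0 && homopolymer_len < 5)
    stop_input("sim_config: homopolymer_len must be >= 5 (or 0 to disable)")
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
demo_genes <- function() {
  # CDKN2A, hg19
  data.frame(gene = "CDKN2A", chrom = "chr9",
             start = 21967752L, end = 21995043L,
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
demo_cn_truth <- function() {
  s <- paste0("CDC", 1:16)
  state <- rep(NA_character_, 16)
  state[c(1, 2, 4)] <- "homo_loss"  # focal biallelic deletions on the array
  state[c(5, 7)] <- "no_loss"       # assayed, no copy loss
  loh <- rep(FALSE, 16)
  loh[c(1, 2, 4, 5)] <- TRUE        # CDC5: copy-neutral LOH at the locus
  data.frame(sample_id = s, gene = "CDKN2A", state = state, loh = loh,
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
demo_fish_truth <- function() {
  s <- paste0("CDC", 1:16)
  state <- rep("no_loss", 16)
  state[c(1, 2, 4, 6, 8, 9, 10)] <- "homo_loss"
  state[c(3, 11)] <- "het_loss"
  data.frame(sample_id = s, state = state, stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
demo_snv_truth <- function() {
  data.frame(sample_id = "CDC5", gene = "CDKN2A", stringsAsFactors = FALSE)
}

# random DNA of length n with no single-base run longer than max_run, so
# clean contexts can never trip the homopolymer filter
random_dna <- function(n, max_run = 3) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  run <- 0L
  last <- ""
  for (i in seq_len(n)) {
    pool <- if (run >= max_run) setdiff(bases, last) else bases
    b <- sample(pool, 1)
    run <- if (b == last) run + 1L else 1L
    last <- b
    out[i] <- b
  }
  paste(out, collapse = "")
}

split_strands <- function(total) {
  fwd <- stats::rbinom(length(total), total, 0.5)
  cbind(fwd = fwd, rev = total - fwd)
}

#' Simulate tumor/normal variant candidates with ground-truth labels
#'
#' Emits one candidate per configured site.  Somatic sites draw tumor alt
#' reads from `Binomial(tumor_depth, somatic_vaf)` split evenly across
#' strands, with normal alt reads arising only through `seq_error_rate`
#' (default 0).  Germline sites are heterozygous (alt fraction ~0.5) in both
#' tumor and normal.  Strand artifacts place all alt reads on one strand;
#' homopolymer artifacts sit inside an embedded single-base run.  Every
#' record carries a reference context of length `2 * context_k + 1` centred
#' on the variant.  Samples listed in `snv_truth` additionally receive one
#' clean somatic nonsense SNV inside the named gene.
#'
#' @param config a [sim_config()].
#' @return list with elements `candidates` (the candidate table) and `truth`
#'   (data.frame `sample_id`, `chrom`, `pos`, `label` with label one of
#'   `somatic`, `germline`, `artifact_strand`, `artifact_homopolymer`).
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 101), {
    ns <- config$n_somatic_sites
    ng <- config$n_germline_sites
    na <- config$n_artifact_sites
    labels <- c(rep("somatic", ns), rep("germline", ng))
    art_strand <- if (na > 0) stats::runif(na) < config$strand_bias_prob else logical(0)
    labels <- c(labels, ifelse(art_strand, "artifact_strand", "artifact_homopolymer"))
    n <- length(labels)
    extra <- config$snv_truth
    n_extra <- if (is.null(extra)) 0L else nrow(extra)

    make_row <- function(i, label) {
      k <- config$context_k
      td <- config$tumor_depth
      nd <- config$normal_depth
      ctx <- random_dna(2 * k + 1)
      cs <- chars(ctx)
      centre <- k + 1L
      if (label == "artifact_homopolymer") {
        # run of homopolymer_len covering the variant position
        b <- cs[centre]
        hi <- min(length(cs), centre + config$homopolymer_len - 1L)
        cs[centre:hi] <- b
        ctx <- paste(cs, collapse = "")
      }
      ref <- cs[centre]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      t_alt <- switch(label,
        somatic = stats::rbinom(1, td, config$somatic_vaf),
        germline = stats::rbinom(1, td, 0.5),
        artifact_strand = stats::rbinom(1, td, config$somatic_vaf),
        artifact_homopolymer = stats::rbinom(1, td, config$somatic_vaf))
      n_alt <- if (label == "germline") stats::rbinom(1, nd, 0.5) else
        stats::rbinom(1, nd, config$seq_error_rate)
      ts <- if (label == "artifact_strand") {
        if (stats::runif(1) < 0.5) c(t_alt, 0L) else c(0L, t_alt)
      } else {
        f <- stats::rbinom(1, t_alt, 0.5); c(f, t_alt - f)
      }
      trs <- split_strands(td - t_alt)
      nas <- split_strands(n_alt)
      nrs <- split_strands(nd - n_alt)
      cons <- if (label %in% c("somatic", "germline"))
        sample(c("missense", "nonsense", "other"), 1, prob = c(0.85, 0.07, 0.08))
      else "other"
      list(context = ctx, ref = ref, alt = alt,
           t_ref_fwd = trs[1, "fwd"], t_ref_rev = trs[1, "rev"],
           t_alt_fwd = ts[1], t_alt_rev = ts[2],
           n_ref_fwd = nrs[1, "fwd"], n_ref_rev = nrs[1, "rev"],
           n_alt_fwd = nas[1, "fwd"], n_alt_rev = nas[1, "rev"],
           consequence = cons)
    }

    rows <- lapply(seq_len(n), function(i) make_row(i, labels[i]))
    sample_pool <- config$cn_truth$sample_id[!is.na(config$cn_truth$state)]
    if (!length(sample_pool)) sample_pool <- paste0("S", seq_len(max(1, config$n_samples)))
    sample_id <- if (n > 0) sample_pool[(seq_len(n) - 1L) %% length(sample_pool) + 1L] else character(0)
    chrom <- if (n > 0) paste0("chr", (seq_len(n) - 1L) %% 22L + 1L) else character(0)
    pos <- if (n > 0) 100000L + seq_len(n) * 1000L else integer(0)

    df <- data.frame(
      sample_id = sample_id, chrom = chrom, pos = pos,
      ref = vapply(rows, `[[`, "", "ref"),
      alt = vapply(rows, `[[`, "", "alt"),
      variant_class = rep("snv", n),
      context = vapply(rows, `[[`, "", "context"),
      consequence = vapply(rows, `[[`, "", "consequence"),
      gene = rep(NA_character_, n),
      t_ref_fwd = vapply(rows, function(r) as.integer(r$t_ref_fwd), 1L),
      t_ref_rev = vapply(rows, function(r) as.integer(r$t_ref_rev), 1L),
      t_alt_fwd = vapply(rows, function(r) as.integer(r$t_alt_fwd), 1L),
      t_alt_rev = vapply(rows, function(r) as.integer(r$t_alt_rev), 1L),
      n_ref_fwd = vapply(rows, function(r) as.integer(r$n_ref_fwd), 1L),
      n_ref_rev = vapply(rows, function(r) as.integer(r$n_ref_rev), 1L),
      n_alt_fwd = vapply(rows, function(r) as.integer(r$n_alt_fwd), 1L),
      n_alt_rev = vapply(rows, function(r) as.integer(r$n_alt_rev), 1L),
      stringsAsFactors = FALSE)

    # truncating SNVs configured per sample x gene (always clean somatic)
    if (n_extra > 0) {
      gx <- merge(extra, config$genes, by = "gene", sort = FALSE)
      xrows <- lapply(seq_len(nrow(gx)), function(i) make_row(i, "somatic"))
      xdf <- data.frame(
        sample_id = gx$sample_id,
        chrom = gx$chrom,
        pos = as.integer((gx$start + gx$end) %/% 2),
        ref = vapply(xrows, `[[`, "", "ref"),
        alt = vapply(xrows, `[[`, "", "alt"),
        variant_class = "snv",
        context = vapply(xrows, `[[`, "", "context"),
        consequence = "nonsense",
        gene = gx$gene,
        t_ref_fwd = vapply(xrows, function(r) as.integer(r$t_ref_fwd), 1L),
        t_ref_rev = vapply(xrows, function(r) as.integer(r$t_ref_rev), 1L),
        t_alt_fwd = vapply(xrows, function(r) as.integer(r$t_alt_fwd), 1L),
        t_alt_rev = vapply(xrows, function(r) as.integer(r$t_alt_rev), 1L),
        n_ref_fwd = vapply(xrows, function(r) as.integer(r$n_ref_fwd), 1L),
        n_ref_rev = vapply(xrows, function(r) as.integer(r$n_ref_rev), 1L),
        n_alt_fwd = vapply(xrows, function(r) as.integer(r$n_alt_fwd), 1L),
        n_alt_rev = vapply(xrows, function(r) as.integer(r$n_alt_rev), 1L),
        stringsAsFactors = FALSE)
      df <- rbind(df, xdf)
      labels <- c(labels, rep("somatic", nrow(gx)))
    }

    truth <- data.frame(sample_id = df$sample_id, chrom = df$chrom,
                        pos = df$pos, label = labels,
                        stringsAsFactors = FALSE)
    list(candidates = df, truth = truth)
  })
}

#' Simulate copy-number segments from per-sample gene copy states
#'
#' For every array-assayed sample x gene in `cn_truth`, emits a focal
#' segment spanning the gene (plus 50 kb flanks) with logR drawn from a
#' normal around the state centre (0 for no loss, -0.7 for single-copy loss,
#' -2.0 for biallelic loss; sd `cn_sd`), plus a copy-neutral background
#' segment spanning the rest of the chromosome.  LOH flags are copied from
#' the truth table (so copy-neutral LOH is representable).  Coordinates are
#' 1-based inclusive.
#'
#' @param config a [sim_config()].
#' @return list with `segments` (data.frame `sample_id`, `chrom`, `start`,
#'   `end`, `logR`, `loh`) and `truth` (the non-NA rows of `cn_truth`).
#' @export
simulate_segments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  centres <- c(no_loss = 0, het_loss = -0.7, homo_loss = -2.0)
  with_seed(derive_seed(config$seed, 202), {
    tr <- config$cn_truth[!is.na(config$cn_truth$state), , drop = FALSE]
    if (nrow(tr) == 0 || nrow(config$genes) == 0)
      return(list(segments = data.frame(sample_id = character(0), chrom = character(0),
                                        start = integer(0), end = integer(0),
                                        logR = numeric(0), loh = logical(0),
                                        stringsAsFactors = FALSE),
                  truth = tr))
    tr <- merge(tr, config$genes, by = "gene", sort = FALSE)
    segs <- lapply(seq_len(nrow(tr)), function(i) {
      st <- tr$state[i]
      focal_start <- max(1L, tr$start[i] - 50000L)
      focal_end <- tr$end[i] + 50000L
      rbind(
        data.frame(sample_id = tr$sample_id[i], chrom = tr$chrom[i],
                   start = 1L, end = 250000000L,
                   logR = stats::rnorm(1, 0, config$cn_sd), loh = FALSE,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = tr$sample_id[i], chrom = tr$chrom[i],
                   start = focal_start, end = focal_end,
                   logR = stats::rnorm(1, centres[[st]], config$cn_sd),
                   loh = isTRUE(tr$loh[i]), stringsAsFactors = FALSE))
    })
    segments <- do.call(rbind, segs)
    rownames(segments) <- NULL
    list(segments = segments,
         truth = config$cn_truth[!is.na(config$cn_truth$state),
                                 c("sample_id", "gene", "state", "loh")])
  })
}

#' Simulate per-cell FISH probe counts for one case
#'
#' Each evaluated nucleus is a non-neoplastic (diploid, 2 target / 2
#' reference signals) cell with probability `fish_normal_fraction`, otherwise
#' a neoplastic cell whose base counts follow the true state: (2,2) for no
#' loss, (1,2) for heterozygous loss, (0,2) for biallelic loss.  Each count
#' is then independently misread by one (plus or minus with equal chance)
#' with probability `fish_noise`, floored at zero.
#'
#' @param config a [sim_config()] (supplies `fish_noise` and
#'   `fish_normal_fraction`).
#' @param true_state one of `"no_loss"`, `"het_loss"`, `"homo_loss"`.
#' @param n_cells number of nuclei evaluated (default 200).
#' @param seed optional seed for this draw; `NULL` uses the current RNG
#'   state (useful for replicate sweeps).
#' @return data.frame with columns `cell_index`, `n_target`, `n_reference`.
#' @export
simulate_fish <- function(config, true_state, n_cells = 200, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_cells < 1) stop_input("simulate_fish: n_cells must be >= 1")
  base <- switch(true_state,
                 no_loss = c(2L, 2L),
                 het_loss = c(1L, 2L),
                 homo_loss = c(0L, 2L),
                 stop_input("unknown FISH state '%s'", true_state))
  draw <- function() {
    is_normal <- stats::runif(n_cells) < config$fish_normal_fraction
    tgt <- ifelse(is_normal, 2L, base[1])
    ref <- ifelse(is_normal, 2L, base[2])
    perturb <- function(x) {
      hit <- stats::runif(n_cells) < config$fish_noise
      sgn <- ifelse(stats::runif(n_cells) < 0.5, -1L, 1L)
      pmax(0L, x + ifelse(hit, sgn, 0L))
    }
    data.frame(cell_index = seq_len(n_cells),
               n_target = perturb(tgt), n_reference = perturb(ref))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a differential-expression table with a configured family signal
#'
#' Exactly `de_family_up` family genes receive positive log2 fold change with
#' adjusted p below 0.05, `de_family_down` receive negative log2 fold change
#' below 0.05, and the remaining family genes are non-significant.  Filler
#' (non-family) genes are added per the config.  Family gene symbols are
#' synthetic (`SLCF001`, ...) unless supplied.
#'
#' @param config a [sim_config()].
#' @param family_genes optional character vector of family symbols (length
#'   `family_size`); auto-generated when `NULL`.
#' @return list with `de` (data.frame `gene`, `log2fc`, `padj`),
#'   `family_genes`, and `truth` (data.frame `gene`, `direction` in
#'   `up`/`down`/`none`).
#' @export
simulate_de_table <- function(config, family_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fam <- family_genes %||% sprintf("SLCF%03d", seq_len(config$family_size))
  if (length(fam) != config$family_size)
    stop_input("family_genes must have length family_size (%d)", config$family_size)
  nu <- config$de_family_up; nd <- config$de_family_down
  with_seed(derive_seed(config$seed, 303), {
    dir <- c(rep("up", nu), rep("down", nd),
             rep("none", config$family_size - nu - nd))
    lfc <- c(stats::runif(nu, 1, 6.5), -stats::runif(nd, 1, 8.5),
             stats::runif(config$family_size - nu - nd, -0.4, 0.4))
    padj <- c(stats::runif(nu + nd, 1e-8, 0.049),
              stats::runif(config$family_size - nu - nd, 0.05, 1))
    fill_n <- config$de_filler_up + config$de_filler_down + config$de_filler_null
    filler <- sprintf("GENE%05d", seq_len(fill_n))
    fl_lfc <- c(stats::runif(config$de_filler_up, 0.5, 9),
                -stats::runif(config$de_filler_down, 0.5, 9),
                stats::runif(config$de_filler_null, -0.4, 0.4))
    fl_p <- c(stats::runif(config$de_filler_up + config$de_filler_down, 1e-8, 0.049),
              stats::runif(config$de_filler_null, 0.05, 1))
    de <- data.frame(gene = c(fam, filler),
                     log2fc = c(lfc, fl_lfc),
                     padj = c(padj, fl_p),
                     stringsAsFactors = FALSE)
    list(de = de, family_genes = fam,
         truth = data.frame(gene = fam, direction = dir, stringsAsFactors = FALSE))
  })
}

#' Simulate IHC percent-positive scores
#'
#' `ihc_high` cases draw percent-positive in 80-100, `ihc_low` in 2-20.
#'
#' @param config a [sim_config()].
#' @return data.frame `sample_id`, `pct_positive`.
#' @export
simulate_ihc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 404), {
    n <- config$ihc_high + config$ihc_low
    data.frame(sample_id = sprintf("IHC%02d", seq_len(n)),
               pct_positive = c(stats::runif(config$ihc_high, 80, 100),
                                stats::runif(config$ihc_low, 2, 20)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate per-sample marker log2 fold changes
#'
#' `marker_up` of `marker_total` samples get positive log2 fold change, the
#' rest negative (tumor vs matched non-tumor for a single marker gene).
#'
#' @param config a [sim_config()].
#' @return data.frame `sample_id`, `log2fc`.
#' @export
simulate_marker_lfc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 505), {
    n <- config$marker_total
    up <- config$marker_up
    data.frame(sample_id = sprintf("T%02d", seq_len(n)),
               log2fc = c(stats::runif(up, 0.5, 4), -stats::runif(n - up, 0.2, 2)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a read set at an indel site with per-read provenance
#'
#' Generates tumor and normal reads as verbatim substrings of either the
#' reference window or the mutant template (reference with the alternative
#' allele substituted), at offsets that always span the indel, together with
#' the per-read truth labels.  Used to exercise and test
#' [realign_indel_support()].
#'
#' @param ref_allele,alt_allele indel alleles, VCF style.
#' @param n_tumor_alt,n_tumor_ref,n_normal_alt,n_normal_ref read counts drawn
#'   from the mutant/reference template for each sample.
#' @param read_len read length (default 20).
#' @param window_len length of the reference window (default 61; the indel
#'   sits at its centre).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return list with `reads` (data.frame `sample`, `seq`, `offset`), `truth`
#'   (adds `from_mutant`), `window`, `site`, `ref_allele`, `alt_allele`.
#' @export
simulate_indel_reads <- function(ref_allele = "A", alt_allele = "ATT",
                                 n_tumor_alt = 6, n_tumor_ref = 4,
                                 n_normal_alt = 0, n_normal_ref = 10,
                                 read_len = 20, window_len = 61,
                                 seed = NULL) {
  gen <- function() {
    site <- (window_len + 1L) %/% 2L
    window <- random_dna(window_len)
    delta <- nchar(alt_allele) - nchar(ref_allele)
    mut <- paste0(substr(window, 1, site - 1), alt_allele,
                  substr(window, site + nchar(ref_allele), nchar(window)))
    span <- max(nchar(ref_allele), nchar(alt_allele))
    lo <- max(0L, site + span - read_len)
    hi <- min(site - 2L, window_len - read_len, nchar(mut) - read_len)
    if (hi < lo)
      stop_input("read_len/window_len leave no valid read placements")
    one <- function(sample, from_mutant) {
      off <- sample(lo:hi, 1)
      tmpl <- if (from_mutant) mut else window
      data.frame(sample = sample,
                 seq = substr(tmpl, off + 1, off + read_len),
                 offset = off, from_mutant = from_mutant,
                 stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, c(
      lapply(seq_len(n_tumor_alt), function(i) one("tumor", TRUE)),
      lapply(seq_len(n_tumor_ref), function(i) one("tumor", FALSE)),
      lapply(seq_len(n_normal_alt), function(i) one("normal", TRUE)),
      lapply(seq_len(n_normal_ref), function(i) one("normal", FALSE))))
    rownames(truth) <- NULL
    list(reads = truth[, c("sample", "seq", "offset")], truth = truth,
         window = window, site = site,
         ref_allele = ref_allele, alt_allele = alt_allele)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate the full synthetic cohort
#'
#' Runs every generator under the config's master seed and returns all
#' tables with their ground-truth sidecars.
#'
#' @param config a [sim_config()].
#' @return list with elements `variants`, `variant_truth`, `segments`,
#'   `cn_truth`, `fish` (long per-cell table over all cases), `fish_truth`,
#'   `de`, `family_genes`, `de_truth`, `ihc`, `marker_lfc`, `snv_truth`,
#'   `genes`, and the `config` itself.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  v <- simulate_variants(config)
  s <- simulate_segments(config)
  d <- simulate_de_table(config)
  ft <- config$fish_truth
  fish <- do.call(rbind, lapply(seq_len(nrow(ft)), function(i) {
    cells <- simulate_fish(config, ft$state[i], n_cells = 200,
                           seed = derive_seed(config$seed, 600 + i))
    cbind(sample_id = ft$sample_id[i], cells, stringsAsFactors = FALSE)
  }))
  list(variants = v$candidates, variant_truth = v$truth,
       segments = s$segments, cn_truth = s$truth,
       fish = fish, fish_truth = ft,
       de = d$de, family_genes = d$family_genes, de_truth = d$truth,
       ihc = simulate_ihc(config), marker_lfc = simulate_marker_lfc(config),
       snv_truth = config$snv_truth, genes = config$genes, config = config)
}

severity_rank <- c(no_loss = 0L, het_loss = 1L, homo_loss = 2L)

#' True integrated gene status per sample implied by a configuration
#'
#' The severest state across the configured array truth, FISH truth and
#' truncating-SNV-under-LOH truth; this is what a perfect noise-free run of
#' the whole pipeline must recover.
#'
#' @param config a [sim_config()].
#' @param gene gene symbol (default the first configured gene).
#' @return data.frame `sample_id`, `final_status`.
#' @export
cohort_truth_status <- function(config, gene = config$genes$gene[1]) {
  ft <- config$fish_truth
  out <- data.frame(sample_id = ft$sample_id,
                    final_status = ft$state, stringsAsFactors = FALSE)
  ct <- config$cn_truth[config$cn_truth$gene == gene, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    s <- out$sample_id[i]
    sev <- severity_rank[[out$final_status[i]]]
    j <- match(s, ct$sample_id)
    loh <- FALSE
    if (!is.na(j)) {
      loh <- isTRUE(ct$loh[j])
      if (!is.na(ct$state[j])) sev <- max(sev, severity_rank[[ct$state[j]]])
    }
    trunc <- !is.null(config$snv_truth) &&
      any(config$snv_truth$sample_id == s & config$snv_truth$gene == gene)
    if (trunc && loh) sev <- 2L
    out$final_status[i] <- names(severity_rank)[sev + 1L]
  }
  out
}
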