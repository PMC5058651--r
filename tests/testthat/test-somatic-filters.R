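test_that("fisher enrichment p-value matches enumeration oracle and fisher.test", {
  cases <- list(c(10, 10, 0, 20), c(5, 5, 5, 5), c(30, 70, 0, 100),
                c(1, 99, 1, 99), c(12, 0, 0, 8), c(0, 10, 5, 5))
  for (cs in cases) {
    p <- fisher_p_greater(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p, fisher_enum_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(cs[1], cs[2], cs[3], cs[4]), 2,
                                    byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("fisher enrichment has the expected trivial behaviour", {
  # no alt reads anywhere: no enrichment possible
  expect_equal(fisher_p_greater(0, 30, 0, 30), 1.0)
  # identical alt proportions are never significantly enriched
  expect_gt(fisher_p_greater(5, 5, 5, 5), 0.5)
  # p-values always in [0, 1]
  set.seed(42)
  at <- sample(0:30, 50, TRUE); rt <- sample(1:30, 50, TRUE)
  an <- sample(0:30, 50, TRUE); rn <- sample(1:30, 50, TRUE)
  p <- fisher_p_greater(at, rt, an, rn)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("fisher enrichment is monotone in the tumor alt count", {
  # fixed depths and fixed normal counts: more tumor alt reads can only
  # strengthen the enrichment
  for (n_alt in c(0, 2, 5)) {
    p <- fisher_p_greater(0:40, 40:0, n_alt, 40 - n_alt)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("fisher enrichment rejects zero-depth input instead of returning NaN", {
  expect_error(fisher_p_greater(0, 0, 5, 5), "depth")
  expect_error(fisher_p_greater(5, 5, 0, 0), "depth")
  expect_error(fisher_tumor_enrichment(stranded_counts(0, 0, 0, 0),
                                       stranded_counts(5, 5, 0, 0)), "depth")
})

test_that("normal-absence check respects the configurable tolerance", {
  p0 <- filter_params()
  p1 <- filter_params(max_normal_alt_reads = 1)
  expect_true(check_normal_absence(stranded_counts(25, 25, 0, 0), p0))
  expect_false(check_normal_absence(stranded_counts(25, 25, 1, 0), p0))
  expect_true(check_normal_absence(stranded_counts(25, 25, 1, 0), p1))  # boundary inclusive
  expect_false(check_normal_absence(stranded_counts(25, 25, 1, 1), p1))
})

test_that("orientation check requires alt reads on both strands", {
  p <- filter_params()
  expect_false(check_orientation(stranded_counts(20, 20, 3, 0), p))
  expect_true(check_orientation(stranded_counts(20, 20, 2, 1), p))
  expect_false(check_orientation(stranded_counts(20, 20, 0, 0), p))
  p2 <- filter_params(min_alt_per_strand = 2)
  expect_false(check_orientation(stranded_counts(20, 20, 2, 1), p2))
})

test_that("homopolymer detection flags runs at or adjacent to the variant", {
  # 5-A run under the centre position
  expect_true(detect_homopolymer("CGTAAAAATGC"))
  # no run of length >= 2 at all
  expect_false(detect_homopolymer("ACGTACGTACG"))
  # run of 4 adjacent to the centre is below the default threshold
  expect_false(detect_homopolymer("ACGTTTTCGTA"))
  # run >= 5 immediately adjacent (distance 1) to the centre fails it
  expect_true(detect_homopolymer("ACGATGAAAAA"))
  # same run two bases away no longer touches the variant
  expect_false(detect_homopolymer("GACGATGCTGAAAAA"))
  # configurable run length
  expect_true(detect_homopolymer("ACGTTTTCGTA",
                                 filter_params(homopolymer_min_run = 4)))
  expect_error(detect_homopolymer("ACGTXCGTACG"), "A/C/G/T/N")
  expect_error(detect_homopolymer("ACGT"), "odd")
})

test_that("indel realignment separates template-derived reads perfectly", {
  rs <- simulate_indel_reads(ref_allele = "A", alt_allele = "ATT",
                             n_tumor_alt = 6, n_tumor_ref = 4,
                             n_normal_alt = 0, n_normal_ref = 10, seed = 5)
  sup <- realign_indel_support(rs$reads, rs$ref_allele, rs$alt_allele,
                               rs$window, rs$site)
  expect_identical(unname(sup["tumor_support"]), 6L)
  expect_identical(unname(sup["normal_support"]), 0L)
})

test_that("indel realignment counts match per-read provenance for deletions too", {
  rs <- simulate_indel_reads(ref_allele = "ATTG", alt_allele = "A",
                             n_tumor_alt = 5, n_tumor_ref = 5,
                             n_normal_alt = 2, n_normal_ref = 8, seed = 11)
  sup <- realign_indel_support(rs$reads, rs$ref_allele, rs$alt_allele,
                               rs$window, rs$site)
  truth_t <- sum(rs$truth$from_mutant[rs$truth$sample == "tumor"])
  truth_n <- sum(rs$truth$from_mutant[rs$truth$sample == "normal"])
  expect_identical(unname(sup["tumor_support"]), truth_t)
  expect_identical(unname(sup["normal_support"]), truth_n)
})

test_that("reads identical to the reference template never support the mutant", {
  rs <- simulate_indel_reads(ref_allele = "A", alt_allele = "AGG",
                             n_tumor_alt = 0, n_tumor_ref = 8,
                             n_normal_alt = 0, n_normal_ref = 8, seed = 2)
  sup <- realign_indel_support(rs$reads, rs$ref_allele, rs$alt_allele,
                               rs$window, rs$site)
  expect_identical(unname(sup), c(0L, 0L))
})

test_that("filter chain verdict is the conjunction of its applicable flags", {
  params <- filter_params()
  clean <- make_candidate()
  germline <- make_candidate(t_alt_fwd = 13L, t_alt_rev = 12L,
                             t_ref_fwd = 13L, t_ref_rev = 12L,
                             n_alt_fwd = 12L, n_alt_rev = 13L,
                             n_ref_fwd = 13L, n_ref_rev = 12L)
  strand_art <- make_candidate(t_alt_fwd = 10L, t_alt_rev = 0L)
  homopoly <- make_candidate(context = "ACGTACGTACAAAAACGTACG")
  v <- apply_somatic_filters(rbind(clean, germline, strand_art, homopoly), params)

  expect_true(v$is_somatic[1])
  expect_true(all(v[1, c("pass_normal_absence", "pass_fisher",
                         "pass_orientation", "pass_homopolymer",
                         "pass_realignment")] == TRUE))
  # germline: fails normal absence and Fisher, nothing else
  expect_false(v$is_somatic[2])
  expect_false(v$pass_normal_absence[2])
  expect_false(v$pass_fisher[2])
  expect_true(v$pass_orientation[2])
  # strand artifact: fails orientation only
  expect_false(v$is_somatic[3])
  expect_false(v$pass_orientation[3])
  expect_true(v$pass_normal_absence[3] && v$pass_fisher[3] && v$pass_homopolymer[3])
  # homopolymer context: fails the context filter only
  expect_false(v$is_somatic[4])
  expect_false(v$pass_homopolymer[4])
  expect_true(v$pass_normal_absence[4] && v$pass_fisher[4] && v$pass_orientation[4])
  # conjunction invariant over all rows
  applicable <- v$pass_normal_absence & v$pass_fisher & v$pass_orientation &
    v$pass_homopolymer & v$pass_realignment
  expect_identical(v$is_somatic, applicable)
})

test_that("indel candidates demand a read set and use realignment support", {
  params <- filter_params()
  rs <- simulate_indel_reads(seed = 9)
  indel <- make_candidate(ref = rs$ref_allele, alt = rs$alt_allele,
                          variant_class = "ins", consequence = "frameshift")
  expect_error(apply_somatic_filters(indel, params), "read set")
  key <- paste("S1", "chr1", 1000, sep = ":")
  reads <- setNames(list(list(reads = rs$reads, window = rs$window,
                              site = rs$site)), key)
  v <- apply_somatic_filters(indel, params, indel_reads = reads)
  expect_true(v$pass_realignment)
  expect_true(v$is_somatic)
  # normal-contaminated read set fails the realignment support thresholds
  rs2 <- simulate_indel_reads(n_normal_alt = 3, seed = 9)
  reads2 <- setNames(list(list(reads = rs2$reads, window = rs2$window,
                               site = rs2$site)), key)
  v2 <- apply_somatic_filters(indel, params, indel_reads = reads2)
  expect_false(v2$pass_realignment)
  expect_false(v2$is_somatic)
})

test_that("summarize_calls counts somatic-passing candidates per consequence", {
  v <- apply_somatic_filters(rbind(
    make_candidate(), make_candidate(pos = 2000L),
    make_candidate(pos = 3000L, consequence = "nonsense"),
    make_candidate(pos = 4000L, consequence = "missense",
                   n_alt_fwd = 10L, n_alt_rev = 10L,
                   t_alt_fwd = 13L, t_alt_rev = 12L)))  # fails, not counted
  s <- summarize_calls(v)
  expect_identical(s$n[s$consequence == "missense"], 2L)
  expect_identical(s$n[s$consequence == "nonsense"], 1L)
  expect_identical(attr(s, "total"), 3L)
  empty <- summarize_calls(apply_somatic_filters(make_candidate()[0, ]))
  expect_true(all(empty$n == 0L))
})
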