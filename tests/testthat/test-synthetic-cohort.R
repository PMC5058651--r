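test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(tumor_depth = 0), "depth")
  expect_error(sim_config(somatic_vaf = 0), "somatic_vaf")
  expect_error(sim_config(fish_noise = 0.5), "fish_noise")
  expect_error(sim_config(de_family_up = 200, de_family_down = 150,
                          family_size = 300), "exceeds")
  expect_error(sim_config(n_somatic_sites = -1), "non-negative")
})

test_that("an empty site configuration emits an empty candidate list", {
  cfg <- sim_config(n_somatic_sites = 0, n_germline_sites = 0,
                    n_artifact_sites = 0, snv_truth = NULL)
  v <- simulate_variants(cfg)
  expect_identical(nrow(v$candidates), 0L)
  expect_identical(nrow(v$truth), 0L)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7)
  expect_identical(simulate_variants(cfg), simulate_variants(cfg))
  expect_identical(simulate_segments(cfg), simulate_segments(cfg))
  expect_identical(simulate_de_table(cfg), simulate_de_table(cfg))
  expect_identical(simulate_fish(cfg, "het_loss", 200, seed = 3),
                   simulate_fish(cfg, "het_loss", 200, seed = 3))
  # a different seed changes the draw
  expect_false(identical(simulate_variants(cfg),
                         simulate_variants(sim_config(seed = 8))))
})

test_that("every emitted variant record carries exactly one truth label", {
  cfg <- sim_config(n_somatic_sites = 40, n_germline_sites = 30,
                    n_artifact_sites = 20, snv_truth = NULL, seed = 3)
  v <- simulate_variants(cfg)
  expect_identical(nrow(v$candidates), 90L)
  expect_identical(nrow(v$truth), 90L)
  expect_true(all(v$truth$label %in%
    c("somatic", "germline", "artifact_strand", "artifact_homopolymer")))
  expect_identical(sum(v$truth$label == "somatic"), 40L)
  expect_identical(sum(v$truth$label == "germline"), 30L)
  expect_identical(sum(v$truth$label %in%
    c("artifact_strand", "artifact_homopolymer")), 20L)
})

test_that("somatic sites draw tumor alt reads at the configured VAF", {
  cfg <- sim_config(n_somatic_sites = 200, n_germline_sites = 0,
                    n_artifact_sites = 0, tumor_depth = 100,
                    somatic_vaf = 0.3, snv_truth = NULL, seed = 1)
  v <- simulate_variants(cfg)
  alt_frac <- (v$candidates$t_alt_fwd + v$candidates$t_alt_rev) /
    (v$candidates$t_alt_fwd + v$candidates$t_alt_rev +
       v$candidates$t_ref_fwd + v$candidates$t_ref_rev)
  expect_lt(abs(mean(alt_frac) - 0.3), 0.02)
  # clean mode: normals carry no alt reads at somatic sites
  expect_true(all(v$candidates$n_alt_fwd + v$candidates$n_alt_rev == 0))
})

test_that("simulated site classes have their characteristic signatures", {
  cfg <- sim_config(n_somatic_sites = 50, n_germline_sites = 50,
                    n_artifact_sites = 60, snv_truth = NULL, seed = 5)
  v <- simulate_variants(cfg)
  cand <- v$candidates
  lab <- v$truth$label
  germ <- lab == "germline"
  expect_gt(mean((cand$n_alt_fwd + cand$n_alt_rev)[germ] / 100), 0.4)
  strand <- lab == "artifact_strand"
  expect_true(all(cand$t_alt_fwd[strand] == 0 | cand$t_alt_rev[strand] == 0))
  homo <- lab == "artifact_homopolymer"
  expect_true(all(vapply(cand$context[homo], detect_homopolymer, logical(1))))
  clean <- lab %in% c("somatic", "germline")
  expect_false(any(vapply(cand$context[clean], detect_homopolymer, logical(1))))
  expect_true(all(nchar(cand$context) == 21))
})

test_that("simulated segments encode the configured copy states", {
  truth <- data.frame(sample_id = c("A", "A", "B"),
                      gene = c("G1", "G2", "G1"),
                      state = c("homo_loss", "no_loss", "het_loss"),
                      loh = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  genes <- data.frame(gene = c("G1", "G2"), chrom = c("chr9", "chr10"),
                      start = c(100000L, 500000L), end = c(150000L, 600000L),
                      stringsAsFactors = FALSE)
  cfg <- sim_config(cn_truth = truth, genes = genes, cn_sd = 0.1, seed = 2)
  s <- simulate_segments(cfg)
  st <- suppressMessages(genome_loss_profile(s$segments, genes))
  merged <- merge(st, truth, by = c("sample_id", "gene"))
  covered <- !is.na(merged$state)
  expect_identical(merged$status[covered], merged$state[covered])
  # homozygous-loss gene is covered by a deeply negative segment
  a_g1 <- merged$min_overlapping_logR[merged$sample_id == "A" & merged$gene == "G1"]
  expect_lt(a_g1, -1)
  # all-no-loss truth yields no segment below the loss threshold over genes
  cfg0 <- sim_config(cn_truth = transform(truth, state = "no_loss", loh = FALSE),
                     genes = genes, cn_sd = 0.1, seed = 2)
  s0 <- simulate_segments(cfg0)
  st0 <- suppressMessages(genome_loss_profile(s0$segments, genes))
  expect_true(all(st0$status == "no_loss"))
  # empty gene list: empty truth mapping
  cfgE <- sim_config(cn_truth = truth[0, ], genes = genes[0, ], seed = 2)
  expect_identical(nrow(simulate_segments(cfgE)$segments), 0L)
})

test_that("noise-free FISH draws on a pure tumor reproduce the base states", {
  cfg <- sim_config(fish_noise = 0, fish_normal_fraction = 0)
  no <- simulate_fish(cfg, "no_loss", 200, seed = 1)
  expect_true(all(no$n_target == 2 & no$n_reference == 2))
  expect_equal(fish_ratio(no), 1.0)
  expect_equal(fish_ratio(simulate_fish(cfg, "homo_loss", 200, seed = 1)), 0.0)
  expect_equal(fish_ratio(simulate_fish(cfg, "het_loss", 200, seed = 1)), 0.5)
})

test_that("noisy heterozygous-loss FISH cases classify correctly", {
  cfg <- sim_config(fish_noise = 0.05)
  r <- fish_ratio(simulate_fish(cfg, "het_loss", 200, seed = 3))
  expect_gt(r, 0.5)
  expect_lt(r, 0.75)
  expect_identical(classify_fish(r), "het_loss")
})

test_that("DE generator hits the configured family signal exactly", {
  cfg <- sim_config(de_family_up = 41, de_family_down = 95, family_size = 300)
  d <- simulate_de_table(cfg)
  s <- family_alteration_summary(d$de, d$family_genes)
  expect_identical(s$n_up, 41L)
  expect_identical(s$n_down, 95L)
  expect_identical(s$n_altered, 136L)
  expect_identical(sum(d$truth$direction == "up"), 41L)
  # degenerate settings
  d0 <- simulate_de_table(sim_config(de_family_up = 0, de_family_down = 0,
                                     family_size = 50))
  s0 <- family_alteration_summary(d0$de, d0$family_genes)
  expect_identical(s0$pct_altered, 0)
  dAll <- simulate_de_table(sim_config(de_family_up = 50, de_family_down = 0,
                                       family_size = 50))
  sAll <- family_alteration_summary(dAll$de, dAll$family_genes)
  expect_identical(sAll$pct_altered, 100)
})

test_that("indel read generator honours counts and provenance", {
  rs <- simulate_indel_reads(n_tumor_alt = 3, n_tumor_ref = 2,
                             n_normal_alt = 1, n_normal_ref = 4, seed = 6)
  expect_identical(nrow(rs$reads), 10L)
  expect_identical(sum(rs$truth$sample == "tumor"), 5L)
  expect_identical(sum(rs$truth$from_mutant), 4L)
  expect_true(all(nchar(rs$reads$seq) == 20))
})
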