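test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(seed = 71, n_amines = 15, n_fas = 6, spike_n = 5,
                    decoy_n = 20, cassette_identities = c(1, NA),
                    n_background_genes = 2L, n_reads = 50)
  a <- gen_compound_lists(cfg)
  b <- gen_compound_lists(cfg)
  expect_identical(a, b)
  lib <- build_library(a$amines, a$fatty_acids)
  expect_identical(gen_feature_table(lib, cfg), gen_feature_table(lib, cfg))
  refs <- cta_reference_proteins()
  g1 <- gen_genomes(cfg, refs)
  g2 <- gen_genomes(cfg, refs)
  expect_identical(g1, g2)
  r1 <- gen_reads(g1, c(0.5, 0.5), cfg)
  r2 <- gen_reads(g1, c(0.5, 0.5), cfg)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_identical(mutate_protein(refs$protein[1], 0.8, 9),
                   mutate_protein(refs$protein[1], 0.8, 9))
  # a different seed changes the draw
  cfg2 <- cfg
  cfg2$seed <- 72L
  expect_false(identical(gen_compound_lists(cfg2), a))
})

test_that("compound lists have the requested sizes, anchors and valid chemistry", {
  cfg <- sim_config(seed = 73, n_amines = 80, n_fas = 20)
  cl <- gen_compound_lists(cfg)
  expect_equal(nrow(cl$amines), 80)
  expect_equal(nrow(cl$fatty_acids), 20)
  expect_true(all(c("dopamine", "ethanolamine", "arginine") %in% cl$amines$name))
  expect_true(all(c("oleic_acid", "linoleic_acid", "alpha_linolenic_acid",
                    "palmitic_acid") %in% cl$fatty_acids$name))
  expect_false(anyDuplicated(cl$amines$name) > 0)
  expect_false(anyDuplicated(cl$fatty_acids$name) > 0)
  # every pair satisfies the condensation preconditions
  for (am in cl$amines$formula) {
    f <- parse_formula(am)
    expect_gte(f[["N"]], 1)
    expect_gte(f[["H"]], 2)
  }
  for (fa in cl$fatty_acids$formula) {
    f <- parse_formula(fa)
    expect_equal(f[["O"]], 2)
    expect_gte(f[["H"]], 2)
  }
  expect_silent(build_library(cl$amines, cl$fatty_acids))
  # TSV output parses back through the compound reader
  dir <- withr::local_tempdir()
  gen_compound_lists(cfg, dir = dir)
  back <- read_compounds(file.path(dir, "amines.tsv"), "amine")
  expect_equal(back$formula, cl$amines$formula)
})

test_that("feature tables place spikes at the stated ppm noise and decoys far away", {
  cfg <- sim_config(seed = 74, n_amines = 20, n_fas = 8, spike_n = 10,
                    decoy_n = 40, mass_error_sd = 0)
  cl <- gen_compound_lists(cfg)
  lib <- build_library(cl$amines, cl$fatty_acids)
  ft <- gen_feature_table(lib, cfg)
  spikes <- ft$truth[ft$truth$is_spike, ]
  obs <- ft$features$mz[match(spikes$feature_id, ft$features$feature_id)]
  expect_equal(obs, spikes$true_mz, tolerance = 1e-12) # sd 0: exact m/z
  # decoys are > 3 tolerances from every library mass
  dec <- ft$features$mz[match(ft$truth$feature_id[!ft$truth$is_spike],
                              ft$features$feature_id)]
  for (m in dec) {
    expect_gt(min(abs((m - lib$precursor_mz) / lib$precursor_mz * 1e6)), 15)
  }
  # a decoy-only table annotates nothing
  dec_tab <- ft$features[ft$features$feature_id %in%
                           ft$truth$feature_id[!ft$truth$is_spike], ]
  expect_equal(nrow(annotate(dec_tab, lib)), 0)
  expect_error(gen_feature_table(lib[1:5, ], sim_config(spike_n = 10)),
               "spike_n")
})

test_that("protein mutation realizes the target identity within two points", {
  set.seed(75)
  base <- random_protein(200)
  same <- mutate_protein(base, 1.0, 3)
  expect_equal(as.character(same), base)
  mut <- mutate_protein(base, 0.9, 3)
  chars_a <- strsplit(base, "")[[1]]
  chars_b <- strsplit(as.character(mut), "")[[1]]
  realized <- mean(chars_a == chars_b)
  expect_gte(realized, 0.88)
  expect_lte(realized, 0.92)
  expect_equal(attr(mut, "realized_identity"), realized)
  expect_error(mutate_protein("ACDEF", 0.87, 1), "short")
  expect_error(mutate_protein(base, 0, 1), "target_identity")
})

test_that("planted operons carry the advertised structure and ground truth", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 76, cassette_identities = c(1, 0.75, NA))
  gn <- gen_genomes(cfg, refs)
  for (g in which(gn$truth$has_cassette)) {
    tr <- gn$truth[g, ]
    genes <- gn$genes[gn$genes$genome_id == tr$genome_id, ]
    trio <- genes[match(c(tr$c_gene, tr$t_gene, tr$a_gene), genes$gene_id), ]
    expect_equal(length(unique(trio$strand)), 1)
    expect_equal(length(unique(trio$contig_id)), 1)
    # T strictly between C and A in coordinates
    expect_true(trio$start[2] > min(trio$end[1], trio$end[3]) ||
                trio$end[2] < max(trio$start[1], trio$start[3]))
    expect_true(trio$start[2] > trio$end[1] & trio$end[2] < trio$start[3])
    # realized identity against the reference matches the recorded truth
    ref_c <- refs$protein[refs$role == "C"]
    chars_a <- strsplit(ref_c, "")[[1]]
    chars_b <- strsplit(trio$protein[1], "")[[1]]
    expect_equal(mean(chars_a == chars_b), tr$realized_identity,
                 tolerance = 1e-9)
  }
  neg <- gn$truth$genome_id[!gn$truth$has_cassette]
  expect_true(all(gn$genes$role[gn$genes$genome_id %in% neg] == "bg"))
})

test_that("simulated reads respect abundances, error rate and overlap truth", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 77, cassette_identities = c(1, NA),
                    n_reads = 500, error_rate = 0)
  gn <- gen_genomes(cfg, refs)
  # abundance 0 for the cassette genome: nothing can come from the cassette
  rd0 <- gen_reads(gn, c(0, 1), cfg)
  expect_true(all(rd0$truth$genome_id == "genome02"))
  expect_true(all(!rd0$truth$from_cassette))
  # error-free reads are exact substrings of their source contig (or its rc)
  rd <- gen_reads(gn, c(0.5, 0.5), cfg)
  for (i in sample(length(rd$reads), 10)) {
    tr <- rd$truth[i, ]
    frag <- substr(gn$contigs[tr$genome_id], tr$start,
                   tr$start + cfg$read_length - 1)
    r <- as.character(rd$reads[[i]])
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    expect_true(r == frag || rc == frag)
  }
  # overlap bookkeeping: from_cassette iff >= 90 nt overlap
  expect_equal(rd$truth$from_cassette, rd$truth$cassette_overlap_nt >= 90)
  expect_error(gen_reads(gn, c(0.7, 0.7), cfg), "sum to 1")
})

test_that("cassette-contained reads always pass the matching rule", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 78, cassette_identities = c(1, NA), error_rate = 0)
  gn <- gen_genomes(cfg, refs)
  db <- stats::setNames(gn$genes$protein[gn$genes$role != "bg"],
                        gn$genes$gene_id[gn$genes$role != "bg"])
  reads <- gen_cassette_reads(gn, "genome01", 15, cfg)
  for (i in seq_along(reads)) {
    expect_false(is.null(match_read(as.character(reads[[i]]), db)))
  }
})

test_that("two-group cohorts separate by cassette abundance", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 79, cassette_identities = c(1, NA),
                    n_background_genes = 3L, n_reads = 600,
                    group_sizes = c(5L, 5L), effect_abundance = c(0.25, 0.01))
  cohort <- gen_group_samples(cfg, dir = dir)
  expect_equal(nrow(cohort$sample_sheet), 10)
  expect_true(all(file.exists(cohort$sample_sheet$fastq)))
  db <- stats::setNames(
    cohort$genomes$genes$protein[cohort$genomes$genes$role != "bg"],
    cohort$genomes$genes$gene_id[cohort$genomes$genes$role != "bg"])
  q <- quantify_samples(cohort$sample_sheet, db)
  expect_gt(mean(q$rpm[q$group == "A"]), mean(q$rpm[q$group == "B"]))
  res <- compare_groups(q)
  expect_lt(res$p_value, 0.05)
})
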