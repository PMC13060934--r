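test_that("alignment identity and coverage behave on constructed cases", {
  set.seed(51)
  p <- random_protein(100)
  self <- align_proteins(p, p)
  expect_equal(self$percent_identity, 100)
  expect_equal(self$subject_coverage, 1)
  expect_equal(self$alignment_length, 100)
  # subject contained in query
  half <- substr(p, 1, 50)
  cont <- align_proteins(p, half)
  expect_equal(cont$subject_coverage, 1)
  expect_equal(cont$alignment_length, 50)
  # exactly 10 substitutions in 100 aa, no gaps -> identity 90
  chars <- strsplit(p, "")[[1]]
  pos <- sample(10:90, 10)
  for (i in pos) chars[i] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                     chars[i])[1]
  mut <- paste(chars, collapse = "")
  res <- align_proteins(p, mut)
  expect_equal(res$percent_identity, 90)
  expect_error(align_proteins("ACDB", p), "alphabet")
  expect_error(align_proteins("", p), "nonempty")
})

test_that("alignment agrees with an exhaustive affine-gap DP oracle on short sequences", {
  set.seed(52)
  for (i in 1:25) {
    q <- random_protein(sample(10:30, 1))
    s <- random_protein(sample(10:30, 1))
    got <- align_proteins(q, s)
    want <- sw_oracle(q, s)
    # the reported score is the DP optimum over all cells
    expect_equal(got$score, want$score, tolerance = 1e-9)
    # the returned alignment realizes that optimum column by column
    expect_equal(score_alignment(got$query_aligned, got$subject_aligned),
                 want$score, tolerance = 1e-9)
    # identity and coverage re-derived independently from the columns
    qc <- strsplit(got$query_aligned, "")[[1]]
    sc <- strsplit(got$subject_aligned, "")[[1]]
    expect_equal(got$percent_identity,
                 sum(qc == sc & qc != "-") / length(qc) * 100, tolerance = 1e-9)
    expect_equal(got$subject_coverage, sum(sc != "-") / nchar(s),
                 tolerance = 1e-9)
    expect_equal(got$alignment_length, length(qc))
  }
})

test_that("role assignment enforces both identity and coverage cutoffs", {
  refs <- cta_reference_proteins()
  ref_c <- refs$protein[refs$role == "C"]
  exact <- data.frame(gene_id = "g1", protein = ref_c)
  asg <- find_homologs(exact, refs)
  expect_equal(asg$role, "C")
  expect_equal(asg$percent_identity, 100)
  # mutated to 60%: below the identity cutoff
  low <- data.frame(gene_id = "g2",
                    protein = as.character(mutate_protein(ref_c, 0.60, 7)))
  expect_lt(align_proteins(low$protein, ref_c)$percent_identity, 70)
  expect_equal(nrow(find_homologs(low, refs)), 0)
  # high identity but truncated to 60% of the reference: coverage fail
  trunc <- data.frame(gene_id = "g3",
                      protein = substr(ref_c, 1, round(0.6 * nchar(ref_c))))
  expect_equal(nrow(find_homologs(trunc, refs)), 0)
  expect_error(find_homologs(exact, refs[refs$role == "T", , drop = FALSE]),
               "no C or A reference")
})

test_that("operon detection requires same contig, same strand, small gaps and one small T", {
  mk_genes <- function(strand_a = "+", gap = 100, t_len = 80, extra_t = FALSE,
                       contig_a = "c1") {
    # C gene 300 aa, T gene t_len aa, A gene 400 aa laid left to right
    starts <- c(1000, 1000 + 903 + gap, 1000 + 903 + gap + t_len * 3 + 3 + gap)
    g <- data.frame(
      genome_id = "g", contig_id = c("c1", "c1", contig_a),
      gene_id = c("C1", "T1", "A1"),
      start = starts, end = starts + c(902, t_len * 3 + 2, 1202),
      strand = c("+", "+", strand_a),
      protein = c(random_protein(300), random_protein(t_len),
                  random_protein(400)),
      stringsAsFactors = FALSE
    )
    if (extra_t) {
      # a second small ORF inside the T-A gap
      g <- rbind(g, data.frame(genome_id = "g", contig_id = "c1",
                               gene_id = "T2", start = starts[3] - 250,
                               end = starts[3] - 60, strand = "+",
                               protein = random_protein(60)))
    }
    g
  }
  asg <- data.frame(gene_id = c("C1", "A1"), role = c("C", "A"),
                    ref_id = "r", percent_identity = c(95, 92),
                    subject_coverage = c(0.9, 0.95), score = c(100, 120),
                    stringsAsFactors = FALSE)
  set.seed(53)
  hit <- detect_cassettes(mk_genes(), asg)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$t_gene, "T1")
  expect_equal(hit$c_identity, 95)
  expect_equal(nrow(detect_cassettes(mk_genes(strand_a = "-"), asg)), 0)
  expect_equal(nrow(detect_cassettes(mk_genes(gap = 10000), asg)), 0)
  expect_equal(nrow(detect_cassettes(mk_genes(contig_a = "c2"), asg)), 0)
  # T too large
  expect_equal(nrow(detect_cassettes(mk_genes(t_len = 200), asg)), 0)
  # two ORFs between C and A: not a clean operon
  expect_equal(nrow(detect_cassettes(mk_genes(gap = 400, extra_t = TRUE), asg)), 0)
})

test_that("planted cassettes are found at high identity and rejected at low", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 54, cassette_identities = c(1, 0.85, 0.60, NA))
  gn <- gen_genomes(cfg, refs)
  hits <- scan_genomes(gn$proteome, gn$genes, refs)
  expect_setequal(unique(hits$genome_id), c("genome01", "genome02"))
  tr <- gn$truth
  for (g in c("genome01", "genome02")) {
    h <- hits[hits$genome_id == g, ]
    expect_equal(h$c_gene, tr$c_gene[tr$genome_id == g])
    expect_equal(h$t_gene, tr$t_gene[tr$genome_id == g])
    expect_equal(h$a_gene, tr$a_gene[tr$genome_id == g])
  }
})

test_that("raising cutoffs never increases the number of role assignments", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 55, cassette_identities = c(1, 0.85, 0.75),
                    n_background_genes = 3L)
  gn <- gen_genomes(cfg, refs)
  prev <- Inf
  for (id_min in c(60, 70, 80, 95)) {
    n <- nrow(find_homologs(gn$proteome, refs, id_min = id_min))
    expect_lte(n, prev)
    prev <- n
  }
  n_cov <- nrow(find_homologs(gn$proteome, refs, cov_min = 0.99))
  expect_lte(n_cov, nrow(find_homologs(gn$proteome, refs, cov_min = 0.80)))
})

test_that("species summaries count isolates with and without the cassette", {
  iso <- data.frame(genome_id = paste0("g", 1:6),
                    species = c("sp1", "sp1", "sp1", "sp2", "sp2", "sp3"),
                    has_cassette = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  s <- summarize_species(iso)
  expect_equal(s$n_with[s$species == "sp1"], 2)
  expect_equal(s$n_without[s$species == "sp1"], 1)
  expect_equal(s$n_with[s$species == "sp2"], 0)
  expect_equal(s$n_isolates, s$n_with + s$n_without)
  expect_error(summarize_species(iso[0, ]), "isolate")
})

test_that("generated genome artifacts round-trip through the readers", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 56, cassette_identities = c(1, NA),
                    n_background_genes = 3L)
  dir <- withr::local_tempdir()
  gn <- gen_genomes(cfg, refs, dir = dir)
  prot <- read_proteome(file.path(dir, "proteome.faa"))
  expect_equal(prot$protein, gn$proteome$protein)
  expect_equal(prot$gene_id, gn$proteome$gene_id)
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(genes$start, gn$genes$start)
  expect_equal(genes$strand, gn$genes$strand)
  # genes lifted from the contig re-translate to the recorded proteins
  for (i in sample(nrow(gn$genes), 4)) {
    g <- gn$genes[i, ]
    cds <- substr(gn$contigs[g$genome_id], g$start, g$end)
    if (g$strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(sub("\\*$", "", aa), g$protein)
  }
})
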