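# independent hit oracle: enumerate every ungapped diagonal window of every
# frame against every subject and apply the len/identity rule directly
diagonal_oracle <- function(read, db, id_min, len_min) {
  frames <- six_frame_translate(read)
  for (pep in frames) {
    p <- strsplit(pep, "")[[1]]
    for (subj in db) {
      s <- strsplit(subj, "")[[1]]
      for (d in (-(length(p) - 1)):(length(s) - 1)) {
        idx <- seq_along(p)
        j <- idx + d
        ok <- j >= 1 & j <= length(s)
        if (sum(ok) < len_min) next
        m <- as.integer(p[ok] == s[j[ok]] & p[ok] != "X" & p[ok] != "*")
        L <- length(m)
        cs <- c(0, cumsum(m))
        for (len in len_min:L) {
          for (st in 1:(L - len + 1)) {
            if ((cs[st + len] - cs[st]) / len >= id_min / 100 - 1e-9) return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

test_that("six-frame translation follows the standard code, N and stop handling", {
  expect_equal(six_frame_translate("ATGGCC")[1], "MA")
  expect_equal(six_frame_translate("ATGNAA")[1], "MX")
  expect_equal(six_frame_translate("ATGTAACCC")[1], "M*P")
  set.seed(61)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1), replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(six_frame_translate(s)[4], six_frame_translate(rc)[1])
    expect_equal(six_frame_translate(s)[5], six_frame_translate(rc)[2])
  }
  expect_error(six_frame_translate("AT"), "length")
})

test_that("read matching enforces the 30-aa / 90% window boundaries exactly", {
  set.seed(62)
  prot <- random_protein(60)
  db <- c(target = prot)
  # 33-codon exact substring: passes with full identity
  hit <- match_read(codon_encode(substr(prot, 10, 42)), db)
  expect_false(is.null(hit))
  expect_equal(hit$window_identity, 100)
  expect_gte(hit$window_length, 30)
  # 29-codon exact substring: below the length floor
  expect_null(match_read(codon_encode(substr(prot, 10, 38)), db))
  # 30 codons with 4 substituted residues: 26/30 = 86.7% < 90%
  chars <- strsplit(substr(prot, 10, 39), "")[[1]]
  for (p in c(5, 12, 19, 26)) {
    chars[p] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], chars[p])[1]
  }
  expect_null(match_read(codon_encode(paste(chars, collapse = "")), db))
  # 3 substitutions (27/30 = 90%) still passes
  chars2 <- strsplit(substr(prot, 10, 39), "")[[1]]
  for (p in c(5, 15, 25)) {
    chars2[p] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], chars2[p])[1]
  }
  hit3 <- match_read(codon_encode(paste(chars2, collapse = "")), db)
  expect_false(is.null(hit3))
})

test_that("read matching agrees with an exhaustive diagonal-window oracle on tiny instances", {
  set.seed(63)
  db <- c(p1 = random_protein(40), p2 = random_protein(40))
  n_hit <- 0
  for (i in 1:30) {
    src <- db[[sample(2, 1)]]
    L <- sample(8:15, 1)
    st <- sample(seq_len(40 - L + 1), 1)
    pep <- strsplit(substr(src, st, st + L - 1), "")[[1]]
    # substitutions at interior positions only: a terminal mismatch creates
    # co-optimal alignments with and without that column, and the windows of
    # the best-scoring alignment are then tie-break dependent
    k <- sample(0:3, 1)
    if (k > 0) {
      for (p in sample(2:(L - 1), k)) {
        pep[p] <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], pep[p])[1]
      }
    }
    read <- codon_encode(paste(pep, collapse = ""))
    if (runif(1) < 0.5) {
      read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    }
    want <- diagonal_oracle(read, db, id_min = 90, len_min = 10)
    got <- match_read(read, db, id_min = 90, len_min = 10)
    expect_equal(!is.null(got), want, info = paste("case", i))
    n_hit <- n_hit + want
  }
  expect_gt(n_hit, 5) # the property exercised both outcomes
  expect_lt(n_hit, 30)
})

test_that("rpm arithmetic, read-order invariance and dilution", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 64, cassette_identities = c(1, NA),
                    n_reads = 400, error_rate = 0)
  gn <- gen_genomes(cfg, refs)
  db <- stats::setNames(gn$genes$protein[gn$genes$role != "bg"],
                        gn$genes$gene_id[gn$genes$role != "bg"])
  rd <- gen_reads(gn, c(0.25, 0.75), cfg)
  q <- quantify_sample(rd$reads, db)
  expect_equal(q$rpm, q$aligned_reads / q$total_reads * 1e6)
  expect_equal(q$aligned_reads, sum(rd$truth$from_cassette))
  # order invariance
  perm <- sample(length(rd$reads))
  q2 <- quantify_sample(rd$reads[perm], db)
  expect_equal(q2$aligned_reads, q$aligned_reads)
  # doubling totals with non-matching reads halves rpm
  neg_cfg <- cfg
  neg_cfg$seed <- 65L
  neg <- gen_reads(gn, c(0, 1), neg_cfg)
  q3 <- quantify_sample(c(rd$reads, neg$reads), db)
  expect_equal(q3$aligned_reads, q$aligned_reads)
  expect_equal(q3$rpm, q$rpm / 2)
  # cassette-negative community: rpm exactly 0
  expect_equal(quantify_sample(neg$reads, db)$rpm, 0)
})

test_that("FASTQ streaming path equals the in-memory path", {
  refs <- cta_reference_proteins()
  cfg <- sim_config(seed = 66, cassette_identities = c(1, NA),
                    n_reads = 300, error_rate = 0.005)
  gn <- gen_genomes(cfg, refs)
  db <- stats::setNames(gn$genes$protein[gn$genes$role != "bg"],
                        gn$genes$gene_id[gn$genes$role != "bg"])
  dir <- withr::local_tempdir()
  rd <- gen_reads(gn, c(0.2, 0.8), cfg, dir = dir)
  mem <- quantify_sample(rd$reads, db)
  stream <- quantify_sample(file.path(dir, "reads.fastq"), db,
                            chunk_size = 64L)
  expect_equal(stream$aligned_reads, mem$aligned_reads)
  expect_equal(stream$total_reads, mem$total_reads)
})

test_that("group comparison wraps the exact Mann-Whitney with BH across endpoints", {
  q <- data.frame(rpm = c(1, 2, 3, 4), group = c("A", "A", "B", "B"))
  res <- compare_groups(q)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$q_value, res$p_value)
  ident <- data.frame(rpm = rep(c(5, 9, 13), 2),
                      group = rep(c("A", "B"), each = 3))
  expect_gte(compare_groups(ident)$p_value, 0.99)
  set.seed(67)
  shifted <- data.frame(rpm = c(rnorm(20), rnorm(20, 2)),
                        group = rep(c("A", "B"), each = 20))
  expect_lt(compare_groups(shifted)$p_value, 0.01)
  multi <- compare_groups(list(a = shifted, b = ident))
  expect_equal(multi$q_value, bh_fdr(multi$p_value))
  expect_error(compare_groups(data.frame(rpm = 1:3, group = c("A", "B", "C"))),
               "2 groups")
})
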