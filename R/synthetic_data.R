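# Synthetic-data generators: compound lists, spiked MS1 feature tables,
# MS2 spectra, genomes with planted C-T-A operons at controlled protein
# identity, and metagenomic read sets with ground truth. Every generator
# is a pure function of (config, seed): one RNG stream per generator,
# seeded from the config seed plus a fixed per-generator offset, so adding
# one generator call never perturbs another.

.SEED_OFFSET <- c(compounds = 101L, features = 211L, ms2 = 307L,
                  genomes = 401L, mutate = 499L, reads = 503L,
                  cohort = 601L, references = 701L)

# Run code under a temporary RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.gen_seed <- function(cfg, generator) {
  (cfg$seed %% 2000000L) * 1000L + .SEED_OFFSET[[generator]]
}

#' Simulation configuration
#'
#' Bundles the knobs of all synthetic-data generators. Defaults describe
#' the emulated study conditions: a 460-amine by 53-fatty-acid compound
#' library; feature tables with 20 spiked conjugates at 2 ppm mass-error
#' SD plus 200 decoys kept at least three MS1 tolerances away; genomes
#' carrying operons mutated to identities bracketing the 70% homology
#' cutoff; 150-nt reads with a flat 0.5% substitution error rate.
#'
#' @param seed Integer master seed.
#' @param n_amines,n_fas Compound-list sizes.
#' @param spike_n,decoy_n Spiked and decoy feature counts.
#' @param mass_error_sd MS1/MS2 mass-error standard deviation in ppm.
#' @param ms1_tol_ppm MS1 tolerance the decoy exclusion zone is scaled to.
#' @param ms2_noise_peaks Uniform noise peaks added per spectrum.
#' @param ms2_omit_fraction Fraction of spiked spectra omitting the
#'   amine-moiety fragment (exercises the `partial` tier).
#' @param cassette_identities Per-genome planted C/A protein identity
#'   targets (fractions); `NA` plants no cassette.
#' @param n_background_genes Background genes per genome.
#' @param n_reads,read_length,error_rate Read-set parameters (flat
#'   per-base substitution rate).
#' @param group_sizes Two group sizes for the cohort generator.
#' @param effect_abundance Cassette-genome abundance in group A and B.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_amines = 460L, n_fas = 53L,
                       spike_n = 20L, decoy_n = 200L, mass_error_sd = 2,
                       ms1_tol_ppm = 5, ms2_noise_peaks = 5L,
                       ms2_omit_fraction = 0,
                       cassette_identities = c(1, 0.85, 0.75, 0.65, 0.60, NA, NA),
                       n_background_genes = 6L,
                       n_reads = 10000L, read_length = 150L,
                       error_rate = 0.005,
                       group_sizes = c(15L, 15L),
                       effect_abundance = c(0.05, 0.005)) {
  cfg <- list(seed = as.integer(seed), n_amines = n_amines, n_fas = n_fas,
              spike_n = spike_n, decoy_n = decoy_n,
              mass_error_sd = mass_error_sd, ms1_tol_ppm = ms1_tol_ppm,
              ms2_noise_peaks = ms2_noise_peaks,
              ms2_omit_fraction = ms2_omit_fraction,
              cassette_identities = cassette_identities,
              n_background_genes = n_background_genes,
              n_reads = n_reads, read_length = read_length,
              error_rate = error_rate, group_sizes = group_sizes,
              effect_abundance = effect_abundance)
  stopifnot(cfg$n_amines >= 1, cfg$n_fas >= 1, cfg$spike_n >= 0,
            cfg$decoy_n >= 0, cfg$mass_error_sd >= 0,
            cfg$ms2_omit_fraction >= 0, cfg$ms2_omit_fraction <= 1,
            cfg$error_rate >= 0, cfg$error_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate amine and fatty-acid compound lists
#'
#' Random chemically valid formulas (amines contain nitrogen and at least
#' two hydrogens; fatty acids are CnH(2n-2k)O2 with chain length n and k
#' unsaturations), always including the real anchor compounds dopamine,
#' ethanolamine, arginine, oleic, linoleic, alpha-linolenic and palmitic
#' acid so that literature-anchored checks can run on generated lists.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; writes `amines.tsv` and
#'   `fatty_acids.tsv`.
#' @return List with data.frames `amines` and `fatty_acids` (columns
#'   `name`, `formula`, `class`).
#' @export
gen_compound_lists <- function(cfg = sim_config(), dir = NULL) {
  anchors_am <- data.frame(
    name = c("dopamine", "ethanolamine", "arginine"),
    formula = c("C8H11NO2", "C2H7NO", "C6H14N4O2"),
    stringsAsFactors = FALSE
  )
  anchors_fa <- data.frame(
    name = c("palmitic_acid", "oleic_acid", "linoleic_acid",
             "alpha_linolenic_acid"),
    formula = c("C16H32O2", "C18H34O2", "C18H32O2", "C18H30O2"),
    stringsAsFactors = FALSE
  )
  out <- .with_seed(.gen_seed(cfg, "compounds"), {
    n_extra_am <- max(cfg$n_amines - nrow(anchors_am), 0L)
    am <- anchors_am[seq_len(min(cfg$n_amines, nrow(anchors_am))), , drop = FALSE]
    if (n_extra_am) {
      C <- sample(2:14, n_extra_am, replace = TRUE)
      N <- sample(1:3, n_extra_am, replace = TRUE)
      O <- sample(0:4, n_extra_am, replace = TRUE)
      d <- vapply(C, function(c) sample(0:min(4L, c - 1L), 1L), integer(1))
      H <- 2L * C + 2L + N - 2L * d
      f <- character(n_extra_am)
      for (i in seq_len(n_extra_am)) {
        cnt <- c(C = C[i], H = H[i], N = N[i], O = O[i])
        f[i] <- render_formula(cnt[cnt > 0])
      }
      am <- rbind(am, data.frame(
        name = sprintf("amine_%03d", seq_len(n_extra_am)),
        formula = f, stringsAsFactors = FALSE))
    }
    n_extra_fa <- max(cfg$n_fas - nrow(anchors_fa), 0L)
    fa <- anchors_fa[seq_len(min(cfg$n_fas, nrow(anchors_fa))), , drop = FALSE]
    if (n_extra_fa) {
      grid <- expand.grid(n = 4:24, k = 0:6)
      grid <- grid[grid$k <= pmax(grid$n - 3L, 0L), , drop = FALSE]
      key <- paste(grid$n, grid$k)
      anchor_key <- c("16 0", "18 1", "18 2", "18 3")
      grid <- grid[!key %in% anchor_key, , drop = FALSE]
      if (n_extra_fa > nrow(grid)) {
        stop("cannot generate ", n_extra_fa, " distinct extra fatty acids")
      }
      pick <- grid[sample(nrow(grid), n_extra_fa), , drop = FALSE]
      fa <- rbind(fa, data.frame(
        name = sprintf("fa_C%d_%d", pick$n, pick$k),
        formula = sprintf("C%dH%dO2", pick$n, 2L * pick$n - 2L * pick$k),
        stringsAsFactors = FALSE))
    }
    list(amines = am, fatty_acids = fa)
  })
  out$amines$class <- "amine"
  out$fatty_acids$class <- "fatty_acid"
  if (!is.null(dir)) {
    utils::write.table(out$amines, file.path(dir, "amines.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$fatty_acids, file.path(dir, "fatty_acids.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate a spiked MS1 feature table with ground truth
#'
#' Spikes `spike_n` randomly chosen conjugates at their theoretical
#' \eqn{[M+H]^+} m/z perturbed by Normal(0, `mass_error_sd`) ppm, and adds
#' `decoy_n` decoy features placed at least three MS1 tolerances (in ppm)
#' away from every library m/z, so false annotations are deterministically
#' zero rather than stochastic.
#'
#' @param library Conjugate library from [build_library()].
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; writes `features.tsv` and
#'   `feature_truth.tsv`.
#' @return List with `features` (feature table) and `truth` (per-feature
#'   ground truth: spiked conjugate or decoy).
#' @export
gen_feature_table <- function(library, cfg = sim_config(), dir = NULL) {
  if (cfg$spike_n > nrow(library)) stop("spike_n exceeds library size")
  res <- .with_seed(.gen_seed(cfg, "features"), {
    idx <- sample(nrow(library), cfg$spike_n)
    eps <- stats::rnorm(cfg$spike_n, 0, cfg$mass_error_sd)
    spike_mz <- library$precursor_mz[idx] * (1 + eps * 1e-6)

    lib_mz <- sort(unique(library$precursor_mz))
    lo <- min(lib_mz) * 0.9
    hi <- max(lib_mz) * 1.1
    excl <- 3 * cfg$ms1_tol_ppm
    decoys <- numeric(0)
    tries <- 0L
    while (length(decoys) < cfg$decoy_n) {
      tries <- tries + 1L
      if (tries > 200L) stop("infeasible decoy placement: exclusion zone too dense")
      cand <- stats::runif(2L * (cfg$decoy_n - length(decoys)), lo, hi)
      pos <- findInterval(cand, lib_mz)
      d_lo <- ifelse(pos >= 1L,
                     abs(cand - lib_mz[pmax(pos, 1L)]) / lib_mz[pmax(pos, 1L)] * 1e6,
                     Inf)
      d_hi <- ifelse(pos < length(lib_mz),
                     abs(cand - lib_mz[pmin(pos + 1L, length(lib_mz))]) /
                       lib_mz[pmin(pos + 1L, length(lib_mz))] * 1e6,
                     Inf)
      ok <- pmin(d_lo, d_hi) > excl
      decoys <- c(decoys, cand[ok])
    }
    decoys <- decoys[seq_len(cfg$decoy_n)]

    n <- cfg$spike_n + cfg$decoy_n
    features <- data.frame(
      feature_id = sprintf("F%05d", seq_len(n)),
      mz = c(spike_mz, decoys),
      rt = stats::runif(n, 0.5, 15),
      intensity = 10^stats::runif(n, 4, 7),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      feature_id = features$feature_id,
      is_spike = c(rep(TRUE, cfg$spike_n), rep(FALSE, cfg$decoy_n)),
      amine_name = c(library$amine_name[idx], rep(NA_character_, cfg$decoy_n)),
      fa_name = c(library$fa_name[idx], rep(NA_character_, cfg$decoy_n)),
      true_mz = c(library$precursor_mz[idx], rep(NA_real_, cfg$decoy_n)),
      ppm_shift = c(eps, rep(NA_real_, cfg$decoy_n)),
      stringsAsFactors = FALSE
    )
    ord <- sample(n)
    list(features = features[ord, ], truth = truth[ord, ])
  })
  rownames(res$features) <- rownames(res$truth) <- NULL
  if (!is.null(dir)) {
    utils::write.table(res$features, file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$truth, file.path(dir, "feature_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Generate MS2 spectra for spiked features
#'
#' For each spiked feature, peaks are placed at both diagnostic-fragment
#' m/z values (with ppm-scale noise) plus uniform-random noise peaks kept
#' away from the fragments; a configurable fraction of spectra omit the
#' amine-moiety fragment so the `partial` confidence tier is exercised.
#'
#' @param truth Ground-truth data.frame from [gen_feature_table()].
#' @param library Conjugate library.
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; writes `spectra.mgf`.
#' @return Named list of spectra in the [read_mgf()] structure.
#' @export
gen_ms2_spectra <- function(truth, library, cfg = sim_config(), dir = NULL) {
  spikes <- truth[truth$is_spike, , drop = FALSE]
  lib_key <- paste(library$amine_name, library$fa_name, sep = "\r")
  spectra <- .with_seed(.gen_seed(cfg, "ms2"), {
    out <- vector("list", nrow(spikes))
    omit <- stats::runif(nrow(spikes)) < cfg$ms2_omit_fraction
    for (i in seq_len(nrow(spikes))) {
      li <- match(paste(spikes$amine_name[i], spikes$fa_name[i], sep = "\r"),
                  lib_key)
      frag <- c(library$amine_fragment_mz[li], library$fatty_amide_mz[li])
      keep <- if (omit[i]) 2L else 1:2
      mzs <- frag[keep] * (1 + stats::rnorm(length(keep), 0, cfg$mass_error_sd) * 1e-6)
      ints <- stats::runif(length(keep), 1e4, 1e6)
      n_noise <- cfg$ms2_noise_peaks
      if (n_noise > 0) {
        noise <- numeric(0)
        while (length(noise) < n_noise) {
          cand <- stats::runif(n_noise, 50, library$precursor_mz[li])
          far <- vapply(cand, function(m) {
            all(abs((m - frag) / frag * 1e6) > 30)
          }, logical(1))
          noise <- c(noise, cand[far])
        }
        noise <- noise[seq_len(n_noise)]
        mzs <- c(mzs, noise)
        ints <- c(ints, stats::runif(n_noise, 1e3, 1e5))
      }
      ord <- order(mzs)
      pk <- cbind(mz = mzs[ord], intensity = ints[ord])
      out[[i]] <- list(feature_id = spikes$feature_id[i],
                       collision_energy = sample(c(20, 30, 40, 50), 1L),
                       peaks = pk)
    }
    names(out) <- spikes$feature_id
    out
  })
  if (!is.null(dir)) {
    path <- file.path(dir, "spectra.mgf")
    con <- file(path, "w")
    on.exit(close(con))
    for (sp in spectra) {
      writeLines(c("BEGIN IONS",
                   paste0("TITLE=", sp$feature_id),
                   paste0("COLLISION_ENERGY=", sp$collision_energy),
                   sprintf("%.6f %.1f", sp$peaks[, 1], sp$peaks[, 2]),
                   "END IONS", ""), con)
    }
  }
  spectra
}

#' Synthetic C/T/A reference proteins
#'
#' Deterministic random amino-acid sequences standing in for reference
#' acyl transferase (C, 280 aa), acyl carrier (T, 80 aa) and fatty
#' acyl-CoA ligase (A, 420 aa) proteins. These are synthetic stand-ins
#' with the size structure of the real cassette (T much smaller than C
#' and A), not biological sequences.
#'
#' @param seed Integer seed (default 42).
#' @return data.frame with `role`, `ref_id`, `protein`.
#' @export
cta_reference_proteins <- function(seed = 42L) {
  .with_seed((seed %% 2000000L) * 1000L + .SEED_OFFSET[["references"]], {
    data.frame(
      role = c("C", "T", "A"),
      ref_id = c("C_ref", "T_ref", "A_ref"),
      protein = vapply(c(280L, 80L, 420L), function(n) {
        paste(sample(.AA20, n, replace = TRUE), collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  })
}

#' Mutate a protein to a target identity
#'
#' Substitution-only mutation (no indels, so identity is exactly
#' controllable): `round((1 - target_identity) * n)` positions are replaced
#' by a different residue. The realized global identity is verified to lie
#' within 2 percentage points of the target.
#'
#' @param seq Protein string.
#' @param target_identity Target identity as a fraction in (0, 1].
#' @param seed Integer seed.
#' @return The mutated protein string, with attribute
#'   `realized_identity`.
#' @export
mutate_protein <- function(seq, target_identity, seed) {
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]")
  }
  n <- nchar(seq)
  k <- round((1 - target_identity) * n)
  realized <- (n - k) / n
  if (abs(realized - target_identity) > 0.02) {
    stop("sequence too short to realize identity ", target_identity,
         " within 2 points")
  }
  out <- .with_seed((seed %% 2000000L) * 1000L + .SEED_OFFSET[["mutate"]], {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample(n, k)
    for (p in pos) {
      chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
    }
    paste(chars, collapse = "")
  })
  attr(out, "realized_identity") <- realized
  out
}

# Back-translate a protein with uniformly random synonymous codons.
.back_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate genomes with planted C-T-A operons
#'
#' Each genome is one contig of background genes (random proteins,
#' 120-300 aa, back-translated with random codons) with, for
#' cassette-positive genomes, a planted C-T-A operon: the C and A proteins
#' are the references mutated to the per-genome target identity, the T
#' protein is the (much smaller) reference carrier, and the three genes sit
#' consecutively on one strand with intergenic gaps of 20-200 bp.
#'
#' @param cfg A [sim_config()]; `cfg$cassette_identities` gives one target
#'   identity per genome (`NA` = no cassette).
#' @param references C/T/A reference data.frame (default
#'   [cta_reference_proteins()]).
#' @param dir Optional output directory; writes `genomes.fna`, `genes.tsv`,
#'   `proteome.faa`, `genome_truth.tsv`.
#' @return List: `contigs` (named character vector of contig DNA), `genes`
#'   (coordinate table with proteins), `proteome` (data.frame), `truth`
#'   (per-genome cassette ground truth).
#' @export
gen_genomes <- function(cfg = sim_config(), references = cta_reference_proteins(),
                        dir = NULL) {
  idents <- cfg$cassette_identities
  n_genomes <- length(idents)
  ref_c <- references$protein[references$role == "C"][1]
  ref_t <- references$protein[references$role == "T"][1]
  ref_a <- references$protein[references$role == "A"][1]
  res <- .with_seed(.gen_seed(cfg, "genomes"), {
    contigs <- character(n_genomes)
    names(contigs) <- sprintf("genome%02d", seq_len(n_genomes))
    gene_rows <- list()
    truth_rows <- list()
    for (g in seq_len(n_genomes)) {
      gid <- names(contigs)[g]
      cid <- "contig1"
      has_cassette <- !is.na(idents[g])
      # assemble the gene roster: background genes with the cassette
      # triplet (if any) inserted at a random slot
      n_bg <- cfg$n_background_genes
      roster <- replicate(n_bg, list(
        protein = paste(sample(.AA20, sample(120:300, 1L), replace = TRUE),
                        collapse = ""),
        role = "bg", strand = sample(c("+", "-"), 1L)
      ), simplify = FALSE)
      cass_idx <- integer(0)
      realized <- NA_real_
      if (has_cassette) {
        mseed <- sample.int(1000000L, 1L)
        c_mut <- mutate_protein(ref_c, idents[g], mseed)
        a_mut <- mutate_protein(ref_a, idents[g], mseed + 1L)
        realized <- attr(c_mut, "realized_identity")
        strand <- sample(c("+", "-"), 1L)
        slot <- sample(0:n_bg, 1L)
        cass <- list(
          list(protein = as.character(c_mut), role = "C", strand = strand),
          list(protein = ref_t, role = "T", strand = strand),
          list(protein = as.character(a_mut), role = "A", strand = strand)
        )
        roster <- append(roster, cass, after = slot)
        cass_idx <- slot + 1:3
      }
      # lay genes on the contig left to right
      pos <- sample(60:200, 1L)
      seqs <- character(0)
      offset <- 0L
      for (i in seq_along(roster)) {
        gene <- roster[[i]]
        coding <- paste0(.back_translate(gene$protein), "TAA")
        if (gene$strand == "-") coding <- .revcomp_chr(coding)
        gap_before <- if (i == 1L) pos
                      else if (i %in% cass_idx && (i - 1L) %in% cass_idx) {
                        sample(20:200, 1L)
                      } else sample(100:400, 1L)
        pad <- .random_dna(gap_before)
        start <- offset + gap_before + 1L
        end <- start + nchar(coding) - 1L
        seqs <- c(seqs, pad, coding)
        offset <- end
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          genome_id = gid, contig_id = cid,
          gene_id = sprintf("%s_g%02d", gid, i),
          start = start, end = end, strand = gene$strand,
          role = gene$role, protein = gene$protein,
          stringsAsFactors = FALSE
        )
      }
      seqs <- c(seqs, .random_dna(sample(60:200, 1L)))
      contigs[g] <- paste(seqs, collapse = "")
      nr <- length(gene_rows)
      truth_rows[[g]] <- data.frame(
        genome_id = gid, has_cassette = has_cassette,
        target_identity = idents[g], realized_identity = realized,
        c_gene = if (has_cassette) gene_rows[[nr - length(roster) + cass_idx[1]]]$gene_id else NA,
        t_gene = if (has_cassette) gene_rows[[nr - length(roster) + cass_idx[2]]]$gene_id else NA,
        a_gene = if (has_cassette) gene_rows[[nr - length(roster) + cass_idx[3]]]$gene_id else NA,
        stringsAsFactors = FALSE
      )
    }
    list(contigs = contigs,
         genes = do.call(rbind, gene_rows),
         truth = do.call(rbind, truth_rows))
  })
  res$proteome <- res$genes[, c("genome_id", "contig_id", "gene_id", "protein")]
  if (!is.null(dir)) {
    dna <- Biostrings::DNAStringSet(res$contigs)
    names(dna) <- paste0(names(res$contigs), "|contig1")
    Biostrings::writeXStringSet(dna, file.path(dir, "genomes.fna"))
    aa <- Biostrings::AAStringSet(res$proteome$protein)
    names(aa) <- paste(res$proteome$genome_id, res$proteome$contig_id,
                       res$proteome$gene_id, sep = "|")
    Biostrings::writeXStringSet(aa, file.path(dir, "proteome.faa"))
    utils::write.table(res$genes[, setdiff(names(res$genes), "protein")],
                       file.path(dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$truth, file.path(dir, "genome_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

# Apply flat-rate substitution errors to a character vector of reads.
.apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  rl <- nchar(reads)
  n_err <- stats::rbinom(length(reads), rl, error_rate)
  for (i in which(n_err > 0L)) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample(rl[i], n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Generate shotgun metagenomic reads from synthetic genomes
#'
#' Reads are sampled uniformly within genomes chosen with the given
#' abundances, from a random strand, with flat-rate per-base substitution
#' errors. The truth table records the source genome and whether the
#' fragment overlaps a planted cassette gene by at least 90 nt.
#'
#' @param genomes Output of [gen_genomes()].
#' @param abundances Per-genome sampling weights summing to 1.
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; writes `reads.fastq` and
#'   `read_truth.tsv`.
#' @param seed_offset Added to the generator seed, so multiple samples can
#'   be drawn from one config.
#' @return List with `reads` (`DNAStringSet`, read ids as names) and
#'   `truth` (data.frame).
#' @export
gen_reads <- function(genomes, abundances, cfg = sim_config(), dir = NULL,
                      seed_offset = 0L) {
  if (abs(sum(abundances) - 1) > 1e-8) stop("abundances must sum to 1")
  if (length(abundances) != length(genomes$contigs)) {
    stop("one abundance per genome required")
  }
  rl <- cfg$read_length
  if (any(nchar(genomes$contigs) < rl)) stop("read_length exceeds a contig length")
  cass <- genomes$genes[genomes$genes$role %in% c("C", "T", "A"), , drop = FALSE]
  res <- .with_seed(.gen_seed(cfg, "reads") + seed_offset, {
    src <- sample.int(length(genomes$contigs), cfg$n_reads, replace = TRUE,
                      prob = abundances)
    starts <- integer(cfg$n_reads)
    for (g in unique(src)) {
      idx <- which(src == g)
      starts[idx] <- sample.int(nchar(genomes$contigs[g]) - rl + 1L,
                                length(idx), replace = TRUE)
    }
    frags <- substring(genomes$contigs[src], starts, starts + rl - 1L)
    flip <- stats::runif(cfg$n_reads) < 0.5
    if (any(flip)) {
      frags[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(frags[flip])))
    }
    frags <- .apply_read_errors(frags, cfg$error_rate)
    gid <- names(genomes$contigs)[src]
    overlap <- numeric(cfg$n_reads)
    for (g in unique(gid[gid %in% cass$genome_id])) {
      gi <- cass[cass$genome_id == g, , drop = FALSE]
      idx <- which(gid == g)
      for (r in seq_len(nrow(gi))) {
        ov <- pmin(starts[idx] + rl - 1L, gi$end[r]) -
              pmax(starts[idx], gi$start[r]) + 1L
        overlap[idx] <- pmax(overlap[idx], ov)
      }
    }
    ids <- sprintf("read_%07d", seq_len(cfg$n_reads))
    truth <- data.frame(
      read_id = ids, genome_id = gid, start = starts,
      cassette_overlap_nt = pmax(overlap, 0),
      from_cassette = overlap >= 90,
      stringsAsFactors = FALSE
    )
    reads <- Biostrings::DNAStringSet(frags)
    names(reads) <- ids
    list(reads = reads, truth = truth)
  })
  if (!is.null(dir)) {
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(res$reads)))
    Biostrings::writeXStringSet(res$reads, file.path(dir, "reads.fastq"),
                                format = "fastq", qualities = qual)
    utils::write.table(res$truth, file.path(dir, "read_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Generate reads fully contained in planted cassette genes
#'
#' Reads sampled entirely inside the planted C/T/A genes of one genome,
#' with substitution errors at `cfg$error_rate`. An error-free read of this
#' kind encodes an exact in-frame stretch of at least
#' `floor((read_length - 2) / 3)` residues of a cassette protein, so it
#' passes the default 90%-identity / 30-aa matching rule by construction.
#'
#' @param genomes Output of [gen_genomes()].
#' @param genome_id Cassette-positive genome to draw from.
#' @param n Number of reads.
#' @param cfg A [sim_config()] (read length and error rate are used).
#' @param seed_offset Added to the generator seed.
#' @return `DNAStringSet` of `n` reads.
#' @export
gen_cassette_reads <- function(genomes, genome_id, n, cfg = sim_config(),
                               seed_offset = 1L) {
  rl <- cfg$read_length
  gi <- genomes$genes[genomes$genes$genome_id == genome_id &
                      genomes$genes$role %in% c("C", "T", "A"), , drop = FALSE]
  gi <- gi[gi$end - gi$start + 1L >= rl, , drop = FALSE]
  if (!nrow(gi)) stop("no cassette gene of length >= read_length in ", genome_id)
  .with_seed(.gen_seed(cfg, "reads") + 7919L + seed_offset, {
    pick <- sample.int(nrow(gi), n, replace = TRUE)
    starts <- gi$start[pick] +
      vapply(gi$end[pick] - gi$start[pick] + 1L - rl,
             function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    frags <- substring(genomes$contigs[genome_id], starts, starts + rl - 1L)
    flip <- stats::runif(n) < 0.5
    if (any(flip)) {
      frags[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(frags[flip])))
    }
    frags <- .apply_read_errors(frags, cfg$error_rate)
    out <- Biostrings::DNAStringSet(frags)
    names(out) <- sprintf("cassette_read_%05d", seq_len(n))
    out
  })
}

#' Generate a two-group cohort of metagenomic samples
#'
#' Emulates a case/control comparison in which group A carries the
#' cassette-positive genome at higher abundance than group B: per-sample
#' abundance is the group mean times lognormal noise (SD 0.25 on the log
#' scale), and reads are drawn per sample from a two-genome community
#' (one cassette-positive, one cassette-negative).
#'
#' @param cfg A [sim_config()]; `group_sizes` and `effect_abundance` set
#'   the design.
#' @param genomes Optional [gen_genomes()] output with at least one
#'   cassette-positive and one cassette-negative genome; built from a
#'   minimal two-genome config sharing `cfg$seed` when omitted.
#' @param dir Directory for per-sample FASTQ files; required.
#' @return List: `sample_sheet` (data.frame `sample_id`, `fastq`, `group`),
#'   `genomes`, and `abundance` (the per-sample cassette-genome abundance).
#' @export
gen_group_samples <- function(cfg = sim_config(), genomes = NULL, dir) {
  if (missing(dir)) stop("an output directory is required for FASTQ files")
  if (is.null(genomes)) {
    gcfg <- cfg
    gcfg$cassette_identities <- c(1, NA)
    genomes <- gen_genomes(gcfg)
  }
  pos <- which(genomes$truth$has_cassette)[1]
  neg <- which(!genomes$truth$has_cassette)[1]
  if (is.na(pos) || is.na(neg)) {
    stop("genomes must include a cassette-positive and a cassette-negative genome")
  }
  n_a <- cfg$group_sizes[1]
  n_b <- cfg$group_sizes[2]
  group <- rep(c("A", "B"), c(n_a, n_b))
  mean_ab <- ifelse(group == "A", cfg$effect_abundance[1], cfg$effect_abundance[2])
  ab <- .with_seed(.gen_seed(cfg, "cohort"), {
    pmin(mean_ab * exp(stats::rnorm(n_a + n_b, 0, 0.25)), 0.9)
  })
  sheet <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_a + n_b)),
    fastq = file.path(dir, sprintf("S%02d.fastq", seq_len(n_a + n_b))),
    group = group, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(sheet))) {
    abund <- numeric(length(genomes$contigs))
    abund[pos] <- ab[i]
    abund[neg] <- 1 - ab[i]
    rd <- gen_reads(genomes, abund, cfg, seed_offset = 13L * i)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(rd$reads)))
    Biostrings::writeXStringSet(rd$reads, sheet$fastq[i], format = "fastq",
                                qualities = qual)
  }
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(sample_sheet = sheet, genomes = genomes, abundance = ab)
}
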