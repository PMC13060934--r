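# Detection of the C-T-A acyl-amine-synthesis operon in bacterial genomes:
# protein homology to reference C (acyl transferase) and A (fatty acyl-CoA
# ligase) proteins, then operon-structure rules with the small acyl carrier
# (T) protein identified positionally between them.

#' Local protein alignment with identity and subject coverage
#'
#' Optimal Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (a gap of length L costs `gap_open + L * gap_extend`). Identity is
#' matches over aligned columns (gap columns count as non-matches; `X`
#' is tolerated in the input but never counted as a match); coverage is the
#' fraction of the subject's residues spanned by the alignment.
#'
#' @param query,subject Amino-acid sequences (single strings over the
#'   20-letter alphabet; `X` allowed).
#' @param gap_open,gap_extend Affine gap penalties (positive; defaults 11, 1).
#' @param substitution_matrix Name of the scoring matrix (default
#'   `"BLOSUM62"`).
#' @return A one-row data.frame: `percent_identity`, `subject_coverage`,
#'   `alignment_length` (columns, including gap columns), `score`, and the
#'   gapped `query_aligned` / `subject_aligned` strings.
#' @export
align_proteins <- function(query, subject, gap_open = 11, gap_extend = 1,
                           substitution_matrix = "BLOSUM62") {
  .check_protein(query, "query")
  .check_protein(subject, "subject")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n_col <- length(ap)
  matches <- sum(ap == as & ap != "-" & ap != "X")
  s_rng <- Biostrings::subject(aln)
  cov <- (Biostrings::end(s_rng) - Biostrings::start(s_rng) + 1L) / nchar(subject)
  data.frame(
    percent_identity = if (n_col) matches / n_col * 100 else 0,
    subject_coverage = if (n_col) cov else 0,
    alignment_length = n_col,
    score = Biostrings::score(aln),
    query_aligned = paste(ap, collapse = ""),
    subject_aligned = paste(as, collapse = ""),
    stringsAsFactors = FALSE
  )
}

.check_protein <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(what, " must be a single nonempty string")
  }
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq)) {
    stop(what, " contains characters outside the amino-acid alphabet (X allowed)")
  }
}

#' Read a gene coordinate table
#'
#' GFF-lite TSV with header and columns `genome_id`, `contig_id`, `gene_id`,
#' `start`, `end` (1-based inclusive nucleotide coordinates), `strand`.
#'
#' @param path TSV path.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("gene table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("gene with start > end in ", path)
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-' in ", path)
  df
}

#' Read a proteome FASTA with `genome|contig|gene` headers
#'
#' @param path Protein FASTA path; each header must be
#'   `genome_id|contig_id|gene_id`.
#' @return data.frame with `genome_id`, `contig_id`, `gene_id`, `protein`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(sub("\\s.*$", "", names(aa)), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("proteome headers in ", path, " must be 'genome|contig|gene'")
  }
  m <- do.call(rbind, parts)
  data.frame(genome_id = m[, 1], contig_id = m[, 2], gene_id = m[, 3],
             protein = as.character(aa), stringsAsFactors = FALSE)
}

#' Read C/A/T reference proteins from FASTA
#'
#' Headers must be `role|name` with role one of `C`, `A`, `T`.
#'
#' @param path FASTA path.
#' @return data.frame with `role`, `ref_id`, `protein`.
#' @export
read_references <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(sub("\\s.*$", "", names(aa)), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("reference headers in ", path, " must be 'role|name'")
  }
  m <- do.call(rbind, parts)
  if (!all(m[, 1] %in% c("C", "A", "T"))) {
    stop("reference roles must be C, A or T in ", path)
  }
  data.frame(role = m[, 1], ref_id = m[, 2], protein = as.character(aa),
             stringsAsFactors = FALSE)
}

#' Assign C/A roles to genes by homology to reference proteins
#'
#' A gene is a candidate C (acyl transferase) or A (fatty acyl-CoA ligase)
#' when its best local alignment to any reference of that role reaches both
#' `id_min` percent identity and `cov_min` coverage of the reference
#' protein. The small acyl carrier (T) protein is not searched by homology;
#' it is identified positionally by [detect_cassettes()].
#'
#' @param proteome data.frame with at least `gene_id` and `protein`
#'   (see [read_proteome()]).
#' @param references data.frame with `role` (`"C"` or `"A"`; `"T"` rows are
#'   ignored), `ref_id`, `protein`.
#' @param id_min Minimum percent identity (default 70).
#' @param cov_min Minimum reference (subject) coverage (default 0.80).
#' @return data.frame with one row per passing (gene, role): `gene_id`,
#'   `role`, `ref_id` of the best reference, `percent_identity`,
#'   `subject_coverage`, `score`.
#' @export
find_homologs <- function(proteome, references, id_min = 70, cov_min = 0.80) {
  refs <- references[references$role %in% c("C", "A"), , drop = FALSE]
  if (!nrow(refs)) stop("no C or A reference proteins supplied")
  out <- list()
  for (g in seq_len(nrow(proteome))) {
    prot <- proteome$protein[g]
    for (role in unique(refs$role)) {
      rr <- refs[refs$role == role, , drop = FALSE]
      best <- NULL
      for (r in seq_len(nrow(rr))) {
        # a passing alignment must span cov_min of the reference; genes far
        # shorter than that cannot pass even with 30% of columns as gaps
        if (nchar(prot) < 0.5 * cov_min * nchar(rr$protein[r])) next
        res <- align_proteins(prot, rr$protein[r])
        if (is.null(best) || res$score > best$score) {
          best <- res
          best$ref_id <- rr$ref_id[r]
        }
      }
      if (!is.null(best) &&
          best$percent_identity >= id_min &&
          best$subject_coverage >= cov_min) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = proteome$gene_id[g], role = role, ref_id = best$ref_id,
          percent_identity = best$percent_identity,
          subject_coverage = best$subject_coverage, score = best$score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), role = character(0),
                      ref_id = character(0), percent_identity = numeric(0),
                      subject_coverage = numeric(0), score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Detect C-T-A operons from role assignments and gene coordinates
#'
#' A cassette hit is a (C, A) candidate pair on the same contig and strand
#' with exactly one small ORF (at most `t_max_len` amino acids) strictly
#' between them in coordinate order — recorded as the T (acyl carrier)
#' gene — and consecutive intergenic gaps (C-T and T-A) each at most
#' `max_gap_bp`. Both coordinate orders (C before A and A before C) are
#' accepted. An isolate "has the cassette" when it has at least one hit.
#'
#' @param genes Gene coordinate data.frame (see [read_gene_table()]) with a
#'   `protein` column or accompanied by protein lengths via `proteome`.
#' @param assignments Role assignments from [find_homologs()].
#' @param max_gap_bp Maximum intergenic gap in bp (default 500).
#' @param t_max_len Maximum T-protein length in amino acids (default 120).
#' @param proteome Optional data.frame `gene_id`/`protein` used for T-ORF
#'   lengths when `genes` has no `protein` column.
#' @return data.frame of cassette hits: `genome_id`, `contig_id`, `c_gene`,
#'   `t_gene`, `a_gene`, `strand`, `span_start`, `span_end`, plus the C and
#'   A identity/coverage evidence.
#' @export
detect_cassettes <- function(genes, assignments, max_gap_bp = 500,
                             t_max_len = 120, proteome = NULL) {
  if (!"protein" %in% names(genes)) {
    if (is.null(proteome)) stop("supply proteins via 'genes$protein' or 'proteome'")
    genes$protein <- proteome$protein[match(genes$gene_id, proteome$gene_id)]
  }
  c_genes <- assignments$gene_id[assignments$role == "C"]
  a_genes <- assignments$gene_id[assignments$role == "A"]
  hits <- list()
  for (cg in c_genes) {
    ci <- match(cg, genes$gene_id)
    for (ag in a_genes) {
      ai <- match(ag, genes$gene_id)
      if (cg == ag) next
      if (genes$genome_id[ci] != genes$genome_id[ai] ||
          genes$contig_id[ci] != genes$contig_id[ai] ||
          genes$strand[ci] != genes$strand[ai]) next
      left <- if (genes$start[ci] < genes$start[ai]) ci else ai
      right <- if (left == ci) ai else ci
      between <- which(genes$genome_id == genes$genome_id[ci] &
                       genes$contig_id == genes$contig_id[ci] &
                       genes$start > genes$end[left] &
                       genes$end < genes$start[right])
      if (length(between) != 1L) next
      ti <- between
      if (genes$strand[ti] != genes$strand[ci]) next
      if (nchar(genes$protein[ti]) > t_max_len) next
      gap1 <- genes$start[ti] - genes$end[left] - 1L
      gap2 <- genes$start[right] - genes$end[ti] - 1L
      if (gap1 > max_gap_bp || gap2 > max_gap_bp) next
      c_ev <- assignments[assignments$gene_id == cg & assignments$role == "C", ]
      a_ev <- assignments[assignments$gene_id == ag & assignments$role == "A", ]
      hits[[length(hits) + 1L]] <- data.frame(
        genome_id = genes$genome_id[ci], contig_id = genes$contig_id[ci],
        c_gene = cg, t_gene = genes$gene_id[ti], a_gene = ag,
        strand = genes$strand[ci],
        span_start = min(genes$start[ci], genes$start[ai]),
        span_end = max(genes$end[ci], genes$end[ai]),
        c_identity = c_ev$percent_identity[1], c_coverage = c_ev$subject_coverage[1],
        a_identity = a_ev$percent_identity[1], a_coverage = a_ev$subject_coverage[1],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(genome_id = character(0), contig_id = character(0),
                      c_gene = character(0), t_gene = character(0),
                      a_gene = character(0), strand = character(0),
                      span_start = integer(0), span_end = integer(0),
                      c_identity = numeric(0), c_coverage = numeric(0),
                      a_identity = numeric(0), a_coverage = numeric(0)))
  }
  do.call(rbind, hits)
}

#' Scan one or more genomes for the cassette
#'
#' Convenience wrapper: role assignment by homology, then operon detection,
#' per genome.
#'
#' @param proteome Protein records (`genome_id`, `contig_id`, `gene_id`,
#'   `protein`).
#' @param genes Gene coordinates (see [read_gene_table()]).
#' @param references C/A reference proteins (see [read_references()]).
#' @param id_min,cov_min Homology cutoffs (defaults 70, 0.80).
#' @param max_gap_bp,t_max_len Operon-structure parameters.
#' @return data.frame of cassette hits across genomes (possibly empty).
#' @export
scan_genomes <- function(proteome, genes, references, id_min = 70,
                         cov_min = 0.80, max_gap_bp = 500, t_max_len = 120) {
  hits <- list()
  for (gid in unique(proteome$genome_id)) {
    p <- proteome[proteome$genome_id == gid, , drop = FALSE]
    g <- genes[genes$genome_id == gid, , drop = FALSE]
    asg <- find_homologs(p, references, id_min = id_min, cov_min = cov_min)
    h <- detect_cassettes(g, asg, max_gap_bp = max_gap_bp,
                          t_max_len = t_max_len, proteome = p)
    if (nrow(h)) hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) {
    return(detect_cassettes(genes[0, , drop = FALSE],
                            data.frame(gene_id = character(0), role = character(0)),
                            proteome = proteome[0, , drop = FALSE]))
  }
  do.call(rbind, hits)
}

#' Summarize cassette presence per species
#'
#' @param isolates data.frame with one row per isolate: `genome_id`,
#'   `species`, and logical `has_cassette`.
#' @return data.frame per species with `n_with`, `n_without`, `n_isolates`.
#' @export
summarize_species <- function(isolates) {
  if (!nrow(isolates)) stop("at least one isolate required")
  sp <- split(isolates$has_cassette, isolates$species)
  out <- data.frame(
    species = names(sp),
    n_with = vapply(sp, sum, integer(1)),
    n_without = vapply(sp, function(x) sum(!x), integer(1)),
    stringsAsFactors = FALSE
  )
  out$n_isolates <- out$n_with + out$n_without
  rownames(out) <- NULL
  out
}
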