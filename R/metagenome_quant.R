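# Translated-read quantification of cassette genes in shotgun metagenomes:
# six-frame translation, local alignment against a protein database, a
# >= 90% identity over >= 30 aligned amino acids rule, and normalization to
# reads per million. An exact-7-mer prefilter (any alignment window
# satisfying the rule must contain an ungapped exact stretch of at least 7
# residues, by pigeonhole over its <= 10% non-match columns) keeps full
# alignment to candidate reads only; it cannot discard a qualifying read.

#' Six-frame translation of a nucleotide read
#'
#' Standard genetic code; frames 1-3 are the forward strand offsets 0-2,
#' frames 4-6 the reverse complement offsets 0-2. Codons containing `N`
#' translate to `X`; stop codons are rendered as `*`. Trailing bases that
#' do not fill a codon are dropped.
#'
#' @param read A single nucleotide string over `A,C,G,T,N`.
#' @return Character vector of 6 peptide strings.
#' @export
six_frame_translate <- function(read) {
  if (!is.character(read) || length(read) != 1L || nchar(read) < 3L) {
    stop("read must be a single nucleotide string of length >= 3")
  }
  .translate_frames_one(read)
}

# Vectorized frame translation: returns a list of 6 AAStringSet objects
# (one per frame) for a DNAStringSet of reads.
.translate_frames <- function(reads) {
  rc <- Biostrings::reverseComplement(reads)
  frames <- vector("list", 6L)
  for (off in 0:2) {
    for (strand in 1:2) {
      src <- if (strand == 1L) reads else rc
      w <- Biostrings::width(src) - off
      keep_len <- pmax(w - w %% 3L, 0L)
      sub <- Biostrings::subseq(src, start = off + 1L,
                                width = keep_len)
      frames[[off + 1L + (strand - 1L) * 3L]] <-
        suppressWarnings(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    }
  }
  frames
}

.translate_frames_one <- function(read) {
  vapply(.translate_frames(Biostrings::DNAStringSet(read)),
         function(x) as.character(x)[1], character(1))
}

# Coerce a protein database argument (AAStringSet, named character vector,
# data.frame with id/protein, or FASTA path) to a named character vector.
.as_protein_db <- function(db) {
  if (inherits(db, "AAStringSet")) {
    out <- as.character(db)
  } else if (is.data.frame(db)) {
    out <- db$protein
    names(out) <- if ("ref_id" %in% names(db)) db$ref_id else db$gene_id
  } else if (is.character(db) && length(db) == 1L && file.exists(db)) {
    out <- as.character(Biostrings::readAAStringSet(db))
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(db)) {
    out <- db
  } else {
    stop("unsupported protein database type")
  }
  if (!length(out)) stop("empty protein database")
  if (is.null(names(out))) names(out) <- paste0("db", seq_along(out))
  out
}

# TRUE when the 0/1 column-match vector contains a window of >= len_min
# columns with mean >= id_min / 100. All window lengths are checked.
.has_window <- function(match_vec, len_min, id_min) {
  L <- length(match_vec)
  if (L < len_min) return(FALSE)
  cs <- c(0, cumsum(match_vec))
  thr <- id_min / 100
  for (len in len_min:L) {
    wins <- cs[(len + 1L):(L + 1L)] - cs[1L:(L - len + 1L)]
    if (any(wins >= thr * len - 1e-9)) return(TRUE)
  }
  FALSE
}

# Best qualifying window (maximum length among windows meeting the rule);
# returns c(length, identity_percent) or NULL.
.best_window <- function(match_vec, len_min, id_min) {
  L <- length(match_vec)
  if (L < len_min) return(NULL)
  cs <- c(0, cumsum(match_vec))
  thr <- id_min / 100
  best <- NULL
  for (len in len_min:L) {
    wins <- cs[(len + 1L):(L + 1L)] - cs[1L:(L - len + 1L)]
    ok <- wins >= thr * len - 1e-9
    if (any(ok)) best <- c(len, max(wins[ok]) / len * 100)
  }
  best
}

# Align a set of peptides against one subject in a single vectorized
# pairwiseAlignment call; returns per-peptide score and the qualifying
# window (or NA) under the len_min/id_min rule.
.align_peptides <- function(peps, subject_seq, id_min, len_min) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(peps),
    subject = Biostrings::AAString(subject_seq),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  sc <- Biostrings::score(aln)
  win_len <- rep(NA_real_, length(peps))
  win_id <- rep(NA_real_, length(peps))
  for (i in seq_along(peps)) {
    if (nchar(ap[i]) < len_min) next
    pc <- strsplit(ap[i], "")[[1]]
    scb <- strsplit(as_[i], "")[[1]]
    m <- as.integer(pc == scb & pc != "-" & pc != "X" & pc != "*")
    win <- .best_window(m, len_min, id_min)
    if (!is.null(win)) {
      win_len[i] <- win[1]
      win_id[i] <- win[2]
    }
  }
  list(score = sc, window_length = win_len, window_identity = win_id)
}

# Best qualifying hit per read for a set of reads (DNAStringSet), given
# their candidate status. Returns a data.frame with one row per read that
# qualifies.
.match_reads <- function(reads, db, id_min, len_min) {
  frames <- .translate_frames(reads)
  pep <- unlist(lapply(frames, as.character), use.names = FALSE)
  read_idx <- rep(seq_along(reads), times = 6L)
  frame_idx <- rep(1:6, each = length(reads))
  keep <- which(nchar(pep) >= len_min)
  # a qualifying window of length L >= len_min has >= id_min% match columns
  # (min BLOSUM62 diagonal 4) and <= (1 - id_min%) non-match columns (worst
  # per-column cost 12 = single-residue gap), so its local score — and hence
  # the optimal local score — is at least this bound
  min_score <- max(0, floor(len_min * (4 * id_min / 100 -
                                       12 * (1 - id_min / 100))))
  hits <- NULL
  for (s in seq_along(db)) {
    if (!length(keep)) break
    sub <- Biostrings::AAString(db[[s]])
    sc0 <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(pep[keep]), subject = sub,
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
    )
    sel <- keep[sc0 >= min_score]
    if (!length(sel)) next
    res <- .align_peptides(pep[sel], db[[s]], id_min, len_min)
    q <- which(!is.na(res$window_length))
    if (!length(q)) next
    h <- data.frame(
      read = read_idx[sel][q], frame = frame_idx[sel][q],
      subject_id = names(db)[s], window_identity = res$window_identity[q],
      window_length = res$window_length[q], score = res$score[q],
      stringsAsFactors = FALSE
    )
    hits <- rbind(hits, h)
  }
  if (is.null(hits)) return(NULL)
  # one hit per read: highest score wins
  hits <- hits[order(hits$read, -hits$score), , drop = FALSE]
  hits[!duplicated(hits$read), , drop = FALSE]
}

#' Match one read against a cassette protein database
#'
#' The read is translated in all six frames and each frame is locally
#' aligned (BLOSUM62, affine gaps 11/1) against every database protein.
#' Each alignment is inspected for a window of at least `len_min` aligned
#' columns with at least `id_min` percent identity; among qualifying
#' alignments the one with the highest score wins, giving at most one hit
#' per read.
#'
#' @param read Nucleotide string.
#' @param db Protein database (named character vector, `AAStringSet`,
#'   data.frame, or FASTA path).
#' @param id_min Minimum percent identity over the window (default 90).
#' @param len_min Minimum window length in aligned amino-acid columns
#'   (default 30).
#' @param read_id Identifier recorded in the hit (default `"read"`).
#' @return One-row data.frame (`read_id`, `frame`, `subject_id`,
#'   `window_identity`, `window_length`, `score`) or `NULL` when the read
#'   does not qualify.
#' @export
match_read <- function(read, db, id_min = 90, len_min = 30, read_id = "read") {
  db <- .as_protein_db(db)
  if (nchar(read) < 3L * len_min) return(NULL)
  h <- .match_reads(Biostrings::DNAStringSet(read), db, id_min, len_min)
  if (is.null(h)) return(NULL)
  data.frame(read_id = read_id, frame = h$frame, subject_id = h$subject_id,
             window_identity = h$window_identity,
             window_length = h$window_length, score = h$score,
             stringsAsFactors = FALSE)
}

# Exact 7-mer index of a protein database. Any alignment window with
# >= 30 columns at >= 90% identity has <= 10% non-match columns, so its
# longest exact ungapped run is >= ceil(0.9 * 30 / (0.1 * 30 + 1)) = 7.
.db_kmers <- function(db, k = 7L) {
  kmers <- unlist(lapply(db, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  unique(kmers)
}

# Candidate filter: which reads share an exact k-mer (in any frame) with
# the database. Reads are processed per frame with vectorized substring.
.candidate_reads <- function(reads, kmers, k = 7L) {
  frames <- .translate_frames(reads)
  hit <- logical(length(reads))
  for (fr in frames) {
    chr <- as.character(fr)
    for (len in unique(nchar(chr))) {
      if (len < k) next
      idx <- which(nchar(chr) == len & !hit)
      if (!length(idx)) next
      sub <- chr[idx]
      found <- logical(length(idx))
      for (i in 1:(len - k + 1L)) {
        found <- found | (substr(sub, i, i + k - 1L) %in% kmers)
      }
      hit[idx] <- hit[idx] | found
    }
  }
  hit
}

#' Quantify cassette-gene abundance in one metagenomic sample
#'
#' Counts reads matching the cassette protein database under the
#' `id_min`/`len_min` rule (at most one count per read) and normalizes to
#' reads per million total reads. FASTQ input is processed in chunks so
#' memory stays bounded in the number of reads held at once.
#'
#' @param reads FASTQ path (plain or gzip) or a `DNAStringSet`.
#' @param db Protein database (see [match_read()]).
#' @param id_min,len_min Matching rule (defaults 90, 30).
#' @param sample_id Identifier for the output row.
#' @param chunk_size Reads per FASTQ chunk (default 10000).
#' @return One-row data.frame: `sample_id`, `aligned_reads`, `total_reads`,
#'   `rpm` (`aligned_reads / total_reads * 1e6`).
#' @export
quantify_sample <- function(reads, db, id_min = 90, len_min = 30,
                            sample_id = "sample", chunk_size = 10000L) {
  db <- .as_protein_db(db)
  kmers <- .db_kmers(db)
  aligned <- 0L
  total <- 0L
  process_chunk <- function(chunk) {
    if (!length(chunk)) return(0L)
    ok <- Biostrings::width(chunk) >= 3L * len_min
    cand <- logical(length(chunk))
    if (any(ok)) cand[ok] <- .candidate_reads(chunk[ok], kmers)
    if (!any(cand)) return(0L)
    h <- .match_reads(chunk[cand], db, id_min, len_min)
    if (is.null(h)) 0L else nrow(h)
  }
  if (inherits(reads, "DNAStringSet")) {
    total <- length(reads)
    if (!total) stop("no reads supplied")
    idx <- split(seq_len(total), ceiling(seq_len(total) / chunk_size))
    for (ii in idx) aligned <- aligned + process_chunk(reads[ii])
  } else {
    skip <- 0L
    repeat {
      chunk <- tryCatch(
        Biostrings::readDNAStringSet(reads, format = "fastq",
                                     nrec = chunk_size, skip = skip),
        error = function(e) {
          stop("failed reading FASTQ ", reads, " near record ", skip + 1L,
               ": ", conditionMessage(e))
        })
      if (!length(chunk)) break
      total <- total + length(chunk)
      aligned <- aligned + process_chunk(chunk)
      skip <- skip + length(chunk)
      if (length(chunk) < chunk_size) break
    }
    if (!total) stop("no reads in ", reads)
  }
  data.frame(sample_id = sample_id, aligned_reads = aligned,
             total_reads = total, rpm = aligned / total * 1e6,
             stringsAsFactors = FALSE)
}

#' Quantify a set of samples from a sample sheet
#'
#' @param sample_sheet data.frame (or TSV path) with columns `sample_id`,
#'   `fastq` (path) and `group`.
#' @param db Protein database.
#' @param ... Passed to [quantify_sample()].
#' @return data.frame with one row per sample (`sample_id`, `group`,
#'   `aligned_reads`, `total_reads`, `rpm`).
#' @export
quantify_samples <- function(sample_sheet, db, ...) {
  if (is.character(sample_sheet)) {
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  }
  req <- c("sample_id", "fastq", "group")
  miss <- setdiff(req, names(sample_sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    q <- quantify_sample(sample_sheet$fastq[i], db,
                         sample_id = sample_sheet$sample_id[i], ...)
    q$group <- sample_sheet$group[i]
    q
  })
  do.call(rbind, rows)
}

#' Compare cassette abundance between two groups
#'
#' Mann-Whitney U test on per-sample reads-per-million values, with
#' Benjamini-Hochberg correction across comparisons when several databases
#' (or endpoints) are tested together.
#'
#' @param quant data.frame with columns `rpm` and `group` (exactly two
#'   group levels), or a named list of such data.frames for multiple
#'   comparisons.
#' @param ... Passed to [mann_whitney_u()].
#' @return data.frame with one row per comparison: group sizes, `U`,
#'   `p_value` and `q_value` (BH across the comparisons supplied).
#' @export
compare_groups <- function(quant, ...) {
  if (is.data.frame(quant)) quant <- list(comparison = quant)
  rows <- lapply(names(quant), function(nm) {
    df <- quant[[nm]]
    lev <- unique(df$group)
    if (length(lev) != 2L) stop("comparison ", nm, " must have exactly 2 groups")
    x <- df$rpm[df$group == lev[1]]
    y <- df$rpm[df$group == lev[2]]
    if (length(x) < 2L || length(y) < 2L) {
      stop("comparison ", nm, " needs >= 2 observations per group")
    }
    res <- mann_whitney_u(x, y, ...)
    data.frame(comparison = nm, group_a = lev[1], group_b = lev[2],
               n_a = length(x), n_b = length(y),
               U = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}
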