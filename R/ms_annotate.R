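# MS1 matching of untargeted features against the conjugate library at a
# ppm tolerance, and MS2 confirmation by the two diagnostic fragments.

#' Read an MS1 feature table
#'
#' Feature tables are TSV with header and columns `feature_id`, `mz`, `rt`
#' (minutes) and `intensity`.
#'
#' @param path TSV path.
#' @return data.frame of features; `feature_id` must be unique, `mz > 0`.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "mz", "rt", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("feature table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(suppressWarnings(as.numeric(df$mz))) | as.numeric(df$mz) <= 0)
  if (length(bad)) {
    stop("nonpositive or malformed m/z in ", path, ", data line(s) ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature_id in ", path)
  }
  df$mz <- as.numeric(df$mz)
  df
}

#' Read MS2 spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: each `BEGIN IONS`/`END IONS` block
#' becomes one spectrum. `TITLE` carries the precursor feature id;
#' `COLLISION_ENERGY` (eV) is optional. Peaks are returned sorted by m/z.
#'
#' @param path MGF path.
#' @return Named list (by feature id) of lists with elements `feature_id`,
#'   `collision_energy` (NA if absent) and `peaks` (two-column matrix,
#'   `mz` and `intensity`). Several spectra of one feature (e.g. different
#'   collision energies) are returned as separate list entries.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("unbalanced BEGIN/END IONS blocks in ", path)
  }
  spectra <- vector("list", length(begins))
  ids <- character(length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    title <- vals[match("TITLE", keys)]
    if (is.na(title)) stop("spectrum ", i, " in ", path, " has no TITLE")
    ce <- suppressWarnings(as.numeric(vals[match("COLLISION_ENERGY", keys)]))
    pk_lines <- block[!kv & nzchar(trimws(block))]
    if (length(pk_lines)) {
      fields <- strsplit(trimws(pk_lines), "[ \t]+")
      pk <- do.call(rbind, lapply(fields, function(x) as.numeric(x[1:2])))
      if (any(is.na(pk))) stop("malformed peak line in spectrum ", title)
      pk <- pk[order(pk[, 1]), , drop = FALSE]
    } else {
      pk <- matrix(numeric(0), ncol = 2)
    }
    colnames(pk) <- c("mz", "intensity")
    ids[i] <- trimws(title)
    spectra[[i]] <- list(feature_id = ids[i], collision_energy = ce, peaks = pk)
  }
  names(spectra) <- ids
  spectra
}

#' Match MS1 features against a conjugate library
#'
#' Every (feature, conjugate) pair whose mass deviation is within `tol_ppm`
#' of the conjugate's theoretical \eqn{[M+H]^+} m/z is reported; a feature
#' may carry several candidate annotations (ambiguity is resolved later by
#' MS2). The ppm error is computed against the theoretical m/z and the
#' boundary is inclusive.
#'
#' @param features Feature data.frame (see [read_features()]).
#' @param library Conjugate library (see [build_library()]).
#' @param tol_ppm MS1 mass tolerance in ppm (default 5).
#' @return data.frame of hits with columns `feature_id`, `mz`, `rt`,
#'   `intensity`, `amine_name`, `fa_name`, `formula`, `precursor_mz`,
#'   `ppm_error`, `amine_fragment_found`, `fatty_amide_fragment_found`,
#'   `confidence` (all `"ms1_only"` at this stage), sorted by feature and
#'   then by absolute ppm error.
#' @export
match_ms1 <- function(features, library, tol_ppm = 5) {
  if (!nrow(library)) stop("empty conjugate library")
  if (tol_ppm < 0) stop("tol_ppm must be nonnegative")
  ord <- order(library$precursor_mz)
  theo <- library$precursor_mz[ord]
  t <- tol_ppm * 1e-6
  # |obs - theo| / theo <= t  <=>  theo in [obs / (1 + t), obs / (1 - t)]
  lo <- findInterval(features$mz / (1 + t), theo, left.open = TRUE) + 1L
  hi <- if (t < 1) findInterval(features$mz / (1 - t), theo)
        else rep(length(theo), nrow(features))
  n_hit <- pmax(hi - lo + 1L, 0L)
  fi <- rep(seq_len(nrow(features)), n_hit)
  li <- unlist(lapply(which(n_hit > 0L), function(i) ord[lo[i]:hi[i]]),
               use.names = FALSE)
  if (!length(fi)) li <- integer(0)
  hits <- data.frame(
    feature_id = features$feature_id[fi],
    mz = features$mz[fi],
    rt = features$rt[fi],
    intensity = features$intensity[fi],
    amine_name = library$amine_name[li],
    fa_name = library$fa_name[li],
    formula = library$formula[li],
    precursor_mz = library$precursor_mz[li],
    amine_fragment_mz = library$amine_fragment_mz[li],
    fatty_amide_mz = library$fatty_amide_mz[li],
    stringsAsFactors = FALSE
  )
  hits$ppm_error <- if (nrow(hits)) ppm_error(hits$mz, hits$precursor_mz) else numeric(0)
  # guard against floating slop at the inclusive boundary
  keep <- abs(hits$ppm_error) <= tol_ppm + 1e-9
  hits <- hits[keep, , drop = FALSE]
  fi <- fi[keep]
  hits$amine_fragment_found <- logical(nrow(hits))
  hits$fatty_amide_fragment_found <- logical(nrow(hits))
  hits$confidence <- rep("ms1_only", nrow(hits))
  hits <- hits[order(fi, abs(hits$ppm_error)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Screen an annotation hit against an MS2 spectrum
#'
#' Each of the two diagnostic fragments — the protonated free amine and the
#' protonated fatty primary amide — is called present when some spectrum
#' peak lies within `tol_ppm` of its theoretical m/z. Confidence tiers:
#' `"confirmed"` (both fragments), `"partial"` (exactly one),
#' `"ms1_only"` (neither).
#'
#' @param hit One-row hit data.frame from [match_ms1()] (carries the
#'   theoretical fragment m/z columns `amine_fragment_mz` and
#'   `fatty_amide_mz`).
#' @param spectrum A spectrum list as returned by [read_mgf()] (its
#'   `feature_id` must equal the hit's).
#' @param tol_ppm MS2 fragment tolerance in ppm (default 10).
#' @return The hit row with `amine_fragment_found`,
#'   `fatty_amide_fragment_found` and `confidence` updated.
#' @export
screen_ms2 <- function(hit, spectrum, tol_ppm = 10) {
  if (!identical(as.character(hit$feature_id), spectrum$feature_id)) {
    stop("spectrum feature_id ", spectrum$feature_id,
         " does not match hit feature_id ", hit$feature_id)
  }
  peaks <- spectrum$peaks[, "mz"]
  hit$amine_fragment_found <-
    .peak_within(peaks, hit$amine_fragment_mz, tol_ppm)
  hit$fatty_amide_fragment_found <-
    .peak_within(peaks, hit$fatty_amide_mz, tol_ppm)
  hit$confidence <- .confidence_tier(hit$amine_fragment_found,
                                     hit$fatty_amide_fragment_found)
  hit
}

.peak_within <- function(peaks, theoretical, tol_ppm) {
  if (!length(peaks)) return(FALSE)
  any(abs(ppm_error(peaks, theoretical)) <= tol_ppm + 1e-9)
}

.confidence_tier <- function(amine_found, amide_found) {
  ifelse(amine_found & amide_found, "confirmed",
         ifelse(amine_found | amide_found, "partial", "ms1_only"))
}

#' Annotate an untargeted feature table with acyl-amine candidates
#'
#' End-to-end screen: MS1 matching of every feature against the library at
#' `ms1_tol_ppm`, then, for features with MS2 spectra, diagnostic-fragment
#' screening at `ms2_tol_ppm`. When a feature has several spectra (e.g.
#' different collision energies) their peak lists are pooled, mirroring a
#' screen across all acquired energies.
#'
#' @param features Feature data.frame (see [read_features()]).
#' @param library Conjugate library.
#' @param spectra Optional list of MS2 spectra from [read_mgf()]; `NULL`
#'   leaves all hits at the `ms1_only` tier.
#' @param ms1_tol_ppm,ms2_tol_ppm Mass tolerances in ppm (defaults 5 and 10).
#' @return Annotation table: one row per MS1 hit, with fragment flags and
#'   confidence tier filled in where spectra exist.
#' @export
annotate <- function(features, library, spectra = NULL,
                     ms1_tol_ppm = 5, ms2_tol_ppm = 10) {
  hits <- match_ms1(features, library, tol_ppm = ms1_tol_ppm)
  if (!nrow(hits)) return(hits)
  if (!is.null(spectra) && length(spectra)) {
    spec_ids <- vapply(spectra, `[[`, character(1), "feature_id")
    pooled <- lapply(split(spectra, spec_ids), function(sp) {
      sort(unlist(lapply(sp, function(s) s$peaks[, "mz"]), use.names = FALSE))
    })
    pk <- pooled[as.character(hits$feature_id)]
    has_spec <- !vapply(pk, is.null, logical(1))
    for (i in which(has_spec)) {
      hits$amine_fragment_found[i] <-
        .peak_within(pk[[i]], hits$amine_fragment_mz[i], ms2_tol_ppm)
      hits$fatty_amide_fragment_found[i] <-
        .peak_within(pk[[i]], hits$fatty_amide_mz[i], ms2_tol_ppm)
    }
    hits$confidence <- .confidence_tier(hits$amine_fragment_found,
                                        hits$fatty_amide_fragment_found)
  }
  hits
}

#' Write an annotation table as TSV
#'
#' @param annotations Annotation data.frame from [annotate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
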