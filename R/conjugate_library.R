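# Combinatorial acyl-amine library: every amine x fatty-acid amide, with
# neutral mass, [M+H]+ precursor m/z and the two diagnostic fragments
# (protonated free amine, protonated fatty primary amide).

#' Read a compound list
#'
#' Compound lists are TSV files with a header and columns `name`, `formula`
#' and optionally `class` (one of `"amine"`, `"fatty_acid"`).
#'
#' @param path Path to the TSV file.
#' @param compound_class If given, keep only rows of this class (and require
#'   a `class` column).
#' @return A data.frame with columns `name`, `formula` and (if present)
#'   `class`; names must be unique within a class.
#' @export
read_compounds <- function(path, compound_class = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("name", "formula")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("compound list ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(compound_class)) {
    if (!"class" %in% names(df)) stop("compound list ", path, " has no 'class' column")
    df <- df[df$class == compound_class, , drop = FALSE]
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate compound names in ", path, ": ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  df
}

# Parse a vector of formula strings into a count matrix (rows = compounds,
# columns = the supported elements), so library-scale mass arithmetic is a
# single matrix operation.
.formula_matrix <- function(formulas) {
  elems <- names(.MONO_MASS)
  mat <- matrix(0L, nrow = length(formulas), ncol = length(elems),
                dimnames = list(NULL, elems))
  for (i in seq_along(formulas)) {
    f <- parse_formula(formulas[[i]])
    mat[i, names(f)] <- f
  }
  mat
}

# Render rows of a count matrix as Hill strings (vectorized).
.render_matrix <- function(mat) {
  elems <- colnames(mat)
  ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  mat <- mat[, ord, drop = FALSE]
  out <- character(nrow(mat))
  parts <- matrix("", nrow = nrow(mat), ncol = ncol(mat))
  for (j in seq_len(ncol(mat))) {
    cnt <- mat[, j]
    parts[, j] <- ifelse(cnt == 0L, "",
                         paste0(ord[j], ifelse(cnt == 1L, "", cnt)))
  }
  do.call(paste0, as.data.frame(parts, stringsAsFactors = FALSE))
}

#' Build the combinatorial acyl-amine library
#'
#' Forms the amide condensation product of every amine with every fatty
#' acid. The result has exactly `nrow(amines) * nrow(fatty_acids)` rows in
#' deterministic order (amine-major, fatty acid minor). Name-distinct
#' compounds with identical formulas are retained as separate conjugates;
#' only [unique_formula_count()] deduplicates at the formula level.
#'
#' @param amines,fatty_acids Data frames with columns `name` and `formula`
#'   (as from [read_compounds()] or [gen_compound_lists()]).
#' @return A data.frame of class `"conjugate_library"` with one row per
#'   conjugate: `amine_name`, `fa_name`, `formula`, `neutral_mass`,
#'   `precursor_mz` (\eqn{[M+H]^+}), `amine_fragment_formula`,
#'   `amine_fragment_mz`, `fatty_amide_formula`, `fatty_amide_mz`.
#' @examples
#' amines <- data.frame(name = "dopamine", formula = "C8H11NO2")
#' fas <- data.frame(name = "oleic", formula = "C18H34O2")
#' build_library(amines, fas)$precursor_mz # 418.33
#' @export
build_library <- function(amines, fatty_acids) {
  if (!nrow(amines) || !nrow(fatty_acids)) {
    stop("amine and fatty-acid lists must be nonempty")
  }
  am <- .formula_matrix(amines$formula)
  fa <- .formula_matrix(fatty_acids$formula)

  bad_am <- which(am[, "N"] < 1L | am[, "H"] < 2L)
  if (length(bad_am)) {
    stop("amine ", amines$name[bad_am[1]], " (", amines$formula[bad_am[1]],
         ") lacks an aminatable group (need >= 1 N, >= 2 H)")
  }
  bad_fa <- which(fa[, "O"] < 2L | fa[, "H"] < 1L)
  if (length(bad_fa)) {
    stop("fatty acid ", fatty_acids$name[bad_fa[1]], " (",
         fatty_acids$formula[bad_fa[1]], ") lacks a carboxyl (need >= 2 O, >= 1 H)")
  }

  n_a <- nrow(am)
  n_f <- nrow(fa)
  ia <- rep(seq_len(n_a), each = n_f)
  jf <- rep(seq_len(n_f), times = n_a)

  conj <- am[ia, , drop = FALSE] + fa[jf, , drop = FALSE]
  conj[, "H"] <- conj[, "H"] - 2L
  conj[, "O"] <- conj[, "O"] - 1L
  if (any(conj < 0L)) {
    k <- which(apply(conj < 0L, 1L, any))[1]
    stop("condensation failed for amine ", amines$name[ia[k]],
         " + fatty acid ", fatty_acids$name[jf[k]])
  }

  mass_vec <- .MONO_MASS[colnames(conj)]
  neutral <- as.numeric(conj %*% mass_vec)
  amine_mz <- as.numeric(am %*% mass_vec) + .PROTON_MASS

  amide <- fa
  amide[, "O"] <- amide[, "O"] - 1L
  amide[, "N"] <- amide[, "N"] + 1L
  amide[, "H"] <- amide[, "H"] + 1L
  amide_mz <- as.numeric(amide %*% mass_vec) + .PROTON_MASS
  amide_formula <- .render_matrix(amide)

  out <- data.frame(
    amine_name = amines$name[ia],
    fa_name = fatty_acids$name[jf],
    formula = .render_matrix(conj),
    neutral_mass = neutral,
    precursor_mz = neutral + .PROTON_MASS,
    amine_fragment_formula = amines$formula[ia],
    amine_fragment_mz = amine_mz[ia],
    fatty_amide_formula = amide_formula[jf],
    fatty_amide_mz = amide_mz[jf],
    stringsAsFactors = FALSE
  )
  class(out) <- c("conjugate_library", "data.frame")
  out
}

#' Count unique conjugate formulas in a library
#'
#' Isomeric pairings (e.g. oleic vs elaidic acid with the same amine)
#' collapse to one formula; the count is the number of distinct canonical
#' Hill strings.
#'
#' @param library A `"conjugate_library"` data.frame from [build_library()].
#' @return Integer count of distinct formulas (at most `nrow(library)`).
#' @export
unique_formula_count <- function(library) {
  length(unique(library$formula))
}

#' Write / read a conjugate library as TSV
#'
#' The library TSV is the single interchange format between the library and
#' annotation stages; masses survive the round trip to at least 6 decimals.
#'
#' @param library A `"conjugate_library"` data.frame.
#' @param path Output (or input) TSV path.
#' @return `read_library()` returns the library data.frame;
#'   `write_library()` returns `path` invisibly.
#' @export
write_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty library file: ", path)
  req <- c("amine_name", "fa_name", "formula", "neutral_mass", "precursor_mz",
           "amine_fragment_formula", "amine_fragment_mz",
           "fatty_amide_formula", "fatty_amide_mz")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("library file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  num <- c("neutral_mass", "precursor_mz", "amine_fragment_mz", "fatty_amide_mz")
  for (col in num) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop("malformed numeric value in ", path, ", column ", col,
           ", data line(s) ", paste(bad, collapse = ", "))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  class(df) <- c("conjugate_library", "data.frame")
  df
}
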