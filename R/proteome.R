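#' Read a proteome FASTA
#'
#' Parses a protein FASTA (plain or gzip) into a `proteome` object: one
#' record per entry, gene identifier taken as the header token before the
#' first whitespace, sequences upper-cased and any trailing stop symbols
#' (`*`) stripped. Records left with no canonical residues are excluded
#' with a warning.
#'
#' @param path FASTA file path.
#' @return A `proteome` object: list with `gene_id`, `sequence` and
#'   `length` (residue count after stop-stripping, including tolerated
#'   non-canonical symbols).
#' @seealso [length_filter()], [exome_profile()]
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty identifier")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  canon <- .canonical_counts(seqs)
  empty <- rowSums(canon) == 0L
  if (any(empty)) {
    warning(sum(empty), " record(s) with no canonical residues excluded: ",
            paste(utils::head(ids[empty], 5L), collapse = ", "),
            if (sum(empty) > 5L) ", ...")
    seqs <- seqs[!empty]; ids <- ids[!empty]
  }
  if (!length(seqs)) stop("no usable records in FASTA file: ", path)
  structure(
    list(gene_id = unname(ids), sequence = unname(seqs),
         length = unname(nchar(seqs)), source = path),
    class = "proteome")
}

#' Assemble a proteome object from in-memory sequences
#'
#' Mainly for testing and synthetic data: applies the same sanitisation as
#' [read_proteome()] (upper-casing, trailing-stop stripping, unique
#' non-empty identifiers).
#'
#' @param sequences Named character vector (names are gene identifiers).
#' @return A `proteome` object.
#' @export
as_proteome <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "")) stop("sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicate gene identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- sub("\\*+$", "", toupper(as.character(sequences)))
  structure(
    list(gene_id = unname(ids), sequence = unname(seqs),
         length = unname(nchar(seqs)), source = NA_character_),
    class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("Proteome: ", length(x$gene_id), " protein records",
      if (!is.na(x$source)) paste0(" from ", x$source), "\n", sep = "")
  cat("Length range: ", min(x$length), "-", max(x$length), " residues\n",
      sep = "")
  invisible(x)
}

#' @export
length.proteome <- function(x) length(x$gene_id)

# Subset a proteome by logical/integer index.
.proteome_subset <- function(x, i) {
  structure(list(gene_id = x$gene_id[i], sequence = x$sequence[i],
                 length = x$length[i], source = x$source),
            class = "proteome")
}

# Per-sequence canonical residue counts (matrix, one row per sequence,
# columns in canonical order) plus an attribute tallying excluded symbols.
.canonical_counts <- function(seqs) {
  af <- Biostrings::alphabetFrequency(Biostrings::AAStringSet(seqs))
  counts <- af[, .AA_CODES, drop = FALSE]
  other <- af[, setdiff(colnames(af), .AA_CODES), drop = FALSE]
  tally <- colSums(other)
  attr(counts, "excluded_symbols") <- tally[tally > 0]
  counts
}

#' Filter proteins by sequence length
#'
#' Retains proteins whose length lies in `[min_len, max_len]` inclusive:
#' only strictly shorter / strictly longer sequences are removed, so the
#' boundary lengths themselves survive. Extreme lengths are trimmed before
#' averaging because very short and very long translations would otherwise
#' distort the exome-average amino-acid usage.
#'
#' @param proteome A `proteome` object.
#' @param min_len,max_len Inclusive length bounds (defaults 100 and 2000
#'   residues).
#' @return List with `retained` (a `proteome`) and `stats` (named list
#'   `n_total`, `n_short`, `n_long`, `n_retained`, `min_len`, `max_len`).
#' @export
#' @examples
#' p <- as_proteome(c(a = strrep("M", 99), b = strrep("K", 100)))
#' length_filter(p)$stats$n_short
length_filter <- function(proteome, min_len = 100L, max_len = 2000L) {
  stopifnot(inherits(proteome, "proteome"))
  if (min_len > max_len) stop("min_len must not exceed max_len")
  len <- proteome$length
  short <- len < min_len
  long <- len > max_len
  keep <- !short & !long
  if (!any(keep)) stop("all proteins filtered")
  stats <- list(n_total = length(len), n_short = sum(short),
                n_long = sum(long), n_retained = sum(keep),
                min_len = as.integer(min_len), max_len = as.integer(max_len))
  list(retained = .proteome_subset(proteome, keep), stats = stats)
}

#' Per-protein amino-acid proportions
#'
#' Canonical residue counts divided by the number of canonical residues.
#' Tolerated non-canonical symbols (B, J, O, U, X, Z) are excluded from
#' both numerator and denominator.
#'
#' @param sequence A single protein sequence (character scalar).
#' @return An `aa_profile` (molar basis).
#' @export
#' @examples
#' protein_profile("MXM")  # X ignored; M = 1
protein_profile <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  counts <- .canonical_counts(sub("\\*+$", "", toupper(sequence)))[1L, ]
  if (sum(counts) == 0) stop("sequence contains no canonical residues")
  aa_profile(counts, basis = "molar")
}

# Row-normalised per-protein proportion matrix for a proteome.
.profile_matrix <- function(proteome) {
  counts <- .canonical_counts(proteome$sequence)
  denom <- rowSums(counts)
  if (any(denom == 0))
    stop("protein(s) with no canonical residues: ",
         paste(utils::head(proteome$gene_id[denom == 0], 5L), collapse = ", "))
  mat <- counts / denom
  rownames(mat) <- proteome$gene_id
  attr(mat, "excluded_symbols") <- attr(counts, "excluded_symbols")
  mat
}

#' Average amino-acid usage of a protein set
#'
#' Combines per-protein usage into a single profile. Under
#' `mean_of_proportions` (the default) every protein contributes equally:
#' the result is the unweighted arithmetic mean of per-protein proportion
#' vectors. Under `pooled_counts` residues are pooled across proteins and
#' normalised, which weights proteins by length. The two coincide exactly
#' when all proteins have equal length.
#'
#' @param proteome A `proteome` (normally already length-filtered).
#' @param averaging_mode `"mean_of_proportions"` or `"pooled_counts"`.
#' @param filter_stats Optional stats list from [length_filter()], carried
#'   into the result's provenance.
#' @return An `exome_profile`: list with `profile` (an `aa_profile`),
#'   filter bookkeeping (`n_total`, `n_short`, `n_long`, `n_retained`,
#'   `min_len`, `max_len`), `averaging_mode` and the tally of
#'   `excluded_symbols`.
#' @seealso [exome_profile()] for the one-stop FASTA-to-profile wrapper.
#' @export
exome_average <- function(proteome,
                          averaging_mode = c("mean_of_proportions",
                                             "pooled_counts"),
                          filter_stats = NULL) {
  stopifnot(inherits(proteome, "proteome"))
  averaging_mode <- match.arg(averaging_mode)
  if (!length(proteome$gene_id)) stop("empty proteome")
  if (identical(averaging_mode, "mean_of_proportions")) {
    mat <- .profile_matrix(proteome)
    prof <- colMeans(mat)
    excl <- attr(mat, "excluded_symbols")
  } else {
    counts <- .canonical_counts(proteome$sequence)
    excl <- attr(counts, "excluded_symbols")
    prof <- colSums(counts) / sum(counts)
  }
  if (is.null(filter_stats)) {
    n <- length(proteome$gene_id)
    filter_stats <- list(n_total = n, n_short = 0L, n_long = 0L,
                         n_retained = n, min_len = NA_integer_,
                         max_len = NA_integer_)
  }
  structure(
    c(list(profile = aa_profile(prof, basis = "molar")),
      filter_stats,
      list(averaging_mode = averaging_mode,
           excluded_symbols = excl,
           source = proteome$source)),
    class = "exome_profile")
}

#' Exome-average amino-acid profile from a proteome
#'
#' One-stop wrapper: read (or take) a proteome, apply the length filter,
#' and average per-protein amino-acid usage into the exome requirement
#' profile \eqn{p} used by [limiting_report()].
#'
#' @param x FASTA file path or a `proteome` object.
#' @param min_len,max_len Length-filter bounds, see [length_filter()].
#' @param averaging_mode See [exome_average()].
#' @return An `exome_profile`.
#' @export
#' @examples
#' p <- as_proteome(c(a = strrep("MK", 60), b = strrep("KV", 75)))
#' exome_profile(p, min_len = 1)
exome_profile <- function(x, min_len = 100L, max_len = 2000L,
                          averaging_mode = c("mean_of_proportions",
                                             "pooled_counts")) {
  averaging_mode <- match.arg(averaging_mode)
  prot <- if (inherits(x, "proteome")) x else read_proteome(x)
  flt <- length_filter(prot, min_len = min_len, max_len = max_len)
  exome_average(flt$retained, averaging_mode = averaging_mode,
                filter_stats = flt$stats)
}

#' @export
print.exome_profile <- function(x, digits = 4, ...) {
  cat("Exome-average amino-acid profile (", x$averaging_mode, ")\n", sep = "")
  cat("Proteins: ", x$n_retained, " retained of ", x$n_total,
      " (", x$n_short, " short, ", x$n_long, " long",
      if (!is.na(x$min_len))
        paste0("; bounds [", x$min_len, ", ", x$max_len, "]"),
      ")\n", sep = "")
  if (length(x$excluded_symbols))
    cat("Non-canonical symbols excluded from counts: ",
        paste0(names(x$excluded_symbols), "=", x$excluded_symbols,
               collapse = ", "), "\n", sep = "")
  print(round(unclass(x$profile), digits))
  invisible(x)
}
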