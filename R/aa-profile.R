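# Canonical one-letter alphabet, fixed order used for all serialised output.
.AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Ambiguity/non-canonical symbols tolerated in input FASTA but excluded from
# residue counts (B, Z ambiguous; J = I/L; U = Sec; O = Pyl; X unknown).
.AA_NONCANONICAL <- c("B", "J", "O", "U", "X", "Z")

# Free (unhydrated, non-salt) L-amino-acid molecular weights in g/mol.
.AA_MW <- c(
  A =  89.09, C = 121.16, D = 133.10, E = 147.13, F = 165.19,
  G =  75.07, H = 155.15, I = 131.17, K = 146.19, L = 131.17,
  M = 149.21, N = 132.12, P = 115.13, Q = 146.15, R = 174.20,
  S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19
)

#' Canonical amino-acid codes
#'
#' The twenty canonical one-letter amino-acid codes in the fixed order
#' (`ACDEFGHIKLMNPQRSTVWY`) used by every profile, table and serialised
#' output in this package.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_codes()
aa_codes <- function() .AA_CODES

#' Free amino-acid molecular weights
#'
#' Molecular weights (g/mol) of the free, unhydrated, non-salt L-amino
#' acids, used to convert mass-based diet recipes to molar proportions.
#' Chemically defined (holidic) media often supply some amino acids as
#' salts or hydrates; pass a corrected table to [recipe_to_profile()] when
#' exactness matters for such recipes.
#'
#' @return Named numeric vector over [aa_codes()].
#' @export
aa_molecular_weights <- function() .AA_MW

#' Amino-acid proportion profile
#'
#' Constructs the package's common currency: a non-negative proportion
#' vector over the 20 canonical amino acids that sums to one. Both the
#' dietary supply vector \eqn{d} and the exome requirement vector \eqn{p}
#' of the limiting-score rule are `aa_profile` objects.
#'
#' @param x Named numeric vector. Names must be canonical one-letter codes;
#'   amino acids not named are set to zero. Values must be non-negative
#'   and not all zero.
#' @param basis Either `"molar"` (the default, required by all scoring
#'   functions) or `"mass"`.
#' @param normalize Divide by the total so the result sums to one
#'   (default `TRUE`). With `normalize = FALSE` the input must already sum
#'   to one within `1e-9`.
#' @return An `aa_profile`: named numeric vector of length 20 in canonical
#'   order with a `basis` attribute.
#' @seealso [recipe_to_profile()], [exome_profile()]
#' @export
#' @examples
#' aa_profile(c(M = 1, K = 3))
aa_profile <- function(x, basis = c("molar", "mass"), normalize = TRUE) {
  basis <- match.arg(basis)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("profile values must be named with amino-acid one-letter codes")
  bad <- setdiff(names(x), .AA_CODES)
  if (length(bad))
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(x)))
    stop("duplicated amino-acid code(s) in profile")
  if (anyNA(x) || any(x < 0))
    stop("profile values must be non-negative and non-missing")
  p <- stats::setNames(numeric(20L), .AA_CODES)
  p[names(x)] <- as.numeric(x)
  s <- sum(p)
  if (s <= 0) stop("profile has zero total")
  if (normalize) {
    p <- p / s
  } else if (abs(s - 1) > 1e-9) {
    stop("profile does not sum to 1 (", format(s), "); use normalize = TRUE")
  }
  structure(p, basis = basis, class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, digits = 4, ...) {
  cat("Amino-acid profile (basis: ", attr(x, "basis"), ")\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
as.data.frame.aa_profile <- function(x, ...) {
  data.frame(aa = .AA_CODES, proportion = as.numeric(x),
             stringsAsFactors = FALSE)
}

# Accept either an aa_profile or a bare named non-negative vector (any
# alphabet); bare vectors are renormalised. Toy alphabets are allowed so the
# scoring rules can be exercised on low-dimensional examples.
.as_proportions <- function(x, arg = "profile") {
  if (inherits(x, "aa_profile")) {
    if (!identical(attr(x, "basis"), "molar"))
      stop(arg, " must be on the molar basis")
    return(stats::setNames(as.numeric(x), names(x)))
  }
  if (!is.numeric(x) || is.null(names(x)))
    stop(arg, " must be an aa_profile or a named numeric vector")
  if (anyNA(x) || any(x < 0)) stop(arg, " has negative or missing values")
  s <- sum(x)
  if (s <= 0) stop(arg, " has zero total")
  stats::setNames(as.numeric(x) / s, names(x))
}

#' Write an amino-acid profile as TSV
#'
#' Writes columns `aa`, `proportion` in canonical order. When `provenance`
#' is supplied it is serialised as a JSON sidecar at `<path>.json`.
#'
#' @param x An `aa_profile` (or `exome_profile`, whose filter statistics
#'   are then added to the sidecar automatically).
#' @param path Output TSV path.
#' @param provenance Optional named list written to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path, provenance = NULL) {
  if (inherits(x, "exome_profile")) {
    stats <- x[c("n_total", "n_short", "n_long", "n_retained",
                 "min_len", "max_len", "averaging_mode")]
    provenance <- c(provenance, stats,
                    list(excluded_symbols = as.list(x$excluded_symbols)))
    x <- x$profile
  }
  stopifnot(inherits(x, "aa_profile"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read an amino-acid profile from TSV
#'
#' Reads the two-column (`aa`, `proportion`) format written by
#' [write_profile_tsv()] and renormalises to the simplex.
#'
#' @param path TSV path.
#' @param basis Basis to stamp on the result.
#' @return An `aa_profile`.
#' @export
read_profile_tsv <- function(path, basis = c("molar", "mass")) {
  basis <- match.arg(basis)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("aa", "proportion") %in% names(tab)))
    stop("profile TSV must have columns 'aa' and 'proportion'")
  aa_profile(stats::setNames(tab$proportion, tab$aa), basis = basis)
}

# Euclidean distance between two profiles on a shared alphabet.
profile_distance <- function(a, b) {
  a <- .as_proportions(a, "a"); b <- .as_proportions(b, "b")
  if (!identical(names(a), names(b))) {
    if (!setequal(names(a), names(b)))
      stop("profiles are over different alphabets")
    b <- b[names(a)]
  }
  sqrt(sum((a - b)^2))
}
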