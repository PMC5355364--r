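#' Essential amino-acid configuration
#'
#' Declares which amino acids are essential for the consumer and which
#' conditionally essential amino acids are made from an essential
#' precursor. The default is the fly/rodent set: ten essential amino acids
#' (arginine counted as essential) and the two conditional pairs
#' phenylalanine -> tyrosine and methionine -> cysteine, where a dietary
#' shortfall of the dependent is met mole-for-mole from the precursor.
#'
#' @param essential Character vector of essential one-letter codes.
#' @param conditional_pairs List of length-2 character vectors
#'   `c(precursor, dependent)`. Each precursor must be essential and each
#'   dependent must not be.
#' @return An `eaa_config` object.
#' @export
#' @examples
#' eaa_config()
eaa_config <- function(essential = c("R", "H", "I", "K", "L",
                                     "M", "F", "T", "W", "V"),
                       conditional_pairs = list(c("F", "Y"), c("M", "C"))) {
  essential <- unique(as.character(essential))
  if (!length(essential)) stop("at least one essential amino acid required")
  for (pr in conditional_pairs) {
    if (length(pr) != 2L)
      stop("conditional pairs must be c(precursor, dependent)")
    if (!pr[1] %in% essential)
      stop("conditional precursor ", pr[1], " must be essential")
    if (pr[2] %in% essential)
      stop("conditional dependent ", pr[2], " must not be essential")
  }
  dep <- vapply(conditional_pairs, `[`, "", 2L)
  if (anyDuplicated(dep)) stop("a dependent appears in more than one pair")
  structure(list(essential = essential,
                 conditional_pairs = conditional_pairs),
            class = "eaa_config")
}

#' @export
print.eaa_config <- function(x, ...) {
  cat("Essential amino acids:", paste(x$essential, collapse = " "), "\n")
  for (pr in x$conditional_pairs)
    cat("Conditional pair: ", pr[1], " -> ", pr[2], "\n", sep = "")
  invisible(x)
}

#' Diet recipe
#'
#' Per-amino-acid amounts of a diet, either as g/L of free amino acid or
#' as molar proportions, before conversion to the molar profile \eqn{d}
#' used for scoring. All twenty amino acids are carried (absent ones as
#' zero); at least one essential amino acid must be positive.
#'
#' @param name Recipe name.
#' @param amounts Named non-negative numeric vector (one-letter codes).
#' @param unit `"g_per_L"` or `"molar_proportion"`.
#' @param total_aa_mass Optional total amino-acid mass (g/L), context for
#'   dose-response work.
#' @param eaa `eaa_config` used for the at-least-one-essential check.
#' @param provenance Optional free-text provenance note.
#' @return A `diet_recipe` object.
#' @export
diet_recipe <- function(name, amounts, unit = c("g_per_L", "molar_proportion"),
                        total_aa_mass = NA_real_, eaa = eaa_config(),
                        provenance = NULL) {
  unit <- match.arg(unit)
  a <- stats::setNames(numeric(20L), .AA_CODES)
  bad <- setdiff(names(amounts), .AA_CODES)
  if (length(bad))
    stop("unknown amino-acid code(s) in recipe: ", paste(bad, collapse = ", "))
  a[names(amounts)] <- as.numeric(amounts)
  if (anyNA(a) || any(a < 0)) stop("recipe amounts must be non-negative")
  if (all(a[eaa$essential] <= 0))
    stop("recipe supplies no essential amino acid")
  structure(list(name = as.character(name), amounts = a, unit = unit,
                 total_aa_mass = total_aa_mass, provenance = provenance),
            class = "diet_recipe")
}

#' @export
print.diet_recipe <- function(x, ...) {
  cat("Diet recipe '", x$name, "' (", x$unit, ")\n", sep = "")
  if (!is.na(x$total_aa_mass))
    cat("Total amino-acid mass: ", x$total_aa_mass, " g/L\n", sep = "")
  print(x$amounts[x$amounts > 0])
  invisible(x)
}

#' Convert a diet recipe to a molar amino-acid profile
#'
#' Mass amounts (g/L) are divided by the free amino-acid molecular weight
#' and renormalised to molar proportions; molar inputs are renormalised
#' only. This is the conversion that makes g/L recipes comparable with the
#' molar exome profile.
#'
#' @param recipe A `diet_recipe`.
#' @param mw_table Named molecular-weight table (g/mol); defaults to
#'   [aa_molecular_weights()]. Override for salt/hydrate nutrient forms.
#' @return An `aa_profile` (molar basis) with the recipe name attached as
#'   attribute `name`.
#' @export
#' @examples
#' r <- diet_recipe("demo", c(G = 1, W = 1, M = 1), unit = "g_per_L")
#' recipe_to_profile(r)
recipe_to_profile <- function(recipe, mw_table = aa_molecular_weights()) {
  stopifnot(inherits(recipe, "diet_recipe"))
  a <- recipe$amounts
  if (identical(recipe$unit, "g_per_L")) {
    need <- names(a)[a > 0]
    missing_mw <- need[!(need %in% names(mw_table)) | is.na(mw_table[need])]
    if (length(missing_mw))
      stop("no molecular weight for amino acid(s): ",
           paste(missing_mw, collapse = ", "))
    moles <- a
    moles[need] <- a[need] / mw_table[need]
    prof <- aa_profile(moles, basis = "molar")
  } else {
    prof <- aa_profile(a, basis = "molar")
  }
  attr(prof, "name") <- recipe$name
  prof
}

#' Write a diet recipe as TSV
#'
#' Two columns `aa`, `amount` preceded by `# name=`, `# unit=` and
#' `# total_aa_mass=` header comments.
#'
#' @param recipe A `diet_recipe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diet_tsv <- function(recipe, path) {
  stopifnot(inherits(recipe, "diet_recipe"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# name=", recipe$name),
               paste0("# unit=", recipe$unit),
               paste0("# total_aa_mass=",
                      ifelse(is.na(recipe$total_aa_mass), "NA",
                             format(recipe$total_aa_mass, digits = 15))),
               "aa\tamount"), con)
  writeLines(paste(.AA_CODES,
                   format(recipe$amounts, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a diet recipe TSV
#'
#' Counterpart of [write_diet_tsv()].
#'
#' @param path TSV path.
#' @param eaa `eaa_config` for validation.
#' @return A `diet_recipe`.
#' @export
read_diet_tsv <- function(path, eaa = eaa_config()) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA_character_) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(paste0("^#\\s*", key, "="), "", m[1])
  }
  nm <- get("name", default = basename(path))
  unit <- get("unit", default = "g_per_L")
  tot <- suppressWarnings(as.numeric(get("total_aa_mass")))
  tab <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                           stringsAsFactors = FALSE)
  if (!all(c("aa", "amount") %in% names(tab)))
    stop("diet TSV must have columns 'aa' and 'amount'")
  diet_recipe(nm, stats::setNames(tab$amount, tab$aa), unit = unit,
              total_aa_mass = tot, eaa = eaa)
}
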