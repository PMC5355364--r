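#' Typical proteome amino-acid composition
#'
#' A realistic default global composition for the synthetic proteome
#' generator: amino-acid frequencies typical of well-annotated eukaryotic
#' protein databases (Swiss-Prot-style usage statistics), normalised to
#' the simplex.
#'
#' @return An `aa_profile` (molar basis).
#' @export
typical_proteome_composition <- function() {
  aa_profile(c(
    A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
    G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
    M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
    S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
  ) / 100)
}

#' Generate a deterministic synthetic proteome
#'
#' Emulates the inputs of an exome-profiling run without any database
#' download: exactly `n_short` sequences shorter than the core range,
#' `n_long` longer, and the remainder inside it. Per-protein amino-acid
#' compositions are drawn from a Dirichlet distribution centred on
#' `global_composition` with the given concentration (larger = proteins
#' more alike), and residues are placed by multinomial draw with a random
#' shuffle. Fully reproducible from `seed`; the caller's RNG state is
#' untouched.
#'
#' @param n_total Total number of proteins.
#' @param n_short Number with length below `length_range_core[1]`
#'   (lengths drawn uniformly from `short_range`).
#' @param n_long Number with length above `length_range_core[2]`
#'   (lengths drawn uniformly from `long_range`).
#' @param length_range_core Inclusive core length range, default
#'   `c(100, 2000)`.
#' @param short_range,long_range Length ranges of the extreme strata,
#'   defaults `c(30, 99)` and `c(2001, 4000)`.
#' @param global_composition Centre of the per-protein composition
#'   distribution; default [typical_proteome_composition()].
#' @param dirichlet_concentration Dirichlet concentration (default 50,
#'   a realistic between-protein usage dispersion).
#' @param seed Integer seed (required).
#' @param path Output FASTA path; default a tempfile. `NA` skips writing.
#' @return List with `path`, `proteome` (a `proteome` object) and
#'   `manifest` (stratum counts, realized pooled composition, lengths,
#'   and the generating parameters).
#' @export
#' @examples
#' sp <- make_synthetic_proteome(50, n_short = 5, n_long = 2, seed = 7,
#'                               path = NA)
#' sp$manifest$n_retained_expected
make_synthetic_proteome <- function(n_total, n_short = 0L, n_long = 0L,
                                    length_range_core = c(100L, 2000L),
                                    short_range = c(30L, 99L),
                                    long_range = c(2001L, 4000L),
                                    global_composition =
                                      typical_proteome_composition(),
                                    dirichlet_concentration = 50,
                                    seed, path = tempfile(fileext = ".fasta")) {
  if (missing(seed)) stop("a seed is required")
  n_total <- as.integer(n_total)
  n_short <- as.integer(n_short)
  n_long <- as.integer(n_long)
  if (n_short + n_long > n_total)
    stop("infeasible strata: n_short + n_long exceeds n_total")
  if (short_range[2] >= length_range_core[1] ||
      long_range[1] <= length_range_core[2])
    stop("stratum length ranges overlap the core range")
  comp <- .as_proportions(global_composition, "global_composition")
  if (dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be positive")
  n_core <- n_total - n_short - n_long
  out <- .with_seed(seed, {
    lengths <- c(
      if (n_short) sample(short_range[1]:short_range[2], n_short, TRUE),
      if (n_core) sample(length_range_core[1]:length_range_core[2],
                         n_core, TRUE),
      if (n_long) sample(long_range[1]:long_range[2], n_long, TRUE))
    alpha <- dirichlet_concentration * comp
    k <- length(comp)
    gam <- matrix(stats::rgamma(n_total * k, shape = rep(alpha, each = n_total)),
                  nrow = n_total)
    props <- gam / rowSums(gam)
    letters20 <- names(comp)
    seqs <- vapply(seq_len(n_total), function(i) {
      counts <- stats::rmultinom(1L, lengths[i], props[i, ])[, 1L]
      paste(sample(rep(letters20, counts)), collapse = "")
    }, "")
    list(lengths = lengths, seqs = seqs)
  })
  ids <- sprintf("g%05d", seq_len(n_total))
  prot <- structure(list(gene_id = ids, sequence = out$seqs,
                         length = out$lengths,
                         source = if (is.na(path)) NA_character_ else path),
                    class = "proteome")
  counts <- .canonical_counts(out$seqs)
  realized <- colSums(counts) / sum(counts)
  if (!is.na(path)) {
    con <- file(path, "wb")
    writeLines(paste0(">", ids, "\n", out$seqs), con, sep = "\n")
    close(con)
  }
  manifest <- list(
    n_total = n_total, n_short = n_short, n_long = n_long,
    n_retained_expected = n_core,
    length_range_core = as.integer(length_range_core),
    short_range = as.integer(short_range),
    long_range = as.integer(long_range),
    dirichlet_concentration = dirichlet_concentration, seed = seed,
    lengths = out$lengths,
    global_composition = unname(comp),
    realized_composition = stats::setNames(unname(realized), names(realized)))
  list(path = path, proteome = prot, manifest = manifest)
}

# Registry of diet recipes transcribed from published formulation tables.
# Empty: no published recipe has been transcribed into this installation.
# Entries, when added, are diet_recipe objects with a provenance note
# naming the table and units they were transcribed from.
.recipe_registry <- list()

#' Packaged diet recipes
#'
#' Registry of diet recipes transcribed from published formulation tables
#' (e.g. exome-matched, mismatched-control, casein- or yeast-derived
#' ratios). Recipes are only ever transcribed, never fabricated: this
#' installation ships with an empty registry, and requesting a recipe that
#' has not been transcribed is an explicit error. Users can supply their
#' own transcriptions as TSV via [read_diet_tsv()].
#'
#' @param name Optional recipe name. When omitted, the full (possibly
#'   empty) named list of packaged recipes is returned.
#' @return A named list of `diet_recipe` objects, or a single
#'   `diet_recipe` when `name` is given.
#' @export
packaged_recipes <- function(name = NULL) {
  if (is.null(name)) return(.recipe_registry)
  if (!name %in% names(.recipe_registry))
    stop("recipe '", name, "' is not packaged: no published formulation ",
         "table for it has been transcribed into this installation. ",
         "Supply it as TSV via read_diet_tsv().")
  .recipe_registry[[name]]
}
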