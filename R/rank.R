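# Run code with a temporarily seeded RNG, restoring the caller's state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Rank genes by similarity of amino-acid usage to the exome average
#'
#' Computes, for every protein, the distance between its amino-acid
#' proportion vector and the exome-average profile, and ranks genes from
#' most similar (rank 1, smallest distance) to least similar. Ties receive
#' average ranks for test statistics (`rank_avg`) and stable ordinal ranks
#' (by distance, then gene identifier) for display (`rank`).
#'
#' @param proteome A `proteome` object (the ranking universe).
#' @param exome An `exome_profile` or `aa_profile` reference.
#' @param metric Distance metric; currently `"euclidean"`.
#' @return A `rank_table`: data frame with columns `gene_id`, `distance`,
#'   `rank`, `rank_avg`, sorted ascending by distance, with attributes
#'   `metric` and `n_universe`.
#' @export
rank_by_similarity <- function(proteome, exome, metric = c("euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(proteome, "proteome"))
  if (!length(proteome$gene_id)) stop("empty proteome")
  if (inherits(exome, "exome_profile")) exome <- exome$profile
  ref <- .as_proportions(exome, "exome")
  mat <- .profile_matrix(proteome)
  ref <- ref[colnames(mat)]
  dist <- sqrt(rowSums((mat - rep(ref, each = nrow(mat)))^2))
  ord <- order(dist, proteome$gene_id)
  tab <- data.frame(gene_id = proteome$gene_id[ord],
                    distance = unname(dist[ord]),
                    rank = seq_along(ord),
                    rank_avg = rank(dist, ties.method = "average")[ord],
                    stringsAsFactors = FALSE)
  structure(tab, metric = metric, n_universe = nrow(tab),
            class = c("rank_table", "data.frame"))
}

#' Test whether a gene set ranks closer to the exome average than chance
#'
#' One-sided test of whether the mean similarity rank of a gene set is
#' smaller (more exome-like) than expected under uniform sampling without
#' replacement of same-size sets from the universe. Average ranks are used
#' as the test statistic.
#'
#' The `normal_approx` method uses the exact null moments of the sampled
#' mean rank, mean \eqn{(N+1)/2} and variance \eqn{(N-n)(N+1)/(12n)}, with
#' a continuity correction of one half applied on the rank-sum scale
#' before standardisation. The `permutation` method draws seeded random
#' same-size sets and reports the add-one estimate
#' \eqn{(1 + \#\{perm \le obs\}) / (1 + B)}.
#'
#' @param table A `rank_table` from [rank_by_similarity()].
#' @param gene_set Character vector of gene identifiers. Identifiers
#'   absent from the universe are dropped with a warning.
#' @param method `"normal_approx"` (default) or `"permutation"`.
#' @param n_permutations Number of permutation draws.
#' @param seed Seed for the permutation draws (required for that method).
#' @param set_name Label carried into the result.
#' @return An `enrichment_result`: list with `set_name`, `n_set`,
#'   `n_universe`, `n_missing`, `mean_rank`, `p_value`, `method`,
#'   `n_permutations`, `seed`.
#' @export
set_mean_rank_test <- function(table, gene_set,
                               method = c("normal_approx", "permutation"),
                               n_permutations = 100000L, seed = NULL,
                               set_name = "gene_set") {
  method <- match.arg(method)
  stopifnot(inherits(table, "rank_table"))
  gene_set <- unique(as.character(gene_set))
  inset <- gene_set %in% table$gene_id
  n_missing <- sum(!inset)
  if (n_missing)
    warning(n_missing, " gene id(s) not in the ranking universe; dropped")
  gene_set <- gene_set[inset]
  if (!length(gene_set)) stop("gene set has empty intersection with universe")
  N <- attr(table, "n_universe")
  n <- length(gene_set)
  if (n >= N && method == "normal_approx" && n > N)
    stop("gene set larger than universe")
  ranks <- table$rank_avg[match(gene_set, table$gene_id)]
  obs <- mean(ranks)
  if (method == "normal_approx") {
    if (n == N) {
      p <- 1
    } else {
      mu_s <- n * (N + 1) / 2
      sd_s <- sqrt(n * (N - n) * (N + 1) / 12)
      p <- stats::pnorm((n * obs + 0.5 - mu_s) / sd_s)
    }
    B <- NA_integer_
  } else {
    if (is.null(seed)) stop("permutation method requires a seed")
    B <- as.integer(n_permutations)
    pool <- table$rank_avg
    hits <- .with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(B)) {
        if (mean(pool[sample.int(N, n)]) <= obs + 1e-12) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + hits) / (1 + B)
  }
  structure(list(set_name = set_name, n_set = n, n_universe = N,
                 n_missing = n_missing, mean_rank = obs, p_value = p,
                 method = method, n_permutations = B,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, digits = 4, ...) {
  cat("Mean-rank gene-set test ('", x$set_name, "', ", x$method, ")\n",
      sep = "")
  cat("n = ", x$n_set, " of ", x$n_universe, " genes",
      if (x$n_missing) paste0(" (", x$n_missing, " dropped)"),
      "\n", sep = "")
  cat("Mean rank = ", format(x$mean_rank, digits = digits),
      " (null mean ", format((x$n_universe + 1) / 2, digits = digits),
      "), one-sided p = ", format(x$p_value, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Read a gene-set file
#'
#' Plain text, one identifier per line; `#` comment lines and blank lines
#' are ignored.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("gene-set file is empty: ", path)
  lines
}
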