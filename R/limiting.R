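# Effective per-essential constraint scores for diet d against exome p.
#
# Unpaired essential i: score_i = d_i / p_i. For a conditional pair
# (precursor P, dependent D): when the dependent is in surplus
# (d_D/p_D >= d_P/p_P) the pair constraint equals the precursor's own
# score; otherwise the shortfall is met mole-for-mole from the precursor
# and the constraint pools to (d_P + d_D) / (p_P + p_D). Pairs whose
# dependent is absent from the alphabet degrade to the unpaired rule
# (relevant only for toy alphabets).
.eaa_scores <- function(d, p, eaa) {
  ess <- eaa$essential
  miss <- setdiff(ess, names(d))
  if (length(miss))
    stop("essential amino acid(s) absent from profile alphabet: ",
         paste(miss, collapse = ", "))
  ord <- order(match(ess, .AA_CODES), ess)
  ess <- ess[ord]
  if (any(p[ess] == 0))
    stop("exome proportion is zero for essential amino acid(s): ",
         paste(ess[p[ess] == 0], collapse = ", "),
         " (the model demands a positive requirement for every essential)")
  scores <- d[ess] / p[ess]
  effective <- scores
  pair_scores <- numeric(0)
  for (pr in eaa$conditional_pairs) {
    P <- pr[1]; D <- pr[2]
    if (!(P %in% ess) || !(D %in% names(d))) next
    surplus <- d[D] * p[P] >= d[P] * p[D]
    ps <- if (surplus) d[P] / p[P] else (d[P] + d[D]) / (p[P] + p[D])
    pair_scores[paste0(P, "+", D)] <- ps
    effective[P] <- ps
  }
  list(essential = ess, scores = scores, pair_scores = pair_scores,
       effective = effective)
}

# Ties at the minimum within a fixed relative tolerance.
.tie_set <- function(effective, r) {
  names(effective)[abs(effective - r) <= 1e-12 * max(1, abs(r))]
}

#' Limiting essential amino acid of a diet
#'
#' Scores a diet against an exome-average requirement profile under the
#' Liebig-style minimum rule: for each essential amino acid \eqn{i} the
#' score is \eqn{d_i / p_i}, the molar dietary proportion over the molar
#' exome proportion, with the conditional pairs (F,Y) and (M,C) pooled to
#' \eqn{(d_P + d_D)/(p_P + p_D)} when the dependent is undersupplied. The
#' minimum score \eqn{r} predicts the output (egg laying, growth)
#' attainable on the diet relative to a perfectly matched one, and its
#' argmin is the limiting amino acid. When a pooled pair binds, the
#' precursor is reported as limiting.
#'
#' A zero dietary supply of an essential amino acid yields \eqn{r = 0}
#' (the diet supports no output) rather than an error; a zero exome
#' requirement for an essential is an error.
#'
#' @param diet Diet profile: an `aa_profile` (molar) or named non-negative
#'   vector (renormalised). Toy alphabets are allowed.
#' @param exome Exome requirement profile: an `exome_profile`,
#'   `aa_profile` (molar) or named vector.
#' @param eaa An [eaa_config()].
#' @return A `limiting_report`: list with `diet` (name), `scores` (raw
#'   per-essential \eqn{d_i/p_i}), `pair_scores`, `effective` (pair-adjusted
#'   per-essential scores), `r`, `limiting_aa` (first of `limiting_set` in
#'   canonical order), `limiting_set` (all tied argmins), `runner_up_aa`
#'   and `runner_up_score`.
#' @export
#' @examples
#' exome <- aa_profile(c(M = 1, K = 2, R = 1, H = 1, I = 1, L = 2, F = 1,
#'                       T = 1, W = 1, V = 1, Y = 1, C = 1, A = 3))
#' diet <- aa_profile(c(M = 0.5, K = 2, R = 1, H = 1, I = 1, L = 2, F = 1,
#'                      T = 1, W = 1, V = 1, Y = 1, C = 1, A = 3))
#' limiting_report(diet, exome)
limiting_report <- function(diet, exome, eaa = eaa_config()) {
  diet_name <- attr(diet, "name")
  if (inherits(exome, "exome_profile")) exome <- exome$profile
  d <- .as_proportions(diet, "diet")
  p <- .as_proportions(exome, "exome")
  if (!setequal(names(d), names(p)))
    stop("diet and exome profiles are over different alphabets")
  p <- p[names(d)]
  sc <- .eaa_scores(d, p, eaa)
  r <- min(sc$effective)
  tie <- .tie_set(sc$effective, r)
  rest <- sc$effective[setdiff(names(sc$effective), tie)]
  structure(
    list(diet = if (is.null(diet_name)) NA_character_ else diet_name,
         scores = sc$scores, pair_scores = sc$pair_scores,
         effective = sc$effective, r = unname(r),
         limiting_aa = tie[1], limiting_set = tie,
         runner_up_aa = if (length(rest)) names(rest)[which.min(rest)]
                        else NA_character_,
         runner_up_score = if (length(rest)) unname(min(rest)) else NA_real_,
         eaa = eaa, d = d, p = p),
    class = "limiting_report")
}

#' @export
print.limiting_report <- function(x, digits = 4, ...) {
  cat("Limiting amino-acid report",
      if (!is.na(x$diet)) paste0(" for diet '", x$diet, "'"), "\n", sep = "")
  cat("r = ", format(x$r, digits = digits), ", limiting: ",
      paste(x$limiting_set, collapse = ", "), "\n", sep = "")
  if (!is.na(x$runner_up_aa))
    cat("Runner-up: ", x$runner_up_aa, " (",
        format(x$runner_up_score, digits = digits), ")\n", sep = "")
  cat("Per-essential scores (pair-adjusted):\n")
  print(round(x$effective, digits))
  if (length(x$pair_scores)) {
    cat("Conditional-pair scores:\n")
    print(round(x$pair_scores, digits))
  }
  invisible(x)
}

#' @export
summary.limiting_report <- function(object, ...) {
  data.frame(aa = names(object$effective),
             score = unname(object$scores[names(object$effective)]),
             effective = unname(object$effective),
             limiting = names(object$effective) %in% object$limiting_set,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predicted output fold change between two diets
#'
#' At equal total amino-acid mass, the predicted output on `diet2`
#' relative to `diet1` is `r(diet2) / r(diet1)`: each diet's output is
#' proportional to its limiting score, so the ratio of limiting scores is
#' the predicted proportional change when switching from the reference
#' `diet1` to `diet2`. (Note the direction: this function returns
#' output(diet2)/output(diet1), i.e. values above one mean `diet2` is
#' predicted to support more output.)
#'
#' @param diet1 Reference diet profile.
#' @param diet2 Comparison diet profile.
#' @inheritParams limiting_report
#' @return A single number, `r(diet2) / r(diet1)`.
#' @export
fold_change <- function(diet1, diet2, exome, eaa = eaa_config()) {
  r1 <- limiting_report(diet1, exome, eaa)$r
  r2 <- limiting_report(diet2, exome, eaa)$r
  if (r1 == 0) stop("reference diet predicts zero output")
  r2 / r1
}

# Increasing constraint g(x) for the limiting amino acid `aa` as its
# dietary amount is multiplied by fold x with all other amounts fixed
# (proportions treated as amounts; no renormalisation). Piecewise linear:
# for a pair precursor the surplus branch x * d_P/p_P holds while the
# dependent covers its own requirement, then pools to
# (x*d_P + d_D)/(p_P + p_D).
.supplement_constraint <- function(x, aa, d, p, eaa) {
  pairs <- Filter(function(pr) pr[1] == aa && pr[2] %in% names(d),
                  eaa$conditional_pairs)
  if (!length(pairs)) return(x * d[[aa]] / p[[aa]])
  D <- pairs[[1]][2]
  surplus <- d[[D]] * p[[aa]] >= x * d[[aa]] * p[[D]]
  ifelse(surplus,
         x * d[[aa]] / p[[aa]],
         (x * d[[aa]] + d[[D]]) / (p[[aa]] + p[[D]]))
}

#' Supplementation breakpoint of the limiting amino acid
#'
#' Predicts the fold-addition `x_star` of the current limiting amino acid
#' at which another essential (or pooled pair) becomes limiting.
#' Supplementation multiplies only that amino acid's dietary amount by the
#' fold `x`, holding all other amounts fixed (the total rises slightly);
#' scores are therefore recomputed un-renormalised, so every other
#' constraint stays constant while the supplemented one rises. Predicted
#' relative output rises linearly with `x` up to `x_star` and is constant
#' beyond.
#'
#' In the ordinary case `x_star = r_next / (d_aa / p_aa)` with `r_next`
#' the minimum constraint excluding `aa`; when `aa` is a conditional-pair
#' precursor whose pooled constraint binds, the exact piecewise-linear
#' solve is used instead.
#'
#' @inheritParams limiting_report
#' @param aa The current limiting amino acid of `diet` (error otherwise).
#' @return An `aa_breakpoint`: list with `x_star`, `next_limiting`, the
#'   baseline `r` and `r_next`, and the underlying `limiting_report`.
#' @export
breakpoint <- function(diet, exome, eaa = eaa_config(), aa) {
  rep <- limiting_report(diet, exome, eaa)
  if (!aa %in% rep$limiting_set)
    stop("breakpoint defined only for the limiting AA (limiting: ",
         paste(rep$limiting_set, collapse = ", "), ")")
  if (rep$d[[aa]] == 0)
    stop("limiting amino acid ", aa,
         " has zero dietary supply; fold supplementation is undefined")
  others <- setdiff(names(rep$effective), aa)
  if (!length(others)) {
    return(structure(list(aa = aa, x_star = Inf,
                          next_limiting = NA_character_, r = rep$r,
                          r_next = Inf, report = rep),
                     class = "aa_breakpoint"))
  }
  r_next <- min(rep$effective[others])
  nxt <- .tie_set(rep$effective[others], r_next)[1]
  d <- rep$d; p <- rep$p
  # invert the increasing piecewise-linear constraint at level r_next
  x1 <- r_next * p[[aa]] / d[[aa]]
  x_star <- x1
  pairs <- Filter(function(pr) pr[1] == aa && pr[2] %in% names(d),
                  eaa$conditional_pairs)
  if (length(pairs)) {
    D <- pairs[[1]][2]
    surplus_at_x1 <- d[[D]] * p[[aa]] >= x1 * d[[aa]] * p[[D]]
    if (!surplus_at_x1)
      x_star <- (r_next * (p[[aa]] + p[[D]]) - d[[D]]) / d[[aa]]
  }
  structure(list(aa = aa, x_star = unname(x_star), next_limiting = nxt,
                 r = rep$r, r_next = unname(r_next), report = rep),
            class = "aa_breakpoint")
}

#' @export
print.aa_breakpoint <- function(x, digits = 4, ...) {
  cat("Supplementation breakpoint for ", x$aa, ": x* = ",
      format(x$x_star, digits = digits), "\n", sep = "")
  cat("Next limiting amino acid: ", x$next_limiting, " (r_next = ",
      format(x$r_next, digits = digits), ", baseline r = ",
      format(x$r, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' Predicted response curve under supplementation
#'
#' Predicted output, relative to the unsupplemented diet, across a grid of
#' fold-additions of the limiting amino acid: output rises with the
#' supplemented constraint until the next constraint `r_next` binds at the
#' breakpoint, then plateaus; an optional empirical ceiling (e.g. the
#' maximum egg laying attained on rich food) caps the curve at
#' `ceiling / r(diet)` on the relative scale.
#'
#' @inheritParams breakpoint
#' @param fold_grid Non-negative fold-addition values `x` (x = 1 is the
#'   unsupplemented diet).
#' @param ceiling Optional empirical maximum output, on the same scale as
#'   `r`.
#' @return A `response_curve`: list with `supplemented_aa`, `fold_grid`,
#'   `predicted_relative_output`, `breakpoint_fold`, `next_limiting_aa`,
#'   `ceiling` and the baseline `r`.
#' @export
response_curve <- function(diet, exome, eaa = eaa_config(), aa,
                           fold_grid, ceiling = NULL) {
  if (any(fold_grid < 0)) stop("fold_grid must be non-negative")
  bp <- breakpoint(diet, exome, eaa, aa)
  rep <- bp$report
  g <- .supplement_constraint(fold_grid, aa, rep$d, rep$p, eaa)
  rel <- pmin(g, bp$r_next) / rep$r
  if (!is.null(ceiling)) rel <- pmin(rel, ceiling / rep$r)
  structure(list(supplemented_aa = aa, fold_grid = fold_grid,
                 predicted_relative_output = unname(rel),
                 breakpoint_fold = bp$x_star,
                 next_limiting_aa = bp$next_limiting,
                 ceiling = ceiling, r = rep$r),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, digits = 4, ...) {
  cat("Predicted response to ", x$supplemented_aa, " supplementation\n",
      sep = "")
  cat("Breakpoint at ", format(x$breakpoint_fold, digits = digits),
      "x (next limiting: ", x$next_limiting_aa, ")\n", sep = "")
  print(data.frame(fold = x$fold_grid,
                   relative_output = round(x$predicted_relative_output,
                                           digits)))
  invisible(x)
}

#' @export
plot.response_curve <- function(x, ...) {
  graphics::plot(x$fold_grid, x$predicted_relative_output, type = "b",
                 xlab = paste0("fold addition of ", x$supplemented_aa),
                 ylab = "predicted relative output", ...)
  graphics::abline(v = x$breakpoint_fold, lty = 2, col = "grey40")
  invisible(x)
}
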