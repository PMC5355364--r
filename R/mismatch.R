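# --- constrained design machinery -------------------------------------------
#
# The constrained problem, after centring on the reference A and scaling by
# the required distance R = ||B - A||, is
#
#   maximise  c'u   over  { u : ||u|| = 1, sum(u) = 0, u >= lower }
#
# with c = (A - B)/R and lower = -A/R; the design is C = A + R u, so the
# sphere constraint is the equidistance requirement and the box constraint
# is non-negativity of C. The feasible set (a sphere cut by a polytope) is
# non-convex, so several deterministic strategies are combined and the best
# feasible candidate kept.

# Projection onto the polytope { sum(x) = 0, x >= lower } (water-filling on
# the shifted simplex, Duchi-style).
.proj_zerosum_box <- function(u, lower) {
  z <- u - lower
  tau <- -sum(lower)
  zs <- sort(z, decreasing = TRUE)
  css <- cumsum(zs)
  j <- which(zs - (css - tau) / seq_along(zs) > 0)
  rho <- if (length(j)) max(j) else 1L
  theta <- (css[rho] - tau) / rho
  pmax(z - theta, 0) + lower
}

# Alternate projections between the polytope and the unit sphere until a
# point satisfies both to high precision; NULL if it fails to converge.
.repair_feasible <- function(u, lower, iters = 400L) {
  for (it in seq_len(iters)) {
    u <- .proj_zerosum_box(u, lower)
    n <- sqrt(sum(u^2))
    if (n < 1e-12) return(NULL)
    u <- u / n
    if (all(u >= lower - 1e-12) && abs(sum(u)) < 1e-10) return(u)
  }
  NULL
}

# Exact maximiser of c'u on the face with active set S (u_S pinned at its
# bound), subject to the sum and norm equalities only: on the free
# coordinates u_F = s/m + sign * t * what, the classical sphere-slice
# solution; sign = -1 gives the antipodal branch. NULL if the face misses
# the sphere. `check` additionally rejects bound-violating solutions.
.face_solution <- function(cvec, lower, S, sign = 1, check = TRUE) {
  k <- length(cvec)
  F <- setdiff(seq_len(k), S)
  m <- length(F)
  if (!m) return(NULL)
  u <- numeric(k)
  u[S] <- lower[S]
  s <- -sum(u[S])
  rho2 <- 1 - sum(u[S]^2)
  t2 <- rho2 - s^2 / m
  if (t2 < -1e-12) return(NULL)
  w <- cvec[F] - mean(cvec[F])
  nw <- sqrt(sum(w^2))
  if (nw > 1e-12) {
    dir <- w / nw
  } else if (m >= 2L) {
    dir <- numeric(m); dir[1] <- 1 / sqrt(2); dir[2] <- -1 / sqrt(2)
  } else dir <- 0
  u[F] <- s / m + sign * sqrt(max(t2, 0)) * dir
  if (abs(sum(u^2) - 1) > 1e-8) return(NULL)
  if (check && any(u < lower - 1e-10)) return(NULL)
  u
}

# Greedy pinning path: repeatedly solve the current face, pin the most
# violated coordinate, and collect every feasible face solution (both
# sphere branches) met along the way.
.greedy_faces <- function(cvec, lower, S = integer(0)) {
  k <- length(cvec)
  out <- list()
  S <- unique(as.integer(S))
  for (iter in seq_len(k)) {
    for (sg in c(1, -1)) {
      sol <- .face_solution(cvec, lower, S, sg)
      if (!is.null(sol)) out[[length(out) + 1L]] <- sol
    }
    raw <- .face_solution(cvec, lower, S, 1, check = FALSE)
    if (is.null(raw)) break
    viol <- which(raw < lower - 1e-10)
    viol <- setdiff(viol, S)
    if (!length(viol)) break
    S <- c(S, viol[which.min((raw - lower)[viol])])
  }
  out
}

# Projected-gradient ascent along the feasible set with step-size backoff.
.pga <- function(u, cvec, lower) {
  best <- u
  for (eta in c(0.5, 0.2, 0.08, 0.02, 0.005)) {
    for (it in 1:80) {
      cand <- .repair_feasible(best + eta * cvec, lower, iters = 120L)
      if (is.null(cand) || sum(cvec * cand) <= sum(cvec * best) + 1e-14)
        break
      best <- cand
    }
  }
  best
}

# Deterministic start directions for the penalised multistart.
.mismatch_starts <- function(cvec, refl, n_starts = 16L) {
  k <- length(cvec)
  ord <- order(refl)          # most negative reflection coordinates first
  starts <- c(list(cvec), lapply(ord, function(i) {
    e <- numeric(k); e[i] <- 1; cvec + e
  }), lapply(ord, function(i) {
    e <- numeric(k); e[i] <- -1; cvec + e
  }))
  starts[seq_len(min(n_starts, length(starts)))]
}

# Full constrained solve; returns the best feasible u.
.solve_constrained <- function(cvec, lower, n_starts = 16L) {
  k <- length(cvec)
  cands <- list()
  add <- function(u) if (!is.null(u)) cands[[length(cands) + 1L]] <<- u

  # the point u = -c (i.e. C = B) is always feasible and anchors the search
  add(-cvec)

  if (k <= 6L) {
    # exhaustive face enumeration: every active set, both sphere branches
    for (size in 0:(k - 2L)) {
      for (S in if (size) utils::combn(k, size, simplify = FALSE) else
           list(integer(0))) {
        add(.face_solution(cvec, lower, S, 1))
        add(.face_solution(cvec, lower, S, -1))
      }
    }
  } else {
    cands <- c(cands, .greedy_faces(cvec, lower))
    obj <- function(v, mu) {
      pv <- v - mean(v)
      n <- sqrt(sum(pv^2))
      if (n < 1e-12) return(1e6)
      u <- pv / n
      -sum(cvec * u) + mu * sum(pmax(lower - u, 0)^2)
    }
    # order starts by how badly the reflection direction violates each bound
    for (v0 in .mismatch_starts(cvec, cvec - lower, n_starts)) {
      v <- v0
      for (mu in c(1e2, 1e4, 1e6))
        v <- stats::optim(v, obj, mu = mu, method = "BFGS",
                          control = list(maxit = 200))$par
      pv <- v - mean(v)
      u_raw <- pv / sqrt(sum(pv^2))
      cands <- c(cands, .greedy_faces(cvec, lower,
                                      S = which(u_raw < lower + 1e-5)))
      add(.repair_feasible(u_raw, lower))
    }
  }

  feas <- Filter(function(u) all(u >= lower - 1e-9) &&
                   abs(sum(u)) < 1e-8 && abs(sum(u^2) - 1) < 1e-7, cands)
  # climb from the most promising feasible candidates
  vals <- vapply(feas, function(u) sum(cvec * u), 0)
  top <- feas[order(vals, decreasing = TRUE)][seq_len(min(3L, length(feas)))]
  for (u0 in top) add(.pga(u0, cvec, lower))

  feas <- Filter(function(u) all(u >= lower - 1e-9) &&
                   abs(sum(u)) < 1e-8 && abs(sum(u^2) - 1) < 1e-7, cands)
  if (!length(feas)) stop("mismatch design optimisation failed: ",
                          "no feasible solution found")
  u <- feas[[which.max(vapply(feas, function(u) sum(cvec * u), 0))]]
  # polish: exact solve on the face the winner sits on, if that helps
  pol <- .face_solution(cvec, lower, which(u < lower + 1e-7), 1)
  if (!is.null(pol) && sum(cvec * pol) >= sum(cvec * u)) u <- pol
  u / sqrt(sum(u^2))
}

#' Design a maximally mismatched, equidistant amino-acid ratio
#'
#' Given a reference profile A (e.g. an exome-matched ratio) and an
#' existing mismatched profile B, constructs a third profile C that is
#' exactly as far from A (Euclidean distance, one dimension per amino
#' acid) as B is, but as far as possible from B — the construction used to
#' derive a second mismatched control ratio that imposes a comparable
#' limitation through different amino acids.
#'
#' The reflection `C = 2A - B` automatically preserves the sum-to-one
#' constraint and globally maximises the distance to B; it is returned
#' exactly whenever it is non-negative (`feasible_reflection = TRUE`, and
#' then `dist_CB = 2 * dist_BA`). Otherwise the constrained problem
#' (maximise `||C - B||` subject to `||C - A|| = ||B - A||`, `C >= 0`,
#' `sum(C) = 1`) is solved by a deterministic multistart search on the
#' sphere-simplex intersection (exhaustive active-set enumeration for
#' alphabets of up to six letters), and the equidistance constraint is
#' verified within `tol`.
#'
#' @param reference Profile A: `aa_profile` or named simplex vector (toy
#'   alphabets allowed).
#' @param source Profile B on the same alphabet.
#' @param tol Tolerance for the equidistance check (default `1e-8`).
#' @param n_starts Number of deterministic starts (default 16).
#' @return A `mismatch_design`: list with `reference`, `source`, `result`
#'   (all proportion vectors), `dist_CA`, `dist_BA`, `dist_CB`,
#'   `feasible_reflection` and `degenerate`.
#' @export
#' @examples
#' A <- c(a = 1, b = 1, c = 1) / 3
#' B <- c(a = 1 / 2, b = 1 / 4, c = 1 / 4)
#' design_mismatch(A, B)
design_mismatch <- function(reference, source, tol = 1e-8, n_starts = 16L) {
  A <- .as_proportions(reference, "reference")
  B <- .as_proportions(source, "source")
  if (!identical(names(A), names(B))) {
    if (!setequal(names(A), names(B)))
      stop("reference and source are over different alphabets")
    B <- B[names(A)]
  }
  R <- sqrt(sum((A - B)^2))
  if (R < 1e-15) {
    return(structure(list(reference = A, source = B, result = A,
                          dist_CA = 0, dist_BA = 0, dist_CB = 0,
                          feasible_reflection = TRUE, degenerate = TRUE),
                     class = "mismatch_design"))
  }
  refl <- 2 * A - B
  if (all(refl >= 0)) {
    C <- refl
  } else {
    u <- .solve_constrained((A - B) / R, -A / R, n_starts = n_starts)
    C <- A + R * u
    C[C < 0 & C > -1e-9] <- 0
  }
  dist_CA <- sqrt(sum((C - A)^2))
  if (abs(dist_CA - R) > tol)
    stop("equidistance constraint violated: |dist_CA - dist_BA| = ",
         format(abs(dist_CA - R)), " > tol = ", format(tol))
  if (any(C < 0)) stop("optimiser returned a negative proportion")
  structure(list(reference = A, source = B,
                 result = stats::setNames(C, names(A)),
                 dist_CA = dist_CA, dist_BA = R,
                 dist_CB = sqrt(sum((C - B)^2)),
                 feasible_reflection = all(refl >= 0), degenerate = FALSE),
            class = "mismatch_design")
}

#' @export
print.mismatch_design <- function(x, digits = 4, ...) {
  cat("Mismatch design", if (x$degenerate) " (degenerate: source = reference)",
      "\n", sep = "")
  cat("dist(C, A) = ", format(x$dist_CA, digits = digits),
      "  dist(B, A) = ", format(x$dist_BA, digits = digits),
      "  dist(C, B) = ", format(x$dist_CB, digits = digits), "\n", sep = "")
  cat("Reflection feasible: ", x$feasible_reflection, "\n", sep = "")
  print(round(x$result, digits))
  invisible(x)
}

#' Compare a mismatch design against an exome profile
#'
#' Verifies that the designed control ratio imposes a limitation
#' comparable to the source ratio: limiting reports for both against the
#' exome, plus all pairwise distances.
#'
#' @param design A `mismatch_design` over the full amino-acid alphabet.
#' @param exome Exome profile (as in [limiting_report()]).
#' @param eaa An [eaa_config()].
#' @return List with `source_report`, `result_report`, and a `distances`
#'   data frame (source-reference, result-reference, result-source).
#' @export
mismatch_report <- function(design, exome, eaa = eaa_config()) {
  stopifnot(inherits(design, "mismatch_design"))
  src <- limiting_report(design$source, exome, eaa)
  res <- limiting_report(design$result, exome, eaa)
  list(source_report = src, result_report = res,
       distances = data.frame(
         pair = c("source-reference", "result-reference", "result-source"),
         distance = c(design$dist_BA, design$dist_CA, design$dist_CB),
         stringsAsFactors = FALSE))
}
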