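# Plain-list serialisations for JSON reports.
.report_as_list <- function(rep) {
  list(diet = rep$diet,
       scores = as.list(rep$scores),
       pair_scores = as.list(rep$pair_scores),
       effective = as.list(rep$effective),
       r = rep$r, limiting_aa = unname(rep$limiting_aa),
       limiting_set = unname(rep$limiting_set),
       runner_up_aa = rep$runner_up_aa,
       runner_up_score = rep$runner_up_score)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Drives the whole toolchain from one JSON config: build (or read) an
#' exome profile, score each diet's limiting amino acid, compute
#' breakpoints, fold changes against a reference diet, an optional
#' mismatch design and an optional gene-set enrichment, writing TSV/JSON
#' reports plus a deterministic provenance log. Re-running an unchanged
#' config produces byte-identical outputs.
#'
#' Config keys: `proteome` (either `fasta` path or a `synthetic` spec with
#' the arguments of [make_synthetic_proteome()]), optional `min_len`,
#' `max_len`, `averaging_mode`, `diets` (array of recipe TSV paths),
#' `analyses` with optional members `limiting`, `breakpoint`,
#' `fold_change` (`{"reference": <diet name>}`), `mismatch`
#' (`{"source": <diet name>}`, reference = exome), `enrichment`
#' (`{"set_file", "method", "n_permutations", "seed"}`), and `out_dir`.
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return Named list of generated file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) jsonlite::read_json(config) else config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("missing config key: out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  note("exomatch pipeline, package version ",
       as.character(utils::packageVersion("exomatch")))
  files <- list()

  if (is.null(cfg$proteome)) stop("missing config key: proteome")
  if (!is.null(cfg$proteome$fasta)) {
    fasta <- cfg$proteome$fasta
    if (!file.exists(fasta)) stop("missing input for config key proteome.fasta: ", fasta)
    prot <- read_proteome(fasta)
    note("proteome: ", fasta, " md5=", unname(tools::md5sum(fasta)))
  } else if (!is.null(cfg$proteome$synthetic)) {
    sp <- cfg$proteome$synthetic
    if (is.null(sp$seed)) stop("missing config key: proteome.synthetic.seed")
    syn <- make_synthetic_proteome(
      n_total = sp$n_total %||% 500L, n_short = sp$n_short %||% 0L,
      n_long = sp$n_long %||% 0L,
      dirichlet_concentration = sp$dirichlet_concentration %||% 50,
      seed = sp$seed, path = file.path(out_dir, "synthetic_proteome.fasta"))
    prot <- syn$proteome
    files$synthetic_fasta <- syn$path
    note("proteome: synthetic, n_total=", syn$manifest$n_total,
         " seed=", syn$manifest$seed,
         " md5=", unname(tools::md5sum(syn$path)))
  } else stop("config key proteome needs either 'fasta' or 'synthetic'")

  exo <- exome_profile(prot, min_len = cfg$min_len %||% 100L,
                       max_len = cfg$max_len %||% 2000L,
                       averaging_mode = cfg$averaging_mode %||%
                         "mean_of_proportions")
  files$exome_profile <- file.path(out_dir, "exome_profile.tsv")
  write_profile_tsv(exo, files$exome_profile)
  note("exome profile: ", exo$n_retained, " of ", exo$n_total,
       " proteins retained, mode=", exo$averaging_mode)

  eaa <- eaa_config()
  diets <- list()
  for (dpath in cfg$diets %||% list()) {
    if (!file.exists(dpath)) stop("missing input for config key diets: ", dpath)
    rec <- read_diet_tsv(dpath)
    diets[[rec$name]] <- recipe_to_profile(rec)
    note("diet: ", rec$name, " from ", dpath,
         " md5=", unname(tools::md5sum(dpath)))
  }

  an <- cfg$analyses %||% list()
  reports <- list()
  if (isTRUE(an$limiting %||% TRUE) && length(diets)) {
    for (nm in names(diets)) reports[[nm]] <- limiting_report(diets[[nm]], exo, eaa)
    files$limiting <- file.path(out_dir, "limiting_reports.json")
    .write_json(lapply(reports, .report_as_list), files$limiting)
    for (nm in names(reports))
      note("limiting[", nm, "]: r=", format(reports[[nm]]$r, digits = 10),
           " aa=", reports[[nm]]$limiting_aa)
  }
  if (isTRUE(an$breakpoint) && length(reports)) {
    bps <- lapply(names(reports), function(nm) {
      bp <- breakpoint(diets[[nm]], exo, eaa, aa = reports[[nm]]$limiting_aa)
      list(diet = nm, aa = bp$aa, x_star = bp$x_star,
           next_limiting = bp$next_limiting, r = bp$r, r_next = bp$r_next)
    })
    files$breakpoint <- file.path(out_dir, "breakpoints.json")
    .write_json(bps, files$breakpoint)
  }
  if (!is.null(an$fold_change) && length(diets) > 1L) {
    refname <- an$fold_change$reference %||% names(diets)[1]
    if (!refname %in% names(diets))
      stop("missing input for config key analyses.fold_change.reference: ",
           refname)
    fc <- lapply(setdiff(names(diets), refname), function(nm)
      list(reference = refname, diet = nm,
           fold_change = fold_change(diets[[refname]], diets[[nm]], exo, eaa)))
    files$fold_change <- file.path(out_dir, "fold_changes.json")
    .write_json(fc, files$fold_change)
  }
  if (!is.null(an$mismatch)) {
    srcname <- an$mismatch$source
    if (is.null(srcname) || !srcname %in% names(diets))
      stop("missing input for config key analyses.mismatch.source")
    des <- design_mismatch(exo$profile, diets[[srcname]])
    mrep <- mismatch_report(des, exo, eaa)
    files$mismatch <- file.path(out_dir, "mismatch_design.tsv")
    write_profile_tsv(aa_profile(des$result), files$mismatch,
                      provenance = list(
                        source = srcname, dist_BA = des$dist_BA,
                        dist_CA = des$dist_CA, dist_CB = des$dist_CB,
                        feasible_reflection = des$feasible_reflection,
                        source_limiting = unname(mrep$source_report$limiting_aa),
                        result_limiting = unname(mrep$result_report$limiting_aa)))
    note("mismatch design from ", srcname, ": dist_CA=",
         format(des$dist_CA, digits = 10))
  }
  if (!is.null(an$enrichment)) {
    en <- an$enrichment
    if (is.null(en$set_file) || !file.exists(en$set_file))
      stop("missing input for config key analyses.enrichment.set_file")
    tab <- rank_by_similarity(prot, exo)
    res <- set_mean_rank_test(tab, read_gene_set(en$set_file),
                              method = en$method %||% "normal_approx",
                              n_permutations = en$n_permutations %||% 100000L,
                              seed = en$seed,
                              set_name = basename(en$set_file))
    files$enrichment <- file.path(out_dir, "enrichment.json")
    .write_json(unclass(res), files$enrichment)
    note("enrichment: mean_rank=", format(res$mean_rank, digits = 10),
         " p=", format(res$p_value, digits = 10))
  }

  files$log <- file.path(out_dir, "pipeline_log.txt")
  writeLines(log, files$log)
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
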