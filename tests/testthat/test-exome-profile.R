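test_that("FASTA parsing follows the header and stop-symbol conventions", {
  path <- write_fasta(c(g1 = "MKV", g2 = "ACDE"))
  prot <- read_proteome(path)
  expect_s3_class(prot, "proteome")
  expect_identical(prot$gene_id, c("g1", "g2"))
  expect_identical(prot$length, c(3L, 4L))

  # trailing stop stripped, sequences upper-cased, description dropped
  path <- write_fasta(c("g1 some description" = "mkv*"))
  prot <- read_proteome(path)
  expect_identical(prot$gene_id, "g1")
  expect_identical(prot$sequence, "MKV")
  expect_identical(prot$length, 3L)

  # duplicate identifiers are an error naming the offender
  path <- write_fasta(c(g1 = "MKV", g1 = "ACDE"))
  expect_error(read_proteome(path), "g1")

  # empty file is an error
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_proteome(empty), "empty")

  # a record with no canonical residues is excluded with a warning
  path <- write_fasta(c(g1 = "MKV", gx = "XXX"))
  expect_warning(prot <- read_proteome(path), "no canonical")
  expect_identical(prot$gene_id, "g1")
})

test_that("parsed records match the generator's bookkeeping (seed 7)", {
  sp <- make_synthetic_proteome(50, n_short = 5, n_long = 3, seed = 7)
  prot <- read_proteome(sp$path)
  expect_length(prot$gene_id, 50L)
  expect_identical(prot$length, sp$manifest$lengths)
  expect_identical(prot$sequence, sp$proteome$sequence)
})

test_that("length filter keeps boundary lengths and keeps its books", {
  prot <- as_proteome(c(a = strrep("K", 99), b = strrep("K", 100),
                        c = strrep("K", 2000), d = strrep("K", 2001)))
  flt <- length_filter(prot)
  expect_identical(sort(flt$retained$length), c(100L, 2000L))
  expect_identical(flt$stats[c("n_total", "n_short", "n_long", "n_retained")],
                   list(n_total = 4L, n_short = 1L, n_long = 1L,
                        n_retained = 2L))

  # brute-force oracle on random lengths, plus the count identity
  set.seed(11)
  lens <- sample(1:3000, 40)
  prot <- as_proteome(stats::setNames(strrep("M", lens), paste0("g", 1:40)))
  flt <- length_filter(prot, 100, 2000)
  expect_identical(flt$stats$n_retained, sum(lens >= 100 & lens <= 2000))
  expect_identical(flt$stats$n_short, sum(lens < 100))
  with(flt$stats, expect_identical(n_total, n_short + n_long + n_retained))

  # idempotence
  again <- length_filter(flt$retained, 100, 2000)
  expect_identical(again$retained$gene_id, flt$retained$gene_id)
  expect_identical(again$stats$n_short, 0L)

  expect_error(length_filter(as_proteome(c(a = "MKV")), 100, 2000),
               "all proteins filtered")
  expect_error(length_filter(prot, 200, 100), "min_len")
})

test_that("per-protein proportions count canonical residues only", {
  p <- protein_profile(strrep("M", 100))
  expect_equal(p[["M"]], 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  p <- protein_profile("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(as.numeric(p), rep(0.05, 20))

  # non-canonical symbols excluded from numerator and denominator
  p <- protein_profile("MXM")
  expect_equal(p[["M"]], 1)
  expect_error(protein_profile("XXX"), "no canonical")
})

test_that("exome averaging modes combine proteins as documented", {
  prot <- as_proteome(c(a = "MM", b = "KK"))
  exo <- exome_average(prot)
  expect_equal(exo$profile[["M"]], 0.5)
  expect_equal(exo$profile[["K"]], 0.5)

  # unequal lengths distinguish the two modes
  prot <- as_proteome(c(a = "M", b = "KKK"))
  by_mean <- exome_average(prot, "mean_of_proportions")
  by_pool <- exome_average(prot, "pooled_counts")
  expect_equal(by_mean$profile[["M"]], 0.5)
  expect_equal(by_pool$profile[["M"]], 0.25)
  expect_equal(by_pool$profile[["K"]], 0.75)

  # permutation invariance
  rev_prot <- as_proteome(c(b = "KKK", a = "M"))
  expect_equal(unclass(exome_average(rev_prot)$profile),
               unclass(by_mean$profile))

  # equal lengths make the two modes coincide (property)
  set.seed(3)
  for (rep in 1:5) {
    seqs <- vapply(1:8, function(i)
      paste(sample(aa_codes(), 50, replace = TRUE), collapse = ""), "")
    prot <- as_proteome(stats::setNames(seqs, paste0("g", 1:8)))
    expect_equal(unclass(exome_average(prot, "mean_of_proportions")$profile),
                 unclass(exome_average(prot, "pooled_counts")$profile),
                 tolerance = 1e-12)
  }
})

test_that("averaging a low-dispersion synthetic proteome recovers the generator composition", {
  target <- typical_proteome_composition()
  sp <- make_synthetic_proteome(200, seed = 5, path = NA,
                                dirichlet_concentration = 1e6,
                                global_composition = target)
  exo <- exome_average(sp$proteome, "pooled_counts")
  expect_lt(max(abs(unclass(exo$profile) - unclass(target))), 0.005)
  expect_equal(sum(exo$profile), 1, tolerance = 1e-9)
})

test_that("the one-stop exome_profile wrapper carries filter provenance", {
  sp <- make_synthetic_proteome(40, n_short = 6, n_long = 4, seed = 2)
  exo <- exome_profile(sp$path)
  expect_identical(exo$n_total, 40L)
  expect_identical(exo$n_short, 6L)
  expect_identical(exo$n_long, 4L)
  expect_identical(exo$n_retained, 30L)
  expect_identical(exo$averaging_mode, "mean_of_proportions")
  expect_equal(sum(exo$profile), 1, tolerance = 1e-9)
})
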