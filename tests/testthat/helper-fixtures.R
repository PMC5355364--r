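# Shared fixtures, built in code.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# A uniform 20-AA profile (every amino acid 0.05).
uniform_profile <- function() {
  aa_profile(stats::setNames(rep(1, 20), aa_codes()))
}

# Random full-alphabet profile from independent gammas (Dirichlet(shape)).
random_profile20 <- function(shape = 2) {
  aa_profile(stats::setNames(stats::rgamma(20, shape) + 1e-6, aa_codes()))
}

# Diet amounts: uniform except for named overrides; returns a named vector
# (amount scale) so tests can control renormalisation explicitly.
uniform_amounts <- function(...) {
  a <- stats::setNames(rep(1, 20), aa_codes())
  ov <- c(...)
  a[names(ov)] <- ov
  a
}
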