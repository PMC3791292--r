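# Shared fixtures: the emulated fifteen-shell protocol and published
# white-matter generating parameters used across tests.

mbi_shells <- function() group_shells(mbi_btable())

# patient corpus-callosum two-compartment parameters (group means)
patient_cc <- list(s0 = 1, mu = 0.55, du = 1.8e-3, dr = 7.1e-5)

# noiseless shell-mean decay for a parameter set
make_decay <- function(params = patient_cc, shells = mbi_shells()) {
  synthesize_shell_signals(shells, s0 = params$s0, mu = params$mu,
                           du = params$du, dr = params$dr,
                           mode = "shell-mean")
}

# write a (bval, bvec) pair to tempfiles, returning the two paths
write_gradient_files <- function(bvals, bvecs_rows) {
  bval <- tempfile(fileext = ".bval")
  bvec <- tempfile(fileext = ".bvec")
  writeLines(paste(bvals, collapse = " "), bval)
  writeLines(vapply(bvecs_rows, paste, "", collapse = " "), bvec)
  c(bval = bval, bvec = bvec)
}

# tiny cohort configuration used where full study size is unnecessary
small_config <- function(seed = 1, n = 4, ...) {
  cohort_config(n_per_group = c(patient = n, control = n), seed = seed, ...)
}
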