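# Small fixture builders shared across the suite. All fixtures are built in
# code under fixed seeds; nothing is read from disk.

# tiny noiseless single-axis experiment, used for exactness checks
noiselessExperiment <- function(axis = "z", nRuns = 4L, nVoxels = 20L,
                                seed = 7L) {
  simulateExperiment(nSubjects = 1L, nRuns = nRuns, nVoxels = nVoxels,
    noise = list(type = "absolute", sd = 0), seed = seed, axes = axis)
}

# small noisy both-axis experiment for decoding/fitting behaviour
noisyExperiment <- function(nSubjects = 1L, nRuns = 6L, nVoxels = 40L,
                            rel = 0.5, seed = 11L, ...) {
  simulateExperiment(nSubjects = nSubjects, nRuns = nRuns,
    nVoxels = nVoxels, noise = list(type = "relative", sd = rel),
    seed = seed, ...)
}

# hand-rolled Moore-Penrose pseudoinverse via SVD (independent of the
# package's solve-based paths); oracle for the IEM algebra
pinvSvd <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
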