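# Shared fixtures, built once per test session and memoised.

.fixtureEnv <- new.env(parent = emptyenv())

fixtureMemo <- function(key, builder) {
  if (is.null(.fixtureEnv[[key]])) .fixtureEnv[[key]] <- builder()
  .fixtureEnv[[key]]
}

# A smooth structured volume (sum of off-centre Gaussian blobs) used by the
# registration and resampling tests; built analytically, independent of the
# package's own smoothing code.
smoothPhantom <- function(dims = c(24, 24, 24), seed = 11) {
  key <- paste0("phantom_", paste(dims, collapse = "x"), "_", seed)
  fixtureMemo(key, function() {
    set.seed(seed)
    co <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                seq_len(dims[3])))
    x <- numeric(nrow(co))
    blobs <- list(list(c = dims / 2 + c(3, -2, 1), s = 9, a = 3),
                  list(c = dims / 2 + c(-5, 4, -3), s = 16, a = 2),
                  list(c = dims / 2 + c(0, -6, 5), s = 25, a = 1.5),
                  list(c = dims / 2, s = 60, a = 1))
    for (b in blobs)
      x <- x + b$a * exp(-rowSums(sweep(co, 2, b$c)^2) / (2 * b$s))
    x <- x + rnorm(length(x), 0, 0.02)
    imageVolume(array(x, dims), spacing = c(1, 1, 1), contrast = "T1c")
  })
}

# A small cohort with a strong planted texture effect, shared across tests.
fixtureTextureCohort <- function() {
  fixtureMemo("texture_cohort", function() {
    spec <- phantomSpec(gridShape = c(20L, 20L, 20L), nPatients = 8,
                        lesionsPerPatient = c(1L, 2L),
                        lesionRadius = c(2.5, 4.5), flipRate = 0,
                        seed = 421L)
    makePhantomCohort(spec)
  })
}

fixtureTextureFeatures <- function() {
  fixtureMemo("texture_features", function()
    extractCohortFeatures(fixtureTextureCohort()))
}
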