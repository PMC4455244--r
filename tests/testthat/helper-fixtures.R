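# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# clean 64^3 base phantom (no noise, no bias)
cleanBase <- function() {
  fixture("cleanBase", function()
    makeBasePhantom(phantomSpec(noiseSd = 0, biasAmplitude = 0)))
}

# base phantom plus additive Gaussian noise of the given SD (deterministic)
noisyVolume <- function(base, sd, seed = 99L) {
  v <- base$volume
  set.seed(seed)
  v@data <- v@data + array(stats::rnorm(length(v@data), 0, sd), dim(v@data))
  v
}

# per-class smooth priors derived from a label volume
smoothPriors <- function(labels, sigma_mm = 2) {
  m <- masksFromLabels(labels)
  lapply(m, smoothVolume, sigma_mm = sigma_mm)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

rotationAngleDeg <- function(R) {
  acos(pmin(pmax((sum(diag(R[1:3, 1:3])) - 1) / 2, -1), 1)) * 180 / pi
}

# small population used by template / tpm tests: 6 subjects at 48^3
smallPopulation <- function() {
  fixture("smallPopulation", function()
    makePopulation(phantomSpec(gridShape = 48L, seed = 7L), 6L))
}

# the template-pipeline fixture used by the acceptance suite: 8 subjects at
# 48^3, preprocessed and landmark-aligned, run through all three stages with
# 4 linear iterations per stage (problem size chosen for the validation
# study; see the methods vignette)
acceptancePipeline <- function() {
  fixture("acceptancePipeline", function() {
    cfg <- pipelineConfig(n_subjects = 8L, grid_shape = 48L,
                          n_iter_rigid = 4L, n_iter_affine = 4L, seed = 11L)
    suppressWarnings(runAll(cfg))
  })
}
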