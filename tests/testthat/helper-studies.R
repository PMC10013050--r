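# Desk-scale simulation studies shared by several acceptance checks: 10
# realizations per network type, N = 1024, ~500 source voxels, fixed master
# seed. Memoized so every test block reuses the same computed study.
.studyCache <- new.env(parent = emptyenv())

deskStudy <- function(system) {
  if (is.null(.studyCache[[system]])) {
    .studyCache[[system]] <- runSimulationStudy(
      system, nRealizations = 10, N = 1024, K = 20,
      spaces = c("initial", "sensor", "source"), nVoxels = 500,
      masterSeed = 42)
  }
  .studyCache[[system]]
}

spaceAuroc <- function(study, space, metric) {
  study$auroc[[metric]][study$auroc$space == space]
}
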