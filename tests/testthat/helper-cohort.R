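# The default synthetic cohort (n = 57, seed 1), extracted once and shared
# by the end-to-end tests; building it runs the full audio + transcript
# chain and takes a couple of minutes.
.cohort_cache <- new.env(parent = emptyenv())

defaultCohortFeatures <- function() {
    if (is.null(.cohort_cache$fs))
        .cohort_cache$fs <- buildCohortFeatureSet(cohortSpec(seed = 1))
    .cohort_cache$fs
}
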