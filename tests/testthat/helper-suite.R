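# The 30-plant synthetic study suite and its analyzed records are expensive
# (~2 min end to end), so they are built once per test run and shared.

.suite_env <- new.env(parent = emptyenv())

SUITE_SEED <- 42L
SUITE_N <- 30L

study_suite <- function() {
  if (is.null(.suite_env$suite))
    .suite_env$suite <- default_suite(SUITE_N, seed = SUITE_SEED)
  .suite_env$suite
}

study_records <- function() {
  if (is.null(.suite_env$records)) {
    cfg <- pipeline_config()
    .suite_env$records <- lapply(study_suite(), function(r)
      analyze_image(r$image, cfg, plant_id = r$plant_id))
  }
  .suite_env$records
}

suite_is_overlap <- function() {
  attr(study_suite(), "manifest")$overlap
}
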