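## Shared fixtures, built in code. The full synthetic study (inputs +
## pipeline run) is expensive, so it is computed once per test session and
## cached.

.fixture_cache <- new.env(parent = emptyenv())

## Default synthetic study at seed 1, with its pipeline run.
get_study_fixture <- function() {
  if (!is.null(.fixture_cache$study)) return(.fixture_cache$study)
  in_dir <- file.path(tempdir(), "hervtriage-sim")
  out_dir <- file.path(tempdir(), "hervtriage-out")
  cfg <- sim_config(seed = 1)
  sim <- simulate_inputs(cfg, in_dir)
  pc <- pipeline_config(in_dir, out_dir, seed = 1)
  res <- suppressWarnings(run_pipeline(pc))
  truth <- utils::read.table(file.path(in_dir, "truth_variants.tsv"),
                             sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  .fixture_cache$study <- list(cfg = cfg, sim = sim, res = res, truth = truth,
                               in_dir = in_dir, out_dir = out_dir)
  .fixture_cache$study
}

## Small deterministic genotype matrix built from explicit records.
make_geno <- function(records, gt, sample_ids, cohort = "case",
                      sample_type = "blood") {
  split_multiallelic(records, gt,
                     samples = data.frame(sample_id = sample_ids,
                                          cohort = cohort,
                                          sample_type = sample_type,
                                          stringsAsFactors = FALSE))
}

## Reference table transcribing the bundled common-variant frequency fixture.
read_common_fixture <- function() {
  path <- system.file("extdata", "common_variants_maf.tsv",
                      package = "hervtriage")
  if (path == "") path <- file.path("..", "..", "inst", "extdata",
                                    "common_variants_maf.tsv")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
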