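# Dataset and definitions shared across engine tests.
engine_dir <- withr::local_tempdir(.local_envir = teardown_env())
engine_ds <- make_dataset(engine_dir, n_samples = 3, n_events = 2000,
                          seed = 5)

cache_files <- function(root, experiment) {
  sort(list.files(file.path(root, experiment), recursive = TRUE,
                  full.names = TRUE))
}
artifact_files <- function(root, experiment) {
  f <- cache_files(root, experiment)
  f[grepl("\\.fcs$", f) | grepl("[0-9]{2}_.*\\.json$", f)]
}
file_md5 <- function(files) unname(tools::md5sum(files))

test_that("pipeline JSON parsing validates structure and reports all
           violations at once", {
  f <- system.file("pipelines", "qc_transformed.json", package = "fcspipe")
  defn <- parse_pipeline_json(f)
  expect_s3_class(defn, "pipeline_definition")
  expect_length(defn$scale_steps, 4)
  expect_length(defn$frame_steps, 8)
  expect_identical(defn$frame_steps[[1]]$fun, "read_sample")
  # a step without ARGS gets an empty argument mapping
  expect_identical(defn$frame_steps[[1]]$args, list())

  minimal <- '{"experimentName":"e",
    "scaleTransformProcessingSteps":[{"name":"a","FUN":"aggregate_samples"}],
    "flowFramesPreProcessingSteps":[
      {"name":"r","FUN":"read_sample"},
      {"name":"m","FUN":"remove_margins"}]}'
  d2 <- parse_pipeline_json(minimal)
  expect_length(d2$frame_steps, 2)

  expect_error(
    parse_pipeline_json('{"experimentName":"e",
      "scaleTransformProcessingSteps":[{"name":"a","FUN":"aggregate_samples"}]}'),
    "flowFramesPreProcessingSteps")
  # several violations reported together
  err <- tryCatch(parse_pipeline_json('{"experimentName":"e",
    "scaleTransformProcessingSteps":[{"name":"a","FUN":"no_such_fun"}],
    "flowFramesPreProcessingSteps":[
      {"name":"x","FUN":"read_sample"},
      {"name":"x","FUN":"remove_margins"},
      {"name":"y"}]}'),
    error = conditionMessage)
  expect_match(err, "unknown step function \"no_such_fun\"")
  expect_match(err, "duplicate step name \"x\"")
  expect_match(err, "missing \"FUN\"")
})

test_that("a full run completes every step and is idempotent on re-run", {
  cache <- file.path(engine_dir, "cache_main")
  defn <- template_defn("qc_transformed", "exp_main", engine_ds$paths)
  st <- run_pipeline(defn, cache)
  expect_true(all(st$status == "completed"))
  expect_identical(nrow(st), 4L + 3L * 8L)

  # re-run: nothing recomputed, no file touched, bit-identical cache
  before <- file.info(cache_files(cache, "exp_main"))[, c("size", "mtime")]
  md5_before <- file_md5(cache_files(cache, "exp_main"))
  Sys.sleep(1)
  st2 <- run_pipeline(defn, cache)
  after <- file.info(cache_files(cache, "exp_main"))[, c("size", "mtime")]
  expect_identical(before, after)
  expect_identical(md5_before, file_md5(cache_files(cache, "exp_main")))
  expect_true(all(st2$status == "completed"))
})

test_that("an argument spelling error yields a completed prefix, an error
           record, and a pending suffix", {
  cache <- file.path(engine_dir, "cache_fail")
  defn <- template_defn("qc_transformed", "exp_fail", engine_ds$paths)
  # misspell one parameter name of the debris-removal step (step 5)
  names(defn$frame_steps[[5]]$args)[
    names(defn$frame_steps[[5]]$args) == "n_clusters"] <- "n_clusterz"
  st <- run_pipeline(defn, cache)
  for (s in unique(st$sample[st$sample != "GLOBAL"])) {
    sub <- st[st$sample == s, ]
    expect_identical(sub$status,
                     c(rep("completed", 4), "error", rep("pending", 3)))
  }
  # the workflow view shows the same prefix/suffix pattern
  g <- workflow_graph(defn, st, "sample_01")
  expect_identical(g$status[1:4], rep("completed", 4))
  expect_identical(g$status[5], "error")
  txt <- capture.output(print(g))
  expect_match(paste(txt, collapse = " "), "\\[ERR\\] remove_debris")
})

test_that("parallel execution produces bit-identical caches", {
  defn1 <- template_defn("qc_transformed", "exp_par", engine_ds$paths)
  cache1 <- file.path(engine_dir, "cache_w1")
  cache4 <- file.path(engine_dir, "cache_w4")
  run_pipeline(defn1, cache1, workers = 1)
  run_pipeline(defn1, cache4, workers = 4)
  f1 <- artifact_files(cache1, "exp_par")
  f4 <- artifact_files(cache4, "exp_par")
  expect_identical(basename(f1), basename(f4))
  expect_identical(file_md5(f1), file_md5(f4))
})

test_that("deleting a cache suffix resumes to an identical end state", {
  cache <- file.path(engine_dir, "cache_main")
  defn <- template_defn("qc_transformed", "exp_main", engine_ds$paths)
  run_pipeline(defn, cache)
  ref <- file_md5(artifact_files(cache, "exp_main"))

  # drop steps >= 5 for one sample (cache entries and status suffix)
  sdir <- file.path(cache, "exp_main", "sample_02")
  drop <- list.files(sdir, pattern = "^0[5-8]_", full.names = TRUE)
  file.remove(drop)
  recs <- jsonlite::read_json(file.path(sdir, "status.json"))
  jsonlite::write_json(recs[1:4], file.path(sdir, "status.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  st <- run_pipeline(defn, cache)
  expect_true(all(st$status == "completed"))
  expect_identical(file_md5(artifact_files(cache, "exp_main")), ref)
})

test_that("cached outputs are retrievable, recomputable, and staleness is
           detected", {
  cache <- file.path(engine_dir, "cache_main")
  defn <- template_defn("qc_transformed", "exp_main", engine_ds$paths)
  run_pipeline(defn, cache)

  out <- get_cached_output(cache, "exp_main", "sample_01", "compensate")
  # recompute oracle: running steps 1..3 functionally gives the same table
  raw <- read_fcs(engine_ds$paths[1])
  manual <- compensate(remove_margins(raw, list("FSC-A" = c(0, 262144),
                                                "SSC-A" = c(0, 262144))))
  expect_identical(event_ids(out), event_ids(manual))
  expect_lt(max(abs(out$values - manual$values) /
                  pmax(abs(manual$values), 1)), 1e-6)

  # the GLOBAL transform set is retrievable
  tset <- get_cached_output(cache, "exp_main", "GLOBAL",
                            "estimate_transforms")
  expect_s3_class(tset, "transform_set")

  # stale: same step, edited definition
  edited <- defn
  edited$frame_steps[[3]]$args <- list(spill = "from-keywords")
  expect_error(get_cached_output(cache, "exp_main", "sample_01",
                                 "compensate", defn = edited),
               "stale")
  # absent: a pending step of a failed experiment
  expect_error(get_cached_output(file.path(engine_dir, "cache_fail"),
                                 "exp_fail", "sample_01",
                                 "remove_dead_cells"),
               "absent")
  expect_error(get_cached_output(cache, "exp_main", "sample_01", "nope"),
               "unknown step")
  expect_error(step_statuses(cache, "no_such_experiment"),
               "unknown experiment")
})

test_that("the same engine code runs both step orders from JSON alone", {
  cache <- file.path(engine_dir, "cache_both")
  d1 <- template_defn("qc_transformed", "order_transformed",
                      engine_ds$paths)
  d2 <- template_defn("qc_raw", "order_raw", engine_ds$paths)
  s1 <- run_pipeline(d1, cache)
  s2 <- run_pipeline(d2, cache)
  expect_true(all(s1$status == "completed"))
  expect_true(all(s2$status == "completed"))
  # orders differ: QC sits at a different position
  expect_identical(s1$fun[s1$sample == "sample_01"][7], "qc_in_time")
  expect_identical(s2$fun[s2$sample == "sample_01"][3], "qc_in_time")
})

test_that("workflow graphs render in step order", {
  cache <- file.path(engine_dir, "cache_main")
  defn <- template_defn("qc_transformed", "exp_main", engine_ds$paths)
  st <- run_pipeline(defn, cache)
  g <- workflow_graph(defn, st, "sample_03")
  expect_identical(g$step_name,
                   vapply(defn$frame_steps, `[[`, "", "name"))
  expect_true(all(g$status == "completed"))
  p <- ggplot2::autoplot(g)
  expect_s3_class(p, "ggplot")
  expect_error(workflow_graph(defn, st, "no_sample"), "unknown sample")
})
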