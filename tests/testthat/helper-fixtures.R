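# Fixtures are generated in code; nothing binary ships with the package.

# A minimal deterministic event table.
tiny_table <- function(n = 10, channels = c("FSC-A", "SSC-A"),
                       sample = "tiny", seed = 42) {
  set.seed(seed)
  m <- matrix(stats::runif(n * length(channels), 0, 1000), n,
              dimnames = list(NULL, channels))
  event_table(m, sample = sample)
}

# A small on-disk synthetic dataset shared within a test file.
make_dataset <- function(dir, n_samples = 3, n_events = 2000, seed = 5,
                         ...) {
  generate_dataset(n_samples, dir,
                   spec = synthetic_spec(n_events = n_events, ...),
                   seed = seed)
}

# Pipeline definition from a shipped template, pointed at a dataset.
template_defn <- function(template, experiment, paths, seed = 11,
                          n_events_per_file = 2000) {
  f <- system.file("pipelines", paste0(template, ".json"),
                   package = "fcspipe")
  defn <- parse_pipeline_json(f)
  defn$experiment_name <- experiment
  defn$sample_files <- paths
  defn$seed <- as.integer(seed)
  defn$scale_steps[[1]]$args$n_files <- length(paths)
  defn$scale_steps[[1]]$args$n_events_per_file <- n_events_per_file
  defn
}

# Metrics by exhaustive per-event iteration: the independent oracle for
# compute_metrics().
brute_force_metrics <- function(G, B, F_G, F_B) {
  universe <- c(G, B)
  fbc <- 0L; fgc <- 0L
  for (e in universe) {
    if (e %in% F_B && e %in% B) fbc <- fbc + 1L
    if (e %in% F_G && e %in% G) fgc <- fgc + 1L
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(sensitivity = div(fbc, length(B)),
    specificity = div(fgc, length(G)),
    precision = div(fbc, length(F_B)),
    recall = div(fgc, length(F_G)))
}

expect_same_ids <- function(a, b) {
  expect_setequal(event_ids(a), event_ids(b))
}
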