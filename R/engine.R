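#' The processing-step registry
#'
#' Pipeline JSON refers to steps by function identifier (`FUN`). The
#' registry maps those identifiers to R functions. Built-in identifiers
#' cover reading, the whole step library, transform estimation and
#' application, and a ground-truth oracle filter; users can register
#' additional functions with `register_step_function()`.
#'
#' A registered function receives the previous step's output as its first
#' argument (the first step of the per-file pipeline receives the sample's
#' file path; the first step of the scale-transform pipeline receives the
#' vector of all sample file paths), plus the `ARGS` of its JSON step
#' description. Two argument names are reserved: an `ARGS` entry named
#' `transformSet` is replaced by the experiment's global transform set at
#' run time, and a `seed` formal not set in `ARGS` receives a
#' deterministically derived per-sample seed.
#'
#' @param name function identifier used in pipeline JSON.
#' @param fun the function to register.
#' @return `register_step_function()` returns `name` invisibly;
#'   `step_function_exists()` a logical; `step_function()` the function.
#' @export
register_step_function <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .step_registry)
  invisible(name)
}

#' @rdname register_step_function
#' @export
step_function_exists <- function(name) {
  exists(name, envir = .step_registry, inherits = FALSE)
}

#' @rdname register_step_function
#' @export
step_function <- function(name) {
  if (!step_function_exists(name)) {
    stop("unknown step function identifier: '", name, "'")
  }
  get(name, envir = .step_registry, inherits = FALSE)
}

.step_registry <- new.env(parent = emptyenv())

# built-in steps; JSON-facing wrappers where formals differ.
# Called from .onLoad (file collation order makes top-level registration
# unsafe).
register_builtin_steps <- function() {
  reg <- function(name, fun) assign(name, fun, envir = .step_registry)
  reg("read_sample", function(path) read_fcs(path))
  reg("remove_margins", remove_margins)
  reg("compensate", compensate)
  reg("qc_in_time", qc_in_time)
  reg("remove_doublets", remove_doublets)
  reg("remove_debris", remove_debris)
  reg("remove_dead_cells",
      function(x, ld_channel, transformSet = NULL) {
        remove_dead_cells(x, ld_channel, tset = transformSet)
      })
  reg("apply_transform",
      function(x, transformSet) apply_transform_set(x, transformSet))
  reg("aggregate_samples", aggregate_samples)
  reg("estimate_transform_set", estimate_transform_set)
  # oracle filter: keep exactly the events a ground-truth file lists
  reg("keep_listed_events", function(x, truth_file) {
    truth <- read_ground_truth(truth_file)
    ids <- truth[[x$sample]]
    if (is.null(ids)) stop("sample '", x$sample, "' absent from ground truth")
    filter_events(x, event_ids(x) %in% ids)
  })
}

#' Parse and validate a pipeline description
#'
#' A pipeline is declared as a JSON document with an experiment name and two
#' ordered step lists: `scaleTransformProcessingSteps` (run once per
#' experiment, producing the channel scale transformations) and
#' `flowFramesPreProcessingSteps` (run per sample file). Each step has a
#' user-chosen `name`, a registered function identifier `FUN`, and an
#' optional `ARGS` mapping (omitted = the step takes no parameter beyond
#' the previous step's output). Validation collects *all* violations —
#' missing keys, unknown `FUN` identifiers, duplicate step names — and
#' reports them together, so configuration errors surface at parse time
#' rather than mid-run.
#'
#' @param json a JSON string, or the path of a JSON file.
#' @return a `pipeline_definition`: list with `experiment_name`,
#'   `scale_steps`, `frame_steps`, `sample_files`, `seed`.
#' @export
parse_pipeline_json <- function(json) {
  txt <- if (length(json) == 1 && !grepl("\\{", json) && file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else json
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  for (key in c("experimentName", "scaleTransformProcessingSteps",
                "flowFramesPreProcessingSteps")) {
    if (is.null(doc[[key]])) note(paste0("missing required key \"", key, "\""))
  }

  check_steps <- function(steps, pipeline) {
    if (is.null(steps)) return(list())
    if (length(steps) == 0) {
      note(paste0("\"", pipeline, "\" must contain at least one step"))
      return(list())
    }
    out <- vector("list", length(steps))
    nms <- character(0)
    for (i in seq_along(steps)) {
      s <- steps[[i]]
      if (is.null(s$name)) {
        note(sprintf("%s[%d]: missing \"name\"", pipeline, i))
        s$name <- sprintf("step_%d", i)
      }
      if (is.null(s$FUN)) {
        note(sprintf("%s[%d] (%s): missing \"FUN\"", pipeline, i, s$name))
      } else if (!step_function_exists(s$FUN)) {
        note(sprintf("%s[%d] (%s): unknown step function \"%s\"",
                     pipeline, i, s$name, s$FUN))
      }
      if (s$name %in% nms) {
        note(sprintf("%s: duplicate step name \"%s\"", pipeline, s$name))
      }
      nms <- c(nms, s$name)
      out[[i]] <- list(name = s$name, fun = s$FUN,
                       args = if (is.null(s$ARGS)) list() else s$ARGS)
    }
    out
  }
  scale_steps <- check_steps(doc$scaleTransformProcessingSteps,
                             "scaleTransformProcessingSteps")
  frame_steps <- check_steps(doc$flowFramesPreProcessingSteps,
                             "flowFramesPreProcessingSteps")

  if (length(problems)) {
    stop("invalid pipeline description:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(experiment_name = doc$experimentName,
                 scale_steps = scale_steps,
                 frame_steps = frame_steps,
                 sample_files = as.character(doc$sampleFiles %||% character(0)),
                 seed = as.integer(doc$seed %||% 0L)),
            class = "pipeline_definition")
}

#' @export
print.pipeline_definition <- function(x, ...) {
  cat("<pipeline_definition> experiment '", x$experiment_name, "'\n", sep = "")
  cat(" scale-transform steps:\n")
  for (s in x$scale_steps) cat("   -", s$name, "->", s$fun, "\n")
  cat(" per-file steps:\n")
  for (s in x$frame_steps) cat("   -", s$name, "->", s$fun, "\n")
  cat(" sample files:", length(x$sample_files), "\n")
  invisible(x)
}

# ---- cache internals -------------------------------------------------------

# Chained definition hashes: editing any upstream step (or the scale
# pipeline feeding the per-file pipeline) invalidates everything downstream.
# Arguments are canonicalized (integer -> double) so a definition hashes the
# same before and after a JSON round trip.
canonicalize_args <- function(x) {
  if (is.list(x)) lapply(x, canonicalize_args)
  else if (is.integer(x)) as.double(x)
  else x
}

step_hashes <- function(steps, root_token) {
  h <- digest::digest(root_token, algo = "sha256")
  vapply(steps, function(s) {
    h <<- digest::digest(list(h, s$name, s$fun, canonicalize_args(s$args)),
                         algo = "sha256")
    h
  }, character(1))
}

cache_dir <- function(cache_root, experiment, sample) {
  file.path(cache_root, experiment, sample)
}

entry_basename <- function(index, name) {
  sprintf("%02d_%s", index, gsub("[^A-Za-z0-9_.-]", "_", name))
}

save_step_output <- function(out, dir, index, name) {
  base <- file.path(dir, entry_basename(index, name))
  if (inherits(out, "event_table")) {
    write_fcs(out, paste0(base, ".fcs"))
    list(file = paste0(base, ".fcs"), n_events = n_events(out))
  } else if (inherits(out, "transform_set")) {
    write_transform_set(out, paste0(base, ".json"))
    list(file = paste0(base, ".json"), n_events = NULL)
  } else {
    jsonlite::write_json(out, paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
    list(file = paste0(base, ".json"), n_events = NULL)
  }
}

load_step_output <- function(file) {
  if (grepl("\\.fcs$", file)) {
    read_fcs(file)
  } else {
    obj <- jsonlite::read_json(file)
    is_tset <- length(obj) > 0 && !is.null(obj[[1]]$type)
    if (is_tset) read_transform_set(file) else obj
  }
}

read_status <- function(dir) {
  f <- file.path(dir, "status.json")
  if (!file.exists(f)) return(list())
  jsonlite::read_json(f, simplifyVector = FALSE)
}

write_status <- function(dir, records) {
  jsonlite::write_json(records, file.path(dir, "status.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Run one step list for one unit (a sample, or GLOBAL), resuming from the
# cache. Returns the list of status records (and writes them to disk when
# anything changed).
run_step_list <- function(steps, dir, hashes, first_input, seed,
                          global_tset = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- read_status(dir)
  records <- list()

  # longest completed cached prefix with matching hashes
  valid <- 0L
  for (i in seq_along(steps)) {
    if (length(old) < i) break
    rec <- old[[i]]
    if (!identical(rec$status, "completed") ||
        !identical(rec$hash, hashes[i]) ||
        is.null(rec$file) || !file.exists(rec$file)) break
    valid <- i
    records[[i]] <- rec
  }
  if (valid == length(steps)) {
    return(list(records = old[seq_len(valid)], ran = FALSE))
  }

  input <- if (valid == 0L) {
    first_input
  } else {
    load_step_output(records[[valid]]$file)
  }

  changed <- FALSE
  for (i in (valid + 1L):length(steps)) {
    s <- steps[[i]]
    fun <- step_function(s$fun)
    args <- s$args
    if ("transformSet" %in% names(args)) {
      if (is.null(global_tset)) {
        stop("step '", s$name, "' requires the global transform set, ",
             "but the scale-transform pipeline did not produce one")
      }
      args$transformSet <- global_tset
    }
    if ("seed" %in% names(formals(fun)) && !("seed" %in% names(args))) {
      args$seed <- seed
    }
    res <- tryCatch(
      list(ok = TRUE, value = do.call(fun, c(list(input), args))),
      error = function(e) list(ok = FALSE, message = conditionMessage(e))
    )
    changed <- TRUE
    if (!res$ok) {
      records[[i]] <- list(index = i, name = s$name, fun = s$fun,
                           hash = hashes[i], status = "error",
                           message = res$message,
                           timestamp = format(Sys.time(), usetz = TRUE))
      write_status(dir, records)
      return(list(records = records, ran = TRUE,
                  error = paste0(s$name, ": ", res$message)))
    }
    saved <- save_step_output(res$value, dir, i, s$name)
    rec <- list(index = i, name = s$name, fun = s$fun,
                hash = hashes[i], status = "completed", file = saved$file,
                n_events = saved$n_events,
                timestamp = format(Sys.time(), usetz = TRUE))
    records[[i]] <- Filter(Negate(is.null), rec)
    # the next step always consumes the *cached* form, so resuming from the
    # cache reproduces an uninterrupted run bit for bit
    input <- load_step_output(saved$file)
  }
  if (changed) write_status(dir, records)
  list(records = records, ran = TRUE)
}

derive_sample_seed <- function(seed, sample) {
  h <- strtoi(substr(digest::digest(sample, algo = "sha256"), 1, 7), 16L)
  as.integer((as.numeric(seed) + h) %% (2^31 - 1))
}

# ---- public engine API -----------------------------------------------------

#' Run a pipeline with caching
#'
#' Executes the scale-transform pipeline once (cached under the `GLOBAL`
#' key), then the per-file pipeline for every sample, feeding each step the
#' previous step's output as implicit first argument. Every step output is
#' cached as a file (`<cache>/<experiment>/<sample|GLOBAL>/<NN_step>.fcs`
#' or `.json`) before the next step starts, together with a chained SHA-256
#' hash of the step definition; valid cache entries are skipped on re-run,
#' so interrupted or edited pipelines resume exactly where the definitions
#' diverge. A failing step records an error and stops that sample only.
#' Results are independent of `workers` because each sample derives its own
#' seed from the experiment seed and the sample name.
#'
#' @param defn a [parse_pipeline_json()] definition.
#' @param cache_root cache directory root.
#' @param sample_files optional character vector of FCS paths, overriding
#'   `defn$sample_files`.
#' @param workers number of parallel worker processes (forked).
#' @param seed experiment seed, overriding `defn$seed`.
#' @return the [step_statuses()] tibble for the experiment, invisibly.
#' @export
run_pipeline <- function(defn, cache_root, sample_files = NULL, workers = 1L,
                         seed = NULL) {
  stopifnot(inherits(defn, "pipeline_definition"))
  paths <- sample_files %||% defn$sample_files
  if (length(paths) == 0) stop("no sample files to process")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("sample files not found: ", paste(missing, collapse = ", "))
  }
  seed <- as.integer(seed %||% defn$seed)
  exp_dir <- file.path(cache_root, defn$experiment_name)
  dir.create(exp_dir, showWarnings = FALSE, recursive = TRUE)
  store_definition(defn, paths, seed, exp_dir)

  scale_hashes <- step_hashes(defn$scale_steps, list("scale", seed))
  global <- run_step_list(defn$scale_steps,
                          cache_dir(cache_root, defn$experiment_name, "GLOBAL"),
                          scale_hashes, first_input = paths, seed = seed)
  if (!is.null(global$error)) {
    stop("scale-transform pipeline failed: ", global$error)
  }
  last <- global$records[[length(global$records)]]
  global_tset <- load_step_output(last$file)

  frame_root <- list("frame", seed, scale_hashes[length(scale_hashes)])
  frame_hashes <- step_hashes(defn$frame_steps, frame_root)
  run_one <- function(path) {
    sample <- sub("\\.fcs$", "", basename(path))
    run_step_list(defn$frame_steps,
                  cache_dir(cache_root, defn$experiment_name, sample),
                  frame_hashes, first_input = path,
                  seed = derive_sample_seed(seed, sample),
                  global_tset = global_tset)
  }
  if (workers > 1L) {
    res <- parallel::mclapply(paths, run_one, mc.cores = workers,
                              mc.set.seed = FALSE)
    err <- vapply(res, function(r) inherits(r, "try-error"), logical(1))
    if (any(err)) stop("worker failure: ", paste(res[err], collapse = "; "))
  } else {
    lapply(paths, run_one)
  }
  invisible(step_statuses(cache_root, defn$experiment_name))
}

store_definition <- function(defn, paths, seed, exp_dir) {
  obj <- list(
    experimentName = defn$experiment_name,
    seed = seed,
    sampleFiles = paths,
    scaleTransformProcessingSteps = lapply(defn$scale_steps, function(s)
      list(name = s$name, FUN = s$fun, ARGS = s$args)),
    flowFramesPreProcessingSteps = lapply(defn$frame_steps, function(s)
      list(name = s$name, FUN = s$fun, ARGS = s$args))
  )
  target <- file.path(exp_dir, "pipeline.json")
  new <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cur <- if (file.exists(target)) {
    paste(readLines(target, warn = FALSE), collapse = "\n")
  } else NULL
  if (!identical(as.character(new), cur)) writeLines(new, target)
  invisible(target)
}

stored_definition <- function(cache_root, experiment) {
  f <- file.path(cache_root, experiment, "pipeline.json")
  if (!file.exists(f)) {
    stop("unknown experiment '", experiment, "' in cache ", cache_root)
  }
  parse_pipeline_json(f)
}

#' Per-step run status of an experiment
#'
#' Derived solely from the cache: a step is `completed` when a hash-valid
#' output file exists, `error` when an error record interrupted the sample,
#' and `pending` when no output has been generated yet. Completed steps
#' always form a prefix of the step list (possibly interrupted by one error
#' record).
#'
#' @param cache_root cache directory root.
#' @param experiment experiment name.
#' @return a tibble with columns `sample`, `step_index`, `step_name`,
#'   `fun`, `status`, `n_events`.
#' @export
step_statuses <- function(cache_root, experiment) {
  defn <- stored_definition(cache_root, experiment)
  exp_dir <- file.path(cache_root, experiment)
  units <- c("GLOBAL", sub("\\.fcs$", "", basename(defn$sample_files)))
  rows <- lapply(units, function(u) {
    steps <- if (u == "GLOBAL") defn$scale_steps else defn$frame_steps
    recs <- read_status(file.path(exp_dir, u))
    status <- rep("pending", length(steps))
    nev <- rep(NA_integer_, length(steps))
    for (i in seq_along(steps)) {
      if (length(recs) < i || is.null(recs[[i]])) break
      status[i] <- recs[[i]]$status
      nv <- recs[[i]]$n_events
      nev[i] <- if (is.null(nv) || length(nv) == 0) NA_integer_
                else as.integer(nv)
      if (!identical(recs[[i]]$status, "completed")) break
    }
    tibble::tibble(sample = u, step_index = seq_along(steps),
                   step_name = vapply(steps, `[[`, "", "name"),
                   fun = vapply(steps, `[[`, "", "fun"),
                   status = status, n_events = nev)
  })
  dplyr::bind_rows(rows)
}

#' Retrieve a cached step output
#'
#' Reconstructs the output of one step of one sample (or of the
#' scale-transform pipeline, `sample = "GLOBAL"`) from the cache, event
#' identifiers included. Retrieval fails with distinct messages when the
#' entry is absent (step never completed) versus stale (the step definition
#' was edited after the entry was written).
#'
#' @param cache_root cache directory root.
#' @param experiment experiment name.
#' @param sample sample name, or `"GLOBAL"`.
#' @param step step index or step name.
#' @param defn optional [parse_pipeline_json()] definition used to check
#'   freshness; default: the definition stored at run time.
#' @return an [event_table()], [transform_set()], or plain list.
#' @export
get_cached_output <- function(cache_root, experiment, sample, step,
                              defn = NULL) {
  defn <- defn %||% stored_definition(cache_root, experiment)
  steps <- if (identical(sample, "GLOBAL")) defn$scale_steps else defn$frame_steps
  idx <- if (is.numeric(step)) as.integer(step) else {
    match(step, vapply(steps, `[[`, "", "name"))
  }
  if (is.na(idx) || idx < 1 || idx > length(steps)) {
    stop("unknown step '", step, "' for sample '", sample, "'")
  }
  seed <- defn$seed
  scale_hashes <- step_hashes(defn$scale_steps, list("scale", seed))
  hashes <- if (identical(sample, "GLOBAL")) scale_hashes else {
    step_hashes(defn$frame_steps,
                list("frame", seed, scale_hashes[length(scale_hashes)]))
  }
  recs <- read_status(cache_dir(cache_root, experiment, sample))
  if (length(recs) < idx || is.null(recs[[idx]]) ||
      !identical(recs[[idx]]$status, "completed")) {
    stop("no cached output for step ", idx, " ('", steps[[idx]]$name,
         "') of sample '", sample, "': entry absent")
  }
  rec <- recs[[idx]]
  if (!identical(rec$hash, hashes[idx])) {
    stop("cached output for step ", idx, " ('", steps[[idx]]$name,
         "') of sample '", sample,
         "' is stale: the step definition changed since it was written")
  }
  if (!file.exists(rec$file)) {
    stop("no cached output for step ", idx, " of sample '", sample,
         "': entry absent (file deleted)")
  }
  load_step_output(rec$file)
}

#' Workflow view of one sample's run
#'
#' A linear chain of the per-file steps with one state per node:
#' `completed`, `error` or `pending`. Printable as text and renderable with
#' [ggplot2::autoplot()].
#'
#' @param defn a [parse_pipeline_json()] definition.
#' @param statuses a [step_statuses()] tibble.
#' @param sample sample name.
#' @return a `workflow_graph` tibble with columns `step_index`, `step_name`,
#'   `status`.
#' @export
workflow_graph <- function(defn, statuses, sample) {
  stopifnot(inherits(defn, "pipeline_definition"))
  rows <- statuses[statuses$sample == sample, ]
  if (nrow(rows) == 0) stop("unknown sample '", sample, "' in statuses")
  out <- tibble::tibble(step_index = rows$step_index,
                        step_name = rows$step_name,
                        status = rows$status)
  class(out) <- c("workflow_graph", class(out))
  attr(out, "sample") <- sample
  out
}

#' @export
print.workflow_graph <- function(x, ...) {
  mark <- c(completed = "[ok]", error = "[ERR]", pending = "[..]")
  cat("workflow for sample '", attr(x, "sample"), "':\n  ", sep = "")
  cat(paste0(mark[x$status], " ", x$step_name, collapse = " -> "), "\n")
  invisible(x)
}

#' @rdname workflow_graph
#' @param object a `workflow_graph`.
#' @param ... unused.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.workflow_graph <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step_index, y = 0)) +
    ggplot2::geom_path(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$status), size = 10,
                        shape = 21) +
    ggplot2::geom_text(ggplot2::aes(label = .data$step_name), angle = 35,
                       vjust = -2.2, hjust = 0, size = 3) +
    ggplot2::scale_fill_manual(values = c(completed = "#4daf4a",
                                          pending = "#ff7f00",
                                          error = "#e41a1c")) +
    ggplot2::scale_x_continuous(limits = c(0.5, nrow(df) + 1.5)) +
    ggplot2::scale_y_continuous(limits = c(-1, 1)) +
    ggplot2::labs(title = paste("Workflow:", attr(object, "sample")),
                  x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}
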