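# One richly planted sample shared by the recovery tests in this file.
sample_10k <- generate_sample(synthetic_spec(n_events = 10000, seed = 101))

pop_of <- function(tbl, labels) {
  labels$population[match(event_ids(tbl), labels$event_id)]
}
removal_rate <- function(before, after, ids) {
  present <- intersect(ids, event_ids(before))
  mean(!present %in% event_ids(after))
}

test_that("margin removal matches a brute-force scan and honours
           inclusivity", {
  vals <- matrix(c(-1, 0, 5, 50, 100, 101), 6, 1,
                 dimnames = list(NULL, "FSC-A"))
  tbl <- event_table(vals)
  kept <- remove_margins(tbl, list("FSC-A" = c(0, 100)))
  expect_setequal(channel_values(kept, "FSC-A"), c(5, 50))
  kept2 <- remove_margins(tbl, list("FSC-A" = c(0, 100)), inclusive = FALSE)
  expect_setequal(channel_values(kept2, "FSC-A"), c(0, 5, 50, 100))
  # unbounded limits keep everything
  all_kept <- remove_margins(tbl, list("FSC-A" = c(-Inf, Inf)))
  expect_identical(event_ids(all_kept), event_ids(tbl))
  expect_error(remove_margins(tbl, list(ZZ = c(0, 1))), "unknown channel")
  expect_error(remove_margins(tbl, list("FSC-A" = c(5, 1))), "low < high")

  # brute-force oracle on random tables and bounds
  set.seed(31)
  for (i in 1:10) {
    t2 <- tiny_table(n = 60, channels = c("A", "B"), seed = i)
    b <- list(A = sort(runif(2, 0, 1000)), B = sort(runif(2, 0, 1000)))
    expected <- integer(0)
    for (r in seq_len(60)) {
      v <- t2$values[r, ]
      if (v["A"] > b$A[1] && v["A"] < b$A[2] &&
          v["B"] > b$B[1] && v["B"] < b$B[2]) {
        expected <- c(expected, event_ids(t2)[r])
      }
    }
    expect_setequal(event_ids(remove_margins(t2, b)), expected)
  }
})

test_that("margin removal eliminates all planted saturated events", {
  tbl <- sample_10k$table
  lab <- sample_10k$labels
  out <- remove_margins(tbl, list("FSC-A" = c(0, 262144),
                                  "SSC-A" = c(0, 262144)))
  margin_ids <- lab$event_id[lab$population == "margin"]
  expect_equal(removal_rate(tbl, out, margin_ids), 1)
  # removed fraction at least the planted margin fraction
  expect_gte(1 - n_events(out) / n_events(tbl), 0.03)
})

test_that("compensation inverts spillover mixing and matches a per-event
           linear solve", {
  # identity spillover: no-op
  tbl <- tiny_table(n = 30, channels = c("FL1", "FL2"), seed = 1)
  id <- parse_spillover("2,FL1,FL2,1,0,0,1")
  expect_equal(compensate(tbl, id)$values, tbl$values)

  # known mixing, unmix, compare with brute-force per-event solve
  set.seed(41)
  S <- parse_spillover("3,FL1,FL2,FL3,1,0.12,0.05,0.08,1,0.1,0.02,0.07,1")
  true <- matrix(rlnorm(300 * 3, log(500), 0.6), 300, 3,
                 dimnames = list(NULL, c("FL1", "FL2", "FL3")))
  raw <- true %*% unclass(S)
  tblr <- event_table(raw)
  comp <- compensate(tblr, S)
  expect_lt(max(abs(comp$values - true) / pmax(true, 1e-12)), 1e-9)
  brute <- t(vapply(seq_len(nrow(raw)), function(i)
    solve(t(unclass(S)), raw[i, ]), numeric(3)))
  expect_equal(comp$values, brute, ignore_attr = TRUE, tolerance = 1e-12)

  # from-keywords equals compensating with the generator's matrix
  spec <- synthetic_spec(n_events = 1000, seed = 42)
  out <- generate_sample(spec)
  expect_equal(compensate(out$table, "from-keywords")$values,
               compensate(out$table, spec$spillover)$values)

  expect_error(compensate(tbl, parse_spillover("2,FLX,FLY,1,0,0,1")),
               "absent")
})

test_that("time QC removes planted unstable windows and spares stable
           signal", {
  tbl <- sample_10k$table
  lab <- sample_10k$labels
  out <- qc_in_time(tbl, channels = c("FL1-A", "FL2-A", "LD-A"),
                    bin_size = 100, mad_cutoff = 6)
  window_ids <- lab$event_id[!lab$good & lab$population == "target"]
  stable_ids <- lab$event_id[lab$good]
  expect_gte(removal_rate(tbl, out, window_ids), 0.90)
  expect_lte(removal_rate(tbl, out, stable_ids), 0.02)

  # stationary signal: false positive rate at most 2%
  stable <- generate_sample(synthetic_spec(
    n_events = 10000,
    fractions = c(target = 1, debris = 0, dead = 0, doublet = 0,
                  margin = 0),
    unstable_window = NULL, seed = 55))$table
  out2 <- qc_in_time(stable, channels = c("FL1-A", "FL2-A", "LD-A"),
                     bin_size = 100, mad_cutoff = 6)
  expect_lte(1 - n_events(out2) / n_events(stable), 0.02)
})

test_that("time QC guards degenerate inputs", {
  # constant signal: MAD of bin medians is zero, nothing flagged
  m <- cbind("FL1-A" = rep(100, 2000), Time = sort(runif(2000, 0, 10)))
  const <- event_table(m)
  out <- qc_in_time(const, channels = "FL1-A", bin_size = 100)
  expect_identical(n_events(out), 2000L)

  # too few events: skipped with a warning, not a failure
  small <- filter_events(const, 1:200)
  expect_warning(out2 <- qc_in_time(small, channels = "FL1-A",
                                    bin_size = 100, min_bins = 5),
                 "skipped")
  expect_identical(n_events(out2), 200L)

  expect_error(qc_in_time(const, "FL1-A", bin_size = 5), ">= 10")
  expect_error(qc_in_time(const, "FL1-A", mad_cutoff = 0), "> 0")
})

test_that("doublet removal follows the median + nmad * MAD rule exactly", {
  # all ratios identical: MAD = 0, threshold = median, nothing removed
  m <- cbind("FSC-A" = rep(200, 50), "FSC-H" = rep(100, 50))
  flat <- event_table(m)
  expect_identical(n_events(remove_doublets(flat)), 50L)

  # planted doublets recovered, singlets spared
  tbl <- sample_10k$table
  lab <- sample_10k$labels
  out <- remove_doublets(tbl)
  doublet_ids <- lab$event_id[lab$population == "doublet"]
  singlet_ids <- lab$event_id[lab$population %in% c("target", "dead")]
  expect_gte(removal_rate(tbl, out, doublet_ids), 0.95)
  expect_lte(removal_rate(tbl, out, singlet_ids), 0.05)

  # removal set equals a brute-force loop applying the same rule
  r <- channel_values(tbl, "FSC-A") / channel_values(tbl, "FSC-H")
  cutoff <- median(r) + 4 * 1.4826 * median(abs(r - median(r)))
  expected <- event_ids(tbl)[vapply(seq_along(r), function(i)
    r[i] <= cutoff, logical(1))]
  expect_setequal(event_ids(out), expected)

  # non-positive heights are dropped from statistics and removed
  m2 <- cbind("FSC-A" = c(200, 210, 190, 205), "FSC-H" = c(100, 0, 95, 102))
  expect_warning(out2 <- remove_doublets(event_table(m2)), "non-positive")
  expect_false(1L %in% event_ids(out2))
})

test_that("debris clustering removes the origin-nearest cluster", {
  tbl <- sample_10k$table
  lab <- sample_10k$labels
  pre <- remove_margins(tbl, list("FSC-A" = c(0, 262144),
                                  "SSC-A" = c(0, 262144)))
  out <- remove_debris(pre, n_clusters = 2, seed = 7)
  debris_ids <- lab$event_id[lab$population == "debris"]
  target_ids <- lab$event_id[lab$population == "target"]
  expect_gte(removal_rate(pre, out, debris_ids), 0.99)
  expect_lte(removal_rate(pre, out, target_ids), 0.01)

  # same seed, identical removal set
  again <- remove_debris(pre, n_clusters = 2, seed = 7)
  expect_identical(event_ids(out), event_ids(again))

  # a different cluster count changes the removal set when the scatter
  # clusters overlap (well-separated blobs yield the same debris cluster
  # either way); the diff quantifies the disagreement
  fuzzy <- generate_sample(synthetic_spec(
    n_events = 6000,
    fractions = c(target = 0.8, debris = 0.2, dead = 0, doublet = 0,
                  margin = 0),
    debris_mean = c(25000, 15000), debris_cov = diag(c(9000^2, 7000^2)),
    unstable_window = NULL, seed = 9))$table
  f2 <- remove_debris(fuzzy, n_clusters = 2, seed = 7)
  f3 <- remove_debris(fuzzy, n_clusters = 3, seed = 7)
  d <- diff_tables(f3, f2)
  expect_gt(length(d$only_left_ids) + length(d$only_right_ids), 0)

  expect_error(remove_debris(pre, n_clusters = 1), ">= 2")
  expect_error(remove_debris(filter_events(pre, 1:15), n_clusters = 2),
               "too few")
})

test_that("dead-cell thresholding finds the inter-mode density valley", {
  # constructed bimodal sample in display units: live at 1.0, dead at 3.0
  set.seed(61)
  live <- rnorm(1800, 1.0, 0.15)
  dead <- rnorm(200, 3.0, 0.15)
  m <- cbind("LD-A" = c(live, dead))
  tbl <- event_table(m)
  out <- remove_dead_cells(tbl, "LD-A", tset = NULL)
  thr <- fcspipe:::dead_cell_threshold(c(live, dead))
  expect_gt(thr, 1.0)
  expect_lt(thr, 3.0)
  dead_idx <- 1801:2000
  expect_gte(mean(!(dead_idx - 1L) %in% event_ids(out)), 0.95)
  expect_lte(mean(!(seq_len(1800) - 1L) %in% event_ids(out)), 0.05)

  # threshold equals a brute-force grid search: argmin of the KDE between
  # the two highest population peaks (>= 5% of the top density, valley
  # below half the lower peak)
  d <- density(c(live, dead), bw = "nrd0", n = 512)
  pk <- integer(0)
  for (i in 2:511) {
    if (d$y[i] > d$y[i - 1] && d$y[i] >= d$y[i + 1] &&
        d$y[i] >= 0.05 * max(d$y)) pk <- c(pk, i)
  }
  pk <- pk[order(d$y[pk], decreasing = TRUE)]
  brute <- NA_real_
  for (p2 in pk[-1]) {
    rng <- sort(c(pk[1], p2))
    v <- rng[1] + which.min(d$y[rng[1]:rng[2]]) - 1L
    if (d$y[v] < 0.5 * min(d$y[pk[1]], d$y[p2])) { brute <- d$x[v]; break }
  }
  expect_equal(thr, brute)

  # unimodal data: fallback to the 0.99 quantile, at most 1% removed
  uni <- event_table(cbind("LD-A" = rnorm(2000, 1, 0.1)))
  expect_warning(out2 <- remove_dead_cells(uni, "LD-A"), "quantile")
  expect_lte(1 - n_events(out2) / 2000, 0.011)

  # constant channel: skipped with warning
  const <- event_table(cbind("LD-A" = rep(1, 100)))
  expect_warning(out3 <- remove_dead_cells(const, "LD-A"), "skipped")
  expect_identical(n_events(out3), 100L)
})

test_that("dead-cell removal on planted samples works through the
           transform set", {
  tbl <- sample_10k$table
  lab <- sample_10k$labels
  comp <- compensate(tbl)
  tset <- estimate_transform_set(comp, c("FL1-A", "FL2-A", "LD-A"))
  out <- remove_dead_cells(comp, "LD-A", tset = tset)
  dead_ids <- lab$event_id[lab$population == "dead"]
  live_ids <- lab$event_id[lab$population == "target"]
  expect_gte(removal_rate(comp, out, dead_ids), 0.95)
  expect_lte(removal_rate(comp, out, live_ids), 0.05)
})

test_that("every step preserves ids as a subset and the channel set", {
  tbl <- sample_10k$table
  comp <- compensate(tbl)
  tset <- estimate_transform_set(comp, c("FL1-A", "FL2-A", "LD-A"))
  steps <- list(
    remove_margins(tbl, list("FSC-A" = c(0, 262144))),
    comp,
    qc_in_time(tbl, channels = "FL1-A", bin_size = 100),
    remove_doublets(tbl),
    remove_debris(tbl, n_clusters = 2, seed = 1),
    remove_dead_cells(comp, "LD-A", tset = tset),
    apply_transform_set(comp, tset)
  )
  for (out in steps) {
    expect_true(all(event_ids(out) %in% event_ids(tbl)))
    expect_identical(channels(out), channels(tbl))
  }
})
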