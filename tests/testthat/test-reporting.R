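test_that("per-scenario summaries average created models in grid order", {
  evs <- rbind(
    do.call(rbind, lapply(sprintf("SP%02d", 1:10), function(id)
      eval_row(id, "NFS", 11.25, "C20-40", rgb = 96, ssim = 0.9, mae = 0.2))),
    eval_row("SP01", "FS", 33.75, "C40", created = FALSE),
    eval_row("SP02", "FS", 33.75, "C40", created = FALSE),
    eval_row("SP01", "NFS", 22.5, "C20", rgb = 95, ssim = 0.8, mae = 0.3),
    eval_row("SP02", "NFS", 22.5, "C20", rgb = 97, ssim = 0.9, mae = 0.1)
  )
  s <- summarize_scenarios(evs)
  expect_equal(nrow(s), 3)
  # grid order: FS before NFS, then by step, then tilt-set order
  expect_equal(s$label, c("FS (C40, 33.75)", "NFS (C20-40, 11.25)",
                          "NFS (C20, 22.5)"))
  expect_equal(s$n_success, c(0L, 10L, 2L))
  expect_true(is.na(s$mean_rgb_similarity[1]) && is.na(s$mean_ssim[1]))
  expect_equal(s$mean_rgb_similarity[2], 96)
  expect_equal(s$mean_ssim[3], 0.85)
  expect_equal(s$mean_mae_mm[3], 0.2)
  # success counts partition the created models
  expect_equal(sum(s$n_success), sum(evs$model_created))
  # invariant to input row order
  s2 <- summarize_scenarios(evs[sample(nrow(evs)), ])
  expect_equal(s2, s)
  expect_error(summarize_scenarios(rbind(evs, evs[1, ])), "duplicate")
})

test_that("best-model selection uses mean ranks with ties as sets", {
  # A dominates B on all three metrics
  evs <- rbind(
    eval_row("SP01", "NFS", 11.25, "C20-40", rgb = 97, ssim = 0.9, mae = 0.1),
    eval_row("SP01", "FS", 11.25, "C20-40", rgb = 96, ssim = 0.8, mae = 0.2)
  )
  expect_equal(select_best(evs)$style, "NFS")
  # A better on both texture metrics, B better on geometry:
  # ranks {1,1,2} vs {2,2,1} -> A wins on mean rank
  evs2 <- rbind(
    eval_row("SP01", "NFS", 11.25, "C20-40", rgb = 97, ssim = 0.9, mae = 0.3),
    eval_row("SP01", "NFS", 22.5, "C20-40", rgb = 96, ssim = 0.8, mae = 0.1)
  )
  best <- select_best(evs2)
  expect_equal(best$step, 11.25)
  expect_equal(best$mean_rank, mean(c(1, 1, 2)))
  # single successful model wins by default
  single <- rbind(eval_row("SP02", "FS", 22.5, "C20", rgb = 90, ssim = 0.7,
                           mae = 0.4),
                  eval_row("SP02", "NFS", 33.75, "C40", created = FALSE))
  expect_equal(select_best(single)$style, "FS")
  # no successes is an error naming the specimen
  none <- eval_row("SP03", "FS", 22.5, "C20", created = FALSE)
  expect_error(select_best(none), "SP03")
  # identical metrics tie: both rows returned
  tie <- rbind(
    eval_row("SP04", "NFS", 11.25, "C20", rgb = 96, ssim = 0.9, mae = 0.2),
    eval_row("SP04", "NFS", 11.25, "C40", rgb = 96, ssim = 0.9, mae = 0.2)
  )
  expect_equal(nrow(select_best(tie)), 2)
})

test_that("select_best never returns a dominated model", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 6
    evs <- do.call(rbind, lapply(seq_len(n), function(i)
      eval_row("SP01", sample(c("FS", "NFS"), 1), c(11.25, 22.5, 33.75)[1 + (i %% 3)],
               tilt_set_names[1 + (i %% 3)],
               rgb = runif(1, 90, 99), ssim = runif(1, 0.5, 1),
               mae = runif(1, 0.05, 0.5))))
    evs <- evs[!duplicated(evs[, c("style", "step", "tilts")]), ]
    best <- select_best(evs)[1, ]
    dominated <- any(
      evs$rgb_similarity > best$rgb_similarity & evs$ssim > best$ssim &
        evs$mae_mm < best$mae_mm
    )
    expect_false(dominated)
  }
})

test_that("report files mirror the summary-table layout", {
  evs <- rbind(
    eval_row("SP01", "NFS", 11.25, "C20-40", rgb = 96.954, ssim = 0.888,
             mae = 0.163),
    eval_row("SP02", "NFS", 11.25, "C20-40", rgb = 96.0, ssim = 0.9,
             mae = 0.2),
    eval_row("SP01", "FS", 33.75, "C40", created = FALSE)
  )
  meas <- rbind(
    meas_df(c(5, 2), c(5.2, NA), feature = c("elytra_length", "first_tibia")),
    meas_df(c(5, 2), c(4.9, NA), feature = c("elytra_length", "first_tibia"),
            specimen_id = "SP02")
  )
  out <- withr::local_tempdir()
  write_report(summarize_scenarios(evs), evs, out, measurements = meas)
  expect_true(all(file.exists(file.path(out,
    c("summary.csv", "summary.json", "per_feature_mae.csv",
      "best_models.csv", "failed_models.csv")))))
  sm <- read.csv(file.path(out, "summary.csv"), check.names = FALSE)
  # zero-success scenario prints em-dash cells; scores print to 2 decimals
  empty_row <- sm[sm$model_parameters == "FS (C40, 33.75)", ]
  expect_equal(empty_row$rgb_similarity, "—")
  expect_equal(empty_row$ssim, "—")
  full_row <- sm[sm$model_parameters == "NFS (C20-40, 11.25)", ]
  expect_equal(full_row$rgb_similarity, "96.48")
  expect_equal(full_row$ssim, "0.89")
  pf <- read.csv(file.path(out, "per_feature_mae.csv"), check.names = FALSE)
  expect_equal(pf$elytra_length, "0.15 (2/2)")
  expect_equal(pf$first_tibia, "N/A (0/2)")
  fl <- read.csv(file.path(out, "failed_models.csv"))
  expect_equal(nrow(fl), 1)
  bm <- read.csv(file.path(out, "best_models.csv"))
  expect_equal(sort(unique(bm$specimen_id)), c("SP01", "SP02"))
})
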