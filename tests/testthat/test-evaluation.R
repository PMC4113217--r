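test_that("selection accuracy counts correct trials within scope", {
  truth <- rep(1:6, 5)
  expect_equal(selection_accuracy(truth, truth), 1.0)
  pred <- truth; pred[c(2, 9, 17)] <- ((truth[c(2, 9, 17)]) %% 6) + 1
  expect_equal(selection_accuracy(truth, pred), 27 / 30)
  expect_equal(selection_accuracy(truth, pred, trials = 1:10), 8 / 10)
  expect_error(selection_accuracy(truth, pred, trials = integer(0)), "empty")
  expect_error(selection_accuracy(1:3, 1:4), "equal length")
})

test_that("symbol accuracy requires both trials of a pair to be correct", {
  truth <- rep(3L, 30)
  expect_equal(symbol_accuracy(truth, truth), 1.0)
  one_wrong <- truth; one_wrong[7] <- 4L
  expect_equal(symbol_accuracy(truth, one_wrong), 14 / 15)
  expect_error(symbol_accuracy(truth[1:29], truth[1:29]), "even")
  # union bound: symbol accuracy >= 2 * selection accuracy - 1
  set.seed(19)
  for (rep in 1:25) {
    n <- 2 * sample(2:20, 1)
    tr <- sample.int(6, n, TRUE)
    pr <- ifelse(runif(n) < 0.7, tr, sample.int(6, n, TRUE))
    expect_gte(symbol_accuracy(tr, pr) + 1e-12,
               2 * selection_accuracy(tr, pr) - 1)
  }
})

test_that("spelled output marks a both-failed pair with the sentinel", {
  g <- symbol_grid()
  truth <- c(1L, 1L, 2L, 2L, 3L, 3L)
  pred <- c(1L, 1L,  2L, 5L,  4L, 5L)   # ok pair, second wrong, both wrong
  out <- spell_symbols(truth, pred, g)
  expect_identical(out[1], "A")               # groups[[1]][[1]]
  expect_identical(out[2], g$groups[[2]][[5]])  # wrong but decodable
  expect_identical(out[3], "°")
})

test_that("time to control finds the first run of three correct trials", {
  expect_identical(time_to_control(c(TRUE, TRUE, TRUE, FALSE)), 1L)
  expect_identical(time_to_control(c(FALSE, TRUE, TRUE, TRUE)), 2L)
  expect_identical(time_to_control(rep(c(TRUE, TRUE, FALSE), 4)), NA_integer_)
  expect_identical(time_to_control(truth = c(1, 2, 3, 3),
                                   pred = c(9, 2, 3, 3)), 2L)
})

test_that("ssAUC maps AUC linearly onto [-1, 1] and flips with the labels", {
  # direct AUC checks
  expect_equal(auc_rank(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, TRUE)), 0.5)
  expect_equal(auc_rank(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(c(1, 2, 5, 6), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # AUC 0.75 -> ssAUC 0.5 through the map, on a one-channel epoch set
  vals <- c(2, 1, 4, 3)                    # targets 2,4; nontargets 1,3
  is_t <- c(TRUE, FALSE, TRUE, FALSE)
  eps <- array(0, dim = c(1, 90, 4))
  eps[1, 31:90, ] <- rep(vals, each = 60)  # constant post-stimulus value
  es <- epoch_set(eps, c(-0.2, 0.7), 100)
  m <- ssauc_map(es, is_t, bandpass = FALSE)
  expect_equal(auc_rank(vals, is_t), 0.75)
  expect_true(all(abs(m[1, ] - 0.5) < 1e-12))
  # antisymmetry under class-label swap (with the visualization band-pass on)
  set.seed(23)
  eps2 <- array(rnorm(2 * 90 * 40), dim = c(2, 90, 40))
  es2 <- epoch_set(eps2, c(-0.2, 0.7), 100)
  lab <- rep(c(TRUE, FALSE), 20)
  expect_equal(ssauc_map(es2, lab), -ssauc_map(es2, !lab), tolerance = 1e-12)
  expect_error(ssauc_map(es2, rep(TRUE, 40)), "both classes")
})

test_that("paired sub-block t-tests match hand computation on a 4-subject toy", {
  acc_a <- rbind(c(0.9, 0.8), c(0.7, 0.9), c(0.8, 0.7), c(0.6, 0.8))
  acc_b <- rbind(c(0.5, 0.8), c(0.6, 0.9), c(0.5, 0.8), c(0.5, 0.7))
  res <- subblock_ttests(acc_a, acc_b)
  # hand computation from the difference scores of sub-block 1
  d <- acc_a[, 1] - acc_b[, 1]
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t[1], t_hand, tolerance = 1e-12)
  expect_equal(res$df[1], 3)
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  expect_equal(res$p[1], p_hand, tolerance = 1e-12)
  expect_identical(res$significant[1], p_hand < 0.05)
})

test_that("the block protocol trains once, resets pools, and fixes predictions", {
  ses <- small_session(seed = 41, n_trials = 6, channels = 6, n_blocks = 3)
  rec <- run_block_protocol(ses, methods = c("supervised", "unsupervised"),
                            calibration_block = 1, seed = 2)
  expect_s3_class(rec, "run_record")
  expect_length(rec$blocks, 2)
  sup <- rec$blocks[[1]]; uns <- rec$blocks[[2]]
  expect_identical(sup$method, "supervised")
  expect_length(sup$online, 6)
  expect_null(sup$posthoc)
  # unsupervised block: trajectory grows one trial at a time (fresh pool)
  expect_length(uns$posthoc_trajectory, 6)
  expect_identical(vapply(uns$posthoc_trajectory, length, 1L), 1:6)
  expect_identical(uns$posthoc, uns$posthoc_trajectory[[6]])
  # supervised predictions are a fixed map of the data: re-running the
  # protocol reproduces them exactly
  rec2 <- run_block_protocol(ses, methods = c("supervised", "unsupervised"),
                             calibration_block = 1, seed = 99)
  expect_identical(rec2$blocks[[1]]$online, sup$online)
  summ <- summarize_run(rec)
  expect_identical(nrow(summ), 2L)
  tab <- run_record_table(rec)
  expect_identical(nrow(tab), 12L)
})

test_that("the extended simulation concatenates blocks into 10-trial sub-blocks", {
  # two 10-trial blocks at 4 channels: structure checks only
  ses <- small_session(seed = 51, n_trials = 10, channels = 4, n_blocks = 2)
  model <- calibrate_supervised(ses, 1)
  rec <- run_extended_simulation(ses, model = model, seed = 3)
  expect_identical(rec$n_subblocks, 2L)          # 20 trials / 10
  expect_identical(dim(rec$subblock_accuracy), c(2L, 3L))
  expect_identical(colnames(rec$subblock_accuracy),
                   c("supervised", "unsupervised", "posthoc"))
  expect_length(rec$online, 20)
  expect_length(rec$posthoc, 20)
  # sub-block accuracies recompute from the per-trial predictions
  expect_equal(unname(rec$subblock_accuracy[1, "unsupervised"]),
               mean((rec$online == rec$truth)[1:10]))
  expect_equal(unname(rec$subblock_accuracy[2, "posthoc"]),
               mean((rec$posthoc == rec$truth)[11:20]))
})

test_that("plot helpers render to a device without error", {
  path <- tempfile(fileext = ".png")
  grDevices::png(path, width = 400, height = 300)
  set.seed(2)
  correct <- matrix(runif(60) > 0.3, nrow = 3)
  plot_error_raster(correct, runs = c("b2", "b4", "b6"))
  plot_block_accuracy(cbind(supervised = c(0.9, 0.95),
                            unsupervised = c(0.6, 0.8)))
  fake <- structure(list(subblock_accuracy = cbind(unsupervised = c(0.5, 0.9),
                                                   posthoc = c(0.9, 1.0)),
                         subblock_size = 10, n_subblocks = 2L),
                    class = "extended_record")
  plot_extended_course(fake)
  grDevices::dev.off()
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("simulated subject cohorts vary amplitude within the stated range", {
  subs <- simulate_subject_sessions(3, amplitude_range = c(0.2, 0.5),
                                    seed = 4, template = small_template(),
                                    n_blocks = 1, trials_per_block = 2)
  expect_length(subs, 3)
  amps <- vapply(subs, function(s) s$template$difference_amplitude, 1)
  expect_true(all(amps >= 0.2 & amps <= 0.5))
  expect_gt(length(unique(amps)), 1)
  # reproducible from the master seed
  subs2 <- simulate_subject_sessions(3, amplitude_range = c(0.2, 0.5),
                                     seed = 4, template = small_template(),
                                     n_blocks = 1, trials_per_block = 2)
  expect_identical(subs, subs2)
})
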