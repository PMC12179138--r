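# Training protocol, checkpointing, and the experiment commands

tiny_data <- function(n_per_class = 1L, seed = 21L) {
  spec <- synthetic_spec(n_per_class = max(8L, n_per_class * 8L), seed = seed,
                         split_fractions = c(0.5, 0.25, 0.25))
  # build a small image list directly to keep the fixtures minimal
  imgs <- lapply(0:7, function(cl) generate_image(cl, spec, seed = seed + cl))
  list(images = imgs, labels = 0:7)
}

test_that("the protocol defaults match the reference settings", {
  tc <- train_config()
  expect_equal(tc$lr, 0.001)
  expect_equal(tc$batch_size, 64L)
  expect_equal(tc$epochs, 60L)
  expect_equal(tc$beta1, 0.9)
  expect_equal(tc$beta2, 0.999)
  expect_equal(tc$weight_decay, 1e-4)
  expect_equal(tc$loss, "cross-entropy")
  expect_equal(tc$n_repeats, 6L)
  expect_false(tc$mixed_precision)
  expect_error(train_config(loss = "hinge"), "cross-entropy")
})

test_that("one epoch trains, logs one record, and checkpoints round-trip bitwise", {
  set.seed(701)
  td <- tiny_data()
  net <- msli_net(msli_config(width_multiplier = 0.25))
  log_file <- tempfile(fileext = ".jsonl")
  cfg <- train_config(batch_size = 4L, epochs = 1L, mixed_precision = TRUE,
                      seed = 3L)
  res <- fit(net, td$images, td$labels, cfg, log_file = log_file)
  expect_equal(nrow(res$history), 1L)
  lines <- readLines(log_file)
  expect_length(lines, 1L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$epoch, 1L)
  expect_equal(rec$split, "train")

  ck <- tempfile(fileext = ".rds")
  save_checkpoint(net, ck, norm = res$norm)
  re <- load_checkpoint(ck)
  p1 <- msli_forward(net, td$images[[1]])
  p2 <- msli_forward(re$net, td$images[[1]])
  expect_identical(p1, p2)
  m1 <- evaluate_model(net, td$images, td$labels, norm = res$norm)
  m2 <- evaluate_model(re$net, td$images, td$labels, norm = re$norm)
  expect_identical(m1$confusion, m2$confusion)
  unlink(c(ck, log_file))
})

test_that("seeded runs are bitwise reproducible", {
  td <- tiny_data()
  run_once <- function() {
    set.seed(77)
    net <- msli_net(msli_config(width_multiplier = 0.25))
    cfg <- train_config(batch_size = 4L, epochs = 1L, mixed_precision = TRUE,
                        seed = 77L)
    res <- fit(net, td$images, td$labels, cfg)
    list(loss = res$history$loss, state = mslinet:::module_state(net))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$loss, b$loss)
  expect_identical(a$state, b$state)
})

test_that("repeat protocol averages the per-run metrics files", {
  out_dir <- tempfile("runs")
  cfg <- list(
    data = list(n_per_class = 8L, seed = 13L),
    model = list(ablation = "baseline", width_multiplier = 0.25),
    train = list(batch_size = 4L, epochs = 1L, n_repeats = 2L, seed = 5L,
                 mixed_precision = TRUE),
    out = list(dir = out_dir)
  )
  res <- cmd_train(cfg)
  expect_length(res$runs, 2L)
  m1 <- jsonlite::fromJSON(file.path(out_dir, "metrics_run1.json"))
  m2 <- jsonlite::fromJSON(file.path(out_dir, "metrics_run2.json"))
  mm <- jsonlite::fromJSON(file.path(out_dir, "metrics_mean.json"))
  expect_equal(mm$accuracy, (m1$accuracy + m2$accuracy) / 2)
  expect_equal(mm$f1, (m1$f1 + m2$f1) / 2)
  # resolved config re-reads and re-resolves to itself
  rc <- resolve_config(file.path(out_dir, "resolved_config.json"))
  expect_equal(rc$train$epochs, 1L)
  expect_equal(rc$model$ablation, "baseline")

  # evaluation artifacts: confusion rows sum to the per-class support
  ds <- mslinet:::config_dataset(rc$data)
  te <- dataset_split(ds, "test")
  eval_dir <- tempfile("eval")
  m <- cmd_evaluate(file.path(out_dir, "checkpoint_run1.rds"), ds,
                    out_dir = eval_dir)
  expect_equal(unname(rowSums(m$confusion)),
               unname(as.vector(table(factor(te$labels, levels = 0:7)))))
  cc <- utils::read.csv(file.path(eval_dir, "confusion.csv"), row.names = 1)
  expect_equal(unname(rowSums(cc)), unname(rowSums(m$confusion)))
  # evaluating twice is deterministic
  m2b <- cmd_evaluate(file.path(out_dir, "checkpoint_run1.rds"), ds)
  expect_identical(m$confusion, m2b$confusion)
  unlink(c(out_dir, eval_dir), recursive = TRUE)
})

test_that("the robustness command emits one row per sigma with derived seeds", {
  set.seed(702)
  td <- tiny_data()
  net <- msli_net(msli_config(width_multiplier = 0.25, use_mdf = FALSE,
                              use_llm = FALSE, use_wssa = FALSE))
  csv <- tempfile(fileext = ".csv")
  rb <- robustness_protocol(net, td$images, td$labels,
                            sigmas = c(0.1, 0.3), seed = 4L, file = csv)
  expect_equal(rb$sigma, c(0.1, 0.3))
  expect_gt(rb$psnr_db[1], rb$psnr_db[2])
  tab <- utils::read.csv(csv)
  expect_equal(names(tab), c("sigma", "psnr_db", "accuracy"))
  expect_equal(nrow(tab), 2L)
  # per-sigma seeds make single rows reproducible in isolation
  rb2 <- robustness_protocol(net, td$images, td$labels, sigmas = 0.3,
                             seed = 4L)
  expect_identical(rb$accuracy[2], rb2$accuracy[1])
  expect_identical(rb$psnr_db[2], rb2$psnr_db[1])
  expect_error(robustness_protocol(net, td$images, td$labels,
                                   sigmas = numeric(0)), "empty")
  unlink(csv)
})
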