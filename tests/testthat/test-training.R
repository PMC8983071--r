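test_that("learning-rate schedule hits its anchors and decays linearly", {
  cfg <- train_config()
  expect_equal(lr_schedule(1, cfg), 1e-5)
  expect_equal(lr_schedule(100, cfg), 1e-5)
  expect_equal(lr_schedule(150, cfg), 5e-6)
  expect_equal(lr_schedule(200, cfg), 0)
  lrs <- lr_schedule(1:200, cfg)
  expect_true(all(diff(lrs) <= 0))                   # non-increasing
  expect_equal(diff(lrs[101:200]), rep(-1e-7, 99))   # piecewise linear
  expect_error(lr_schedule(0, cfg), "out of range")
  expect_error(lr_schedule(201, cfg), "out of range")
  expect_error(train_config(epochs = 50, decay_start_epoch = 60))
})

test_that("the fake-image pool is capacity-bounded and seed-deterministic", {
  eng <- asNamespace("srcycle")
  mk <- function(i) matrix(i, 2, 2)
  run <- function(seed) {
    set.seed(seed)
    pool <- eng$image_pool(5L)
    seen <- list()
    for (i in 1:20) {
      q <- eng$pool_query(pool, list(mk(i)))
      pool <- q$pool
      seen[[i]] <- q$images[[1]][1, 1]
      expect_lte(length(pool$images), 5L)
    }
    unlist(seen)
  }
  expect_identical(run(3), run(3))
  expect_false(identical(run(3), run(4)))
  # disabled pool passes everything through
  q <- eng$pool_query(eng$image_pool(0L), list(mk(9)))
  expect_identical(q$images[[1]], mk(9))
})

test_that("training steps are deterministic and keep finite gradients", {
  cfg <- tiny_net_cfg(k = 1L, ch = 4L)
  tc <- train_config(epochs = 2, decay_start_epoch = 1, lr0 = 1e-3,
                     seed = 21, pool_size = 4)
  mk_run <- function() {
    m <- srcycle_model(cfg, tc, loss_weights(), lr_size = 16, d_channels = 4)
    set.seed(21)
    tot <- numeric(10)
    for (i in 1:10) {
      bx <- array(runif(16 * 16 * 2, -1, 1), c(16, 16, 1, 2))
      by <- array(runif(32 * 32 * 2, -1, 1), c(32, 32, 1, 2))
      r <- train_step(m, bx, by, 1e-3)
      m <- r$model
      expect_true(all(vapply(unclass(r$losses), is.finite, TRUE)))
      tot[i] <- r$losses$total
    }
    list(tot = tot, sum = srcycle:::net_param_checksum(m$nets$G1))
  }
  a <- mk_run(); b <- mk_run()
  expect_identical(a$tot, b$tot)
  expect_identical(a$sum, b$sum)
  # size mismatch is rejected
  m <- srcycle_model(cfg, tc, loss_weights(), lr_size = 16, d_channels = 4)
  expect_error(train_step(m, array(0, c(16, 16, 1, 1)),
                          array(0, c(24, 24, 1, 1)), 1e-3), "mismatch")
})

test_that("MMSR supervision drives LD toward zero on paired phantoms", {
  # lambda5 = lambda6 = lambda7 = 0: pure MMSR training on
  # paired-by-construction phantom patches; the downsample loss collapses
  cfg <- tiny_net_cfg(k = 1L, ch = 6L)
  tc <- train_config(epochs = 2, decay_start_epoch = 1, lr0 = 2e-3,
                     seed = 5, pool_size = 0)
  w <- loss_weights(lambda5 = 0, lambda6 = 0, lambda7 = 0)
  m <- srcycle_model(cfg, tc, w, lr_size = 16, d_channels = 4)
  spec <- phantom_spec(hr_size = 32, scale = 2, seed = 1)
  hrs <- lapply(1:4, function(s) generate_micro_phantom(spec, seed = s)$data)
  by <- array(unlist(hrs), c(32, 32, 1, 4))
  bx <- array(unlist(lapply(hrs, average_pool_downsample, 2)),
              c(16, 16, 1, 4))
  set.seed(5)
  first <- NULL; last <- NULL
  for (i in 1:120) {
    r <- train_step(m, bx, by, 2e-3)
    m <- r$model
    if (i == 1) first <- r$losses$LD
    last <- r$losses$LD
  }
  expect_lt(last, 0.1 * first)
})

test_that("fit writes logs and checkpoints, and resume reproduces the run", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  set.seed(31)
  clin <- lapply(1:8, function(i)
    image_patch(rand_mat(16, seed = i), intensity_domain("clinical")))
  micro <- lapply(1:8, function(i)
    image_patch(rand_mat(32, seed = 100 + i), intensity_domain("micro")))
  cfg <- tiny_net_cfg(k = 1L, ch = 4L)
  tc <- train_config(epochs = 2, batch_size = 4, lr0 = 1e-3,
                     decay_start_epoch = 1, pool_size = 4, seed = 41,
                     checkpoint_every = 1)
  m_full <- fit(clin, micro, tc, cfg, loss_weights(), out_dir = dir_a,
                d_channels = 4)
  log_a <- read.csv(file.path(dir_a, "loss_log.csv"))
  expect_identical(nrow(log_a), 4L)                   # 2 epochs x 2 steps
  expect_true(file.exists(file.path(dir_a, "checkpoint_epoch001.rds")))
  expect_true(file.exists(file.path(dir_a, "checkpoint_epoch002.rds")))
  # resume from the epoch-1 checkpoint must reproduce epoch 2 exactly
  m_res <- fit(clin, micro, tc, cfg, loss_weights(), out_dir = dir_b,
               resume_from = file.path(dir_a, "checkpoint_epoch001.rds"))
  log_b <- read.csv(file.path(dir_b, "loss_log.csv"))
  expect_equal(log_b[1:2, c("total", "Lcyc", "LD")],
               log_a[3:4, c("total", "Lcyc", "LD")],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(srcycle:::net_param_checksum(m_res$nets$G1),
               srcycle:::net_param_checksum(m_full$nets$G1),
               tolerance = 1e-12)
  expect_error(fit(list(), micro, tc, cfg), "non-empty")
})

test_that("inference uses only G1, is deterministic and tags the micro domain", {
  cfg <- tiny_net_cfg(k = 1L, ch = 4L)
  tc <- train_config(epochs = 2, decay_start_epoch = 1, seed = 51)
  m <- srcycle_model(cfg, tc, loss_weights(), lr_size = 16, d_channels = 4)
  p <- image_patch(rand_mat(16, seed = 6), intensity_domain("clinical"))
  o1 <- infer(p, m)
  o2 <- infer(p, m)
  expect_s3_class(o1, "image_patch")
  expect_identical(o1$domain$name, "micro")
  expect_identical(dim(o1$data), c(32L, 32L))
  expect_true(all(abs(o1$data) <= 1))
  expect_identical(o1$data, o2$data)
  # batches preserve order
  ps <- lapply(1:3, function(i)
    image_patch(rand_mat(16, seed = i), intensity_domain("clinical")))
  os <- infer(ps, m)
  expect_identical(os[[2]]$data, infer(ps[[2]], m)$data)
  bad <- image_patch(matrix(1200, 16, 16), intensity_domain("clinical"),
                     normalized = FALSE)
  expect_error(infer(bad, m), "normalize")
})

test_that("checkpoints round-trip the full model state", {
  cfg <- tiny_net_cfg(k = 1L, ch = 4L)
  tc <- train_config(epochs = 2, decay_start_epoch = 1, seed = 61)
  m <- srcycle_model(cfg, tc, loss_weights(), lr_size = 16, d_channels = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(srcycle:::net_param_checksum(m2$nets$G1),
               srcycle:::net_param_checksum(m$nets$G1))
  expect_identical(m2$net_cfg, m$net_cfg)
  ck <- readRDS(path)
  expect_match(ck$config_text, "lambda3: 0.7")        # embedded text config
  saveRDS(list(schema = "other"), path)
  expect_error(load_checkpoint(path), "schema")
})
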