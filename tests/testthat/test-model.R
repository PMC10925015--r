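fit_tiny <- function(epochs = 5, seed = 1, n_drugs = 3, n_cells = 6,
                     n_genes = 15, ...) {
  fx <- make_fixture(fixture_spec(n_drugs = n_drugs, n_cells = n_cells,
                                  n_genes = n_genes, noise_sd = 0.1,
                                  seed = seed))
  cfg <- small_config(epochs = epochs, seed = seed, ...)
  list(fx = fx, model = cdr_fit(fx$responses, fx$drug_table, fx$omics, cfg))
}

test_that("the fused head is deterministic and affine at zero initialization", {
  cfg <- small_config()
  L <- cfg$d_graph + cfg$d_seq + cfg$d_gene
  hp <- cdrnet:::head_params(L, cfg, seed = 1)
  z <- rep(0, L)
  y1 <- fuse_and_predict(z[1:cfg$d_graph],
                         z[1:cfg$d_seq], z[1:cfg$d_gene], hp, cfg)
  expect_identical(y1, fuse_and_predict(z[1:cfg$d_graph], z[1:cfg$d_seq],
                                        z[1:cfg$d_gene], hp, cfg))
  hp0 <- lapply(hp, function(m) m * 0)
  attributes(hp0) <- attributes(hp)
  hp0$out.b[] <- 0.37
  expect_equal(fuse_and_predict(z[1:cfg$d_graph], z[1:cfg$d_seq],
                                z[1:cfg$d_gene], hp0, cfg), 0.37)
  expect_error(fuse_and_predict(rep(0, 3), rep(0, 3), rep(0, 3), hp, cfg),
               class = "cdrnet_shape_error")
})

test_that("a trained head is sensitive to the gene embedding", {
  r <- fit_tiny(epochs = 8)
  m <- r$model
  cfg <- m$config
  hp <- m$params[grep("^h\\.", names(m$params))]
  names(hp) <- sub("^h\\.", "", names(hp))
  set.seed(9)
  ge <- rnorm(cfg$d_graph); se <- rnorm(cfg$d_seq); xe <- rnorm(cfg$d_gene)
  y0 <- fuse_and_predict(ge, se, xe, hp, cfg)
  y1 <- fuse_and_predict(ge, se, xe + 0.1, hp, cfg)
  expect_gt(abs(y1 - y0), 0)
})

test_that("random splits hit the requested sizes and are seed-stable", {
  recs <- data.frame(drug_id = rep(paste0("d", 1:10), each = 10),
                     cell_line_id = rep(paste0("c", 1:10), 10),
                     ln_ic50 = rnorm(100))
  s1 <- split_dataset(recs, "random", fraction = 0.8, seed = 3)
  expect_equal(sum(s1$split == "TRAIN"), 80L)
  expect_equal(sum(s1$split == "TEST"), 20L)
  expect_identical(s1, split_dataset(recs, "random", fraction = 0.8, seed = 3))
  s2 <- split_dataset(recs, "drug_blind", fraction = 0.8, seed = 3)
  expect_length(intersect(s2$drug_id[s2$split == "TRAIN"],
                          s2$drug_id[s2$split == "TEST"]), 0L)
  s3 <- split_dataset(recs, "cell_blind", fraction = 0.8, seed = 3)
  expect_length(intersect(s3$cell_line_id[s3$split == "TRAIN"],
                          s3$cell_line_id[s3$split == "TEST"]), 0L)
  s4 <- split_dataset(recs, "random", fraction = 0.7, seed = 1,
                      valid_fraction = 0.1)
  expect_equal(sum(s4$split == "VALID"), 10L)
})

test_that("infeasible blind splits are refused", {
  # two drugs with very uneven record counts cannot reach an 0.5 fraction
  recs <- data.frame(drug_id = rep(c("a", "b"), c(95, 5)),
                     cell_line_id = paste0("c", 1:100),
                     ln_ic50 = rnorm(100))
  expect_error(split_dataset(recs, "drug_blind", fraction = 0.5, seed = 1),
               class = "cdrnet_infeasible_split_error")
})

test_that("training reduces the loss and is reproducible under a seed", {
  r1 <- fit_tiny(epochs = 6, seed = 5)
  h <- r1$model$history$train_mse
  expect_length(h, 6L)
  expect_lt(h[6], h[1])
  r2 <- fit_tiny(epochs = 6, seed = 5)
  expect_identical(h, r2$model$history$train_mse)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("unknown drugs or cell lines are reported as data errors", {
  fx <- make_fixture(fixture_spec(n_drugs = 2, n_cells = 4, n_genes = 10))
  bad <- fx$responses
  bad$drug_id[1] <- "ghost"
  expect_error(cdr_fit(bad, fx$drug_table, fx$omics, small_config(epochs = 1)),
               class = "cdrnet_data_error")
  bad2 <- fx$responses
  bad2$cell_line_id[1] <- "phantom"
  expect_error(cdr_fit(bad2, fx$drug_table, fx$omics, small_config(epochs = 1)),
               class = "cdrnet_data_error")
})

test_that("augmented fits triple the train records and keep TEST clean", {
  fx <- make_fixture(fixture_spec(n_drugs = 3, n_cells = 5, n_genes = 10,
                                  seed = 4))
  recs <- split_dataset(fx$responses, "random", fraction = 0.8, seed = 4)
  m <- cdr_fit(recs, fx$drug_table, fx$omics,
               small_config(epochs = 2, augment_factor = 3, seed = 4))
  n_train_orig <- sum(recs$split == "TRAIN")
  n_train_aug <- sum(m$records$split == "TRAIN")
  expect_equal(n_train_aug, 3L * n_train_orig)
  virt <- setdiff(m$drug_table$drug_id, fx$drug_table$drug_id)
  expect_gt(length(virt), 0L)
  expect_false(any(m$records$drug_id[m$records$split != "TRAIN"] %in% virt))
})

test_that("early stopping watches validation RMSE", {
  fx <- make_fixture(fixture_spec(n_drugs = 3, n_cells = 8, n_genes = 10,
                                  seed = 6))
  recs <- split_dataset(fx$responses, "random", fraction = 0.7, seed = 6,
                        valid_fraction = 0.15)
  m <- cdr_fit(recs, fx$drug_table, fx$omics,
               small_config(epochs = 40, patience = 3, seed = 6))
  expect_lte(length(m$history$train_mse), 40L)
  expect_equal(length(m$history$valid_rmse), length(m$history$train_mse))
})

test_that("checkpoints round-trip bitwise", {
  r <- fit_tiny(epochs = 3, seed = 7)
  f <- tempfile(fileext = ".rds")
  cdr_save(r$model, f)
  m2 <- cdr_load(f)
  p1 <- predict(r$model)
  p2 <- predict(m2)
  expect_identical(p1, p2)
  expect_identical(r$model$params, m2$params)
})

test_that("model S3 methods behave like a regression fit", {
  r <- fit_tiny(epochs = 4, seed = 8)
  m <- r$model
  expect_output(print(m), "Drug-response model")
  s <- summary(m)
  expect_s3_class(s$metrics$TRAIN, "cdr_metrics")
  expect_length(residuals(m), nrow(r$fx$responses))
  expect_equal(fitted(m) + residuals(m), r$fx$responses$ln_ic50,
               tolerance = 1e-12)
  expect_type(coef(m), "list")
  sims <- simulate(m, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(r$fx$responses), 2L))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(m); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("pair bookkeeping reports the panel arithmetic", {
  bk <- pair_bookkeeping(561, 221, 106496)
  expect_identical(bk$total_pairs, 123981)
  expect_identical(bk$missing, 17485)
  expect_identical(bk$missing_pct, 14.10)
  expect_error(pair_bookkeeping(2, 2, 5), class = "cdrnet_data_error")
})

test_that("missing-pair imputation predicts exactly the unobserved grid", {
  r <- fit_tiny(epochs = 3, seed = 9, n_drugs = 3, n_cells = 2)
  m <- r$model
  obs <- r$fx$responses[-1, ]   # drop one pair -> one missing
  out <- predict_missing(m, observed = obs)
  expect_equal(nrow(out$imputed), 1L)
  expect_equal(nrow(out$ranking), 1L)
  full <- predict_missing(m, observed = r$fx$responses)
  expect_equal(nrow(full$imputed), 0L)
  # ranking ascends: most sensitive first
  obs2 <- r$fx$responses[r$fx$responses$cell_line_id ==
                           r$fx$responses$cell_line_id[1], ][0, ]
  out2 <- predict_missing(m, observed = obs2)
  expect_equal(nrow(out2$imputed), 6L)
  expect_equal(nrow(out2$ranking), 3L)
  expect_true(!is.unsorted(out2$ranking$mean_pred_ln_ic50))
})
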