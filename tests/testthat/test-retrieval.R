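test_that("candidate clusters are the nearest centers in ascending order", {
  centers <- withr::with_seed(3, matrix(rnorm(20), 10, 2))
  q <- withr::with_seed(4, rnorm(2))
  d <- rowSums((centers - matrix(q, 10, 2, byrow = TRUE))^2)
  full_sort <- order(d, seq_len(10))
  for (m in c(1, 3, 10)) {
    got <- candidate_clusters(q, centers, m)
    expect_identical(as.integer(got), full_sort[seq_len(m)])
  }
  # query placed exactly at a center
  got <- candidate_clusters(centers[3, ], centers, 2)
  expect_identical(got[1], 3L)
  expect_equal(attr(got, "distances")[3], 0)
  expect_error(candidate_clusters(q, centers, 11), "m_candidates")
  expect_error(candidate_clusters(q, centers, 0), "m_candidates")
})

test_that("majority vote is benign only on a strict benign majority", {
  expect_identical(classify_majority(c(0, 0, 0, 0, 0)), 0L)
  expect_identical(classify_majority(c(1, 1, 1, 0, 0)), 1L)
  expect_identical(classify_majority(c(0, 0, 1, 1)), 1L)  # tie -> malignant
  expect_error(classify_majority(integer(0)), "empty")
})

test_that("precision at p is the matching fraction", {
  expect_equal(precision_at_p(c(1, 1, 1), 1), 1.0)
  expect_equal(precision_at_p(c(0, 0), 1), 0.0)
  expect_equal(precision_at_p(c(1, 1, 1, 1, 0), 1), 0.8)
})

test_that("a database image queries itself back at maximal similarity", {
  db <- small_db()
  imgs <- small_dataset()
  res <- prune_retrieve(imgs[[4]], db, m_candidates = db$cluster_model$k, p = 1)
  expect_identical(res$id[1], imgs[[4]]$id)
  expect_identical(res$sim[1], db$model$r)
  expect_identical(attr(res, "predicted_label"), imgs[[4]]$label)
})

test_that("unpruned retrieval equals the exhaustive ranking oracle", {
  db <- small_db()
  f <- small_features()
  for (qi in c(2, 17, 33, 50)) {
    qf <- drop(as.matrix(f[qi, paste0("f", 1:104)]))
    res <- prune_retrieve(qf, db, m_candidates = db$cluster_model$k, p = 10)
    oracle <- exhaustive_rank_oracle(db, qf)
    expect_identical(res$id, oracle$id[1:10])
    expect_identical(res$sim, as.integer(oracle$sim[1:10]))
  }
})

test_that("equal-similarity records are ordered by cluster distance then id", {
  db <- small_db()
  f <- small_features()
  qf <- drop(as.matrix(f[1, paste0("f", 1:104)]))
  res <- prune_retrieve(qf, db, m_candidates = db$cluster_model$k, p = 20)
  for (i in seq_len(nrow(res) - 1)) {
    a <- res[i, ]; b <- res[i + 1, ]
    expect_true(
      a$sim > b$sim ||
        (a$sim == b$sim && a$d < b$d) ||
        (a$sim == b$sim && a$d == b$d && a$id < b$id)
    )
  }
})

test_that("pruned results are a subset of candidate-cluster records", {
  db <- small_db()
  imgs <- small_dataset()
  res <- prune_retrieve(imgs[[10]], db, m_candidates = 2, p = 8)
  cand <- unique(res$cluster)
  expect_lte(length(cand), 2)
  # every returned sim is >= any omitted candidate-pool sim
  qf <- compute_feature_vector(imgs[[10]], db$config)
  oracle <- exhaustive_rank_oracle(db, qf)
  pool_ids <- db$records$id[db$records$cluster %in% cand]
  omitted <- setdiff(pool_ids, res$id)
  if (length(omitted) > 0) {
    expect_gte(min(res$sim), max(oracle$sim[oracle$id %in% omitted]))
  }
})

test_that("p larger than the candidate pool returns the pool with a warning", {
  db <- small_db()
  imgs <- small_dataset()
  expect_warning(
    res <- prune_retrieve(imgs[[1]], db, m_candidates = 1, p = 1000),
    "pool"
  )
  expect_identical(length(unique(res$cluster)), 1L)
  expect_identical(nrow(res), sum(db$records$cluster == res$cluster[1]))
})

test_that("evaluation on the training images themselves is perfect at p = 1", {
  db <- small_db()
  f <- small_features()
  expect_message(
    ev <- evaluate_retrieval(db, f, m_candidates = db$cluster_model$k, p = 1),
    "excluding"
  )
  expect_equal(ev$summary$mean_precision_at_p, 1.0)
  expect_identical(ev$summary$n_queries, 60L)
})

test_that("an empty stratum reports NA accuracy", {
  db <- small_db()
  one <- generate_dataset(1, 0, master_seed = 999)
  ev <- evaluate_retrieval(db, one, m_candidates = 4, p = 5)
  expect_equal(ev$summary$accuracy_benign, 1.0)
  expect_true(is.na(ev$summary$accuracy_malignant))
})

test_that("the evaluation report equals a from-scratch per-query loop", {
  db <- small_db()
  test_imgs <- generate_dataset(8, 8, master_seed = 77)
  ev <- evaluate_retrieval(db, test_imgs, m_candidates = 2, p = 5)
  precisions <- numeric(0)
  correct <- logical(0)
  for (img in test_imgs) {
    res <- prune_retrieve(img, db, m_candidates = 2, p = 5)
    precisions <- c(precisions, precision_at_p(res, img$label))
    correct <- c(correct, attr(res, "predicted_label") == img$label)
  }
  expect_equal(ev$summary$mean_precision_at_p, mean(precisions))
  expect_equal(ev$summary$accuracy_overall, mean(correct))
})

test_that("the distance tie rule never hurts mean precision", {
  db <- small_db()
  test_imgs <- generate_dataset(15, 15, master_seed = 55)
  ev_d <- evaluate_retrieval(db, test_imgs, m_candidates = 2, p = 5,
                             tie_rule = "distance")
  ev_i <- evaluate_retrieval(db, test_imgs, m_candidates = 2, p = 5,
                             tie_rule = "id")
  expect_gte(ev_d$summary$mean_precision_at_p, ev_i$summary$mean_precision_at_p)
})

test_that("a saved database answers queries identically after reload", {
  db <- small_db()
  dir <- withr::local_tempdir()
  save_hash_database(db, dir)
  db2 <- load_hash_database(dir)
  imgs <- small_dataset()
  for (qi in c(3, 41)) {
    r1 <- prune_retrieve(imgs[[qi]], db, m_candidates = 3, p = 5)
    r2 <- prune_retrieve(imgs[[qi]], db2, m_candidates = 3, p = 5)
    expect_identical(r1$id, r2$id)
    expect_identical(r1$sim, r2$sim)
    expect_equal(r1$d, r2$d, tolerance = 1e-12)
  }
})

test_that("tidy, glance and autoplot methods cover the result objects", {
  db <- small_db()
  expect_s3_class(tidy(db$model), "tbl_df")
  expect_identical(nrow(tidy(db$model)), db$model$r)
  expect_identical(glance(db$cluster_model)$k, db$cluster_model$k)
  ev <- evaluate_retrieval(db, generate_dataset(3, 3, master_seed = 5),
                           m_candidates = 2, p = 5)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_s3_class(glance(ev), "tbl_df")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(db$model), "ggplot")
  expect_s3_class(autoplot(small_dataset()[[1]]), "ggplot")
})
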