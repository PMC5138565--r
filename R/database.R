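# End-to-end hash database construction and plain-text persistence.

#' Build the hash code database
#'
#' Runs the whole learning phase on a feature table: fit the standardizer,
#' partition the standardized training matrix by normalized spectral
#' clustering, train the supervised kernel hash functions, and encode every
#' training image into a packed binary code.
#'
#' Desk-scale note: `m_anchor` defaults to `min(300, floor(l / 2))` so the
#' anchor set always respects `m_anchor < l` on small synthetic datasets; at
#' paper scale (thousands of images) this reproduces the 300-anchor default.
#'
#' @param features Tibble from [extract_features()] (`id`, `label`,
#'   `f1` ... `f104`).
#' @param k Number of clusters (paper default 35; use fewer for small
#'   databases).
#' @param r Code length in bits (default 48).
#' @param m_anchor,l,sigma,delta Passed to [train_ksh()] /
#'   [spectral_cluster()]; `NULL` picks the documented defaults.
#' @param seed Integer seed for all selection randomness.
#' @param config The [feature_config()] used to extract `features`; stored so
#'   queries are featurized identically.
#' @return An object of class `hash_database`: `records` (tibble `id`,
#'   `label`, `cluster`), `packed` (byte matrix of codes), `centers`,
#'   `cluster_model`, `model` (`ksh_model`), `standardizer`, `config`.
#' @export
#' @examples
#' \donttest{
#' imgs <- generate_dataset(30, 30, master_seed = 7)
#' feats <- extract_features(imgs)
#' db <- build_hash_database(feats, k = 4, r = 16, seed = 7)
#' res <- prune_retrieve(imgs[[1]], db, m_candidates = 2, p = 5)
#' }
build_hash_database <- function(features, k = 35L, r = 48L, m_anchor = NULL,
                                l = NULL, sigma = NULL, delta = NULL,
                                seed = 1L, config = feature_config()) {
  stopifnot(is.data.frame(features), all(c("id", "label") %in% names(features)))
  if (anyDuplicated(features$id)) abort("record ids must be unique")
  n <- nrow(features)
  l <- as.integer(l %||% min(1000L, n))
  m_anchor <- as.integer(m_anchor %||% min(300L, max(1L, l %/% 2L)))
  std <- fit_standardizer(features)
  Xs <- apply_standardizer(features, std)
  cm <- spectral_cluster(Xs, k = k, delta = delta, seed = seed)
  hm <- train_ksh(Xs, features$label, r = r, m_anchor = m_anchor, l = l,
                  sigma = sigma, seed = seed)
  bits <- encode_features(Xs, hm)
  structure(
    list(records = tibble(id = features$id,
                          label = as.integer(features$label),
                          cluster = cm$assignments),
         packed = pack_code_matrix(bits),
         centers = cm$centers,
         cluster_model = cm,
         model = hm,
         standardizer = std,
         config = config),
    class = "hash_database"
  )
}

#' @export
print.hash_database <- function(x, ...) {
  cat(sprintf("<hash_database: %d records, %d-bit codes, k = %d clusters>\n",
              nrow(x$records), x$model$r, x$cluster_model$k))
  cat(sprintf("labels: %d benign / %d malignant\n",
              sum(x$records$label == 0), sum(x$records$label == 1)))
  invisible(x)
}

#' Persist / restore a hash database as plain text
#'
#' The model directory holds JSON metadata (`meta.json`: code length, kernel
#' bandwidth, bias, cluster bandwidth, feature configuration) and CSV tables
#' for the standardizer, anchors, coefficient matrix, cluster centers and the
#' per-record code database (codes as hexadecimal strings).
#'
#' @param db A [build_hash_database()] object.
#' @param dir Model directory (created if absent).
#' @return `save_hash_database()`: `dir` invisibly;
#'   `load_hash_database()`: the restored `hash_database`.
#' @export
save_hash_database <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  meta <- list(
    r = db$model$r, sigma = db$model$sigma, bias = db$model$bias,
    kernel_mean = db$model$kernel_mean, m_anchor = db$model$m_anchor,
    l = db$model$l, seed = db$model$seed, objective = db$model$objective,
    trace = db$model$trace,
    delta = db$cluster_model$delta, k = db$cluster_model$k,
    config = unclass(db$config)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  w(data.frame(name = db$standardizer$names, center = db$standardizer$center,
               scale = db$standardizer$scale), "standardizer.csv")
  w(as.data.frame(db$model$anchors), "anchors.csv")
  w(as.data.frame(db$model$A), "coefficients.csv")
  w(as.data.frame(db$centers), "centers.csv")
  codes_hex <- apply(db$packed, 2, function(b) {
    paste(sprintf("%02x", b), collapse = "")
  })
  w(data.frame(id = db$records$id, label = db$records$label,
               cluster = db$records$cluster, code = codes_hex), "database.csv")
  invisible(dir)
}

#' @rdname save_hash_database
#' @export
load_hash_database <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  stdf <- rd("standardizer.csv")
  std <- structure(list(center = stats::setNames(stdf$center, stdf$name),
                        scale = stats::setNames(stdf$scale, stdf$name),
                        names = stdf$name),
                   class = "nodule_standardizer")
  anchors <- as.matrix(rd("anchors.csv"))
  colnames(anchors) <- stdf$name
  A <- as.matrix(rd("coefficients.csv"))
  centers <- as.matrix(rd("centers.csv"))
  colnames(centers) <- stdf$name
  recs <- rd("database.csv")
  packed <- vapply(recs$code, function(h) {
    strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L)
  }, integer(ceiling(meta$r / 8)), USE.NAMES = FALSE)
  packed <- matrix(packed, nrow = ceiling(meta$r / 8))
  attr(packed, "r") <- meta$r
  model <- structure(
    list(anchors = anchors, A = A, sigma = meta$sigma, bias = meta$bias,
         r = as.integer(meta$r), kernel_mean = meta$kernel_mean,
         trace = meta$trace, objective = meta$objective,
         m_anchor = as.integer(meta$m_anchor), l = as.integer(meta$l),
         seed = as.integer(meta$seed)),
    class = "ksh_model"
  )
  cm <- structure(
    list(centers = centers, assignments = as.integer(recs$cluster),
         delta = meta$delta, k = as.integer(meta$k),
         sizes = tabulate(recs$cluster, meta$k)),
    class = "cluster_model"
  )
  cfg <- feature_config(meta$config$k_levels, meta$config$glcm_distance,
                        meta$config$tau_cal, meta$config$tau_cav)
  structure(
    list(records = tibble(id = as.character(recs$id),
                          label = as.integer(recs$label),
                          cluster = as.integer(recs$cluster)),
         packed = packed, centers = centers, cluster_model = cm,
         model = model, standardizer = std, config = cfg),
    class = "hash_database"
  )
}
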