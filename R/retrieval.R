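# Cluster-pruned hash-code retrieval with the distance tie-breaking decision
# rule, majority-vote classification, and precision@p evaluation.

#' Candidate clusters of a query
#'
#' Squared Euclidean distances from the standardized query vector to every
#' cluster center; the `m_candidates` nearest clusters, in ascending distance
#' order (ties broken by lower cluster index), restrict the search.
#'
#' @param q Standardized query feature vector.
#' @param centers `k x d` matrix of cluster centers.
#' @param m_candidates Number of candidate clusters, `1 <= m_candidates <= k`.
#' @return Integer vector of cluster indices, with the full distance vector
#'   attached as attribute `distances`.
#' @export
candidate_clusters <- function(q, centers, m_candidates) {
  k <- nrow(centers)
  if (m_candidates < 1 || m_candidates > k) {
    abort("m_candidates must lie in 1..k")
  }
  q <- as.numeric(q)
  d <- colSums((t(centers) - q)^2)
  ord <- order(d, seq_len(k))
  structure(ord[seq_len(m_candidates)], distances = d)
}

#' Majority-vote benign/malignant classification
#'
#' Benign (0) iff the benign labels among the returned images strictly
#' outnumber the malignant ones; otherwise malignant (1) — a tie is called
#' malignant.
#'
#' @param result A `nodule_query` result (or a vector of 0/1 labels).
#' @return 0 or 1.
#' @export
classify_majority <- function(result) {
  labels <- if (is.data.frame(result)) result$label else result
  if (length(labels) == 0) abort("cannot classify from an empty result")
  if (sum(labels == 0) > sum(labels == 1)) 0L else 1L
}

#' Retrieval precision
#'
#' Fraction of returned images whose benign/malignant label matches the
#' query's.
#'
#' @param result A `nodule_query` result (or a vector of 0/1 labels).
#' @param query_label True label of the query.
#' @return A value in `[0, 1]`.
#' @export
precision_at_p <- function(result, query_label) {
  labels <- if (is.data.frame(result)) result$label else result
  if (length(labels) == 0) abort("cannot score an empty result")
  mean(labels == query_label)
}

# core ranking: returns row indices of db records in retrieval order
rank_candidates <- function(db, q_std, q_bytes, m_candidates, tie_rule) {
  cand <- candidate_clusters(q_std, db$centers, m_candidates)
  dists <- attr(cand, "distances")
  pool <- which(db$records$cluster %in% cand)
  if (length(pool) == 0) {
    return(list(pool = integer(0), sims = integer(0), d = numeric(0)))
  }
  sims <- code_sims(db$packed[, pool, drop = FALSE], q_bytes, db$model$r)
  d <- dists[db$records$cluster[pool]]
  ord <- if (tie_rule == "distance") {
    order(-sims, d, db$records$id[pool])
  } else {
    order(-sims, db$records$id[pool])
  }
  list(pool = pool[ord], sims = sims[ord], d = d[ord])
}

#' Cluster-pruned retrieval of similar images
#'
#' Runs the full query pipeline: extract the query's features (when given an
#' image), standardize them with the *training* standardizer, encode with the
#' hash model, restrict the search to the records of the `m_candidates`
#' clusters whose centers are nearest the query, and rank by code inner
#' product (descending). Records with equal inner product are ordered by
#' smaller cluster distance — the image whose cluster is closer to the query
#' is returned first — and remaining ties by ascending record id. Setting
#' `tie_rule = "id"` disables the distance rule (plain id-order tie-break),
#' which is useful for measuring its effect.
#'
#' @param query A `nodule_image`, or a named feature vector / one-row feature
#'   tibble (raw scale, as produced by [extract_features()]).
#' @param db A [build_hash_database()] object.
#' @param m_candidates Number of candidate clusters; default
#'   `min(8, db$cluster_model$k)`.
#' @param p Number of similar images to return.
#' @param tie_rule `"distance"` (the decision rule) or `"id"`.
#' @param exclude_id Optional record id excluded from the search (used when a
#'   query is known to be present in the database).
#' @return A tibble of class `nodule_query` with columns `rank`, `id`, `sim`,
#'   `d`, `cluster`, `label`, and attributes `predicted_label` and
#'   `query_code`.
#' @export
prune_retrieve <- function(query, db, m_candidates = NULL, p = 5L,
                           tie_rule = c("distance", "id"), exclude_id = NULL) {
  tie_rule <- match.arg(tie_rule)
  if (nrow(db$records) == 0) abort("database is empty")
  if (p < 1) abort("p must be >= 1")
  m_candidates <- m_candidates %||% min(8L, db$cluster_model$k)
  qf <- if (inherits(query, "nodule_image")) {
    compute_feature_vector(query, db$config)
  } else {
    drop(feature_matrix(query)[1, ])
  }
  q_std <- drop(apply_standardizer(matrix(qf, nrow = 1), db$standardizer))
  q_bits <- drop(encode_features(matrix(q_std, nrow = 1), db$model))
  q_bytes <- as.integer(unclass(pack_code(q_bits)))

  db_use <- db
  if (!is.null(exclude_id) && any(db$records$id %in% exclude_id)) {
    keep <- !(db$records$id %in% exclude_id)
    db_use$records <- db$records[keep, ]
    db_use$packed <- db$packed[, keep, drop = FALSE]
  }
  rk <- rank_candidates(db_use, q_std, q_bytes, m_candidates, tie_rule)
  if (p > length(rk$pool)) {
    warn(sprintf("p = %d exceeds the candidate pool (%d); returning the whole pool",
                 p, length(rk$pool)))
    p <- length(rk$pool)
  }
  top <- seq_len(p)
  res <- tibble(
    rank = top,
    id = db_use$records$id[rk$pool[top]],
    sim = as.integer(rk$sims[top]),
    d = rk$d[top],
    cluster = db_use$records$cluster[rk$pool[top]],
    label = db_use$records$label[rk$pool[top]]
  )
  structure(res, class = c("nodule_query", class(res)),
            predicted_label = classify_majority(res),
            query_code = q_bits)
}

#' Evaluate retrieval and classification on a test set
#'
#' Loops [prune_retrieve()] over the test queries and reports mean
#' precision@p plus majority-vote classification accuracy, overall and
#' stratified by true label (`NA` for an empty stratum). If a test id
#' collides with a database record id, that record is excluded from the
#' query's search (and a message is emitted once).
#'
#' @param db A [build_hash_database()] object.
#' @param queries List of `nodule_image` objects, or a feature tibble with
#'   `id`, `label`, `f1` ... columns.
#' @param m_candidates,p,tie_rule Passed to [prune_retrieve()].
#' @return An object of class `nodule_evaluation`: a list with `summary`
#'   (one-row tibble: `mean_precision_at_p`, `accuracy_overall`,
#'   `accuracy_benign`, `accuracy_malignant`, `n_queries`), `per_query`
#'   (tibble), and `config` (echo of the evaluation settings).
#' @export
evaluate_retrieval <- function(db, queries, m_candidates = NULL, p = 5L,
                               tie_rule = c("distance", "id")) {
  tie_rule <- match.arg(tie_rule)
  if (is.data.frame(queries)) {
    qlist <- purrr::pmap(list(seq_len(nrow(queries))), function(i) {
      list(id = queries$id[i], label = queries$label[i],
           features = drop(feature_matrix(queries[i, ])[1, ]))
    })
  } else {
    if (length(queries) == 0) abort("test set is empty")
    qlist <- purrr::map(queries, function(img) {
      list(id = img$id, label = img$label,
           features = compute_feature_vector(img, db$config))
    })
  }
  if (length(qlist) == 0) abort("test set is empty")
  collisions <- intersect(vapply(qlist, `[[`, character(1), "id"),
                          db$records$id)
  if (length(collisions) > 0) {
    message(sprintf("%d query id(s) present in the database; excluding the own record per query",
                    length(collisions)))
  }
  rows <- purrr::map(qlist, function(q) {
    res <- prune_retrieve(q$features, db, m_candidates, p, tie_rule,
                          exclude_id = if (q$id %in% collisions) q$id else NULL)
    tibble(id = q$id, label = q$label,
           predicted = attr(res, "predicted_label"),
           precision = precision_at_p(res, q$label))
  })
  per_query <- dplyr::bind_rows(rows)
  acc <- function(df) if (nrow(df) == 0) NA_real_ else mean(df$predicted == df$label)
  summary <- tibble(
    mean_precision_at_p = mean(per_query$precision),
    accuracy_overall = acc(per_query),
    accuracy_benign = acc(dplyr::filter(per_query, .data$label == 0)),
    accuracy_malignant = acc(dplyr::filter(per_query, .data$label == 1)),
    n_queries = nrow(per_query)
  )
  structure(
    list(summary = summary, per_query = per_query,
         config = list(m_candidates = m_candidates %||% min(8L, db$cluster_model$k),
                       p = p, tie_rule = tie_rule, r = db$model$r,
                       k = db$cluster_model$k)),
    class = "nodule_evaluation"
  )
}

#' @export
print.nodule_evaluation <- function(x, ...) {
  cat(sprintf("<nodule_evaluation: %d queries, p = %d, m_candidates = %d, tie rule '%s'>\n",
              x$summary$n_queries, x$config$p, x$config$m_candidates,
              x$config$tie_rule))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.nodule_evaluation <- function(x, ...) x$per_query

#' @export
glance.nodule_evaluation <- function(x, ...) x$summary

#' @export
#' @rdname autoplot-nodulehash
autoplot.nodule_evaluation <- function(object, ...) {
  s <- object$summary
  df <- tibble(
    metric = factor(c("precision@p", "accuracy overall", "accuracy benign",
                      "accuracy malignant"),
                    levels = c("precision@p", "accuracy overall",
                               "accuracy benign", "accuracy malignant")),
    value = c(s$mean_precision_at_p, s$accuracy_overall, s$accuracy_benign,
              s$accuracy_malignant)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Retrieval evaluation") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` methods for the package's result objects: a gray-scale
#' raster for `nodule_image`, the greedy per-bit objective trace for
#' `ksh_model`, and a metric bar chart for `nodule_evaluation`.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-nodulehash
NULL
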