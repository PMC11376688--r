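# D-ring binding-pocket geometry: distance features, PCA, Ward hierarchical
# clustering, and excited-state lifetime stratification by interaction
# pattern.

#' Per-frame distance features between labelled atoms
#'
#' @param traj A `bilin_trajectory`.
#' @param pairs Character vector of `"labelA-labelB"` pairs (or a list of
#'   length-2 character vectors). Column order follows `pairs`.
#' @return Tibble with one row per frame and one distance column (angstrom)
#'   per pair, preceded by `time_ps`.
#' @export
distance_features <- function(traj, pairs = default_pocket_pairs()) {
  if (is.character(pairs)) pairs <- strsplit(pairs, "-", fixed = TRUE)
  labels <- unique(traj$label)
  cols <- lapply(pairs, function(p) {
    if (length(p) != 2) abort("each pair needs exactly two labels")
    if (p[1] == p[2]) {
      abort(paste0("degenerate pair: ", p[1], " with itself"))
    }
    for (l in p) {
      if (!l %in% labels) abort(paste0("unknown atom label: ", l))
    }
    d <- atom_track(traj, p[1]) - atom_track(traj, p[2])
    sqrt(rowSums(d * d))
  })
  names(cols) <- vapply(pairs, paste, "", collapse = "-")
  out <- as_tibble(cols)
  dplyr::bind_cols(tibble(time_ps = frame_table(traj)$time_ps), out)
}

#' Principal component analysis of pocket distance features
#'
#' Columns are z-scored by default (set `scale = FALSE` for centering only).
#' Components are orthonormal and explained-variance fractions non-increasing.
#'
#' @param features Tibble or matrix of distance features (a `time_ps` column
#'   is dropped if present).
#' @param n_components Number of components to retain (default all).
#' @param scale Z-score columns before decomposition (default `TRUE`).
#' @return A `pocket_pca` list: `loadings` (columns are components),
#'   `scores` (tibble), `explained_variance` (fractions), `sdev`.
#' @export
pocket_pca <- function(features, n_components = NULL, scale = TRUE) {
  x <- feature_matrix(features)
  fit <- prcomp(x, center = TRUE, scale. = scale)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  if (is.null(n_components)) n_components <- ncol(fit$rotation)
  n_components <- min(n_components, ncol(fit$rotation))
  idx <- seq_len(n_components)
  structure(list(loadings = fit$rotation[, idx, drop = FALSE],
                 scores = as_tibble(as.data.frame(fit$x[, idx, drop = FALSE])),
                 explained_variance = ev[idx], sdev = fit$sdev[idx],
                 center = fit$center,
                 scale = if (scale) fit$scale else NULL),
            class = "pocket_pca")
}

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  features <- as.data.frame(features)
  features$time_ps <- NULL
  m <- as.matrix(features)
  if (anyNA(m)) abort("feature matrix contains missing values")
  m
}

#' Ward hierarchical clustering of PC scores
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`hclust` method `ward.D2` on Euclidean distances), cut at k clusters.
#' Labels are integers `0 .. k-1` in order of first appearance.
#'
#' @param scores Matrix or tibble of coordinates (rows are frames).
#' @param k Number of clusters.
#' @return A `pocket_clusters` list: `labels` (0-based), `k`,
#'   `linkage_heights` (non-decreasing merge costs), `pc_scores`.
#' @export
ward_cluster <- function(scores, k) {
  x <- feature_matrix(scores)
  if (k > nrow(x)) abort("k exceeds the number of rows")
  hc <- hclust(dist(x), method = "ward.D2")
  raw <- cutree(hc, k = k)
  remap <- match(raw, unique(raw)) - 1L
  structure(list(labels = remap, k = as.integer(k),
                 linkage_heights = hc$height,
                 pc_scores = as_tibble(as.data.frame(x)),
                 hclust = hc),
            class = "pocket_clusters")
}

#' @export
print.pocket_clusters <- function(x, ...) {
  cat(sprintf("Ward clustering: %d rows in %d clusters (%s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' @rdname ward_cluster
#' @param x A `pocket_clusters`.
#' @param ... Unused.
#' @export
tidy.pocket_clusters <- function(x, ...) {
  dplyr::bind_cols(tibble(row = seq_along(x$labels), cluster = x$labels),
                   x$pc_scores)
}

#' Cluster the binding pocket from distance features
#'
#' The full pipeline of the pocket analysis: z-scored PCA, retention of the
#' leading components covering at least `var_retained` of the variance, and
#' Ward clustering in the retained PC space. Mean silhouette widths for cuts
#' at k-1, k, and k+1 are reported as diagnostics of the cluster-count
#' choice.
#'
#' @inheritParams pocket_pca
#' @param k Number of clusters (default 3).
#' @param var_retained Minimum explained-variance fraction retained
#'   (default 0.9).
#' @return A `pocket_clusters` with additional fields `pca` and
#'   `silhouette` (named vector of mean silhouette widths).
#' @export
cluster_pocket <- function(features, k = 3, var_retained = 0.9,
                           scale = TRUE) {
  pca <- pocket_pca(features, scale = scale)
  n_keep <- which(cumsum(pca$explained_variance) >= var_retained)[1]
  n_keep <- max(n_keep, 2)
  scores <- pca$scores[, seq_len(min(n_keep, ncol(pca$scores))),
                       drop = FALSE]
  out <- ward_cluster(scores, k)
  ks <- unique(pmax(2, c(k - 1, k, k + 1)))
  d <- dist(feature_matrix(scores))
  sil <- vapply(ks, function(kk) {
    if (kk >= length(out$labels)) return(NA_real_)
    lab <- cutree(out$hclust, k = kk)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  out$pca <- pca
  out$silhouette <- setNames(sil, paste0("k", ks))
  out
}

#' Mean silhouette width of a k-cut on clustered data
#'
#' @param clusters A `pocket_clusters`.
#' @param k Number of clusters for the cut.
#' @return Mean silhouette width.
#' @export
silhouette_width <- function(clusters, k) {
  lab <- cutree(clusters$hclust, k = k)
  mean(cluster::silhouette(lab,
                           dist(feature_matrix(clusters$pc_scores)))[,
                             "sil_width"])
}

# ---- lifetime stratification ----------------------------------------------

#' Stratify excited-state lifetimes by pocket interaction pattern
#'
#' Groups hop records by a per-trajectory interaction-pattern label (e.g.
#' "NH-Asp196 + water on CO" vs "Gln190 on CO") and summarizes each group's
#' survival: count, censored fraction, and median hop time (Kaplan-Meier
#' median, so censoring is handled; `NA` when the survival never reaches
#' one half).
#'
#' @param records Hop-record tibble.
#' @param patterns Either a vector of pattern labels aligned with `records`
#'   rows, or a tibble with columns `trajectory_id`, `pattern`. Factor
#'   levels with no members are reported with `n = 0`.
#' @return Tibble with columns `pattern`, `n`, `n_censored`,
#'   `censored_fraction`, `median_hop_ps`, ordered by `pattern`.
#' @export
stratify_lifetimes <- function(records, patterns) {
  records <- validate_hop_records(records)
  if (is.data.frame(patterns)) {
    idx <- match(records$trajectory_id, patterns$trajectory_id)
    if (anyNA(idx)) abort("patterns lack some trajectory ids")
    pat <- patterns$pattern[idx]
  } else {
    if (length(patterns) != nrow(records)) {
      abort("patterns must match the number of records")
    }
    pat <- patterns
  }
  pat <- as.factor(pat)
  out <- lapply(levels(pat), function(lv) {
    rec <- records[pat == lv, ]
    if (nrow(rec) == 0) {
      return(tibble(pattern = lv, n = 0L, n_censored = 0L,
                    censored_fraction = NA_real_,
                    median_hop_ps = NA_real_))
    }
    cens <- is.na(rec$hop_time_ps)
    time <- ifelse(cens, rec$censor_time_ps, rec$hop_time_ps)
    fit <- survival::survfit(survival::Surv(time, !cens) ~ 1)
    med <- unname(quantile(fit, probs = 0.5)$quantile)
    tibble(pattern = lv, n = nrow(rec), n_censored = sum(cens),
           censored_fraction = mean(cens), median_hop_ps = med)
  })
  bind_rows(out)
}
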