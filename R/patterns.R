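#' Haufe forward-model activation pattern
#'
#' Converts linear decoder weights into the activation pattern of the
#' corresponding forward model, `a = Cov(X) w`, where `Cov(X)` is the
#' sample covariance of the feature matrix the weights were trained on.
#' Unlike the weights themselves, pattern entries are interpretable: their
#' sign and size reflect how each feature (FC path) covaries with the
#' decoder output. No normalisation is applied; scale is carried through
#' to averaging across iterations.
#'
#' @param weights length-p weight vector.
#' @param X_sample N x p feature matrix (N >= 2).
#' @return length-p activation pattern.
#' @export
haufe_pattern <- function(weights, X_sample) {
  X_sample <- as.matrix(X_sample)
  if (length(weights) != ncol(X_sample))
    stop_fmt("weights length (%d) != feature count (%d)", length(weights),
             ncol(X_sample))
  if (nrow(X_sample) < 2) stop_fmt("need at least 2 samples")
  a <- as.vector(cov(X_sample) %*% weights)
  names(a) <- colnames(X_sample)
  a
}

#' Mean activation pattern across iterations
#' @param iteration_patterns matrix (iterations x paths) or list of
#'   per-iteration pattern vectors.
#' @return length-p arithmetic mean pattern.
#' @export
mean_pattern <- function(iteration_patterns) {
  if (is.list(iteration_patterns))
    iteration_patterns <- do.call(rbind, iteration_patterns)
  if (is.null(dim(iteration_patterns)))
    iteration_patterns <- matrix(iteration_patterns, nrow = 1)
  if (nrow(iteration_patterns) == 0) stop_fmt("no iteration patterns")
  colMeans(iteration_patterns)
}

#' Edge-wise two-sample t statistics
#'
#' Pooled-variance Student t per FC path between the two groups on the
#' *full* (unbalanced) cohort, oriented FHD minus control, df = N - 2.
#' This is the post-hoc univariate companion to the multivariate
#' classification.
#'
#' @param ft an `fc_feature_table` for one seed.
#' @return data.frame of class `fc_edge_t`: target region id/name,
#'   group means, `t`, `df`, `p` per path (atlas order).
#' @export
edge_group_t <- function(ft) {
  g_fhd <- ft$labels == "FHD"
  if (!any(g_fhd) || all(g_fhd)) stop_fmt("both groups must be present")
  n1 <- sum(g_fhd); n2 <- sum(!g_fhd)
  res <- lapply(seq_len(ncol(ft$X)), function(j) {
    ts <- two_sample_t(ft$X[g_fhd, j], ft$X[!g_fhd, j])
    data.frame(target_id = ft$feature_map$region_id[j],
               target_name = ft$feature_map$name[j],
               group_mean_fhd = mean(ft$X[g_fhd, j]),
               group_mean_control = mean(ft$X[!g_fhd, j]),
               t = ts$t, df = ts$df, p = ts$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  stopifnot(all(out$df == n1 + n2 - 2))
  class(out) <- c("fc_edge_t", "data.frame")
  out
}

#' Correlation between pattern values and univariate t values
#'
#' Pearson correlation across paths between the mean Haufe pattern and the
#' edge-wise group t statistics, with df = n_paths - 2. A strong positive
#' correlation indicates that paths with larger group differences (in
#' either direction) contribute more to the classification.
#'
#' @param mean_pattern length-p mean pattern vector.
#' @param t_values length-p vector of edge t statistics.
#' @return list with `r`, `df`, `p` (two-sided).
#' @export
pattern_t_correlation <- function(mean_pattern, t_values) {
  if (length(mean_pattern) != length(t_values))
    stop_fmt("vectors must have equal length")
  n <- length(mean_pattern)
  if (n < 3) stop_fmt("need at least 3 paths")
  if (sd(mean_pattern) == 0 || sd(t_values) == 0)
    stop_fmt("zero variance input")
  r <- cor(mean_pattern, t_values)
  df <- n - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Rank FC paths by mean pattern value
#'
#' Returns the k most positive and k most negative paths of an edge
#' pattern table. Ties are broken by atlas order.
#'
#' @param edge_table data.frame with at least `target_id`, `target_name`
#'   and `mean_pattern_value` columns (see [edge_pattern_table()]).
#' @param k number of paths per direction.
#' @return list with data.frames `top_positive` and `top_negative`.
#' @export
rank_paths <- function(edge_table, k) {
  if (k > nrow(edge_table)) stop_fmt("k exceeds path count")
  ord <- order(-edge_table$mean_pattern_value,
               seq_len(nrow(edge_table)))  # ties: atlas order
  desc <- edge_table[ord, , drop = FALSE]
  asc <- edge_table[order(edge_table$mean_pattern_value,
                          seq_len(nrow(edge_table))), , drop = FALSE]
  list(top_positive = utils::head(desc, k),
       top_negative = utils::head(asc, k))
}

#' Combined per-path report for one seed
#'
#' Joins the mean Haufe pattern from the classification run with the
#' edge-wise two-sample t statistics and appends the pattern-vs-t
#' correlation as an attribute.
#'
#' @param dists an `fc_seed_dists` with a `mean_pattern`.
#' @param ft the seed's `fc_feature_table` (full cohort).
#' @return data.frame of class `fc_edge_patterns` with columns of
#'   [edge_group_t()] plus `mean_pattern_value`; attribute `correlation`
#'   holds the [pattern_t_correlation()] result.
#' @export
edge_pattern_table <- function(dists, ft) {
  et <- edge_group_t(ft)
  if (is.null(dists$mean_pattern))
    stop_fmt("seed distributions carry no mean pattern")
  stopifnot(length(dists$mean_pattern) == nrow(et))
  et$mean_pattern_value <- as.vector(dists$mean_pattern)
  attr(et, "correlation") <- pattern_t_correlation(et$mean_pattern_value,
                                                   et$t)
  class(et) <- c("fc_edge_patterns", class(et))
  et
}
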