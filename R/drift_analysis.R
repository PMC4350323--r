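# Sample-level drift summaries of PAS profiles: correlation clustering,
# PCA embedding, and passage-ordered trend classification.

#' Pearson correlation of samples with hierarchical clustering
#'
#' Correlates PAS column vectors (samples) across pathways and clusters them
#' hierarchically with distance 1 - r and complete linkage. Samples with a
#' constant PAS profile have undefined correlation and are excluded with a
#' warning.
#'
#' @param pas A \code{pas_matrix} with >= 2 samples and >= 2 pathways.
#' @param linkage Agglomeration method for \code{\link[stats]{hclust}},
#'   default \code{"complete"}.
#' @return List of class \code{correlation_matrix}: \code{cor} (sample x
#'   sample Pearson r), \code{order} (dendrogram leaf order, sample ids),
#'   \code{hclust}, \code{excluded} (sample ids dropped), and the matching
#'   \code{sample_info}.
#' @export
correlation_cluster <- function(pas, linkage = "complete") {
  stopifnot(inherits(pas, "pas_matrix"))
  V <- pas$values
  V <- V[stats::complete.cases(V), , drop = FALSE]
  if (nrow(V) < 2L || ncol(V) < 2L)
    stop("need >= 2 pathways and >= 2 samples")
  sds <- apply(V, 2, stats::sd)
  excluded <- colnames(V)[sds == 0]
  if (length(excluded)) {
    warning("constant PAS profile(s) excluded from correlation: ",
            paste(excluded, collapse = ", "))
    V <- V[, sds > 0, drop = FALSE]
  }
  if (ncol(V) < 2L) stop("fewer than 2 non-constant samples")
  C <- stats::cor(V)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  hc <- stats::hclust(stats::as.dist(1 - C), method = linkage)
  info <- pas$sample_info[match(colnames(V), pas$sample_info$sample_id), ,
                          drop = FALSE]
  rownames(info) <- NULL
  structure(list(cor = C, order = colnames(V)[hc$order], hclust = hc,
                 excluded = excluded, sample_info = info),
            class = "correlation_matrix")
}

#' Mean between-group correlation
#'
#' Average Pearson r over all (sample of group a, sample of group b) pairs.
#'
#' @param cm A \code{correlation_matrix}.
#' @param group_a,group_b Group labels.
#' @return Single numeric.
#' @export
mean_between_group_cor <- function(cm, group_a, group_b) {
  stopifnot(inherits(cm, "correlation_matrix"))
  ia <- cm$sample_info$group == group_a
  ib <- cm$sample_info$group == group_b
  if (!any(ia) || !any(ib)) stop("empty group")
  mean(cm$cor[ia, ib])
}

#' PCA embedding of samples in PAS space
#'
#' Samples are observations, pathways are variables; variables are centered
#' but not scaled, and components come from the SVD (\code{prcomp}). The
#' first \code{n_components} coordinates are returned together with the
#' explained-variance fractions.
#'
#' @param pas A \code{pas_matrix} with >= 4 samples.
#' @param n_components Number of leading components, default 3 (truncated to
#'   the rank with a warning if larger).
#' @return List of class \code{pca_embedding}: \code{scores} (sample x
#'   component), \code{explained} (fractions, all components),
#'   \code{sample_info}.
#' @export
pca_embed <- function(pas, n_components = 3) {
  stopifnot(inherits(pas, "pas_matrix"))
  V <- pas$values
  V <- V[stats::complete.cases(V), , drop = FALSE]
  if (ncol(V) < 4L) stop("need >= 4 samples for a PCA embedding")
  pc <- stats::prcomp(t(V), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-12)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncated")
    n_components <- rank
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  info <- pas$sample_info[match(colnames(V), pas$sample_info$sample_id), ,
                          drop = FALSE]
  rownames(info) <- NULL
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained = explained, sample_info = info),
            class = "pca_embedding")
}

#' Euclidean distance between two group centroids in the embedding
#'
#' @param emb A \code{pca_embedding}.
#' @param group_a,group_b Group labels.
#' @return Single numeric distance over the embedded components.
#' @export
centroid_distance <- function(emb, group_a, group_b) {
  stopifnot(inherits(emb, "pca_embedding"))
  ca <- colMeans(emb$scores[emb$sample_info$group == group_a, , drop = FALSE])
  cb <- colMeans(emb$scores[emb$sample_info$group == group_b, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Passage-ordered drift classification of pathways
#'
#' Per pathway, mean PAS is taken within each ordered passage group and the
#' successive differences classify the trend: \code{steadily_up} if every
#' difference exceeds \code{flat_threshold}, \code{steadily_down} if every
#' difference is below \code{-flat_threshold}, \code{flat} if all
#' differences are within the threshold, otherwise \code{non_monotonic}.
#'
#' @param pas A \code{pas_matrix} whose sample groups are passage labels.
#' @param passage_levels Character vector of >= 3 group labels in increasing
#'   passage order (e.g. \code{c("P30", "P50", "P70", "P80")}).
#' @param flat_threshold Minimal mean-PAS step treated as a real change,
#'   default 0.05 PAS units.
#' @return data.frame of class \code{drift_profile}: pathway_id, one
#'   \code{mean_<level>} column per passage group, and \code{trend}.
#' @export
passage_drift <- function(pas, passage_levels, flat_threshold = 0.05) {
  stopifnot(inherits(pas, "pas_matrix"), length(passage_levels) >= 3L,
            flat_threshold >= 0)
  info <- pas$sample_info
  for (lv in passage_levels)
    if (!any(info$group == lv)) stop("empty passage group '", lv, "'")
  means <- vapply(passage_levels, function(lv)
    rowMeans(pas$values[, info$group == lv, drop = FALSE]),
    numeric(nrow(pas$values)))
  if (!is.matrix(means))
    means <- matrix(means, nrow = 1L,
                    dimnames = list(rownames(pas$values), passage_levels))
  classify <- function(m) {
    if (any(!is.finite(m))) return(NA_character_)
    d <- diff(m)
    if (all(d > flat_threshold)) "steadily_up"
    else if (all(d < -flat_threshold)) "steadily_down"
    else if (all(abs(d) <= flat_threshold)) "flat"
    else "non_monotonic"
  }
  trend <- apply(means, 1L, classify)
  out <- data.frame(pathway_id = rownames(pas$values), means,
                    trend = trend, stringsAsFactors = FALSE,
                    check.names = FALSE)
  colnames(out)[1L + seq_along(passage_levels)] <-
    paste0("mean_", passage_levels)
  rownames(out) <- NULL
  class(out) <- c("drift_profile", "data.frame")
  out
}
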