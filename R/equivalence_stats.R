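# Standardized-margin equivalence tests on PAS distributions.
#
# The null hypothesis is a relevant DIFFERENCE between groups; rejecting it
# declares the groups similar (equivalent). Following the standardized-
# difference framework, the pairwise test rejects when the pooled-variance
# |t| falls below the alpha-quantile of its distribution at the equivalence
# boundary — a noncentral F quantile at noncentrality
#   lambda = eps^2 * nA*nB/(nA+nB)          (pairwise, eps default 0.74)
#   lambda = N * eps^2                      (k-group ANOVA, eps default
#                                            0.74/sqrt(2), so the margins
#                                            are comparable across tests).
# Margins are in pooled-SD units, which makes verdicts comparable across
# pathways with different PAS scales.

#' Noncentral F quantile
#'
#' Returns q with \code{CDF_ncF(df1, df2, ncp)(q) = prob}, refined by root
#' bisection on \code{stats::pf} to a CDF round-trip error below 1e-10
#' (the closed-form \code{stats::qf} start point alone is not that tight).
#'
#' @param prob Probability in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @param ncp Noncentrality parameter (>= 0); 0 gives the central quantile.
#' @return The quantile (single numeric).
#' @export
noncentral_f_quantile <- function(prob, df1, df2, ncp = 0) {
  stopifnot(prob > 0, prob < 1, df1 >= 1, df2 >= 1, ncp >= 0)
  q0 <- stats::qf(prob, df1, df2, ncp = ncp)
  if (!is.finite(q0) || q0 <= 0) q0 <- 1
  f <- function(q) stats::pf(q, df1, df2, ncp = ncp) - prob
  lo <- q0 / 2; hi <- q0 * 2
  while (f(lo) > 0 && lo > .Machine$double.xmin) lo <- lo / 2
  while (f(hi) < 0) {
    hi <- hi * 2
    if (!is.finite(hi)) stop("noncentral F quantile bracket diverged (prob=",
                             prob, ", df1=", df1, ", df2=", df2, ", ncp=", ncp, ")")
  }
  r <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-14,
                      f.lower = f(lo), f.upper = f(hi))
  q <- r$root
  if (abs(stats::pf(q, df1, df2, ncp = ncp) - prob) > 1e-8)
    stop("noncentral F quantile failed to converge (prob=", prob,
         ", df1=", df1, ", df2=", df2, ", ncp=", ncp, ")")
  q
}

new_equivalence_result <- function(comparison, statistic, df, noncentrality,
                                   critical_value, epsilon, alpha, equivalent,
                                   mean_pas_per_group, pathway_id = NA_character_) {
  structure(list(comparison = comparison, pathway_id = pathway_id,
                 statistic = statistic, df = df, noncentrality = noncentrality,
                 critical_value = critical_value, epsilon = epsilon,
                 alpha = alpha, equivalent = equivalent,
                 mean_pas_per_group = mean_pas_per_group),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat("equivalence test [", paste(x$comparison, collapse = " vs "), "]: ",
      "statistic = ", signif(x$statistic, 4),
      ", critical = ", signif(x$critical_value, 4),
      ", eps = ", signif(x$epsilon, 4),
      " -> ", if (isTRUE(x$equivalent)) "EQUIVALENT" else "not equivalent",
      "\n", sep = "")
  invisible(x)
}

#' Pairwise equivalence t-test
#'
#' Pooled-variance two-sample t statistic; equivalence (similarity) is
#' declared when |t| < C with C the square root of the alpha-quantile of the
#' noncentral F(1, nA+nB-2) distribution at
#' \code{lambda = epsilon^2 * nA*nB/(nA+nB)}. With zero pooled variance the
#' test is degenerate: equivalence iff the two means are equal (logged).
#'
#' @param x,y Numeric PAS values of the two groups (each n >= 2).
#' @param epsilon Standardized equivalence margin (pooled-SD units),
#'   default 0.74.
#' @param alpha Significance level, default 0.05.
#' @param labels Group labels for reporting.
#' @return An \code{equivalence_result}.
#' @export
equivalence_t_test <- function(x, y, epsilon = 0.74, alpha = 0.05,
                               labels = c("A", "B")) {
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)),
            epsilon > 0, alpha > 0, alpha < 1)
  n1 <- length(x); n2 <- length(y); df <- n1 + n2 - 2L
  lambda <- epsilon^2 * n1 * n2 / (n1 + n2)
  crit <- sqrt(noncentral_f_quantile(alpha, 1, df, lambda))
  sp2 <- ((n1 - 1L) * stats::var(x) + (n2 - 1L) * stats::var(y)) / df
  if (sp2 == 0) {
    message("zero pooled variance; degenerate equivalence verdict by mean equality")
    tt <- if (mean(x) == mean(y)) 0 else Inf
  } else {
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  new_equivalence_result(
    comparison = labels, statistic = tt, df = df, noncentrality = lambda,
    critical_value = crit, epsilon = epsilon, alpha = alpha,
    equivalent = abs(tt) < crit,
    mean_pas_per_group = stats::setNames(c(mean(x), mean(y)), labels))
}

#' k-group equivalence F-test (equivalence one-way ANOVA)
#'
#' One-way ANOVA F statistic over k >= 3 groups; equivalence is declared
#' when F < the alpha-quantile of the noncentral F(k-1, N-k) distribution at
#' \code{lambda = N * epsilon^2}. With zero within-group variance the test
#' is degenerate: equivalence iff all group means are equal (logged).
#'
#' @param groups List of k numeric vectors (each n >= 2). The study design
#'   uses k of 3 or 4; k = 2 is allowed (the F statistic is then the squared
#'   pooled t) mainly to expose the pairwise/ANOVA consistency of the two
#'   constructions.
#' @param epsilon Standardized margin, default \code{0.74/sqrt(2)} so that
#'   verdicts are comparable with the pairwise test at margin 0.74.
#' @param alpha Significance level, default 0.05.
#' @return An \code{equivalence_result}.
#' @export
equivalence_f_test <- function(groups, epsilon = 0.74 / sqrt(2), alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L, epsilon > 0,
            alpha > 0, alpha < 1)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 samples")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("G", seq_along(groups))
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  lambda <- N * epsilon^2
  crit <- noncentral_f_quantile(alpha, k - 1, N - k, lambda)
  if (ssw == 0) {
    message("zero within-group variance; degenerate equivalence verdict by mean equality")
    Fstat <- if (ssb == 0) 0 else Inf
  } else {
    Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  }
  new_equivalence_result(
    comparison = labels, statistic = Fstat, df = c(k - 1L, N - k),
    noncentrality = lambda, critical_value = crit, epsilon = epsilon,
    alpha = alpha, equivalent = Fstat < crit,
    mean_pas_per_group = stats::setNames(m, labels))
}

# all subsets of size >= 2, largest first
group_subsets <- function(labels) {
  k <- length(labels)
  subs <- list()
  for (size in seq(k, 2L)) {
    cmb <- utils::combn(labels, size, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  subs
}

#' Venn assignment of pathways by group-wise PAS equivalence
#'
#' For every pathway, every subset of groups of size >= 2 is tested for
#' equivalence (pairwise t-test; 3- and 4-group F-test), and the pathway is
#' assigned to the Venn region of the LARGEST subset declared equivalent
#' (ties broken by the smallest test statistic). The direction tag is the
#' sign of the mean PAS pooled over the assigned subset's samples. Pathways
#' with no equivalent subset remain unassigned (region NA).
#'
#' @param pas A \code{pas_matrix}.
#' @param epsilon_pair Margin for pairwise tests, default 0.74.
#' @param epsilon_multi Margin for 3-/4-group tests, default
#'   \code{0.74/sqrt(2)}.
#' @param alpha Significance level, default 0.05. No multiplicity correction
#'   is applied across pathways or subsets.
#' @param group_order Canonical group order for region labels; defaults to
#'   order of appearance in \code{pas$sample_info}.
#' @return Object of class \code{venn_summary}: list with
#'   \code{assignments} (data.frame pathway_id, region, size, statistic,
#'   critical, direction), \code{counts} (named region -> count), and
#'   \code{tests} (long data.frame of every subset test).
#' @export
venn_similarity <- function(pas, epsilon_pair = 0.74,
                            epsilon_multi = 0.74 / sqrt(2), alpha = 0.05,
                            group_order = NULL) {
  stopifnot(inherits(pas, "pas_matrix"))
  info <- pas$sample_info
  if (is.null(group_order)) group_order <- unique(info$group)
  glabs <- group_order[group_order %in% info$group]
  sizes <- table(factor(info$group, glabs))
  if (length(glabs) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 samples each")
  idx <- lapply(stats::setNames(glabs, glabs),
                function(g) which(info$group == g))
  subs <- group_subsets(glabs)
  region_id <- function(members) paste(members, collapse = "+")
  # critical values depend only on the subset's sizes — compute once
  crits <- lapply(subs, function(s) {
    n <- vapply(idx[s], length, integer(1))
    if (length(s) == 2L) {
      lam <- epsilon_pair^2 * n[1] * n[2] / sum(n)
      sqrt(noncentral_f_quantile(alpha, 1, sum(n) - 2L, lam))
    } else {
      lam <- sum(n) * epsilon_multi^2
      noncentral_f_quantile(alpha, length(s) - 1L, sum(n) - length(s), lam)
    }
  })
  pw_ids <- rownames(pas$values)
  tests <- list(); assigns <- list()
  for (pw in pw_ids) {
    v <- pas$values[pw, ]
    if (any(!is.finite(v))) {
      assigns[[pw]] <- data.frame(pathway_id = pw, region = NA_character_,
                                  size = NA_integer_, statistic = NA_real_,
                                  critical = NA_real_, direction = NA_character_,
                                  stringsAsFactors = FALSE)
      next
    }
    best <- NULL
    for (i in seq_along(subs)) {
      s <- subs[[i]]
      gvals <- lapply(idx[s], function(j) v[j])
      res <- if (length(s) == 2L) {
        suppressMessages(equivalence_t_test(gvals[[1]], gvals[[2]],
                                            epsilon = epsilon_pair,
                                            alpha = alpha, labels = s))
      } else {
        suppressMessages(equivalence_f_test(gvals, epsilon = epsilon_multi,
                                            alpha = alpha))
      }
      stat_cmp <- if (length(s) == 2L) abs(res$statistic) else res$statistic
      tests[[length(tests) + 1L]] <- data.frame(
        pathway_id = pw, comparison = region_id(s), k = length(s),
        statistic = res$statistic, critical = res$critical_value,
        equivalent = res$equivalent, stringsAsFactors = FALSE)
      if (res$equivalent &&
          (is.null(best) || length(s) > length(best$members) ||
           (length(s) == length(best$members) && stat_cmp < best$stat_cmp))) {
        best <- list(members = s, stat_cmp = stat_cmp, res = res)
      }
    }
    if (is.null(best)) {
      assigns[[pw]] <- data.frame(pathway_id = pw, region = NA_character_,
                                  size = NA_integer_, statistic = NA_real_,
                                  critical = NA_real_, direction = NA_character_,
                                  stringsAsFactors = FALSE)
    } else {
      pooled <- mean(v[unlist(idx[best$members])])
      assigns[[pw]] <- data.frame(
        pathway_id = pw, region = region_id(best$members),
        size = length(best$members), statistic = best$res$statistic,
        critical = best$res$critical_value,
        direction = if (pooled > 0) "up" else if (pooled < 0) "down" else "zero",
        stringsAsFactors = FALSE)
    }
  }
  assignments <- do.call(rbind, assigns)
  rownames(assignments) <- NULL
  assigned <- assignments[!is.na(assignments$region), , drop = FALSE]
  counts <- table(assigned$region)
  structure(list(assignments = assignments,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 tests = do.call(rbind, tests),
                 groups = glabs, epsilon_pair = epsilon_pair,
                 epsilon_multi = epsilon_multi, alpha = alpha),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("venn_summary over groups:", paste(x$groups, collapse = ", "), "\n")
  if (length(x$counts)) {
    for (r in names(sort(x$counts, decreasing = TRUE)))
      cat("  ", r, ": ", x$counts[[r]], " pathway(s)\n", sep = "")
  }
  cat("  unassigned: ", sum(is.na(x$assignments$region)), "\n", sep = "")
  invisible(x)
}

#' Flag near-zero pathways in the all-group Venn region
#'
#' Among pathways assigned to the full region (equivalent across all
#' groups), flags those whose grand mean |PAS| is at most
#' \code{delta} times the pooled within-group SD of that pathway's PAS —
#' pathways deviating around zero similarly in every group.
#'
#' @param pas A \code{pas_matrix}.
#' @param venn A \code{venn_summary} computed from \code{pas}.
#' @param delta Standardized near-zero margin, default 0.74.
#' @return Character vector of flagged pathway ids.
#' @export
near_zero_pathways <- function(pas, venn, delta = 0.74) {
  stopifnot(inherits(pas, "pas_matrix"), inherits(venn, "venn_summary"))
  full <- paste(venn$groups, collapse = "+")
  cand <- venn$assignments$pathway_id[!is.na(venn$assignments$region) &
                                        venn$assignments$region == full]
  if (length(cand) == 0L) return(character(0))
  info <- pas$sample_info
  flagged <- character(0)
  for (pw in cand) {
    v <- pas$values[pw, ]
    ssw <- 0; dfw <- 0
    for (g in venn$groups) {
      gv <- v[info$group == g]
      ssw <- ssw + sum((gv - mean(gv))^2)
      dfw <- dfw + length(gv) - 1L
    }
    pooled_sd <- sqrt(ssw / dfw)
    if (abs(mean(v)) <= delta * pooled_sd) flagged <- c(flagged, pw)
  }
  flagged
}

#' Write a Venn summary as JSON
#'
#' JSON object region -> \{count, pathway_ids, directions\}.
#'
#' @param venn A \code{venn_summary}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_venn_json <- function(venn, path) {
  stopifnot(inherits(venn, "venn_summary"))
  a <- venn$assignments[!is.na(venn$assignments$region), , drop = FALSE]
  out <- lapply(split(a, a$region), function(d)
    list(count = nrow(d), pathway_ids = d$pathway_id, directions = d$direction))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
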