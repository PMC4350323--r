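# Pathway Activation Strength (PAS) scoring.
#
# For a case sample against a within-dataset reference group, each gene n
# contributes ARR_n * BTIF_n * log10(CNR_n) to its pathway's PAS:
#   CNR_n  case-to-normal ratio: expression in the case sample divided by the
#          mean expression over the reference samples (linear scale);
#   BTIF_n 0/1 significance flag, decided at case-GROUP level: pooled-variance
#          two-sided Student's t-test on log2 values, BH-FDR adjusted, plus a
#          |fold-change| >= 1.5 gate — or universally 1 in unfiltered mode;
#   ARR_n  the gene's activator/repressor role coefficient in the pathway.
# Positive PAS = pathway up-regulation.

#' Per-gene case-to-normal ratios
#'
#' @param case_sample Named numeric vector (or 1-column matrix) of linear
#'   intensities for one case sample.
#' @param reference Gene x sample matrix of reference-group intensities
#'   (linear scale, positive).
#' @param ref_center Reference centering: \code{"arithmetic"} (default) or
#'   \code{"geometric"} mean of the reference samples.
#' @return Named numeric vector of strictly positive ratios over the genes
#'   shared by case and reference; genes missing from the reference are
#'   dropped with a warning.
#' @export
compute_cnr <- function(case_sample, reference,
                        ref_center = c("arithmetic", "geometric")) {
  ref_center <- match.arg(ref_center)
  if (is.matrix(case_sample)) {
    stopifnot(ncol(case_sample) == 1L)
    case_sample <- stats::setNames(case_sample[, 1L], rownames(case_sample))
  }
  stopifnot(!is.null(names(case_sample)), is.matrix(reference),
            ncol(reference) >= 1L)
  if (any(case_sample <= 0) || any(reference <= 0))
    stop("expression values must be strictly positive (apply the floor first)")
  genes <- intersect(names(case_sample), rownames(reference))
  missing <- setdiff(names(case_sample), rownames(reference))
  if (length(missing))
    warning(length(missing), " gene(s) missing from reference dropped: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ...")
  if (length(genes) == 0L) stop("no genes shared with the reference")
  ctr <- if (ref_center == "arithmetic")
    rowMeans(reference[genes, , drop = FALSE])
  else
    exp(rowMeans(log(reference[genes, , drop = FALSE])))
  case_sample[genes] / ctr
}

#' Group-level differential expression against a reference
#'
#' Per gene: two-sided pooled-variance Student's t-test on log2-transformed
#' values (case group vs reference group), BH step-up FDR adjustment across
#' all tested genes, and group fold change on the linear scale (ratio of
#' case-group mean to reference-group mean). With fewer than 2 samples on
#' either side all p-values are 1 (with a warning); a gene with zero
#' variance in both groups and equal means gets p = 1.
#'
#' @param case_matrix Gene x sample matrix of case-group intensities.
#' @param reference_matrix Gene x sample matrix of reference intensities.
#' @return data.frame(gene, FC, p, q) over the shared gene universe.
#' @export
test_differential <- function(case_matrix, reference_matrix) {
  stopifnot(is.matrix(case_matrix), is.matrix(reference_matrix))
  genes <- intersect(rownames(case_matrix), rownames(reference_matrix))
  if (length(genes) == 0L)
    stop("case and reference matrices share no genes")
  X <- case_matrix[genes, , drop = FALSE]
  Y <- reference_matrix[genes, , drop = FALSE]
  n1 <- ncol(X); n2 <- ncol(Y)
  FC <- rowMeans(X) / rowMeans(Y)
  if (n1 < 2L || n2 < 2L) {
    warning("fewer than 2 samples in case or reference group; all p set to 1")
    p <- rep(1, length(genes))
  } else {
    lx <- log2(X); ly <- log2(Y)
    m1 <- rowMeans(lx); m2 <- rowMeans(ly)
    v1 <- rowSums((lx - m1)^2) / (n1 - 1L)
    v2 <- rowSums((ly - m2)^2) / (n2 - 1L)
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tt <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tt), df)
    zero <- se == 0
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, FC = unname(FC), p = unname(p), q = unname(q),
             stringsAsFactors = FALSE)
}

#' Significance flags (BTIF) from fold change and FDR
#'
#' Filtered mode: \code{BTIF = 1} iff \code{max(FC, 1/FC) >= fc_threshold}
#' and \code{q < fdr}. Unfiltered mode: \code{BTIF = 1} for every gene, so
#' PAS accumulates the expression level of all member genes.
#'
#' @param FC Linear-scale group fold changes (> 0).
#' @param q BH-adjusted p-values in [0, 1].
#' @param mode \code{"filtered"} or \code{"unfiltered"}.
#' @param fc_threshold Fold-change gate, default 1.5.
#' @param fdr FDR gate, default 0.05.
#' @return Integer 0/1 vector.
#' @export
compute_btif <- function(FC, q, mode = c("filtered", "unfiltered"),
                         fc_threshold = 1.5, fdr = 0.05) {
  mode <- match.arg(mode)
  stopifnot(all(FC > 0), all(q >= 0 & q <= 1))
  if (mode == "unfiltered") return(rep(1L, length(FC)))
  as.integer(pmax(FC, 1 / FC) >= fc_threshold & q < fdr)
}

#' PAS of one pathway for one sample
#'
#' \code{PAS = sum over member genes n of ARR_n * BTIF_n * log10(CNR_n)}.
#' Member genes absent from the ratio vector contribute 0 (with a warning);
#' a pathway with no member gene present is undefined and returns NA.
#'
#' @param pathway A \code{\link{pathway_definition}}.
#' @param cnr Named per-gene case-to-normal ratios.
#' @param btif Named (or same-order) 0/1 flags for the genes of \code{cnr}.
#' @return Single numeric PAS value (NA if no member gene is present).
#' @export
compute_pas <- function(pathway, cnr, btif) {
  stopifnot(inherits(pathway, "pathway_definition"))
  if (is.null(names(btif))) names(btif) <- names(cnr)
  genes <- intersect(names(pathway$gene_roles), names(cnr))
  if (length(genes) == 0L) {
    warning("pathway '", pathway$pathway_id,
            "' has no member gene in the matrix; PAS undefined")
    return(NA_real_)
  }
  absent <- setdiff(names(pathway$gene_roles), genes)
  if (length(absent))
    warning("pathway '", pathway$pathway_id, "': ", length(absent),
            " member gene(s) absent contribute 0")
  sum(pathway$gene_roles[genes] * btif[genes] * log10(cnr[genes]))
}

#' PAS matrix for a multi-dataset study
#'
#' Each dataset is processed separately against its designated within-dataset
#' reference group: per-sample CNRs, one group-level BTIF per (dataset, case
#' group) shared by that group's samples, and one PAS column per scored
#' sample. Columns from all datasets are concatenated with group labels. A
#' group that is its own reference (e.g. the Young group in the donor-age
#' study, or the low-passage group in a senescence series) is scored
#' unfiltered by default: against its own group mean every gene has FC = 1
#' and p = 1, so filtered-mode PAS would be identically zero.
#'
#' @param matrices Named list of \code{\link{expression_matrix}} objects
#'   (names = dataset ids).
#' @param groups Named character vector sample_id -> group label for every
#'   sample; samples labelled \code{"excluded"} are never scored.
#' @param collection A \code{\link{pathway_collection}}.
#' @param reference_groups Named character vector dataset_id -> label of that
#'   dataset's reference group.
#' @param mode \code{"filtered"} (default) or \code{"unfiltered"} for the
#'   non-reference case groups.
#' @param score_groups Labels to score (default: every non-excluded label
#'   present in \code{groups}). Reference-only labels can thus be left out.
#' @param reference_scoring How to score samples of a dataset's own reference
#'   group: \code{"unfiltered"} (default), \code{"filtered"}, or
#'   \code{"skip"}.
#' @param fc_threshold,fdr Gates passed to \code{\link{compute_btif}}.
#' @param ref_center Passed to \code{\link{compute_cnr}}.
#' @return Object of class \code{pas_matrix}: list with \code{values}
#'   (pathway x sample matrix), \code{sample_info}
#'   (data.frame sample_id, dataset_id, group), \code{mode} and
#'   \code{reference_groups}.
#' @export
compute_pas_matrix <- function(matrices, groups, collection, reference_groups,
                               mode = c("filtered", "unfiltered"),
                               score_groups = NULL,
                               reference_scoring = c("unfiltered", "filtered", "skip"),
                               fc_threshold = 1.5, fdr = 0.05,
                               ref_center = "arithmetic") {
  mode <- match.arg(mode)
  reference_scoring <- match.arg(reference_scoring)
  stopifnot(inherits(collection, "pathway_collection"),
            is.list(matrices), !is.null(names(matrices)))
  if (is.null(score_groups))
    score_groups <- setdiff(unique(groups), "excluded")
  cols <- list(); info <- list()
  for (ds in names(matrices)) {
    V <- matrices[[ds]]$values
    samp <- colnames(V)
    g <- groups[samp]
    if (any(is.na(g))) stop("dataset '", ds, "': unannotated sample(s)")
    if (!ds %in% names(reference_groups))
      stop("dataset '", ds, "' has no designated reference group")
    refg <- reference_groups[[ds]]
    ref_samp <- samp[g == refg]
    if (length(ref_samp) == 0L)
      stop("dataset '", ds, "': reference group '", refg, "' has no samples")
    refM <- V[, ref_samp, drop = FALSE]
    A <- arr_matrix(collection, rownames(V))
    pw_present <- rowSums(A != 0) > 0
    for (grp in intersect(unique(g), score_groups)) {
      case_samp <- samp[g == grp]
      if (grp == refg && reference_scoring == "skip") next
      grp_mode <- if (grp == refg) reference_scoring else mode
      if (grp_mode == "unfiltered") {
        btif <- rep(1L, nrow(V))
      } else {
        de <- test_differential(V[, case_samp, drop = FALSE], refM)
        btif <- compute_btif(de$FC, de$q, mode = "filtered",
                             fc_threshold = fc_threshold, fdr = fdr)
      }
      ctr <- if (ref_center == "arithmetic") rowMeans(refM)
             else exp(rowMeans(log(refM)))
      L <- log10(V[, case_samp, drop = FALSE] / ctr)  # genes x case samples
      pas <- A %*% (btif * L)
      pas[!pw_present, ] <- NA_real_
      cols[[length(cols) + 1L]] <- pas
      info[[length(info) + 1L]] <- data.frame(
        sample_id = case_samp, dataset_id = ds, group = grp,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cols) == 0L) stop("no samples were scored")
  values <- do.call(cbind, cols)
  sample_info <- do.call(rbind, info)
  colnames(values) <- sample_info$sample_id
  rownames(sample_info) <- NULL
  structure(list(values = values, sample_info = sample_info, mode = mode,
                 reference_groups = reference_groups),
            class = "pas_matrix")
}

#' @export
print.pas_matrix <- function(x, ...) {
  cat("pas_matrix: ", nrow(x$values), " pathways x ", ncol(x$values),
      " samples (mode: ", x$mode, ")\n", sep = "")
  print(table(x$sample_info$group))
  invisible(x)
}

#' Write a PAS matrix and its sample sidecar as TSV
#'
#' @param pas A \code{pas_matrix}.
#' @param path Output path for the pathway x sample table; the sidecar of
#'   sample -> dataset/group labels goes to \code{<path>.samples.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_pas_matrix <- function(pas, path) {
  stopifnot(inherits(pas, "pas_matrix"))
  tab <- data.frame(pathway_id = rownames(pas$values), pas$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pas$sample_info, paste0(path, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a PAS matrix written by \code{\link{write_pas_matrix}}
#'
#' @param path Path given to \code{\link{write_pas_matrix}}.
#' @param mode Mode tag to attach.
#' @return A \code{pas_matrix}.
#' @export
read_pas_matrix <- function(path, mode = "filtered") {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  sample_info <- utils::read.delim(paste0(path, ".samples.tsv"),
                                   header = TRUE, stringsAsFactors = FALSE)
  structure(list(values = values, sample_info = sample_info, mode = mode,
                 reference_groups = NULL),
            class = "pas_matrix")
}
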