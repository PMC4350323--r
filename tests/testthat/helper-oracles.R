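# Independent oracles used against the pipeline implementations.
# These are deliberately written as direct loops over scalar operations and
# share no code with the package internals.

# Benjamini-Hochberg step-up by the textbook recursion.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# Loop-based PAS for one dataset with one reference group: per-gene t-tests
# through stats::t.test, BH via bh_stepup, scalar CNR and PAS sums.
brute_pas_matrix <- function(mat, groups, collection, reference_group,
                             mode = "filtered", score_groups = NULL,
                             reference_scoring = "unfiltered",
                             fc_threshold = 1.5, fdr = 0.05) {
  V <- mat$values
  g <- groups[colnames(V)]
  ref_samp <- colnames(V)[g == reference_group]
  if (is.null(score_groups)) score_groups <- setdiff(unique(g), "excluded")
  ref_mean <- numeric(nrow(V))
  for (i in seq_len(nrow(V))) ref_mean[i] <- mean(V[i, ref_samp])
  pw_ids <- names(collection$pathways)
  out <- NULL; out_samples <- character(0)
  for (grp in intersect(unique(g), score_groups)) {
    case_samp <- colnames(V)[g == grp]
    grp_mode <- if (grp == reference_group) reference_scoring else mode
    btif <- rep(1L, nrow(V))
    if (grp_mode == "filtered") {
      p <- numeric(nrow(V)); fc <- numeric(nrow(V))
      for (i in seq_len(nrow(V))) {
        x <- log2(V[i, case_samp]); y <- log2(V[i, ref_samp])
        p[i] <- if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) 1
                else stats::t.test(x, y, var.equal = TRUE)$p.value
        fc[i] <- mean(V[i, case_samp]) / ref_mean[i]
      }
      q <- bh_stepup(p)
      for (i in seq_len(nrow(V)))
        btif[i] <- as.integer(max(fc[i], 1 / fc[i]) >= fc_threshold && q[i] < fdr)
    }
    for (s in case_samp) {
      pas <- rep(NA_real_, length(pw_ids))
      for (k in seq_along(pw_ids)) {
        pdef <- collection$pathways[[k]]
        acc <- NA_real_
        for (gene in names(pdef$gene_roles)) {
          i <- match(gene, rownames(V))
          if (is.na(i)) next
          cnr <- V[i, s] / ref_mean[i]
          term <- pdef$gene_roles[[gene]] * btif[i] * log10(cnr)
          acc <- if (is.na(acc)) term else acc + term
        }
        pas[k] <- acc
      }
      out <- cbind(out, pas)
      out_samples <- c(out_samples, s)
    }
  }
  dimnames(out) <- list(pw_ids, out_samples)
  out
}

# Random toy study: one dataset, reference + one case group, small enough
# for the brute oracle.
random_toy_study <- function(n_genes = 8, n_ref = 3, n_case = 3,
                             n_pathways = 3) {
  genes <- sprintf("t%02d", seq_len(n_genes))
  n <- n_ref + n_case
  V <- matrix(stats::runif(n_genes * n, 0.5, 20), n_genes, n,
              dimnames = list(genes, sprintf("s%02d", seq_len(n))))
  # shift some genes in the cases so the filter sometimes fires
  shift <- sample(n_genes, max(1L, n_genes %/% 3L))
  V[shift, n_ref + seq_len(n_case)] <- V[shift, n_ref + seq_len(n_case)] *
    stats::runif(length(shift), 1.5, 4)
  mat <- expression_matrix(V, "TOY")
  defs <- lapply(seq_len(n_pathways), function(k) {
    sz <- sample(2:max(3L, n_genes %/% 2L), 1L)
    gs <- sample(genes, sz)
    arr <- sample(c(-1, -0.5, 0.5, 1), sz, replace = TRUE)
    pathway_definition(sprintf("toy%02d", k), stats::setNames(arr, gs))
  })
  collection <- pathway_collection(defs, "toy")
  groups <- stats::setNames(rep(c("ref", "case"), c(n_ref, n_case)),
                            colnames(V))
  list(mat = mat, collection = collection, groups = groups)
}

# pas_matrix built directly from a value matrix, for stats/drift unit tests
make_pas <- function(values, groups, dataset_id = "DS", mode = "filtered") {
  structure(list(
    values = values,
    sample_info = data.frame(sample_id = colnames(values),
                             dataset_id = dataset_id, group = groups,
                             stringsAsFactors = FALSE),
    mode = mode, reference_groups = NULL), class = "pas_matrix")
}
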