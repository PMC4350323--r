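# Synthetic multi-dataset expression studies with known ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# several independent datasets, each with a within-dataset reference group
# and one or more case groups; per-pathway coordinated regulation of member
# genes whose direction follows each gene's activator/repressor role
# (activators up and repressors down when a pathway is "activated");
# multiplicative log-normal noise; and small dataset-level baseline offsets
# standing in for platform differences. Expression is emitted on the linear
# scale, exactly what expression_io consumes.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a random pathway collection
#'
#' Pathways get disjoint synthetic gene symbols; each gene is an activator
#' (ARR +1) with probability \code{activator_fraction}, else a repressor
#' (ARR -1). With \code{graded = TRUE} half of the assigned roles are
#' softened to +0.5 / -0.5.
#'
#' @param n_pathways Number of pathways (default 65, the size of a typical
#'   curated signaling collection).
#' @param genes_per_pathway Genes per pathway, default 20.
#' @param activator_fraction Probability a gene is an activator, default 0.75.
#' @param graded If TRUE, use the graded five-level roles.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @param name Collection label.
#' @return A \code{\link{pathway_collection}}.
#' @export
generate_pathway_collection <- function(n_pathways = 65, genes_per_pathway = 20,
                                        activator_fraction = 0.75,
                                        graded = FALSE, seed = NULL,
                                        name = "synthetic") {
  stopifnot(n_pathways >= 1L, genes_per_pathway >= 1L,
            activator_fraction >= 0, activator_fraction <= 1)
  with_seed(seed, {
    defs <- lapply(seq_len(n_pathways), function(i) {
      genes <- sprintf("g%05d", (i - 1L) * genes_per_pathway +
                         seq_len(genes_per_pathway))
      arr <- ifelse(stats::runif(genes_per_pathway) < activator_fraction, 1, -1)
      if (graded) {
        soft <- stats::runif(genes_per_pathway) < 0.5
        arr[soft] <- arr[soft] * 0.5
      }
      pathway_definition(sprintf("pw%02d", i), stats::setNames(arr, genes))
    })
    pathway_collection(defs, name)
  })
}

#' Synthetic study configuration
#'
#' @param datasets Named list; each element is
#'   \code{list(samples = named integer vector group -> count,
#'   reference = reference group label)}.
#' @param effect_map Numeric pathway x group matrix of log2 effect sizes
#'   applied to member genes (each gene's direction is the effect sign times
#'   the sign of its ARR); missing groups/pathways default to 0.
#' @param noise_sd Log2-scale SD of the per-measurement noise, default 0.3.
#' @param dataset_offset_sd Log2-scale SD of per-gene dataset baseline
#'   offsets, default 0.2 (emulates multi-platform pooling).
#' @param background_genes Genes outside every pathway, default 300.
#' @param baseline_log2_range Range of per-gene baseline log2 intensities,
#'   default \code{c(4, 12)}.
#' @param floor Expression floor, default 1e-6.
#' @return List of class \code{synthetic_study_config}.
#' @export
synthetic_study_config <- function(datasets, effect_map = NULL,
                                   noise_sd = 0.3, dataset_offset_sd = 0.2,
                                   background_genes = 300,
                                   baseline_log2_range = c(4, 12),
                                   floor = 1e-6) {
  stopifnot(is.list(datasets), length(datasets) >= 1L, !is.null(names(datasets)),
            noise_sd > 0, dataset_offset_sd >= 0, background_genes >= 0)
  for (ds in names(datasets)) {
    d <- datasets[[ds]]
    if (is.null(d$samples) || is.null(names(d$samples)) || any(d$samples < 1))
      stop("dataset '", ds, "': samples must be a named vector of positive counts")
    if (is.null(d$reference) || !d$reference %in% names(d$samples))
      stop("dataset '", ds, "': reference group must be one of its sample groups")
  }
  structure(list(datasets = datasets, effect_map = effect_map,
                 noise_sd = noise_sd, dataset_offset_sd = dataset_offset_sd,
                 background_genes = background_genes,
                 baseline_log2_range = baseline_log2_range, floor = floor),
            class = "synthetic_study_config")
}

# age sampling per group for the annotation table
sample_age <- function(group, n) {
  switch(group,
         Young  = sample(15:30, n, replace = TRUE),
         Middle = sample(40:55, n, replace = TRUE),
         Old    = sample(60:85, n, replace = TRUE),
         HGPS   = sample(2:16, n, replace = TRUE),
         ctrl   = sample(31:39, n, replace = TRUE),
         rep(NA_integer_, n))
}

#' Generate expression data for a synthetic study
#'
#' Per gene g and sample s of group G:
#' \code{log2 value = baseline_g + offset_(g, dataset) +
#' sign(ARR_g) * effect_map[pathway(g), G] + N(0, noise_sd^2)}, exported on
#' the linear scale (2^x). Reference groups carry zero effect unless the
#' effect map says otherwise. The ground truth records the expected PAS sign
#' per (pathway, group) as the sign of the planted effect.
#'
#' @param config A \code{\link{synthetic_study_config}}.
#' @param collection A \code{\link{pathway_collection}} (e.g. from
#'   \code{\link{generate_pathway_collection}}).
#' @param seed Optional integer seed.
#' @return List of class \code{synthetic_study}: \code{matrices} (named list
#'   of \code{expression_matrix}), \code{annotation} (with \code{group}
#'   column), \code{groups} (named vector sample -> label),
#'   \code{reference_groups}, \code{collection}, \code{config} and
#'   \code{ground_truth} (list with \code{pas_sign} pathway x group matrix).
#' @export
generate_expression <- function(config, collection, seed = NULL) {
  stopifnot(inherits(config, "synthetic_study_config"),
            inherits(collection, "pathway_collection"))
  with_seed(seed, {
    pw_ids <- pathway_ids(collection)
    gene2pw <- unlist(unname(lapply(collection$pathways, function(p)
      stats::setNames(rep(p$pathway_id, length(p$gene_roles)),
                      names(p$gene_roles)))))
    if (anyDuplicated(names(gene2pw)))
      stop("synthetic generation requires pathway-disjoint gene sets")
    arr_sign <- unlist(unname(lapply(collection$pathways, function(p)
      stats::setNames(sign(p$gene_roles), names(p$gene_roles)))))
    bg <- if (config$background_genes > 0)
      sprintf("bg%05d", seq_len(config$background_genes)) else character(0)
    genes <- c(names(gene2pw), bg)
    G <- length(genes)
    all_groups <- unique(unlist(lapply(config$datasets, function(d) names(d$samples))))
    # dense effect matrix, zero-filled
    E <- matrix(0, length(pw_ids), length(all_groups),
                dimnames = list(pw_ids, all_groups))
    if (!is.null(config$effect_map)) {
      em <- config$effect_map
      if (is.null(rownames(em)) || is.null(colnames(em)))
        stop("effect_map needs pathway rownames and group colnames")
      if (!all(rownames(em) %in% pw_ids) || !all(colnames(em) %in% all_groups))
        stop("effect_map references unknown pathways or groups")
      E[rownames(em), colnames(em)] <- em
    }
    # per-gene effect row index (NA for background genes => zero effect)
    gene_pw <- c(gene2pw, stats::setNames(rep(NA_character_, length(bg)), bg))
    gene_row <- match(gene_pw, pw_ids)
    gene_sign <- c(arr_sign, stats::setNames(rep(0, length(bg)), bg))
    baseline <- stats::runif(G, config$baseline_log2_range[1L],
                             config$baseline_log2_range[2L])
    names(baseline) <- genes
    matrices <- list(); ann <- list()
    for (ds in names(config$datasets)) {
      d <- config$datasets[[ds]]
      offset <- stats::rnorm(G, 0, config$dataset_offset_sd)
      n_tot <- sum(d$samples)
      grp_of <- rep(names(d$samples), d$samples)
      sids <- sprintf("%s_s%02d", ds, seq_len(n_tot))
      lg <- matrix(baseline + offset, G, n_tot) +
        matrix(stats::rnorm(G * n_tot, 0, config$noise_sd), G, n_tot)
      for (j in seq_len(n_tot)) {
        ci <- match(grp_of[j], colnames(E))
        eff <- E[cbind(gene_row, ci)]
        eff[is.na(eff)] <- 0
        lg[, j] <- lg[, j] + gene_sign * eff
      }
      dimnames(lg) <- list(genes, sids)
      matrices[[ds]] <- expression_matrix(2^lg, ds, floor = config$floor)
      ann[[ds]] <- data.frame(
        sample_id = sids, dataset_id = ds,
        condition = ifelse(grp_of == "HGPS", "HGPS", "normal"),
        age = NA_real_, passage = NA_real_, group = grp_of,
        stringsAsFactors = FALSE)
      for (g in unique(grp_of)) {
        sel <- grp_of == g
        ann[[ds]]$age[sel] <- sample_age(g, sum(sel))
      }
    }
    annotation <- do.call(rbind, ann)
    rownames(annotation) <- NULL
    groups <- stats::setNames(annotation$group, annotation$sample_id)
    reference_groups <- vapply(config$datasets, `[[`, character(1), "reference")
    ground_truth <- list(pas_sign = sign(E))
    structure(list(matrices = matrices, annotation = annotation,
                   groups = groups, reference_groups = reference_groups,
                   collection = collection, config = config,
                   ground_truth = ground_truth),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: ", length(x$matrices), " dataset(s), ",
      nrow(x$annotation), " samples, ",
      length(x$collection$pathways), " pathways\n", sep = "")
  print(table(x$annotation$group))
  invisible(x)
}

#' Ready-made study presets mirroring the published study designs
#'
#' \code{"aging4"}: four groups Young/Middle/Old/HGPS with 15/25/16/26
#' samples spread over 7 pseudo-datasets (4 donor-age datasets whose Young
#' samples are the reference; 3 progeria datasets with healthy control
#' fibroblasts as reference). Planted structure: pathways 1-13 share an
#' identical activation effect in Middle, Old and HGPS (Venn region
#' Middle+Old+HGPS); pathways 14-25 share it in Middle and HGPS only;
#' pathways 26-30 are null everywhere (equivalent and near zero in all four
#' groups); pathways 31-65 have distinct per-group effects. Effects are
#' +-1.6 log2 for planted regions and (0.8, 1.6, 2.4) log2 for the distinct
#' profiles.
#'
#' \code{"senescence"}: one dataset of cultured fibroblasts at 30 (3
#' samples, reference), 50 (4), 70 (3) and 80 (2) passages. Pathways 1-15
#' drift steadily up with passage, 16-30 steadily down, 31-40 are
#' non-monotonic, 41-65 flat.
#'
#' @param preset \code{"aging4"} or \code{"senescence"}.
#' @param seed Integer seed (default 1); the whole bundle is reproducible
#'   from it.
#' @param n_pathways,genes_per_pathway,activator_fraction Collection shape.
#' @return A \code{synthetic_study} whose \code{ground_truth} additionally
#'   carries \code{region} (planted Venn region per pathway, NA when none),
#'   \code{near_zero} (planted null pathway ids), \code{trend} (planted
#'   passage trends, senescence only), \code{score_groups} and
#'   \code{group_order}.
#' @export
make_paper_like_study <- function(preset = c("aging4", "senescence"), seed = 1,
                                  n_pathways = 65, genes_per_pathway = 20,
                                  activator_fraction = 0.75) {
  preset <- match.arg(preset)
  collection <- generate_pathway_collection(
    n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
    activator_fraction = activator_fraction, seed = seed,
    name = paste0("synthetic_", preset))
  pw <- pathway_ids(collection)
  if (preset == "aging4") {
    datasets <- list(
      AGE1 = list(samples = c(Young = 4, Middle = 6, Old = 4), reference = "Young"),
      AGE2 = list(samples = c(Young = 4, Middle = 6, Old = 4), reference = "Young"),
      AGE3 = list(samples = c(Young = 4, Middle = 6, Old = 4), reference = "Young"),
      AGE4 = list(samples = c(Young = 3, Middle = 7, Old = 4), reference = "Young"),
      HG1  = list(samples = c(HGPS = 18, ctrl = 4), reference = "ctrl"),
      HG2  = list(samples = c(HGPS = 5, ctrl = 3), reference = "ctrl"),
      HG3  = list(samples = c(HGPS = 3, ctrl = 3), reference = "ctrl"))
    E <- matrix(0, length(pw), 4, dimnames = list(pw, c("Young", "Middle", "Old", "HGPS")))
    i_triple <- seq_len(min(13L, length(pw)))
    i_pair   <- intersect(14:25, seq_along(pw))
    i_null   <- intersect(26:30, seq_along(pw))
    i_rest   <- setdiff(seq_along(pw), c(i_triple, i_pair, i_null))
    E[i_triple, c("Middle", "Old", "HGPS")] <- 1.6
    E[i_pair, c("Middle", "HGPS")] <- 1.6
    E[i_pair, "Old"] <- -1.6
    if (length(i_rest)) {
      s <- ifelse(seq_along(i_rest) %% 2L == 1L, 1, -1)
      E[i_rest, "Middle"] <- 0.8 * s
      E[i_rest, "Old"]    <- 1.6 * s
      E[i_rest, "HGPS"]   <- 2.4 * s
    }
    config <- synthetic_study_config(datasets, effect_map = E)
    study <- generate_expression(config, collection, seed = seed + 1L)
    region <- rep(NA_character_, length(pw))
    region[i_triple] <- "Middle+Old+HGPS"
    region[i_pair] <- "Middle+HGPS"
    region[i_null] <- "Young+Middle+Old+HGPS"
    study$ground_truth$region <- stats::setNames(region, pw)
    study$ground_truth$near_zero <- pw[i_null]
    study$ground_truth$score_groups <- c("Young", "Middle", "Old", "HGPS")
    study$ground_truth$group_order <- c("Young", "Middle", "Old", "HGPS")
  } else {
    datasets <- list(
      SEN1 = list(samples = c(P30 = 3, P50 = 4, P70 = 3, P80 = 2),
                  reference = "P30"))
    E <- matrix(0, length(pw), 4, dimnames = list(pw, c("P30", "P50", "P70", "P80")))
    i_up   <- seq_len(min(15L, length(pw)))
    i_down <- intersect(16:30, seq_along(pw))
    i_nm   <- intersect(31:40, seq_along(pw))
    E[i_up, c("P50", "P70", "P80")] <- rep(c(0.8, 1.6, 2.4), each = length(i_up))
    E[i_down, c("P50", "P70", "P80")] <- rep(-c(0.8, 1.6, 2.4), each = length(i_down))
    E[i_nm, c("P50", "P70", "P80")] <- rep(c(0.8, 1.6, 0.8), each = length(i_nm))
    config <- synthetic_study_config(datasets, effect_map = E)
    study <- generate_expression(config, collection, seed = seed + 1L)
    study$annotation$passage <- as.numeric(sub("^P", "", study$annotation$group))
    study$annotation$age <- NA_real_
    trend <- rep("flat", length(pw))
    trend[i_up] <- "steadily_up"
    trend[i_down] <- "steadily_down"
    trend[i_nm] <- "non_monotonic"
    study$ground_truth$trend <- stats::setNames(trend, pw)
    study$ground_truth$score_groups <- c("P30", "P50", "P70", "P80")
    study$ground_truth$group_order <- c("P30", "P50", "P70", "P80")
  }
  study
}

#' Score a synthetic study with the PAS pipeline
#'
#' Convenience wrapper: runs \code{\link{compute_pas_matrix}} on a
#' \code{synthetic_study} with its own reference designations, scoring the
#' study's analysis groups (reference/Young-type groups unfiltered, case
#' groups per \code{mode}).
#'
#' @param study A \code{synthetic_study}.
#' @param mode Case-group scoring mode, default \code{"filtered"}.
#' @param ... Passed on to \code{\link{compute_pas_matrix}}.
#' @return A \code{pas_matrix}.
#' @export
score_study <- function(study, mode = "filtered", ...) {
  stopifnot(inherits(study, "synthetic_study"))
  compute_pas_matrix(study$matrices, study$groups, study$collection,
                     study$reference_groups, mode = mode,
                     score_groups = study$ground_truth$score_groups, ...)
}

#' Write a synthetic study to disk in the pipeline's file dialects
#'
#' One expression TSV per dataset, the annotation TSV, the pathway TSV, a
#' ground-truth JSON and a small manifest JSON tying them together.
#'
#' @param study A \code{synthetic_study}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_files <- character(0)
  for (ds in names(study$matrices)) {
    f <- file.path(dir, paste0("expression_", ds, ".tsv"))
    write_expression_matrix(study$matrices[[ds]], f)
    expr_files[ds] <- basename(f)
  }
  write_sample_annotation(study$annotation, file.path(dir, "annotation.tsv"))
  write_pathway_collection(study$collection, file.path(dir, "pathways.tsv"))
  gt <- study$ground_truth
  gt$pas_sign <- NULL  # matrices round-trip poorly through JSON; signs are derivable
  # named vectors must go out as objects, not bare arrays; JSON null would be
  # dropped on unlist, so unplanted (NA) regions are stored as ""
  for (fld in c("region", "trend"))
    if (!is.null(gt[[fld]])) {
      v <- gt[[fld]]
      v[is.na(v)] <- ""
      gt[[fld]] <- as.list(v)
    }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(datasets = as.list(expr_files),
                   reference_groups = as.list(study$reference_groups),
                   score_groups = study$ground_truth$score_groups,
                   group_order = study$ground_truth$group_order)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a study written by \code{\link{write_study}}
#'
#' @param dir Directory produced by \code{\link{write_study}}.
#' @return List with \code{matrices}, \code{annotation}, \code{groups},
#'   \code{reference_groups}, \code{collection}, \code{score_groups},
#'   \code{group_order} and \code{ground_truth}.
#' @export
load_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  matrices <- lapply(stats::setNames(nm = names(manifest$datasets)), function(ds)
    read_expression_matrix(file.path(dir, manifest$datasets[[ds]]),
                           dataset_id = ds))
  annotation <- read_sample_annotation(file.path(dir, "annotation.tsv"))
  # the annotation written by write_study carries the group column verbatim
  ann_raw <- utils::read.delim(file.path(dir, "annotation.tsv"),
                               stringsAsFactors = FALSE)
  groups <- stats::setNames(ann_raw$group, ann_raw$sample_id)
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  for (fld in c("region", "trend"))
    if (!is.null(ground_truth[[fld]])) {
      v <- unlist(ground_truth[[fld]])
      v[v == ""] <- NA_character_
      ground_truth[[fld]] <- v
    }
  list(matrices = matrices, annotation = annotation, groups = groups,
       reference_groups = unlist(manifest$reference_groups),
       collection = load_pathway_collection(file.path(dir, "pathways.tsv")),
       score_groups = manifest$score_groups,
       group_order = manifest$group_order,
       ground_truth = ground_truth)
}
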