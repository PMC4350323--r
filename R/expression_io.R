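# Expression-matrix and sample-annotation I/O, plus group assignment.
#
# Matrices are gene x sample intensities on the LINEAR scale (microarray
# convention after normalization and un-logging). Duplicate gene rows are
# collapsed and nonpositive intensities floored so ratios and logs are
# always defined.

#' Construct an expression matrix object
#'
#' @param values Numeric gene x sample matrix with rownames (gene symbols)
#'   and colnames (sample ids); linear scale, all finite.
#' @param dataset_id Token identifying the dataset the samples came from.
#' @param floor Positive floor applied to nonpositive values.
#' @return Object of class \code{expression_matrix}: list with elements
#'   \code{values} and \code{dataset_id}.
#' @export
expression_matrix <- function(values, dataset_id, floor = 1e-6) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene rows must be collapsed before construction")
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  values[values <= 0] <- floor
  structure(list(values = values, dataset_id = dataset_id),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", x$dataset_id, "]: ",
      nrow(x$values), " genes x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

collapse_duplicate_genes <- function(values, collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  if (!anyDuplicated(rownames(values))) return(values)
  fun <- if (collapse == "max") max else mean
  grp <- rownames(values)
  out <- do.call(rbind, lapply(split(seq_len(nrow(values)), factor(grp, unique(grp))),
                               function(i) apply(values[i, , drop = FALSE], 2, fun)))
  out[unique(grp), , drop = FALSE]
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: header row with a leading \code{gene} column then one column
#' per sample; GCT 1.2: the standard two-line header then
#' \code{Name}/\code{Description} columns. In both dialects duplicate gene
#' rows are collapsed (per-gene maximum by default) and nonpositive entries
#' are floored to \code{floor}.
#'
#' @param path File path.
#' @param dialect \code{"tsv"} or \code{"gct"}.
#' @param dataset_id Dataset token; defaults to the file name stem.
#' @param log2_input If \code{TRUE} the file stores log2 intensities and is
#'   un-logged (\code{2^x}) on read; source datasets mix conventions.
#' @param collapse Duplicate-gene collapse rule, \code{"max"} (default) or
#'   \code{"mean"}.
#' @param floor Positive floor for nonpositive intensities (default 1e-6).
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   dataset_id = sub("\\.[^.]*$", "", basename(path)),
                                   log2_input = FALSE,
                                   collapse = c("max", "mean"),
                                   floor = 1e-6) {
  dialect <- match.arg(dialect)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (dialect == "gct") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 4L || !startsWith(lines[[1L]], "#1.2"))
      stop("'", path, "' is not a GCT 1.2 file")
    sample_ids <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]][-(1:2)]
    tab <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    hdr <- readLines(path, n = 100L, warn = FALSE)
    hdr <- hdr[!grepl("^\\s*#", hdr) & nzchar(hdr)][1L]
    sample_ids <- strsplit(hdr, "\t", fixed = TRUE)[[1L]][-1L]
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (nrow(tab) == 0L) stop("'", path, "' has no data rows")
    genes <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -1L, drop = FALSE])
  }
  if (ncol(values) == 0L) stop("'", path, "' has no sample columns")
  if (!is.numeric(values) || anyNA(values))
    stop("'", path, "' has ragged rows or non-numeric expression values")
  if (anyDuplicated(sample_ids))
    stop("'", path, "': duplicate sample id(s)")
  colnames(values) <- sample_ids
  rownames(values) <- genes
  if (log2_input) values <- 2^values
  values <- collapse_duplicate_genes(values, collapse)
  expression_matrix(values, dataset_id, floor = floor)
}

#' Write an expression matrix as TSV
#'
#' @param x An \code{\link{expression_matrix}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with columns \code{sample_id}, \code{dataset_id}, \code{condition}
#' (\code{normal} or \code{HGPS}), \code{age} (years; may be blank) and
#' \code{passage} (positive integer; may be blank).
#'
#' @param path File path.
#' @return A data.frame with those columns (\code{age}, \code{passage}
#'   numeric with NA for blanks).
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#",
                           colClasses = "character")
  need <- c("sample_id", "dataset_id", "condition")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation '", path, "' lacks column(s): ", paste(miss, collapse = ", "))
  ann$age <- if ("age" %in% names(ann)) suppressWarnings(as.numeric(ann$age)) else NA_real_
  ann$passage <- if ("passage" %in% names(ann)) suppressWarnings(as.numeric(ann$passage)) else NA_real_
  if (anyDuplicated(paste(ann$dataset_id, ann$sample_id)))
    stop("annotation '", path, "': duplicate sample within a dataset")
  if (any(!is.na(ann$age) & ann$age < 0)) stop("negative donor age in '", path, "'")
  ann
}

#' Write a sample annotation table
#'
#' @param ann Annotation data.frame (see \code{\link{read_sample_annotation}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Assign donor-age / disease groups
#'
#' The study's four groups: HGPS samples are grouped by condition regardless
#' of age; normal samples by donor age with closed intervals
#' Young = [15, 30], Middle = [40, 55], Old = 60+ years. Ages falling in the
#' gaps (under 15, 31-39, 56-59) are labelled \code{excluded} — the printed
#' ranges are disjoint and any other reading would contaminate the groups.
#'
#' @param condition Character vector, \code{"normal"} or \code{"HGPS"}.
#' @param age Numeric donor ages (years); may be NA for HGPS samples only.
#' @return Character vector of labels in
#'   \{\code{Young}, \code{Middle}, \code{Old}, \code{HGPS}, \code{excluded}\}.
#' @export
assign_age_group <- function(condition, age) {
  stopifnot(length(condition) == length(age))
  bad_cond <- !condition %in% c("normal", "HGPS")
  if (any(bad_cond))
    stop("unknown condition(s): ", paste(unique(condition[bad_cond]), collapse = ", "))
  if (any(condition == "normal" & is.na(age)))
    stop("normal sample(s) with missing donor age cannot be grouped")
  out <- rep("excluded", length(condition))
  out[condition == "HGPS"] <- "HGPS"
  norm <- condition == "normal"
  out[norm & age >= 15 & age <= 30] <- "Young"
  out[norm & age >= 40 & age <= 55] <- "Middle"
  out[norm & age >= 60] <- "Old"
  out
}

#' Assemble samples into analysis groups across datasets
#'
#' Combines annotated samples from several expression matrices into the
#' group each belongs to. Every annotated sample must be present in exactly
#' one matrix; excluded samples are reported, not silently dropped.
#'
#' @param annotation Annotation data.frame with a \code{group} column (e.g.
#'   from \code{\link{assign_age_group}}) plus \code{sample_id}/\code{dataset_id}.
#' @param matrices Named list of \code{\link{expression_matrix}} objects
#'   (names = dataset ids).
#' @return List with \code{groups}: named list group label ->
#'   data.frame(dataset_id, sample_id); and \code{excluded}: data.frame of
#'   excluded samples.
#' @export
assemble_groups <- function(annotation, matrices) {
  stopifnot(is.data.frame(annotation), "group" %in% names(annotation))
  hits <- vapply(annotation$sample_id, function(s)
    sum(vapply(matrices, function(m) s %in% colnames(m$values), logical(1))),
    integer(1))
  if (any(hits == 0L))
    stop("annotated sample(s) absent from all matrices: ",
         paste(annotation$sample_id[hits == 0L], collapse = ", "))
  if (any(hits > 1L))
    stop("sample(s) present in more than one matrix: ",
         paste(annotation$sample_id[hits > 1L], collapse = ", "))
  excluded <- annotation[annotation$group == "excluded", , drop = FALSE]
  kept <- annotation[annotation$group != "excluded", , drop = FALSE]
  if (nrow(kept) == 0L)
    warning("all annotated samples are excluded; groups are empty")
  groups <- lapply(split(kept[, c("dataset_id", "sample_id")], kept$group),
                   function(d) { rownames(d) <- NULL; d })
  if (nrow(excluded) > 0L)
    message(nrow(excluded), " sample(s) excluded from grouping: ",
            paste(excluded$sample_id, collapse = ", "))
  list(groups = groups, excluded = excluded)
}
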