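# Pathway collections with per-gene activator/repressor roles.
#
# A pathway is a named gene set in which every member gene carries a discrete
# activator/repressor role coefficient (ARR): +1 activator, +0.5 rather
# activator, 0 unknown, -0.5 rather repressor, -1 repressor. ARR gives each
# gene's contribution its sign when pathway activation is scored.

#' Role token to ARR coefficient mapping
#'
#' The five-level activator/repressor role convention used throughout the
#' package: \code{activator} = +1, \code{rather_activator} = +0.5,
#' \code{unknown} = 0, \code{rather_repressor} = -0.5, \code{repressor} = -1.
#'
#' @format Named numeric vector of length 5.
#' @export
ARR_ROLES <- c(
  activator        = 1.0,
  rather_activator = 0.5,
  unknown          = 0.0,
  rather_repressor = -0.5,
  repressor        = -1.0
)

arr_to_role <- function(arr) {
  names(ARR_ROLES)[match(arr, ARR_ROLES)]
}

#' Construct a pathway definition
#'
#' @param pathway_id Short unique identifier token.
#' @param gene_roles Named numeric vector mapping gene symbol to ARR
#'   coefficient; each coefficient must be one of -1, -0.5, 0, 0.5, 1.
#' @param display_name Free-text name; defaults to \code{pathway_id}.
#' @return An object of class \code{pathway_definition}.
#' @export
pathway_definition <- function(pathway_id, gene_roles, display_name = pathway_id) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L, nzchar(pathway_id))
  if (length(gene_roles) == 0L)
    stop("pathway '", pathway_id, "': gene_roles must be non-empty")
  if (is.null(names(gene_roles)) || any(!nzchar(names(gene_roles))))
    stop("pathway '", pathway_id, "': all gene_roles must be named")
  if (anyDuplicated(names(gene_roles)))
    stop("pathway '", pathway_id, "': duplicate gene(s): ",
         paste(unique(names(gene_roles)[duplicated(names(gene_roles))]), collapse = ", "))
  bad <- !gene_roles %in% ARR_ROLES
  if (any(bad))
    stop("pathway '", pathway_id, "': ARR coefficient(s) outside {-1,-0.5,0,0.5,1}: ",
         paste(unique(gene_roles[bad]), collapse = ", "))
  structure(
    list(pathway_id = pathway_id,
         display_name = display_name,
         gene_roles = gene_roles),
    class = "pathway_definition"
  )
}

#' Construct a pathway collection
#'
#' @param pathways List of \code{\link{pathway_definition}} objects; order is
#'   preserved and is the row order of downstream PAS matrices.
#' @param collection_name Free-text collection label.
#' @return An object of class \code{pathway_collection}.
#' @export
pathway_collection <- function(pathways, collection_name = "collection") {
  if (length(pathways) == 0L)
    stop("a pathway collection must contain at least one pathway")
  if (!all(vapply(pathways, inherits, logical(1), "pathway_definition")))
    stop("all elements must be pathway_definition objects")
  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids))
    stop("duplicate pathway_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(pathways) <- ids
  structure(
    list(pathways = pathways, collection_name = collection_name),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- vapply(x$pathways, function(p) length(p$gene_roles), integer(1))
  cat("pathway_collection '", x$collection_name, "': ",
      length(x$pathways), " pathways, ",
      sum(sizes), " gene roles (",
      min(sizes), "-", max(sizes), " genes per pathway)\n", sep = "")
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

pathway_ids <- function(collection) names(collection$pathways)

#' Load a pathway collection from a role-annotated TSV
#'
#' Reads the package's three-column tab-delimited pathway dialect:
#' a header line followed by rows \code{pathway_id<TAB>gene_symbol<TAB>role},
#' where role is one of \code{activator}, \code{rather_activator},
#' \code{unknown}, \code{rather_repressor}, \code{repressor}. Lines starting
#' with \code{#} are ignored. Pathways keep their order of first appearance.
#' Gene symbols are opaque, case-sensitive strings; no aliasing is applied.
#'
#' @param path Path to the TSV file.
#' @param collection_name Label for the returned collection; defaults to the
#'   file name without extension.
#' @return A \code{\link{pathway_collection}}.
#' @export
load_pathway_collection <- function(path,
                                    collection_name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) <= 1L)
    stop("pathway file '", path, "' contains no data rows")
  # drop header
  line_no <- line_no[-1L]
  lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != 3L))
    stop("pathway file '", path, "': expected 3 tab-separated fields on line ",
         line_no[which(nfld != 3L)[1L]])
  pid  <- vapply(parts, `[[`, character(1), 1L)
  gene <- vapply(parts, `[[`, character(1), 2L)
  role <- vapply(parts, `[[`, character(1), 3L)
  unknown_role <- !role %in% names(ARR_ROLES)
  if (any(unknown_role)) {
    i <- which(unknown_role)[1L]
    stop("pathway file '", path, "': unknown role token '", role[i],
         "' on line ", line_no[i])
  }
  dup <- duplicated(paste(pid, gene, sep = "\r"))
  if (any(dup)) {
    i <- which(dup)[1L]
    stop("pathway file '", path, "': duplicate (pathway, gene) pair ('",
         pid[i], "', '", gene[i], "') on line ", line_no[i])
  }
  arr <- unname(ARR_ROLES[role])
  defs <- lapply(unique(pid), function(id) {
    sel <- pid == id
    pathway_definition(id, stats::setNames(arr[sel], gene[sel]))
  })
  pathway_collection(defs, collection_name)
}

#' Write a pathway collection to the role-annotated TSV dialect
#'
#' Inverse of \code{\link{load_pathway_collection}}: the round trip
#' \code{load(write(x))} reproduces \code{x}'s ids, gene order and ARR values.
#'
#' @param collection A \code{\link{pathway_collection}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pathway_collection <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  rows <- unlist(lapply(collection$pathways, function(p) {
    paste(p$pathway_id, names(p$gene_roles), arr_to_role(unname(p$gene_roles)),
          sep = "\t")
  }), use.names = FALSE)
  writeLines(c("pathway_id\tgene_symbol\trole", rows), path)
  invisible(path)
}

#' Import a GMT gene-set file as an all-activator pathway collection
#'
#' Standard GMT (one set per line: name, description, then gene symbols).
#' GMT carries no per-gene role information, so every gene is imported with
#' ARR = +1 (activator).
#'
#' @param path Path to a GMT file.
#' @param collection_name Label for the returned collection.
#' @return A \code{\link{pathway_collection}}.
#' @export
read_gmt_collection <- function(path,
                                collection_name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file '", path, "' is empty")
  defs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT file '", path, "': line ", i, " has no genes")
    genes <- unique(f[-(1:2)])
    pathway_definition(f[1L], stats::setNames(rep(1.0, length(genes)), genes),
                       display_name = if (nzchar(f[2L])) f[2L] else f[1L])
  })
  pathway_collection(defs, collection_name)
}

# pathway-by-gene ARR matrix over a given gene universe; genes absent from
# the universe are dropped (their contribution to PAS is 0 by convention).
arr_matrix <- function(collection, genes) {
  A <- matrix(0, nrow = length(collection$pathways), ncol = length(genes),
              dimnames = list(pathway_ids(collection), genes))
  for (p in collection$pathways) {
    g <- intersect(names(p$gene_roles), genes)
    A[p$pathway_id, g] <- p$gene_roles[g]
  }
  A
}
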