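#' Gene-set collection
#'
#' A named list of gene sets (character vectors of gene symbols) plus an
#' optional background universe, as used by [overrepresentation()]. When no
#' background is supplied, the union of all set members is used.
#'
#' @param sets Named list of character vectors; duplicate genes within a set
#'   are collapsed.
#' @param background Optional character vector of background gene symbols.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background = NULL) {
  if (length(sets) == 0) stop("collection must contain at least one set")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- vapply(sets, length, 1L) == 0
  if (any(empty))
    stop("empty gene set(s): ", paste(names(sets)[empty], collapse = ", "))
  blank <- vapply(sets, function(g) any(!nzchar(g) | is.na(g)), TRUE)
  if (any(blank))
    stop("gene set(s) with empty gene symbols: ",
         paste(names(sets)[blank], collapse = ", "))
  if (!is.null(background)) background <- unique(as.character(background))
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets;",
      if (is.null(x$background)) "background = union of sets"
      else paste0("background of ", length(x$background), " genes"), "\n")
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with fewer than
#' three fields are a parse error. Duplicate genes within a set are stored
#' once; distinct sets may share genes.
#'
#' @param path Path to the GMT file.
#' @param background Optional background gene universe (defaults to the
#'   union of all sets at analysis time).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file ", path, " is empty")
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf < 3))
    stop("GMT parse error at line ", which(nf < 3)[1],
         ": expected at least 3 tab-separated fields")
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, background = background)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions
#'   (the second GMT field); defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
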