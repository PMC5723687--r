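# Shared plain-text readers/writers. Everything is tab-delimited UTF-8 with
# a header row; missing values are empty fields ("." is not a missing
# marker). CRLF input is accepted.

check_nonempty <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (file.size(path) == 0) abort(paste0("No records in ", path, " (empty file)."))
}

#' Read / write a subject phenotype table
#'
#' One row per subject, tab-delimited with a header; must contain a
#' `subject_id` column (checked) and typically family id, sex, age,
#' biomarker, covariate and survival columns.
#'
#' @param path file path.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_phenotypes <- function(path) {
  check_nonempty(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (!"subject_id" %in% names(tab)) {
    abort(paste0("Phenotype file ", path, " lacks a `subject_id` column."))
  }
  if (anyDuplicated(tab$subject_id)) {
    abort(paste0("Duplicate subject ids in ", path, " (first at line ",
                 which(duplicated(tab$subject_id))[1] + 1, ")."))
  }
  tab
}

#' @rdname read_phenotypes
#' @param cohort data frame to write.
#' @export
write_phenotypes <- function(cohort, path) {
  readr::write_tsv(tibble::as_tibble(cohort), path, na = "")
  invisible(path)
}

#' Read / write a features-by-subjects matrix as TSV
#'
#' Feature id in column 1, one column per subject.
#'
#' @param path file path.
#' @return A numeric matrix with feature row names (read) or `path` (write).
#' @export
read_matrix_tsv <- function(path) {
  check_nonempty(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate feature ids in ", path, " (first: ",
                 ids[duplicated(ids)][1], ")."))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(paste0("Non-numeric values in matrix ", path, "."))
  rownames(m) <- ids
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with feature ids as row names.
#' @param id_col name of the leading id column (default `feature`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature") {
  tab <- tibble::as_tibble(m, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), tab)
  readr::write_tsv(tab, path, na = "")
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes (at least
#' two leading fields). Duplicate set names are an error.
#'
#' @param path file path.
#' @return A named list of character vectors with a `description` attribute
#'   (read) or `path` (write).
#' @export
read_gmt <- function(path) {
  check_nonempty(path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0("No records in ", path, "."))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2)
  if (length(short)) {
    abort(paste0("Malformed GMT line ", short[1], " in ", path,
                 ": fewer than 2 fields."))
  }
  nms <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nms)) {
    abort(paste0("Duplicate set name in ", path, ": ", nms[duplicated(nms)][1]))
  }
  sets <- lapply(parts, function(x) x[-(1:2)][nzchar(x[-(1:2)])])
  names(sets) <- nms
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2), nms)
  class(sets) <- "gene_set_collection"
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an undirected edge list
#'
#' Two-column TSV with header; self-loops dropped, unordered duplicates
#' deduplicated.
#'
#' @param path file path.
#' @return Tibble (`from`, `to`) (read) or `path` (write).
#' @export
read_edge_list <- function(path) {
  check_nonempty(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort(paste0("Edge list ", path, " needs two columns."))
  bad <- which(!complete.cases(tab[, 1:2]))
  if (length(bad)) {
    abort(paste0("Malformed edge at line ", bad[1] + 1, " of ", path, "."))
  }
  edges <- tibble::tibble(from = as.character(tab[[1]]), to = as.character(tab[[2]]))
  edges <- dplyr::filter(edges, .data$from != .data$to)
  dplyr::distinct(tibble::tibble(from = pmin(edges$from, edges$to),
                                 to = pmax(edges$from, edges$to)))
}

#' @rdname read_edge_list
#' @param edges data frame with `from`, `to`.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(tibble::as_tibble(edges)[, c("from", "to")], path)
  invisible(path)
}

#' Read a CpG-to-gene map
#'
#' TSV with at least `cpg_id` and `gene` columns (a third `position` column
#' is kept when present).
#'
#' @param path file path.
#' @return Tibble.
#' @export
read_cpg_map <- function(path) {
  check_nonempty(path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cpg_id", "gene")
  if (!all(need %in% names(tab))) {
    abort(paste0("CpG map ", path, " must have columns cpg_id and gene."))
  }
  tab
}

#' Read / write a one-symbol-per-line gene list
#'
#' @param path file path.
#' @return Character vector (read) or `path` (write).
#' @export
read_gene_list <- function(path) {
  check_nonempty(path)
  x <- readLines(path, warn = FALSE)
  x <- sub("\r$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
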