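# GMT gene-set collections used by the over-representation step.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members are collapsed; a line with fewer than three
#' fields (i.e. no members) is an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors, class `"gene_sets"`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("empty GMT file: %s", path)
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) stopf("GMT line with fewer than 3 fields: %s", ln)
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  structure(sets, class = "gene_sets")
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (as from [read_gene_sets()]).
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- descriptions[[nm]] %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
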