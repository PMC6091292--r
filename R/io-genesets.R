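#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, `name TAB description TAB gene TAB
#' gene ...`. File order is preserved; duplicate genes within a line are
#' dropped (first occurrence kept). Lines with fewer than three fields and
#' duplicated pathway names are hard errors.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (pathway name -> member genes),
#'   with a `description` character attribute parallel to the names.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("GMT line %d has %d field(s); need name, description, >=1 gene",
          which(nf < 3L)[1L], nf[which(nf < 3L)[1L]])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stopf("duplicate pathway name(s) in GMT: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write pathway gene sets as a GMT file
#' @param sets named list of character vectors; an optional `description`
#'   attribute supplies the second column (default `"na"`).
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
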