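#' Named gene sets and GMT input/output
#'
#' Gene sets are plain character vectors of gene identifiers with a `name`
#' attribute; collections are named lists of such vectors (the same shape
#' `fgsea` uses). `read_gmt()` wraps `fgsea::gmtPathways()`.
#'
#' @param members Character vector of gene identifiers (deduplicated).
#' @param name Set label.
#' @return `gene_set()` returns a `pm_gene_set` character vector.
#' @export
gene_set <- function(members, name = "gene_set") {
  structure(sort(unique(as.character(members))),
            name = name, class = c("pm_gene_set", "character"))
}

#' @export
print.pm_gene_set <- function(x, ...) {
  cat(sprintf("<pm_gene_set> %s: %d genes\n", attr(x, "name"), length(x)))
  if (length(x)) cat(" ", paste(head(x, 8), collapse = ", "),
                     if (length(x) > 8) "..." else "", "\n")
  invisible(x)
}

set_name <- function(x, default = "gene_set") {
  attr(x, "name", exact = TRUE) %||% default
}

#' @param path File path of a tab-separated GMT file (set name, description,
#'   then member genes).
#' @rdname gene_set
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @param sets Named list of character vectors (or a single `pm_gene_set`).
#' @rdname gene_set
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "pm_gene_set")) {
    sets <- setNames(list(as.character(sets)), set_name(sets))
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- imap(sets, ~ paste(c(.y, "pathmod", .x), collapse = "\t"))
  writeLines(unlist(lines), path)
  invisible(path)
}
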