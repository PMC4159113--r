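#' Construct a gene set
#'
#' A named collection of unique gene identifiers: a signature, a target list,
#' or a derived induced set.
#'
#' @param name set name (non-empty string).
#' @param members character vector of gene ids; duplicates are dropped.
#' @param description free-text description (GMT second field).
#' @return An object of class `GeneSet` with fields `name`, `description`
#'   and `members` (unique, in first-occurrence order).
#' @examples
#' gene_set("nrf2_targets", c("HMOX1", "NQO1", "GCLC"))
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("`name` must be a non-empty string")
  members <- as.character(members)
  if (anyNA(members) || any(!nzchar(members)))
    stop("gene set members must be non-empty strings")
  members <- unique(members)
  structure(list(name = name, description = description, members = members),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes", x$name, length(x$members)))
  if (nzchar(x$description)) cat(" -", x$description)
  cat("\n")
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$members)

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields are an error reported with their line number.
#'
#' @param path file path.
#' @return named list of `GeneSet` objects (names = set names).
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(f)))
    sets[[i]] <- gene_set(f[1], f[-(1:2)], description = f[2])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a `GeneSet` or list of `GeneSet` objects.
#' @param path output file path.
#' @return `path`, invisibly. `read_gmt(write_gmt(sets, path))` recovers the
#'   sets exactly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "GeneSet"))
    if (!length(s$members))
      stop("cannot write empty gene set '", s$name, "' to GMT")
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# internal set algebra on GeneSet objects, preserving deterministic
# (byte-order) member ordering
gs_sorted <- function(members) sort(unique(members), method = "radix")

gs_intersect <- function(a, b, name, description = "") {
  gene_set(name, gs_sorted(intersect(a$members, b$members)),
           description = description)
}

gs_setdiff <- function(a, b, name, description = "") {
  gene_set(name, gs_sorted(setdiff(a$members, b$members)),
           description = description)
}
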