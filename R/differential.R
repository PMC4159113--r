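#' Define a two-group contrast for fold-change calling
#'
#' @param group_a sample ids of the "numerator" group (e.g. treated).
#' @param group_b sample ids of the "denominator" group (e.g. control).
#' @param fc_threshold linear fold-change threshold, strictly greater than 1
#'   (default 2: genes must change by more than 2-fold, i.e. |log2 FC| > 1).
#' @return A `ContrastSpec` object.
#' @export
contrast_spec <- function(group_a, group_b, fc_threshold = 2) {
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b))
    stop("contrast groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("contrast groups must be disjoint; shared sample(s): ",
         paste(intersect(group_a, group_b), collapse = ", "))
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1 ||
      fc_threshold <= 1)
    stop("`fc_threshold` must be a single number > 1")
  structure(list(group_a = group_a, group_b = group_b,
                 fc_threshold = fc_threshold),
            class = "ContrastSpec")
}

check_samples_present <- function(mat, ids) {
  missing <- setdiff(ids, samples(mat))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
}

#' Per-gene mean log2 expression over a sample group
#'
#' @param mat an `ExpressionMatrix` (log2 scale).
#' @param group non-empty vector of sample ids present in `mat`.
#' @return named numeric vector, one mean per gene, in matrix gene order.
#' @export
mean_log_expression <- function(mat, group) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  group <- as.character(group)
  if (!length(group)) stop("`group` must be non-empty")
  check_samples_present(mat, group)
  rowMeans(mat$values[, group, drop = FALSE])
}

#' Per-gene log2 fold change for a contrast
#'
#' Difference of group mean log2 values (group_a minus group_b), the
#' log-space equivalent of a fold change of geometric means.
#'
#' @param mat an `ExpressionMatrix`.
#' @param contrast a [contrast_spec()].
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mat, contrast) {
  stopifnot(inherits(contrast, "ContrastSpec"))
  mean_log_expression(mat, contrast$group_a) -
    mean_log_expression(mat, contrast$group_b)
}

#' Genes up-regulated beyond a fold-change threshold
#'
#' A gene is called up-regulated when its mean log2 expression in `group_a`
#' exceeds that in `group_b` by strictly more than `log2(fc_threshold)`
#' (">2-fold" is read as a strict inequality).
#'
#' @inheritParams log2_fold_change
#' @param name name for the returned set.
#' @return A `GeneSet`; may be empty if no gene passes.
#' @export
up_regulated_set <- function(mat, contrast, name = "up_regulated") {
  lfc <- log2_fold_change(mat, contrast)
  hits <- names(lfc)[lfc > log2(contrast$fc_threshold)]
  gene_set(name, gs_sorted(hits),
           description = sprintf(">%g-fold up, %d vs %d samples",
                                 contrast$fc_threshold,
                                 length(contrast$group_a),
                                 length(contrast$group_b)))
}

#' Up- and down-regulated gene sets for a contrast
#'
#' `down` is `up` with the groups swapped; "differentially expressed" is
#' their union at the same threshold.
#'
#' @inheritParams up_regulated_set
#' @param name_prefix prefix for the two set names.
#' @return list with `GeneSet` elements `up`, `down` and `differential`
#'   (their union).
#' @export
differential_set <- function(mat, contrast, name_prefix = "differential") {
  up <- up_regulated_set(mat, contrast, name = paste0(name_prefix, "_up"))
  swapped <- contrast_spec(contrast$group_b, contrast$group_a,
                           contrast$fc_threshold)
  down <- up_regulated_set(mat, swapped, name = paste0(name_prefix, "_down"))
  diff <- gene_set(name_prefix, gs_sorted(c(up$members, down$members)),
                   description = "union of up and down at threshold")
  list(up = up, down = down, differential = diff)
}

#' Oxidative-stress genes preactivated in de-differentiated cells
#'
#' The core intersection construct: genes induced by oxidative stress in
#' differentiated cells that are already up-regulated in de-differentiated
#' cells without any stress.
#'
#' @param ros_induced_in_differentiated `GeneSet` of stress-induced genes in
#'   the differentiated genotype.
#' @param up_in_dedifferentiated `GeneSet` of genes basally up-regulated in
#'   the de-differentiated genotype.
#' @param name name for the returned set.
#' @return A `GeneSet`, the exact intersection.
#' @export
preactivated_set <- function(ros_induced_in_differentiated,
                             up_in_dedifferentiated,
                             name = "preactivated") {
  stopifnot(inherits(ros_induced_in_differentiated, "GeneSet"),
            inherits(up_in_dedifferentiated, "GeneSet"))
  gs_intersect(ros_induced_in_differentiated, up_in_dedifferentiated, name,
               description = "stress-induced in differentiated, basally up in de-differentiated")
}

#' Preactivated genes uniquely induced in differentiated cells
#'
#' Preactivated genes whose stress induction is seen only in the
#' differentiated genotype (i.e. not also induced in the de-differentiated
#' one).
#'
#' @param induced_in_diff `GeneSet` of stress-induced genes in differentiated
#'   cells; the preactivated set must be contained in it.
#' @param induced_in_dediff `GeneSet` of stress-induced genes in
#'   de-differentiated cells.
#' @param preactivated `GeneSet` from [preactivated_set()].
#' @param name name for the returned set.
#' @return A `GeneSet`: `preactivated` minus `induced_in_dediff`.
#' @export
uniquely_induced_set <- function(induced_in_diff, induced_in_dediff,
                                 preactivated, name = "uniquely_induced") {
  stopifnot(inherits(induced_in_diff, "GeneSet"),
            inherits(induced_in_dediff, "GeneSet"),
            inherits(preactivated, "GeneSet"))
  stray <- setdiff(preactivated$members, induced_in_diff$members)
  if (length(stray))
    stop("preactivated set is not contained in the induced set; offending id(s): ",
         paste(stray, collapse = ", "))
  gs_setdiff(preactivated, induced_in_dediff, name,
             description = "preactivated, induced only in differentiated cells")
}
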