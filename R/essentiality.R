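# Variable merging and essentiality scoring.
#
# Objects whose feasibility column is identical across all N knockouts of
# a study are statistically indistinguishable, so they are merged into one
# variable before scoring and classification (typically collapsing a
# gene with its transcription, transcript, translation and protein). The
# essentiality score of a variable is the fraction of inviable strains
# among all experimental strains whose damage blocks it; score 1 defines
# unconditional essentiality within the studied context.

fm_column_keys <- function(blocked) {
  m <- methods::as(blocked, "CsparseMatrix")
  p <- m@p
  vapply(seq_len(ncol(m)), function(j) {
    if (p[j + 1L] == p[j]) return("")
    paste(m@i[(p[j] + 1L):p[j + 1L]], collapse = ",")
  }, "")
}

#' Merge variables with identical feasibility columns
#'
#' Columns that agree on every knockout of the study are merged and
#' considered as a single variable; the partition is recorded in `groups`
#' so the full matrix can be reconstructed losslessly. No phenotype
#' information is consulted.
#'
#' @param fmatrix a `refnet_fmatrix`.
#' @return A reduced `refnet_fmatrix` whose column count equals the number
#'   of distinct feasibility columns; each retained column is named after
#'   the first object of its group and `groups` maps it to all members.
#' @export
merge_identical_variables <- function(fmatrix) {
  keys <- fm_column_keys(fmatrix$blocked)
  keep <- which(!duplicated(keys))
  grp <- match(keys, keys[keep])
  members <- lapply(seq_along(keep), function(g) {
    unlist(fmatrix$groups[grp == g], use.names = FALSE)
  })
  out <- fmatrix
  out$blocked <- fmatrix$blocked[, keep, drop = FALSE]
  out$objects <- fmatrix$objects[keep]
  out$object_type <- fmatrix$object_type[keep]
  out$groups <- unname(members)
  out
}

check_phenotypes <- function(fmatrix, phenotypes) {
  if (is.null(phenotypes)) phenotypes <- fmatrix$experiments$phenotype
  if (length(phenotypes) != nrow(fmatrix$blocked))
    stop("phenotype vector length (", length(phenotypes),
         ") does not match the number of knockout rows (",
         nrow(fmatrix$blocked), ")", call. = FALSE)
  bad <- !(phenotypes %in% c("viable", "inviable"))
  if (any(bad))
    stop("phenotype must be 'viable' or 'inviable'; offending rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  phenotypes
}

#' Essentiality score per variable
#'
#' For variable i, `n_blocking` counts the experimental knockouts whose
#' damage blocks i, `n_lethal_blocking` those with an inviable phenotype,
#' and the score is their ratio: the probability of an inviable phenotype
#' given that i was infeasible. Variables never blocked have no evidence
#' and their score is reported as `NA`, never 0.
#'
#' @param fmatrix a `refnet_fmatrix` (typically reduced by
#'   [merge_identical_variables()]).
#' @param phenotypes `"viable"`/`"inviable"` per row; defaults to the
#'   phenotypes stored with the experiments.
#' @return A data frame with one row per variable: `variable`,
#'   `n_blocking`, `n_lethal_blocking`, `score`, `group_size`.
#' @export
essentiality_scores <- function(fmatrix, phenotypes = NULL) {
  phenotypes <- check_phenotypes(fmatrix, phenotypes)
  inv <- phenotypes == "inviable"
  n_blocking <- Matrix::colSums(fmatrix$blocked)
  n_lethal <- Matrix::colSums(fmatrix$blocked[inv, , drop = FALSE])
  score <- ifelse(n_blocking > 0, n_lethal / n_blocking, NA_real_)
  data.frame(variable = fmatrix$objects,
             n_blocking = as.integer(n_blocking),
             n_lethal_blocking = as.integer(n_lethal),
             score = score,
             group_size = lengths(fmatrix$groups),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Unconditionally essential variables
#'
#' Variables whose blockage coincided with the inviable phenotype in every
#' observing experiment (score exactly 1). Because a variable blocked by
#' few knockouts carries a potentially biased score, a minimum support on
#' `n_blocking` can be required; the default of 1 applies no extra filter.
#'
#' @param records output of [essentiality_scores()].
#' @param min_support minimum `n_blocking` (default 1).
#' @return Character vector of variable ids.
#' @export
unconditionally_essential <- function(records, min_support = 1) {
  records$variable[!is.na(records$score) & records$score == 1 &
                     records$n_blocking >= min_support]
}

#' Expand merged variables back to objects
#'
#' @param fmatrix a reduced `refnet_fmatrix`.
#' @param variables character vector of variable ids.
#' @return Character vector of all member object ids of those variables.
#' @export
variable_members <- function(fmatrix, variables) {
  unlist(fmatrix$groups[match(variables, fmatrix$objects)],
         use.names = FALSE)
}

#' Resolve conflicting phenotype labels for repeated strains
#'
#' Experimental sources overlap, so the same strain id can appear with
#' disagreeing labels. Conflicts are resolved by majority vote; exact ties
#' keep the viable label (with a warning), discarding the inviable claim
#' as the less conservative one.
#'
#' @param experiments a knockout experiment table with phenotypes.
#' @return The experiment table with one row per strain id.
#' @export
resolve_phenotype_conflicts <- function(experiments) {
  if (!anyDuplicated(experiments$strain)) return(experiments)
  keep <- integer()
  ties <- character()
  for (s in unique(experiments$strain)) {
    idx <- which(experiments$strain == s)
    ph <- experiments$phenotype[idx]
    n_inv <- sum(ph == "inviable")
    n_via <- sum(ph == "viable")
    label <- if (n_inv > n_via) "inviable" else "viable"
    if (n_inv == n_via && n_inv > 0) ties <- c(ties, s)
    keep <- c(keep, idx[match(label, ph)])
  }
  if (length(ties))
    warning("tied phenotype labels resolved to viable for strain(s): ",
            paste(ties, collapse = ", "), call. = FALSE)
  out <- experiments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset the rows (experiments) of a feasibility matrix
#'
#' @param fmatrix a `refnet_fmatrix`.
#' @param rows integer or logical row index.
#' @return A `refnet_fmatrix` restricted to those experiments.
#' @export
fm_subset <- function(fmatrix, rows) {
  out <- fmatrix
  out$blocked <- fmatrix$blocked[rows, , drop = FALSE]
  out$experiments <- fmatrix$experiments[rows, , drop = FALSE]
  out
}
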