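# Boolean feasibility model and knockout damage propagation.
#
# Every object carries a Boolean feasibility: a species exists in its
# functional form, or an interaction may occur. An interaction is feasible
# iff all the species it needs (substrates and controllers) are feasible
# ('and' rule); a species is feasible iff at least one interaction
# producing it is feasible ('or' rule). Species with no producers (genes,
# medium-like metabolites, orphan proteins) are roots and stay feasible
# unless explicitly knocked out. A knockout clamps the given genes
# infeasible, starts from the all-feasible state, and propagates blockage
# to the greatest fixed point; the set of infeasible objects is the damage.

#' Compile a network into a Boolean feasibility model
#'
#' Computes, for every interaction, its requirement set (substrate ids
#' united with controller ids) and, for every species, its producer set
#' (interactions listing it as a product). Species with an empty producer
#' set are recorded as roots. Metabolic reactions without a controller
#' (uncatalyzed) require only their substrates; their count is reported in
#' the model so the assumption is visible.
#'
#' @param network a valid, finalized `refnet_network`.
#' @param exclude_species character vector of species ids (typically
#'   ubiquitous currency metabolites) to leave out of all requirement
#'   sets; empty by default, and recorded in the model when used.
#' @return An object of class `refnet_boolean`.
#' @export
compile_boolean_model <- function(network, exclude_species = character()) {
  assert_valid_network(network)
  sp <- network$species
  ix <- network$interactions
  ns <- nrow(sp)
  ni <- nrow(ix)
  sp_index <- stats::setNames(seq_len(ns), sp$id)

  requirements <- vector("list", ni)
  prods <- vector("list", ni)
  for (k in seq_len(ni)) {
    req <- unique(c(ix$substrates[[k]]$species, ix$controllers[[k]]))
    req <- setdiff(req, exclude_species)
    requirements[[k]] <- unname(sp_index[req])
    prods[[k]] <- unname(sp_index[unique(ix$products[[k]]$species)])
  }
  needed_by <- vector("list", ns)
  producers_n <- integer(ns)
  for (k in seq_len(ni)) {
    for (s in requirements[[k]]) needed_by[[s]] <- c(needed_by[[s]], k)
    for (s in prods[[k]]) producers_n[s] <- producers_n[s] + 1L
  }

  structure(list(
    species_id = sp$id,
    species_type = sp$species_type,
    interaction_id = ix$id,
    interaction_type = ix$interaction_type,
    requirements = requirements,
    products = prods,
    needed_by = needed_by,
    producers_n = producers_n,
    roots = sp$id[producers_n == 0L],
    gene_index = sp_index[sp$species_type == "gene"],
    excluded_species = exclude_species,
    n_uncatalyzed = sum(ix$interaction_type == "metabolic_reaction" &
                          lengths(ix$controllers) == 0L)
  ), class = "refnet_boolean")
}

#' @export
print.refnet_boolean <- function(x, ...) {
  cat(sprintf("<refnet_boolean> %d species (%d roots), %d interactions\n",
              length(x$species_id), length(x$roots),
              length(x$interaction_id)))
  if (x$n_uncatalyzed > 0)
    cat(sprintf("  note: %d uncatalyzed metabolic reactions (substrates-only rule)\n",
                x$n_uncatalyzed))
  if (length(x$excluded_species))
    cat(sprintf("  note: %d species excluded from requirement sets\n",
                length(x$excluded_species)))
  invisible(x)
}

knockout_indices <- function(model, genes) {
  idx <- model$gene_index[genes]
  if (anyNA(idx))
    stop("unknown gene id: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  unname(idx)
}

# core propagation: returns list(species = logical blocked, interactions =
# logical blocked). Worklist over the blockage-only dynamics; the greatest
# fixed point below the all-feasible start is order-independent.
propagate_blockage <- function(model, knocked_idx) {
  ns <- length(model$species_id)
  blocked_s <- logical(ns)
  blocked_i <- logical(length(model$interaction_id))
  left <- model$producers_n
  blocked_s[knocked_idx] <- TRUE
  stack <- knocked_idx
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (k in model$needed_by[[s]]) {
      if (blocked_i[k]) next
      blocked_i[k] <- TRUE
      for (p in model$products[[k]]) {
        left[p] <- left[p] - 1L
        if (left[p] == 0L && !blocked_s[p]) {
          blocked_s[p] <- TRUE
          stack <- c(stack, p)
        }
      }
    }
  }
  list(species = blocked_s, interactions = blocked_i)
}

#' Simulate the damage of a gene knockout
#'
#' The listed genes are clamped infeasible while every other object starts
#' feasible; the 'and'/'or' feasibility rules are then evaluated to the
#' unique greatest fixed point. An interaction is infeasible iff any
#' required object is infeasible; a non-root species is infeasible iff all
#' its producers are; roots other than the knocked genes stay feasible.
#' The result is independent of evaluation order.
#'
#' @param model a `refnet_boolean` model.
#' @param genes character vector of gene ids to knock out (all clamped
#'   simultaneously; multi-gene strains list 2 or 3).
#' @return An object of class `refnet_damage`: a list with `knockout`,
#'   `infeasible` (blocked object ids, knocked genes included) and `size`.
#' @export
simulate_knockout <- function(model, genes) {
  idx <- knockout_indices(model, genes)
  st <- propagate_blockage(model, idx)
  infeasible <- c(model$species_id[st$species],
                  model$interaction_id[st$interactions])
  structure(list(knockout = genes, infeasible = infeasible,
                 size = length(infeasible)),
            class = "refnet_damage")
}

#' @export
print.refnet_damage <- function(x, ...) {
  cat(sprintf("<refnet_damage> knockout {%s}: %d blocked objects\n",
              paste(x$knockout, collapse = ", "), x$size))
  invisible(x)
}

#' Create a knockout experiment table
#'
#' @param strain strain identifiers.
#' @param genes list of character vectors (1 to 3 gene ids per strain).
#' @param phenotype `"viable"` or `"inviable"` per strain (optional,
#'   `NA` when not yet measured).
#' @return A data frame with a list column `genes`.
#' @export
knockout_experiments <- function(strain, genes, phenotype = NA_character_) {
  n <- length(strain)
  if (!is.list(genes)) genes <- as.list(genes)
  stopifnot(length(genes) == n, all(lengths(genes) >= 1L))
  df <- data.frame(strain = as.character(strain),
                   phenotype = rep_len(as.character(phenotype), n),
                   stringsAsFactors = FALSE)
  df$genes <- genes
  df[, c("strain", "genes", "phenotype")]
}

#' Compute the feasibility matrix of a knockout study
#'
#' Runs [simulate_knockout()] for every experiment and stores the results
#' as a binary matrix with one row per strain and one column per object
#' (species first, then interactions). An entry is `TRUE` when the object
#' stayed feasible; the `FALSE` entries of row i are exactly the damage of
#' experiment i. The blocked entries are held sparsely since damage sets
#' are small relative to the network.
#'
#' @param model a `refnet_boolean` model.
#' @param experiments a knockout experiment table
#'   (see [knockout_experiments()]).
#' @return An object of class `refnet_fmatrix` with components `blocked`
#'   (sparse logical strains x objects matrix of infeasible entries),
#'   `objects`, `object_type`, `experiments` and `groups` (merged-variable
#'   partition; singletons until [merge_identical_variables()]).
#' @export
batch_damage <- function(model, experiments) {
  ns <- length(model$species_id)
  objects <- c(model$species_id, model$interaction_id)
  object_type <- c(model$species_type, model$interaction_type)
  n <- nrow(experiments)
  ii <- jj <- vector("list", n)
  for (r in seq_len(n)) {
    idx <- knockout_indices(model, experiments$genes[[r]])
    st <- propagate_blockage(model, idx)
    cols <- c(which(st$species), ns + which(st$interactions))
    ii[[r]] <- rep.int(r, length(cols))
    jj[[r]] <- cols
  }
  blocked <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = TRUE,
    dims = c(n, length(objects)),
    dimnames = list(experiments$strain, objects))
  structure(list(blocked = blocked, objects = objects,
                 object_type = object_type, experiments = experiments,
                 groups = as.list(objects)),
            class = "refnet_fmatrix")
}

#' @export
print.refnet_fmatrix <- function(x, ...) {
  cat(sprintf("<refnet_fmatrix> %d knockout experiments x %d variables (%d objects; %d blocked entries)\n",
              nrow(x$blocked), ncol(x$blocked), length(unlist(x$groups)),
              length(x$blocked@i)))
  invisible(x)
}

#' Per-type damage statistics over single-gene knockouts
#'
#' For each object type, the damage probability is the fraction of
#' knockouts blocking at least one object of that type; the mean and SD of
#' blocked-object counts are conditional on the damage reaching the type
#' (knockouts blocking none of it are excluded from the mean). Structural
#' consequences of the layered network: genes and transcriptions have
#' probability 1 with mean 1 (SD 0), and at most one protein is blocked
#' per single knockout.
#'
#' @param fmatrix a `refnet_fmatrix`.
#' @param single_only restrict to single-gene knockouts (default `TRUE`).
#' @return A data frame with one row per object type: `object_type`,
#'   `n_knockouts`, `damage_probability`, `mean_blocked`, `sd_blocked`
#'   (mean and SD are `NA` when no knockout reaches the type).
#' @export
damage_statistics <- function(fmatrix, single_only = TRUE) {
  rows <- if (single_only) which(lengths(fmatrix$experiments$genes) == 1L)
  else seq_len(nrow(fmatrix$blocked))
  if (length(rows) == 0)
    stop("no knockout rows to summarize", call. = FALSE)
  types <- unique(c(SPECIES_TYPES, INTERACTION_TYPES, fmatrix$object_type))
  types <- types[types %in% fmatrix$object_type]
  b <- fmatrix$blocked[rows, , drop = FALSE]
  ind <- Matrix::sparseMatrix(
    i = seq_along(fmatrix$object_type),
    j = match(fmatrix$object_type, types),
    x = 1, dims = c(length(fmatrix$object_type), length(types)))
  counts <- as.matrix(b %*% ind)  # knockouts x types blocked-object counts
  res <- data.frame(object_type = types,
                    n_knockouts = length(rows),
                    damage_probability = colMeans(counts > 0),
                    mean_blocked = NA_real_, sd_blocked = NA_real_,
                    stringsAsFactors = FALSE)
  for (t in seq_along(types)) {
    hit <- counts[counts[, t] > 0, t]
    if (length(hit)) {
      res$mean_blocked[t] <- mean(hit)
      res$sd_blocked[t] <- if (length(hit) > 1) stats::sd(hit) else 0
    }
  }
  rownames(res) <- NULL
  res
}
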