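# Constraint-based metabolic damage.
#
# A stoichiometric model holds the metabolite x reaction matrix, flux
# bounds, exchange flags and optional gene-protein-reaction (GPR) rules.
# A knockout disables the reactions whose GPR evaluates false; a
# flux-balance method then detects every reaction that cannot carry a
# steady-state flux (blocked), and a metabolite is blocked when all its
# producing reactions are blocked and it cannot be taken up from the
# medium. Under the maximally permissive medium (all exchange reactions
# open in both directions, subsuming aerobic complex-medium conditions)
# the blockage is unconditional: it is present under every medium.

# ---- GPR rules -------------------------------------------------------

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[toks != ""]
}

gpr_parse_expr <- function(toks, pos) {
  res <- gpr_parse_term(toks, pos)
  args <- list(res$node)
  pos <- res$pos
  while (pos <= length(toks) && toupper(toks[pos]) == "OR") {
    res <- gpr_parse_term(toks, pos + 1L)
    args[[length(args) + 1L]] <- res$node
    pos <- res$pos
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, pos = pos)
}

gpr_parse_term <- function(toks, pos) {
  res <- gpr_parse_factor(toks, pos)
  args <- list(res$node)
  pos <- res$pos
  while (pos <= length(toks) && toupper(toks[pos]) == "AND") {
    res <- gpr_parse_factor(toks, pos + 1L)
    args[[length(args) + 1L]] <- res$node
    pos <- res$pos
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, pos = pos)
}

gpr_parse_factor <- function(toks, pos) {
  if (pos > length(toks))
    stop("malformed GPR rule: unexpected end of expression", call. = FALSE)
  tok <- toks[pos]
  if (tok == "(") {
    res <- gpr_parse_expr(toks, pos + 1L)
    if (res$pos > length(toks) || toks[res$pos] != ")")
      stop("malformed GPR rule: missing ')'", call. = FALSE)
    return(list(node = res$node, pos = res$pos + 1L))
  }
  if (tok == ")" || toupper(tok) %in% c("AND", "OR"))
    stop("malformed GPR rule: unexpected token '", tok, "'", call. = FALSE)
  list(node = list(op = "gene", gene = tok), pos = pos + 1L)
}

#' Parse a gene-protein-reaction rule
#'
#' GPR associations are Boolean expressions over gene identifiers with
#' `AND` (complex subunits) and `OR` (isozymes) connectives and
#' parentheses, e.g. `"(g1 AND g2) OR g3"`.
#'
#' @param text rule string; `NA` or `""` yields `NULL` (no rule).
#' @return A parsed rule of class `refnet_gpr`, or `NULL`.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || trimws(text) == "") return(NULL)
  toks <- gpr_tokenize(text)
  res <- gpr_parse_expr(toks, 1L)
  if (res$pos <= length(toks))
    stop("malformed GPR rule: trailing token '", toks[res$pos], "'",
         call. = FALSE)
  structure(res$node, class = "refnet_gpr")
}

gpr_eval_node <- function(node, knocked) {
  switch(node$op,
         gene = !(node$gene %in% knocked),
         and = all(vapply(node$args, gpr_eval_node, TRUE, knocked = knocked)),
         or = any(vapply(node$args, gpr_eval_node, TRUE, knocked = knocked)))
}

#' Evaluate a GPR rule under a knockout
#'
#' Knocked genes are false, all others true; standard Boolean evaluation
#' decides whether the enzyme of the reaction is still available.
#'
#' @param rule a `refnet_gpr` (from [parse_gpr()]) or a rule string;
#'   `NULL`/`NA` (no rule) evaluates to `TRUE`.
#' @param knocked_genes character vector of knocked-out gene ids.
#' @return Logical availability.
#' @export
evaluate_gpr <- function(rule, knocked_genes) {
  if (!is.null(rule) && !inherits(rule, "refnet_gpr"))
    rule <- parse_gpr(rule)
  if (is.null(rule)) return(TRUE)
  gpr_eval_node(rule, knocked_genes)
}

#' Genes referenced by a GPR rule
#' @param rule a `refnet_gpr` or rule string.
#' @return Character vector of gene ids.
#' @export
gpr_genes <- function(rule) {
  if (!is.null(rule) && !inherits(rule, "refnet_gpr"))
    rule <- parse_gpr(rule)
  if (is.null(rule)) return(character())
  gpr_node_genes(rule)
}

gpr_node_genes <- function(node) {
  if (node$op == "gene") return(node$gene)
  unique(unlist(lapply(node$args, gpr_node_genes)))
}

# ---- Stoichiometric model -------------------------------------------

#' Construct a stoichiometric model
#'
#' @param stoich metabolite x reaction matrix with dimnames (substrate
#'   coefficients negative, product coefficients positive); dense or
#'   sparse.
#' @param lb,ub lower/upper flux bounds per reaction. Reversible internal
#'   reactions are assumed pre-split, so non-exchange reactions must have
#'   `lb = 0`; exchange reactions may carry a negative lower bound
#'   (uptake flows into the system as negative flux).
#' @param exchange logical vector flagging exchange reactions (boundary
#'   reactions touching exactly one metabolite); by default, single
#'   metabolite columns are auto-detected.
#' @param gpr character vector of GPR rule strings (`NA` = no rule).
#' @param compartment optional compartment label per metabolite.
#' @param medium character vector of exchange reaction ids open for
#'   uptake; defaults to all exchange reactions.
#' @return An object of class `refnet_smodel`.
#' @export
stoichiometric_model <- function(stoich, lb, ub, exchange = NULL,
                                 gpr = NULL, compartment = NULL,
                                 medium = NULL) {
  S <- Matrix::Matrix(stoich, sparse = TRUE)
  if (is.null(dimnames(S)) || is.null(rownames(S)) || is.null(colnames(S)))
    stop("stoichiometric matrix needs metabolite row names and reaction column names",
         call. = FALSE)
  nr <- ncol(S)
  if (is.null(exchange))
    exchange <- Matrix::colSums(S != 0) == 1L
  exchange <- as.logical(rep_len(exchange, nr))
  if (is.null(gpr)) gpr <- rep(NA_character_, nr)
  model <- structure(list(
    S = S, lb = rep_len(as.numeric(lb), nr), ub = rep_len(as.numeric(ub), nr),
    exchange = exchange, gpr = as.character(gpr),
    metabolites = rownames(S), reactions = colnames(S),
    compartment = if (is.null(compartment)) rep(NA_character_, nrow(S))
    else rep_len(as.character(compartment), nrow(S)),
    medium = if (is.null(medium)) colnames(S)[exchange] else medium
  ), class = "refnet_smodel")
  validate_smodel(model)
  model
}

validate_smodel <- function(model) {
  S <- model$S
  empty <- Matrix::colSums(S != 0) == 0
  if (any(empty))
    stop("reaction touches no metabolite: ",
         paste(model$reactions[empty], collapse = ", "), call. = FALSE)
  multi <- model$exchange & Matrix::colSums(S != 0) != 1L
  if (any(multi))
    stop("exchange reaction must touch exactly one metabolite: ",
         paste(model$reactions[multi], collapse = ", "), call. = FALSE)
  bad <- !model$exchange & model$lb < 0
  if (any(bad))
    stop("internal reactions must be irreversible (lb >= 0; split reversibles first): ",
         paste(model$reactions[bad], collapse = ", "), call. = FALSE)
  if (any(model$lb > model$ub))
    stop("lower bound exceeds upper bound", call. = FALSE)
  invisible(model)
}

#' @export
print.refnet_smodel <- function(x, ...) {
  cat(sprintf("<refnet_smodel> %d metabolites x %d reactions (%d exchange, %d with GPR)\n",
              nrow(x$S), ncol(x$S), sum(x$exchange), sum(!is.na(x$gpr))))
  invisible(x)
}

# Decide whether reaction j can carry flux of the given sign inside the
# steady-state flux region {v : S v = 0, lb <= v <= ub}. The region
# contains 0 and the bounds contain 0, so v_j can be nonzero iff the
# strictly convex program min 0.5*||v||^2 - sign * v_j has a solution with
# v_j of that sign (moving from the origin along any feasible direction
# with the right sign strictly lowers the objective). The Goldfarb-Idnani
# dual active-set method behind quadprog::solve.QP handles the degenerate
# vertices that defeat plain simplex codes on these problems. Linearly
# dependent rows of S are dropped via a rank-revealing QR first.
flux_direction <- function(S, lb, ub, j, sign) {
  S <- as.matrix(S)
  n <- ncol(S)
  qrS <- qr(t(S))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  Seq <- S[keep, , drop = FALSE]
  d <- numeric(n)
  d[j] <- sign
  sol <- quadprog::solve.QP(
    Dmat = diag(n), dvec = d,
    Amat = cbind(t(Seq), diag(n), -diag(n)),
    bvec = c(rep(0, nrow(Seq)), lb, -ub),
    meq = nrow(Seq))
  sol$solution
}

#' Detect reactions that cannot carry flux
#'
#' A reaction is blocked iff its maximal attainable flux magnitude under
#' steady state (`S v = 0`) and the bounds is below tolerance. Each
#' candidate reaction is tested in both flux directions (the maximize /
#' minimize pair of the flux-variability test, decided by a strictly
#' convex program per direction); reactions observed carrying flux in any
#' solved program are cleared without their own solve. The all-zero flux
#' vector always satisfies the constraints, so the base problem is
#' feasible and the returned set includes the disabled reactions.
#'
#' @param model a `refnet_smodel`.
#' @param disabled reaction ids clamped to zero flux (e.g. GPR-disabled).
#' @param tol flux magnitude below which a reaction counts as carrying no
#'   flux (default `1e-9`).
#' @param big bound magnitude substituted for infinite bounds.
#' @return Character vector of blocked reaction ids (disabled included).
#' @export
find_blocked_reactions <- function(model, disabled = character(),
                                   tol = 1e-9, big = 1000) {
  lb <- pmax(model$lb, -big)
  ub <- pmin(model$ub, big)
  off <- match(disabled, model$reactions)
  if (anyNA(off))
    stop("unknown reaction id in 'disabled': ",
         paste(disabled[is.na(off)], collapse = ", "), call. = FALSE)
  lb[off] <- 0
  ub[off] <- 0
  n <- ncol(model$S)
  can_flux <- logical(n)
  for (j in seq_len(n)) {
    if (can_flux[j] || (lb[j] == 0 && ub[j] == 0)) next
    v <- flux_direction(model$S, lb, ub, j, +1)
    can_flux[abs(v) > tol] <- TRUE
    if (can_flux[j]) next
    v <- flux_direction(model$S, lb, ub, j, -1)
    can_flux[abs(v) > tol] <- TRUE
  }
  model$reactions[!can_flux]
}

#' Blocked metabolites given blocked reactions and a medium
#'
#' A metabolite is blocked iff all the reactions producing it are blocked
#' and its uptake is not possible from the cultivation medium. Producers
#' are non-exchange reactions with a positive stoichiometric coefficient
#' for the metabolite; uptake is possible when an exchange reaction for
#' the metabolite is open in the medium, so a metabolite with an open
#' uptake is never blocked. A metabolite with no producers and no open
#' uptake is blocked (the producer condition holds vacuously).
#'
#' @param model a `refnet_smodel`.
#' @param blocked_reactions character vector of blocked reaction ids.
#' @param medium exchange reaction ids open for uptake; defaults to
#'   `model$medium`.
#' @return Character vector of blocked metabolite ids.
#' @export
blocked_metabolites <- function(model, blocked_reactions,
                                medium = model$medium) {
  stopifnot(all(blocked_reactions %in% model$reactions))
  S <- model$S
  is_blocked <- model$reactions %in% blocked_reactions
  open_uptake <- model$reactions %in% medium & model$exchange
  out <- character()
  for (m in seq_len(nrow(S))) {
    row <- S[m, ]
    producers <- which(row > 0 & !model$exchange)
    uptake <- any(open_uptake & row != 0)
    if (!uptake && all(is_blocked[producers]))
      out <- c(out, model$metabolites[m])
  }
  out
}

#' Unconditional metabolic damage of a knockout
#'
#' Opens every exchange reaction in both directions (the cell may take up
#' and secrete every metabolite for which an exchange exists -- a complex
#' aerobic medium is a special case), disables the reactions whose GPR
#' rule evaluates false under the knockout, and composes
#' [find_blocked_reactions()] and [blocked_metabolites()]. Reactions
#' blocked under this maximally permissive medium are blocked under every
#' other medium. The constitutively blocked baseline (no knockout) is
#' reported separately and the knockout damage is returned net of it, so
#' only the additional blockage counts as damage.
#'
#' @param model a `refnet_smodel` with exchange reactions.
#' @param knocked_genes character vector of knocked-out gene ids.
#' @param baseline optional precomputed baseline blocked set (reaction
#'   ids) to avoid recomputation across a batch of knockouts.
#' @param tol,big passed to [find_blocked_reactions()].
#' @return An object of class `refnet_mdamage`: list with `disabled`
#'   (GPR-false reactions), `blocked` (all blocked reactions),
#'   `blocked_metabolites`, `baseline` and `baseline_metabolites`
#'   (constitutively blocked), and `damage_reactions` /
#'   `damage_metabolites` (net of baseline).
#' @export
unconditional_damage <- function(model, knocked_genes, baseline = NULL,
                                 tol = 1e-9, big = 1000) {
  if (!any(model$exchange))
    stop("model has no exchange reactions; cannot define a medium",
         call. = FALSE)
  open <- model
  open$lb[model$exchange] <- -big
  open$ub[model$exchange] <- big
  open$medium <- model$reactions[model$exchange]

  rules <- lapply(model$gpr, parse_gpr)
  disabled <- model$reactions[!vapply(rules, evaluate_gpr, TRUE,
                                      knocked_genes = knocked_genes)]
  if (is.null(baseline))
    baseline <- find_blocked_reactions(open, character(), tol = tol,
                                       big = big)
  blocked <- find_blocked_reactions(open, disabled, tol = tol, big = big)
  mets <- blocked_metabolites(open, blocked)
  base_mets <- blocked_metabolites(open, baseline)
  structure(list(
    knockout = knocked_genes,
    disabled = disabled,
    blocked = blocked,
    blocked_metabolites = mets,
    baseline = baseline,
    baseline_metabolites = base_mets,
    damage_reactions = setdiff(blocked, baseline),
    damage_metabolites = setdiff(mets, base_mets)
  ), class = "refnet_mdamage")
}

#' Write a stoichiometric model as a TSV trio
#'
#' `reactions.tsv` holds one row per reaction (id, lb, ub, exchange, gpr),
#' `stoichiometry.tsv` the nonzero coefficients as (metabolite, reaction,
#' coef) triples, and `metabolites.tsv` the metabolite list with optional
#' compartments. [read_stoichiometric_model()] is the inverse.
#'
#' @param model a `refnet_smodel`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_stoichiometric_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(id = model$reactions, lb = model$lb, ub = model$ub,
                       exchange = model$exchange,
                       gpr = ifelse(is.na(model$gpr), "", model$gpr)),
            file.path(dir, "reactions.tsv"))
  tri <- Matrix::summary(methods::as(model$S, "TsparseMatrix"))
  write_tsv(data.frame(metabolite = model$metabolites[tri$i],
                       reaction = model$reactions[tri$j],
                       coef = tri$x),
            file.path(dir, "stoichiometry.tsv"))
  write_tsv(data.frame(id = model$metabolites,
                       compartment = ifelse(is.na(model$compartment), "",
                                            model$compartment)),
            file.path(dir, "metabolites.tsv"))
  invisible(dir)
}

#' Read a stoichiometric model from a TSV trio
#'
#' @param dir directory written by [write_stoichiometric_model()].
#' @return A `refnet_smodel`.
#' @export
read_stoichiometric_model <- function(dir) {
  rx <- read_tsv(file.path(dir, "reactions.tsv"))
  met <- read_tsv(file.path(dir, "metabolites.tsv"))
  tri <- read_tsv(file.path(dir, "stoichiometry.tsv"))
  S <- Matrix::sparseMatrix(
    i = match(tri$metabolite, met$id),
    j = match(tri$reaction, rx$id),
    x = as.numeric(tri$coef),
    dims = c(nrow(met), nrow(rx)),
    dimnames = list(met$id, rx$id))
  stoichiometric_model(
    S, lb = as.numeric(rx$lb), ub = as.numeric(rx$ub),
    exchange = as.logical(rx$exchange),
    gpr = ifelse(rx$gpr == "", NA_character_, rx$gpr),
    compartment = ifelse(met$compartment == "", NA_character_,
                         met$compartment))
}

#' @export
print.refnet_mdamage <- function(x, ...) {
  cat(sprintf("<refnet_mdamage> knockout {%s}: %d disabled, %d blocked (%d baseline), damage %d reactions + %d metabolites\n",
              paste(x$knockout, collapse = ", "), length(x$disabled),
              length(x$blocked), length(x$baseline),
              length(x$damage_reactions), length(x$damage_metabolites)))
  invisible(x)
}
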