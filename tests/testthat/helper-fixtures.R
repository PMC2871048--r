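# Shared fixtures and independent oracles, built in code.

# minimal central-dogma chain: gene -> transcription -> transcript ->
# translation -> protein (5 objects)
chain_network <- function() {
  sp <- species_table(c("g:0001", "tr:0001", "p:0001"),
                      c("gene", "transcript", "protein"),
                      primary_sequence = c("ATG", "ATG", "M"))
  ix <- interaction_table(
    c("ix:txn:0001", "ix:tln:0001"),
    c("transcription", "translation"),
    substrates = list(stoich(), stoich()),
    products = list(stoich("tr:0001"), stoich("p:0001")),
    controllers = list("g:0001", "tr:0001"))
  new_network(sp, ix)
}

# two genes with distinct transcripts translating to one shared protein:
# knocking either gene leaves the protein feasible via the other route
redundant_route_network <- function() {
  sp <- species_table(
    c("g:0001", "g:0002", "tr:0001", "tr:0002", "p:0001"),
    c("gene", "gene", "transcript", "transcript", "protein"),
    primary_sequence = c("AAA", "CCC", "AAA", "CCC", "K"))
  ix <- interaction_table(
    c("ix:txn:0001", "ix:txn:0002", "ix:tln:0001", "ix:tln:0002"),
    c("transcription", "transcription", "translation", "translation"),
    substrates = replicate(4, stoich(), simplify = FALSE),
    products = list(stoich("tr:0001"), stoich("tr:0002"),
                    stoich("p:0001"), stoich("p:0001")),
    controllers = list("g:0001", "g:0002", "tr:0001", "tr:0002"))
  new_network(sp, ix)
}

small_network_config <- function(seed, ...) {
  network_config(n_genes = 30, n_complex_records = 60, n_metabolites = 30,
                 n_reactions = 25, n_exchange = 5, seed = seed, ...)
}

# independent Boolean oracle: repeatedly re-evaluate every rule in a
# shuffled order until no value changes
oracle_damage <- function(network, knocked) {
  sp <- network$species
  ix <- network$interactions
  feas <- stats::setNames(rep(TRUE, nrow(sp) + nrow(ix)),
                          c(sp$id, ix$id))
  feas[knocked] <- FALSE
  produced <- unique(unlist(lapply(ix$products, function(p) p$species)))
  is_root <- stats::setNames(!(sp$id %in% produced), sp$id)
  producers <- lapply(sp$id, function(s) {
    ix$id[vapply(ix$products, function(p) s %in% p$species, TRUE)]
  })
  names(producers) <- sp$id
  reqs <- lapply(seq_len(nrow(ix)), function(k) {
    unique(c(ix$substrates[[k]]$species, ix$controllers[[k]]))
  })
  names(reqs) <- ix$id
  is_ix <- stats::setNames(c(rep(FALSE, nrow(sp)), rep(TRUE, nrow(ix))),
                           c(sp$id, ix$id))
  repeat {
    changed <- FALSE
    for (id in sample(names(feas))) {
      new <- if (is_ix[[id]]) {
        all(feas[reqs[[id]]])
      } else if (id %in% knocked) {
        FALSE
      } else if (is_root[[id]]) {
        TRUE
      } else {
        any(feas[producers[[id]]])
      }
      if (new != feas[[id]]) {
        feas[id] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  names(feas)[!feas]
}

# independent GPR oracle: translate the rule text to an R logical
# expression and eval it under the assignment
oracle_gpr <- function(text, knocked) {
  expr <- gsub("\\bAND\\b", "&&", gsub("\\bOR\\b", "||", text,
                                       ignore.case = TRUE),
               ignore.case = TRUE)
  genes <- setdiff(strsplit(gsub("[()]", " ", text), "\\s+")[[1]],
                   c("", "AND", "OR", "and", "or"))
  env <- list2env(as.list(stats::setNames(!(genes %in% knocked), genes)),
                  parent = baseenv())
  eval(parse(text = expr), envir = env)
}

random_gpr <- function(genes) {
  pick <- function() sample(genes, 1)
  clause <- function() {
    k <- sample(1:3, 1)
    paste(replicate(k, pick()), collapse = sample(c(" AND ", " OR "), 1))
  }
  k <- sample(1:3, 1)
  paste(sprintf("(%s)", replicate(k, clause())),
        collapse = sample(c(" AND ", " OR "), 1))
}

python_bin <- function() {
  p <- Sys.which("python")
  if (p == "") p <- Sys.which("python3")
  unname(p)
}

# independent blocked-reaction oracle: one maximize/minimize LP pair per
# reaction via scipy.optimize.linprog (HiGHS)
scipy_blocked_oracle <- function(models) {
  script <- c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "models = json.load(open(sys.argv[1]))",
    "out = []",
    "for mod in models:",
    "    S = np.array(mod['S']); lb = np.array(mod['lb']); ub = np.array(mod['ub'])",
    "    n = S.shape[1]",
    "    blocked = []",
    "    for j in range(n):",
    "        c = np.zeros(n); c[j] = 1.0",
    "        hi = linprog(-c, A_eq=S, b_eq=np.zeros(S.shape[0]), bounds=list(zip(lb, ub)), method='highs')",
    "        lo = linprog(c, A_eq=S, b_eq=np.zeros(S.shape[0]), bounds=list(zip(lb, ub)), method='highs')",
    "        if abs(-hi.fun) < 1e-9 and abs(lo.fun) < 1e-9:",
    "            blocked.append(j)",
    "    out.append(blocked)",
    "json.dump(out, open(sys.argv[2], 'w'))")
  pyf <- tempfile(fileext = ".py")
  writeLines(script, pyf)
  inf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  payload <- lapply(models, function(m) {
    list(S = unname(as.matrix(m$S)), lb = m$lb, ub = m$ub)
  })
  jsonlite::write_json(payload, inf, digits = NA)
  status <- system2(python_bin(), c(pyf, inf, outf))
  stopifnot(status == 0)
  lapply(jsonlite::fromJSON(outf, simplifyVector = FALSE),
         function(idx) unlist(idx) + 1)
}

network_genes <- function(network) {
  network$species$id[network$species$species_type == "gene"]
}

single_knockout_experiments <- function(network) {
  genes <- network_genes(network)
  knockout_experiments(genes, as.list(genes))
}
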