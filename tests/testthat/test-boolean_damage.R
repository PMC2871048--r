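test_that("compilation derives requirement sets, producer sets and roots", {
  net <- chain_network()
  model <- compile_boolean_model(net)
  # transcription requires only its gene; translation only its transcript
  expect_equal(model$requirements[[1]],
               match("g:0001", model$species_id))
  expect_equal(model$requirements[[2]],
               match("tr:0001", model$species_id))
  # gene is a root; transcript/protein each have one producer
  expect_equal(model$roots, "g:0001")
  expect_equal(model$producers_n[match("tr:0001", model$species_id)], 1L)

  # a 2-substrate enzymatic reaction has a requirement set of size 3
  sp <- species_table(c("p:e", "m:a", "m:b", "m:c"),
                      c("protein", "metabolite", "metabolite", "metabolite"),
                      primary_sequence = c("M", NA, NA, NA))
  ix <- interaction_table("ix:rxn:1", "metabolic_reaction",
                          substrates = list(stoich(c("m:a", "m:b"))),
                          products = list(stoich("m:c")),
                          controllers = list("p:e"))
  m2 <- compile_boolean_model(new_network(sp, ix))
  expect_length(m2$requirements[[1]], 3)
})

test_that("knockout damage propagates down the chain and stops at redundancy", {
  model <- compile_boolean_model(chain_network())
  d <- simulate_knockout(model, "g:0001")
  expect_setequal(d$infeasible, c("g:0001", "ix:txn:0001", "tr:0001",
                                  "ix:tln:0001", "p:0001"))
  expect_equal(d$size, 5)

  # protein with a second producing translation survives: damage size 4
  m2 <- compile_boolean_model(redundant_route_network())
  d2 <- simulate_knockout(m2, "g:0001")
  expect_setequal(d2$infeasible, c("g:0001", "ix:txn:0001", "tr:0001",
                                   "ix:tln:0001"))
  expect_equal(d2$size, 4)

  expect_error(simulate_knockout(model, "g:9999"), "unknown gene")
})

test_that("the fixed point equals the shuffled-order oracle on random networks", {
  set.seed(71)
  for (i in 1:6) {
    gen <- generate_network(small_network_config(seed = 300 + i))
    model <- compile_boolean_model(gen$network)
    genes <- network_genes(gen$network)
    for (g in list(sample(genes, 1), sample(genes, 2))) {
      mine <- simulate_knockout(model, g)$infeasible
      expect_setequal(mine, oracle_damage(gen$network, g))
    }
  }
})

test_that("damage is monotone in the knocked-out gene set", {
  set.seed(72)
  gen <- generate_network(small_network_config(seed = 888))
  model <- compile_boolean_model(gen$network)
  genes <- network_genes(gen$network)
  for (i in 1:20) {
    k1 <- sample(genes, sample(1:2, 1))
    k2 <- union(k1, sample(genes, 1))
    d1 <- simulate_knockout(model, k1)$infeasible
    d2 <- simulate_knockout(model, k2)$infeasible
    expect_true(all(d1 %in% d2))
  }
})

test_that("the feasibility matrix rows reproduce the per-strain damage", {
  model <- compile_boolean_model(chain_network())
  ex <- knockout_experiments(c("s1", "s2", "s3"),
                             list("g:0001", "g:0001", "g:0001"))
  fm <- batch_damage(model, ex)
  expect_equal(dim(fm$blocked), c(3, 5))
  expect_equal(unname(Matrix::rowSums(fm$blocked)), c(5, 5, 5))
  # duplicate experiments give identical rows
  expect_identical(fm$blocked[1, ], fm$blocked[2, ])

  # double knockout blocks at least the union of the single knockouts
  gen <- generate_network(small_network_config(seed = 21))
  m <- compile_boolean_model(gen$network)
  genes <- network_genes(gen$network)[1:2]
  fm2 <- batch_damage(m, knockout_experiments(
    c("a", "b", "ab"), list(genes[1], genes[2], genes)))
  un <- (fm2$blocked[1, ] | fm2$blocked[2, ])
  expect_true(all(which(un) %in% which(fm2$blocked[3, ])))
})

test_that("per-type damage statistics reflect the layered structure", {
  gen <- generate_network(small_network_config(seed = 31))
  model <- compile_boolean_model(gen$network)
  fm <- batch_damage(model, single_knockout_experiments(gen$network))
  st <- damage_statistics(fm)
  row <- function(t) st[st$object_type == t, ]
  expect_equal(row("gene")$damage_probability, 1)
  expect_equal(row("gene")$mean_blocked, 1)
  expect_equal(row("transcription")$damage_probability, 1)
  expect_equal(row("transcription")$mean_blocked, 1)
  expect_equal(row("transcription")$sd_blocked, 0)
  # at most one protein blocked per single knockout
  expect_equal(row("protein")$mean_blocked, 1)
  expect_equal(row("protein")$sd_blocked, 0)
})

test_that("types never reached report probability 0 and undefined means", {
  net <- chain_network()
  model <- compile_boolean_model(net)
  fm <- batch_damage(model, knockout_experiments("s1", list("g:0001")))
  st <- damage_statistics(fm)
  expect_false("metabolic_reaction" %in% st$object_type)

  # a network that has metabolism no knockout can reach
  sp <- rbind(net$species,
              species_table(c("m:a", "m:b"), "metabolite"))
  ix <- rbind(net$interactions,
              interaction_table("ix:rxn:1", "metabolic_reaction",
                                substrates = list(stoich("m:a")),
                                products = list(stoich("m:b")),
                                controllers = list(character())))
  m2 <- compile_boolean_model(new_network(sp, ix))
  fm2 <- batch_damage(m2, knockout_experiments("s1", list("g:0001")))
  st2 <- damage_statistics(fm2)
  mrow <- st2[st2$object_type == "metabolic_reaction", ]
  expect_equal(mrow$damage_probability, 0)
  expect_true(is.na(mrow$mean_blocked))

  expect_error(damage_statistics(fm_subset(fm, integer())), "no knockout")
})

test_that("an excluded ubiquitous metabolite no longer spreads blockage", {
  sp <- species_table(c("g:1", "tr:1", "p:1", "m:atp", "m:x", "m:y"),
                      c("gene", "transcript", "protein", "metabolite",
                        "metabolite", "metabolite"),
                      primary_sequence = c("A", "A", "M", NA, NA, NA))
  ix <- interaction_table(
    c("ix:txn:1", "ix:tln:1", "ix:rxn:atp", "ix:rxn:use"),
    c("transcription", "translation", "metabolic_reaction",
      "metabolic_reaction"),
    substrates = list(stoich(), stoich(), stoich(), stoich(c("m:atp", "m:x"))),
    products = list(stoich("tr:1"), stoich("p:1"), stoich("m:atp"),
                    stoich("m:y")),
    controllers = list("g:1", "tr:1", "p:1", character()))
  net <- new_network(sp, ix)
  # with ATP required, knocking the gene kills its producer and the consumer
  m_with <- compile_boolean_model(net)
  expect_true("ix:rxn:use" %in% simulate_knockout(m_with, "g:1")$infeasible)
  # excluded from requirement sets, the consumer survives
  m_excl <- compile_boolean_model(net, exclude_species = "m:atp")
  expect_false("ix:rxn:use" %in% simulate_knockout(m_excl, "g:1")$infeasible)
  expect_equal(m_excl$excluded_species, "m:atp")
})
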