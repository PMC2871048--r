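test_that("GPR rules evaluate isozymes with OR and complexes with AND", {
  expect_true(evaluate_gpr("g1 OR g2", "g1"))
  expect_false(evaluate_gpr("g1 AND g2", "g1"))
  expect_true(evaluate_gpr("(g1 AND g2) OR g3", c("g1")))
  expect_false(evaluate_gpr("(g1 AND g2) OR g3", c("g2", "g3")))
  expect_true(evaluate_gpr(NA, "g1"))  # no rule = always available
  expect_setequal(gpr_genes("(g1 AND g2) OR (g2 AND g3)"),
                  c("g1", "g2", "g3"))
  expect_error(parse_gpr("g1 AND"), "malformed")
  expect_error(parse_gpr("(g1 OR g2"), "malformed")
  expect_error(parse_gpr("g1 g2"), "trailing")
})

test_that("GPR evaluation agrees with an expression-evaluation oracle", {
  set.seed(55)
  pool <- sprintf("g%d", 1:6)
  for (i in 1:100) {
    rule <- random_gpr(pool)
    knocked <- sample(pool, sample(0:4, 1))
    expect_equal(evaluate_gpr(rule, knocked), oracle_gpr(rule, knocked),
                 info = rule)
  }
})

chain4_model <- function() {
  # EX_A -> A -> B -> EX_B (4 reactions, all can carry unit flux)
  S <- matrix(c(-1, -1, 0, 0,
                0, 1, -1, 0,
                0, 0, 1, -1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c("EX_A", "v1", "v2", "EX_C")))
  stoichiometric_model(S, lb = c(-1000, 0, 0, -1000), ub = 1000,
                       exchange = c(TRUE, FALSE, FALSE, TRUE),
                       gpr = c(NA, "g1", "g2 OR g3", NA))
}

test_that("a feasible chain is unblocked and a cut blocks it entirely", {
  m <- chain4_model()
  expect_length(find_blocked_reactions(m), 0)
  expect_setequal(find_blocked_reactions(m, disabled = "v1"),
                  c("EX_A", "v1", "v2", "EX_C"))
  expect_error(find_blocked_reactions(m, disabled = "nope"), "unknown")
})

test_that("metabolite blockage follows the producers-and-medium rule", {
  m <- chain4_model()
  # all reactions blocked, no medium: every metabolite blocked
  expect_setequal(blocked_metabolites(m, m$reactions, medium = character()),
                  c("A", "B", "C"))
  # B's only producer v1 blocked and no uptake for B -> blocked
  expect_true("B" %in% blocked_metabolites(m, "v1"))
  # A has an open (unblocked) uptake exchange -> never blocked
  expect_false("A" %in% blocked_metabolites(m, c("v1", "v2")))
  # a metabolite with one unblocked producer among several is not blocked
  S <- matrix(c(1, 1, 1), 1, dimnames = list("X", c("r1", "r2", "r3")))
  m2 <- stoichiometric_model(S, lb = 0, ub = 1000,
                             exchange = c(FALSE, FALSE, FALSE))
  expect_length(blocked_metabolites(m2, c("r1", "r2"),
                                    medium = character()), 0)
  expect_equal(blocked_metabolites(m2, c("r1", "r2", "r3"),
                                   medium = character()), "X")
})

test_that("blocked sets match the per-reaction LP-pair oracle on random toys", {
  set.seed(91)
  models <- list()
  setups <- list()
  for (i in 1:8) {
    mod <- generate_stoichiometric_model(seed = 500 + i, n_genes = 0)
    dis <- sample(mod$reactions[!mod$exchange], 2)
    lb <- mod$lb
    ub <- mod$ub
    j <- match(dis, mod$reactions)
    lb[j] <- 0
    ub[j] <- 0
    models[[i]] <- list(S = mod$S, lb = lb, ub = ub)
    setups[[i]] <- list(mod = mod, dis = dis)
  }
  oracle <- scipy_blocked_oracle(models)
  for (i in seq_along(models)) {
    mine <- find_blocked_reactions(setups[[i]]$mod,
                                   disabled = setups[[i]]$dis)
    expect_setequal(mine, setups[[i]]$mod$reactions[oracle[[i]]])
  }
})

test_that("the all-open medium blocks a subset of any restricted medium", {
  set.seed(92)
  for (i in 1:8) {
    mod <- generate_stoichiometric_model(seed = 700 + i, n_genes = 0)
    open <- mod
    open$lb[mod$exchange] <- -1000
    open$ub[mod$exchange] <- 1000
    b_open <- find_blocked_reactions(open)
    restr <- open
    closed <- which(mod$exchange)[stats::runif(sum(mod$exchange)) < 0.5]
    restr$lb[closed] <- 0
    expect_true(all(b_open %in% find_blocked_reactions(restr)))
  }
})

test_that("unconditional damage composes GPR, flux and metabolite blockage", {
  m <- chain4_model()
  md <- unconditional_damage(m, "g1")
  expect_equal(md$disabled, "v1")
  expect_setequal(md$blocked, c("EX_A", "v1", "v2", "EX_C"))
  expect_length(md$baseline, 0)
  expect_setequal(md$damage_reactions, md$blocked)
  expect_setequal(md$blocked_metabolites, "B")  # A and C have open uptake

  # isozyme redundancy shields v2
  md2 <- unconditional_damage(m, "g2")
  expect_length(md2$disabled, 0)
  expect_length(md2$damage_reactions, 0)

  # dead-end pathway shows up in the baseline, not the damage
  S <- matrix(c(-1, -1, 0,
                0, 1, -1,
                0, 0, 1),
              3, byrow = TRUE,
              dimnames = list(c("A", "B", "D"),
                              c("EX_A", "v1", "vdead")))
  m3 <- stoichiometric_model(S, lb = c(-1000, 0, 0), ub = 1000,
                             exchange = c(TRUE, FALSE, FALSE),
                             gpr = c(NA, NA, "g9"))
  md3 <- unconditional_damage(m3, "g1")
  expect_true("vdead" %in% md3$baseline)  # D has no outlet ever
  expect_false("vdead" %in% md3$damage_reactions)
})

test_that("knockout blockage always contains the no-knockout baseline", {
  set.seed(93)
  for (i in 1:5) {
    mod <- generate_stoichiometric_model(seed = 900 + i, n_genes = 4)
    md <- unconditional_damage(mod, sample(sprintf("g%d", 1:4), 1))
    expect_true(all(md$baseline %in% md$blocked))
    expect_true(all(md$disabled %in% md$blocked))
  }
})

test_that("stoichiometric models round-trip through the TSV trio", {
  mod <- generate_stoichiometric_model(seed = 15, n_genes = 4)
  dir <- withr::local_tempdir()
  write_stoichiometric_model(mod, dir)
  back <- read_stoichiometric_model(dir)
  expect_equal(as.matrix(back$S), as.matrix(mod$S))
  expect_equal(back$lb, mod$lb)
  expect_equal(back$ub, mod$ub)
  expect_identical(back$exchange, mod$exchange)
  expect_identical(back$gpr, mod$gpr)
  expect_setequal(find_blocked_reactions(back),
                  find_blocked_reactions(mod))
})

test_that("model invariants are enforced at construction", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "r1"))
  expect_error(stoichiometric_model(S, lb = -5, ub = 5,
                                    exchange = FALSE), "irreversible")
  S2 <- matrix(0, 1, 1, dimnames = list("A", "r1"))
  expect_error(stoichiometric_model(S2, lb = 0, ub = 1), "no metabolite")
  S3 <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "r1"))
  expect_error(stoichiometric_model(S3, lb = 0, ub = 1, exchange = TRUE),
               "exactly one metabolite")
})
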