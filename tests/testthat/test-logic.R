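# Combinatorial logic engine: enumeration, DNF compilation, occupancy ratio.

test_that("enumeration yields 32 unique configurations over 8 gate forms", {
  cfgs <- enumerate_configurations()
  expect_length(cfgs, 32)
  ids <- vapply(cfgs, `[[`, character(1), "variant_id")
  expect_equal(anyDuplicated(ids), 0)
  expect_equal(length(unique(vapply(cfgs, `[[`, character(1), "gate"))), 8)
  # valency letters map a..d -> (n_T, n_G) = (1,1), (1,2), (2,1), (2,2)
  expect_equal(unname(vapply(cfgs[c("3a", "3b", "3c", "3d")],
                             function(cf) c(cf$n_T, cf$n_G), integer(2))),
               matrix(c(1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L), nrow = 2))
  # the winning variant 6d: dimer TCF-1 AND (Notch OR dimer GATA-3)
  cf <- logic_config("6d")
  expect_equal(cf$gate, "TCF-1 AND (Notch OR GATA-3)")
  expect_equal(c(cf$n_T, cf$n_G), c(2L, 2L))
  expect_error(logic_config("9a"), "unknown variant")
})

test_that("compiled rate laws equal the truth-table oracle on all 32", {
  for (cf in enumerate_configurations()) {
    rl <- compile_rate_law(cf)
    expect_equal(canon_minterms(rl$minterms), oracle_minterms(cf),
                 info = cf$variant_id)
    # idempotence: recompiling gives identical minterms
    expect_identical(rl$minterms, compile_rate_law(cf)$minterms)
    expect_true(n_kappa(rl) >= 1 && n_kappa(rl) <= 3)
    # every minterm is non-empty
    expect_true(all(lengths(rl$minterms) >= 1))
  }
})

test_that("specific compilations match hand-expanded DNF", {
  rl1a <- compile_rate_law(logic_config("1a"))
  expect_equal(rl1a$minterms,
               list(c(Notch = 1L), c(`TCF-1` = 1L), c(`GATA-3` = 1L)))
  rl8b <- compile_rate_law(logic_config("8b"))
  expect_equal(rl8b$minterms,
               list(c(Notch = 1L, `TCF-1` = 1L, `GATA-3` = 2L)))
  rl6d <- compile_rate_law(logic_config("6d"))
  expect_equal(rl6d$minterms,
               list(c(Notch = 1L, `TCF-1` = 2L),
                    c(`TCF-1` = 2L, `GATA-3` = 2L)))
  expect_equal(format(rl6d), "k1*N*T^2 + k2*T^2*G^2")
})

test_that("gate parser rejects malformed expressions with a useful token", {
  expect_error(parse_gate("Notch NAND TCF-1"), "unrecognised token")
  expect_error(parse_gate("Notch AND (TCF-1"), "parenthesis")
  expect_error(parse_gate("AND Notch"), "unexpected token")
})

test_that("production ratio matches forced arithmetic and domain checks", {
  rl <- compile_rate_law(logic_config("1a"))
  conc <- c(Notch = 1, `TCF-1` = 1, `GATA-3` = 1)
  # weighted terms 1 + 1 + 2 -> 4/5
  expect_equal(production_ratio(rl, c(1, 1, 2), conc), 0.8)
  expect_equal(production_ratio(rl, c(1, 1, 2),
                                c(Notch = 0, `TCF-1` = 0, `GATA-3` = 0)), 0)
  expect_error(production_ratio(rl, c(-1, 1, 2), conc), "nonnegative")
  expect_error(production_ratio(rl, c(1, 1), conc), "one kappa")
  expect_error(production_ratio(rl, c(1, 1, 2),
                                c(Notch = -1, `TCF-1` = 0, `GATA-3` = 0)),
               "nonnegative")
})

test_that("production ratio is in [0,1) and monotone over random cases", {
  set.seed(101)
  cfgs <- enumerate_configurations()
  for (i in 1:1000) {
    cf <- cfgs[[sample.int(32, 1)]]
    rl <- compile_rate_law(cf)
    kap <- 10 ^ runif(n_kappa(rl), -4, 2)
    conc <- c(Notch = runif(1, 0, 5), `TCF-1` = runif(1, 0, 5),
              `GATA-3` = runif(1, 0, 5))
    r <- production_ratio(rl, kap, conc)
    expect_gte(r, 0)
    expect_lt(r, 1)
    # weak monotonicity in every kappa and activator concentration
    j <- sample.int(n_kappa(rl), 1)
    kap2 <- kap; kap2[j] <- kap2[j] * 1.5
    expect_gte(production_ratio(rl, kap2, conc), r)
    g <- sample(names(conc), 1)
    conc2 <- conc; conc2[g] <- conc2[g] + 1
    expect_gte(production_ratio(rl, kap, conc2), r)
  }
})

test_that("all-Notch-minterm configurations shut off at zero Notch", {
  for (id in c("5a", "5d", "8a", "8b", "8d")) {
    rl <- compile_rate_law(logic_config(id))
    expect_true(all(vapply(rl$minterms, function(m) "Notch" %in% names(m),
                           logical(1))))
    expect_equal(production_ratio(rl, rep(1, n_kappa(rl)),
                                  c(Notch = 0, `TCF-1` = 3, `GATA-3` = 3)),
                 0)
  }
})
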