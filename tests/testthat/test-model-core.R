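test_that("Izhikevich parameter draws follow the per-type generative rules", {
  set.seed(11)
  for (ct in c("MT", "GC", "PC", "FFI_FBI")) {
    p <- draw_izhikevich_params(ct, 500)
    expect_equal(p$b, rep(0.2, 500))
    r <- p$r
    switch(ct,
      MT = {
        expect_equal(p$a, 0.1 - 0.08 * r^4)
        expect_equal(p$d, 2 + 6 * r^4)
        expect_equal(p$c, rep(-65, 500))
      },
      PC = {
        expect_equal(p$a, 0.02 + 0.08 * r)
        expect_equal(p$d, 8 - 6 * r)
      },
      {
        expect_equal(p$a, 0.1 - 0.08 * r^2)
        expect_equal(p$c, -65 + 15 * r^2)
        expect_equal(p$d, rep(2, 500))
      })
    # implied parameter ranges
    expect_true(all(p$a >= 0.02 & p$a <= 0.1))
    expect_true(all(p$d >= 2 & p$d <= 8))
    expect_true(all(p$c >= -65 & p$c <= -50))
  }
  expect_error(draw_izhikevich_params("astrocyte", 5),
               class = "olfdrift_unknown_cell_type")
})

test_that("random weight blocks respect density, mean and sign", {
  set.seed(21)
  expect_equal(length(build_weight_block(50, 40, 0, 0.3)@x), 0)
  W <- build_weight_block(200, 150, 1, 0.25)
  expect_equal(length(W@x), 200 * 150)
  # sample mean within 3 SE of the nominal mean (uniform on (0, 0.5))
  se <- (0.5 / sqrt(12)) / sqrt(length(W@x))
  expect_lt(abs(mean(W@x) - 0.25), 3 * se)
  Wneg <- build_weight_block(100, 100, 0.2, -0.4)
  expect_true(all(Wneg@x <= 0))
  expect_error(build_weight_block(10, 10, 1.2, 0.1),
               class = "olfdrift_bad_rules")
  # realized density within 3 binomial SD
  W2 <- build_weight_block(300, 300, 0.05, 0.1)
  n <- 300 * 300
  expect_lt(abs(length(W2@x) - n * 0.05), 3 * sqrt(n * 0.05 * 0.95))
})

test_that("network assembly has the required shapes and structure", {
  spec <- mini_population_spec()
  set.seed(31)
  net <- build_network(spec)
  expect_s4_class(net$blocks$mtgc, "dgCMatrix")
  expect_equal(dim(W_mob(net)), rep(spec$n_mt + spec$n_gc, 2))
  expect_equal(dim(W_ff(net)), c(spec$n_pc + spec$n_ffi, spec$n_mt))
  expect_equal(dim(W_pcx(net)), rep(spec$n_pc + spec$n_ffi + spec$n_fbi, 2))
  expect_equal(dim(W_fb(net)), c(spec$n_gc, spec$n_pc))
  # the default (full-scale) spec has the reference dimensions
  ps <- population_spec()
  expect_equal(ps$n_mt + ps$n_gc, 13750)
  expect_equal(ps$n_pc + ps$n_ffi + ps$n_fbi, 12500)

  # cross-glomerular MC->MC entries are exactly zero
  glom <- mt_glomerulus_map(spec)
  tm <- as(net$blocks$mtmt, "TsparseMatrix")
  expect_true(all(glom[tm@i + 1] == glom[tm@j + 1]))
  expect_true(all(tm@i != tm@j))  # no autapses

  # sign discipline on every block
  exc <- c("mtmt", "mtgc", "mtpc", "mtffi", "pcpc", "pcfbi", "fb")
  inh <- c("gcmc", "gcgc", "ffipc", "fbipc", "ffiffi", "fbifbi")
  for (b in exc) expect_true(all(net$blocks[[b]]@x >= 0), label = b)
  for (b in inh) expect_true(all(net$blocks[[b]]@x <= 0), label = b)

  # feedback OFF -> zero block; delays cover the configured range
  net_off <- build_network(spec, feedback_on = FALSE)
  expect_equal(length(net_off$blocks$fb@x), 0)
  expect_true(all(net$delays_mtgc >= 1 & net$delays_mtgc <= 25))

  # realized per-block densities within 3 binomial SD of the rules
  rules <- net$rules
  dims <- list(mtgc = c(spec$n_gc, spec$n_mt), gcmc = c(spec$n_mt, spec$n_gc),
               mtpc = c(spec$n_pc, spec$n_mt), fbipc = c(spec$n_pc, spec$n_fbi))
  for (b in names(dims)) {
    p <- rules$density[rules$block == b]
    n <- prod(dims[[b]])
    expect_lt(abs(length(net$blocks[[b]]@x) - n * p),
              3 * sqrt(n * p * (1 - p)) + 1, label = b)
  }
})

test_that("network build is a pure function of the seed", {
  spec <- tiny_spec()
  set.seed(77); a <- build_network(spec)
  set.seed(77); b <- build_network(spec)
  for (nm in names(a$blocks)) expect_identical(a$blocks[[nm]], b$blocks[[nm]])
  expect_identical(a$delays_mtgc, b$delays_mtgc)
})

test_that("input-scale preservation keeps expected per-cell drive invariant", {
  full <- default_connectivity_rules(population_spec())
  mini <- default_connectivity_rules(mini_population_spec())
  expect_equal(full$effective_mean, full$mean_strength)  # multiplier 1 at scale 1
  # expected summed input per postsynaptic cell: density x pool x mean
  pool_f <- olfdrift:::block_pre_pool(population_spec())
  pool_m <- olfdrift:::block_pre_pool(mini_population_spec())
  for (b in c("mtgc", "gcmc", "mtpc", "fbipc")) {
    drive_f <- full$density[full$block == b] * pool_f[b] *
      full$effective_mean[full$block == b]
    drive_m <- mini$density[mini$block == b] * pool_m[b] *
      mini$effective_mean[mini$block == b]
    expect_equal(drive_m, drive_f, tolerance = 1e-12)
  }
})

test_that("weight dissimilarity separates identity from independent redraws", {
  spec <- tiny_spec()
  set.seed(41); a <- build_network(spec)
  expect_equal(weight_dissimilarity(a, a), 0)
  set.seed(42); b <- build_network(spec)
  set.seed(43); c3 <- build_network(spec)
  d_ab <- weight_dissimilarity(a, b)
  d_ac <- weight_dissimilarity(a, c3)
  # independent redraws sit on a plateau far from zero (Monte-Carlo oracle:
  # two independent pairs agree with each other)
  expect_gt(d_ab, 0.5)
  expect_lt(abs(d_ab - d_ac), 0.25)
  empty <- empty_network(spec)
  expect_error(weight_dissimilarity(empty, empty),
               class = "olfdrift_zero_variance")
})

test_that("reciprocal partner counting matches toy and binomial expectations", {
  # toy: 2 M/T, 2 GC, all four cross links present -> 2 partners each
  toy <- list(blocks = list(
    mtgc = Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                                x = rep(0.1, 4), dims = c(2, 2)),
    gcmc = Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                                x = rep(-0.1, 4), dims = c(2, 2))))
  class(toy) <- "olf_network"
  expect_equal(reciprocal_partner_count(toy), c(2L, 2L))

  # independent Bernoulli sampling: expectation n_gc x d_mtgc x d_gcmc
  spec <- mini_population_spec()
  set.seed(51)
  net <- build_network(spec)
  counts <- reciprocal_partner_count(net)
  expected <- spec$n_gc * 0.3 * 0.02
  expect_lt(abs(mean(counts) - expected),
            3 * sqrt(expected) / sqrt(spec$n_mt) + 0.5)
  # reciprocity boost raises the count
  set.seed(51)
  netb <- build_network(spec, reciprocity_boost = 0.5)
  expect_gt(mean(reciprocal_partner_count(netb)), mean(counts))
})

test_that("network round-trips through plain-text serialization", {
  spec <- tiny_spec()
  set.seed(61)
  net <- build_network(spec)
  dir <- withr_local_tempdir()
  write_network(net, dir)
  net2 <- read_network(dir)
  for (nm in names(net$blocks))
    expect_equal(as.matrix(net$blocks[[nm]]), as.matrix(net2$blocks[[nm]]),
                 label = nm)
  expect_equal(net$delays_mtgc, net2$delays_mtgc)
  expect_equal(net2$spec$n_gc, spec$n_gc)
})
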