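# Haar wavelet analysis/synthesis and the subband attention block

test_that("Haar analysis reproduces the closed-form examples", {
  # constant map: all energy in LL
  x <- array(1, c(2, 2, 1))
  s <- haar_dwt2(x)
  expect_equal(as.vector(s$LL), 2)
  expect_equal(as.vector(s$LH), 0)
  expect_equal(as.vector(s$HL), 0)
  expect_equal(as.vector(s$HH), 0)

  # sign alternation across the width axis: pure horizontal detail
  x2 <- array(c(1, 1, -1, -1), c(2, 2, 1))  # rows (1,-1) / (1,-1)
  s2 <- haar_dwt2(x2)
  expect_equal(as.vector(s2$LH), 2)
  expect_equal(as.vector(s2$LL), 0)
  expect_equal(as.vector(s2$HL), 0)
  expect_equal(as.vector(s2$HH), 0)

  # synthesis of a bare LL coefficient is the constant map
  z <- array(0, c(1, 1, 1))
  y <- haar_idwt2(list(LL = array(2, c(1, 1, 1)), LH = z, HL = z, HH = z))
  expect_equal(y, array(1, c(2, 2, 1)))
  expect_true(all(haar_idwt2(list(LL = z, LH = z, HL = z, HH = z)) == 0))
})

test_that("analysis matches the block-filter oracle and conserves energy", {
  set.seed(301)
  x <- rand_map(6, 4, 3)
  s <- haar_dwt2(x)
  ref <- dwt_ref(array(x, c(6, 4, 3, 1)))
  for (b in names(ref)) {
    expect_lt(max(abs(s[[b]] - ref[[b]][, , , 1])), 1e-6)
  }
  e_in <- sum(x^2)
  e_out <- sum(vapply(s, function(z) sum(z^2), numeric(1)))
  expect_lt(abs(e_out - e_in) / e_in, 1e-4)
  expect_error(haar_dwt2(rand_map(5, 4, 1)), "even")
})

test_that("synthesis inverts analysis to machine precision", {
  set.seed(302)
  for (i in 1:5) {
    d <- c(2 * sample(1:14, 2), sample(1:4, 1))
    x <- rand_map(d[1], d[2], d[3])
    expect_lt(max(abs(haar_idwt2(haar_dwt2(x)) - x)), 1e-5)
  }
  bad <- haar_dwt2(rand_map(4, 4, 2))
  bad$HH <- bad$HH[1, , , drop = FALSE]
  expect_error(haar_idwt2(bad), "identical shape")
})

test_that("attention core: zero maps to zero, shape is kept, oracle agrees", {
  set.seed(303)
  msa <- msa_block(8L)
  zero_parameters(msa)
  expect_true(all(msa_forward(msa, array(0, c(7, 7, 8))) == 0))

  msa2 <- msa_block(8L)
  x <- rand_map(7, 7, 8)
  expect_equal(dim(msa_forward(msa2, x)), dim(x))

  msa3 <- msa_block(4L)
  x3 <- rand_map(12, 12, 4, 1)
  expect_lt(max(abs(msa_forward(msa3, x3) - msa_ref(msa3, x3))), 1e-5)
  expect_error(msa_forward(msa3, rand_map(6, 6, 8)), "4 channels")
})

test_that("gate laws: unit gates reproduce the input, zero gates annihilate it", {
  set.seed(304)
  blk <- wssa_block(2L)
  x <- rand_map(8, 8, 2)
  blk$gate_override <- 1
  expect_lt(max(abs(wssa_forward(blk, x) - x)), 1e-5)
  blk$gate_override <- 0
  expect_true(all(wssa_forward(blk, x) == 0))
  blk$gate_override <- NULL
  expect_error(wssa_forward(blk, rand_map(7, 8, 2)), "even")
})

test_that("free gates stay inside (0,1) and the full oracle composition agrees", {
  set.seed(305)
  blk <- wssa_block(2L)
  x <- rand_map(8, 8, 2)
  y <- wssa_forward(blk, x)
  expect_equal(dim(y), c(8, 8, 2))
  expect_lt(max(abs(y - wssa_ref(blk, array(x, c(8, 8, 2, 1)))[, , , 1])), 1e-5)

  # gates are sigmoid outputs: reconstructing with unit gates must strictly
  # dominate the gated reconstruction energy unless the input is zero
  s <- haar_dwt2(x)
  e_sub <- sum(vapply(s, function(z) sum(z^2), numeric(1)))
  expect_lt(sum(y^2), e_sub)
})

test_that("subband-dropping variants bypass attention for the dropped band", {
  set.seed(306)
  x <- rand_map(8, 8, 2)
  for (dropb in c("LL", "LH", "HL", "HH")) {
    blk <- wssa_block(2L, drop_subband = dropb)
    expect_equal(blk$mods$msa$channels, 6L)  # 3C stacked, C = 2
    blk$gate_override <- 1
    expect_lt(max(abs(wssa_forward(blk, x) - x)), 1e-5)
    blk$gate_override <- 0
    y0 <- wssa_forward(blk, x)
    # only the unweighted dropped subband survives zero gates
    s <- haar_dwt2(x)
    kept0 <- s
    for (b in names(kept0)) if (b != dropb) kept0[[b]] <- kept0[[b]] * 0
    expect_lt(max(abs(y0 - haar_idwt2(kept0))), 1e-5)
  }
  expect_error(wssa_block(2L, drop_subband = "XX"), "LL/LH/HL/HH")
})

test_that("comparison wirings: plain round trip and per-subband attention", {
  set.seed(307)
  x <- rand_map(8, 8, 2)
  owt <- wssa_block(2L, mode = "owt")
  expect_lt(max(abs(wssa_forward(owt, x) - x)), 1e-5)
  expect_equal(count_parameters(owt), 0)

  per <- wssa_block(2L, mode = "per_subband_msa")
  y <- wssa_forward(per, x)
  expect_equal(dim(y), c(8, 8, 2))
  # oracle: independent MSA per subband, then synthesis
  s <- dwt_ref(array(x, c(8, 8, 2, 1)))
  for (b in names(s)) s[[b]] <- msa_ref(per$mods[[paste0("msa_", b)]], s[[b]])
  expect_lt(max(abs(y - idwt_ref(s)[, , , 1])), 1e-5)
})
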