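test_that("simple model charges p for anything but GT..AG", {
  m <- splice_model("simple", p = 13)
  expect_equal(donor_cost(m, "AAGTCC", 2), 0L)   # bases 3-4 are GT
  expect_equal(donor_cost(m, "AACTCC", 2), 13L)
  expect_equal(donor_cost(m, "AAGTCC", 5), 13L)  # window off the end
  expect_equal(acceptor_cost(m, "CCAGTT", 4), 0L)
  expect_equal(acceptor_cost(m, "CCATTT", 4), 13L)
  expect_equal(acceptor_cost(m, "CC", 1), 13L)
})

test_that("default donor table scores all 64 3-mers exactly", {
  m <- splice_model("default")
  nts <- c("A", "C", "G", "T")
  for (b1 in nts) for (b2 in nts) for (b3 in nts) {
    tri <- paste0(b1, b2, b3)
    want <- if (tri %in% c("GTA", "GTG")) 0L
      else if (tri %in% c("GTC", "GTT")) 8L
      else if (b1 == "G" && b2 == "C") 15L
      else if (b1 == "A" && b2 == "T") 21L
      else 30L
    expect_equal(donor_cost(m, paste0("AA", tri, "AA"), 2), want,
                 label = paste("donor", tri))
  }
})

test_that("default acceptor table scores all 64 3-mers exactly", {
  m <- splice_model("default")
  nts <- c("A", "C", "G", "T")
  for (b1 in nts) for (b2 in nts) for (b3 in nts) {
    tri <- paste0(b1, b2, b3)
    want <- if (tri %in% c("CAG", "TAG")) 0L
      else if (tri %in% c("AAG", "GAG")) 8L
      else if (b2 == "A" && b3 == "C") 21L
      else 30L
    expect_equal(acceptor_cost(m, paste0("AA", tri, "AA"), 5), want,
                 label = paste("acceptor", tri))
  }
})

test_that("default costs stay in the published value sets; simple p=30 bounds them", {
  m <- splice_model("default")
  s30 <- splice_model("simple", p = 30)
  nts <- c("A", "C", "G", "T")
  for (b1 in nts) for (b2 in nts) for (b3 in nts) {
    seq <- paste0("AA", b1, b2, b3, "AA")
    dc <- donor_cost(m, seq, 2); ac <- acceptor_cost(m, seq, 5)
    expect_true(dc %in% c(0L, 8L, 15L, 21L, 30L))
    expect_true(ac %in% c(0L, 8L, 21L, 30L))
    # for non-GT donors / non-AG acceptors the simple model is an upper bound
    if (!(b1 == "G" && b2 == "T"))
      expect_lte(dc, donor_cost(s30, seq, 2))
    if (!(b2 == "A" && b3 == "G"))
      expect_lte(ac, acceptor_cost(s30, seq, 5))
  }
})

test_that("frequency scaling reproduces the published acceptor penalty", {
  expect_equal(blosum_scaled_penalty(99.81, 0.10), 20L)
  expect_equal(blosum_scaled_penalty(50, 50), 0L)
  expect_equal(blosum_scaled_penalty(96, 3), 10L)
  expect_error(blosum_scaled_penalty(0, 1), "positive")
})
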