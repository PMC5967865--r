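test_that("trinucleotide mixes have the designed compositions", {
  m1 <- mix_definition("mix1")
  expect_equal(sum(m1$frequencies), 1, tolerance = 1e-12)
  expect_equal(unname(m1$frequencies["A"]), 0.106)
  expect_equal(unname(m1$frequencies["W"]), 0.05)
  expect_equal(unname(m1$frequencies["G"]), 0.02)
  expect_equal(sum(m1$frequencies > 0), 18)

  for (nm in c("mix1", "mix2", "mix3")) {
    m <- mix_definition(nm)
    expect_equal(sum(m$frequencies), 1, tolerance = 1e-9)
    expect_identical(unname(m$frequencies[c("C", "P")]), c(0, 0))
  }
  m2 <- mix_definition("mix2")
  expect_identical(unname(m2$frequencies[c("D", "A")]), c(0, 0))
  expect_equal(sum(m2$frequencies > 0), 16)
  m3 <- mix_definition("mix3")
  expect_identical(unname(m3$frequencies[c("D", "N", "Q", "G", "S", "M")]),
                   rep(0, 6))
  expect_equal(sum(m3$frequencies > 0), 12)
  # proportional renormalization preserves within-support ratios
  expect_equal(m2$frequencies[["S"]] / m2$frequencies[["E"]], 0.106 / 0.05)
  # uniform renormalization flattens them
  mu <- mix_definition("mix3", renormalization = "uniform")
  expect_true(all(abs(mu$frequencies[mu$frequencies > 0] - 1 / 12) < 1e-12))
  expect_error(mix_definition("mix4"), "unknown mix")
})

test_that("primer parsing yields the printed slot structure", {
  s1 <- parse_randomized_primer(sybody_primer("CDR1_a_b"))
  rand <- Filter(function(x) x$kind == "randomized", s1)
  expect_identical(vapply(rand, `[[`, "", "mix"),
                   c("mix1", "mix1", "mix1", "mix2", "mix3"))
  # the fixed ATG codon sits between the mix2 and mix3 slots
  kinds <- vapply(s1, `[[`, "", "kind")
  i <- which(kinds == "randomized")
  between <- s1[[i[4] + 1L]]
  expect_identical(between$kind, "fixed")
  expect_identical(between$codon, "ATG")
  expect_identical(i[5], i[4] + 2L)

  # CDR3_c: 9 mix1 + 1 mix2
  s3c <- parse_randomized_primer(sybody_primer("CDR3_c"))
  mixes <- vapply(Filter(function(x) x$kind == "randomized", s3c), `[[`, "",
                  "mix")
  expect_identical(sum(mixes == "mix1"), 9L)
  expect_identical(sum(mixes == "mix2"), 1L)
  expect_length(mixes, 10)

  # a primer with no placeholders has no randomized slots
  expect_equal(n_randomized(parse_randomized_primer("ATG GCA TTT")), 0)
  # non-triplet whitespace is cosmetic: the fixed run is re-split so that
  # its right edge stays in frame with the following placeholder
  s <- parse_randomized_primer("GA AGA CCT 111")
  expect_identical(vapply(Filter(function(x) x$kind == "fixed", s), `[[`, "",
                          "codon"), c("GA", "AGA", "CCT"))
  expect_error(parse_randomized_primer("ATG 444 GCA"), "'444'")
  expect_error(parse_randomized_primer("ATG NNN"), "'NNN'")
})

test_that("randomized-slot counts match the three library designs", {
  counts <- c(concave = 15L, loop = 16L, convex = 18L)
  for (lib in names(counts)) {
    expect_equal(n_randomized(randomization_scheme(lib)),
                 counts[[lib]], info = lib)
  }
})

test_that("theoretical diversity equals brute-force enumeration on toy schemes", {
  cases <- list(
    character(0),
    "mix1",
    c("mix3", "ATG"),
    c("mix2", "mix3"),
    c("mix1", "GCA", "mix3", "mix3"),
    c("ATG", "GCA")
  )
  for (mixes in cases) {
    slots <- toy_slots(mixes)
    expect_equal(as.numeric(theoretical_diversity(slots)),
                 enumerate_diversity(slots),
                 info = paste(mixes, collapse = "+"))
  }
})

test_that("library diversities are exact and round to the reported values", {
  exact <- c(concave = "831979165027663872",
             loop = "42645432044894552064",
             convex = "27634239965091669737472")
  reported <- c(concave = 8.3e17, loop = 4.3e19, convex = 2.8e22)
  for (lib in names(exact)) {
    d <- theoretical_diversity(randomization_scheme(lib))
    expect_identical(as.character(d), exact[[lib]], info = lib)
    expect_equal(diversity_signif(d), reported[[lib]], info = lib)
  }
})

test_that("library sampling is seed-reproducible and respects the scheme", {
  sch <- randomization_scheme("concave")
  a <- sample_library(sch, 25, seed = 11)
  b <- sample_library(sch, 25, seed = 11)
  expect_identical(as.character(a$dna), as.character(b$dna))
  c2 <- sample_library(sch, 25, seed = 12)
  expect_false(identical(as.character(a$dna), as.character(c2$dna)))

  # members never carry C or P at randomized positions
  expect_false(any(unlist(a$members) %in% c("C", "P")))

  # framework residues outside the CDR windows are untouched; at most the 15
  # randomized positions differ (plus none elsewhere)
  fw_prot <- strsplit(translate_dna(sybody_framework("concave")), "")[[1]]
  for (p in as.character(a$protein)[1:5]) {
    pv <- strsplit(p, "")[[1]]
    expect_equal(length(pv), length(fw_prot))
    expect_lte(sum(pv != fw_prot), 15)
  }
  # the scaffold's single disulfide: exactly two cysteines, never more
  expect_true(all(vapply(as.character(a$protein), function(p)
    lengths(regmatches(p, gregexpr("C", p, fixed = TRUE))), 1L) == 2L))

  expect_equal(length(sample_library(sch, 0, seed = 1)$dna), 0L)
  expect_error(sample_library(sch, -1, seed = 1), ">= 0")
})

test_that("sampled amino-acid frequencies follow the mix distribution", {
  # 4 mix1 slots x 25000 members = 1e5 independent draws from mix1
  sch <- randomization_scheme("toy",
    primers = c(CDR1 = "111 111 111 111"))
  lib <- sample_library(sch, 25000, seed = 42)
  draws <- unlist(lib$members)
  f <- mix_definition("mix1")$frequencies
  f <- f[f > 0]
  counts <- table(factor(draws, levels = names(f)))
  gof <- suppressWarnings(stats::chisq.test(counts, p = f))
  expect_gt(gof$p.value, 0.01)
})
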