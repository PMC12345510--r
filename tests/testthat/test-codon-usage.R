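test_that("translation table 5 has 62 sense codons and the expected quirks", {
  code <- genetic_code("5")
  expect_length(code$sense, 62)
  expect_setequal(code$stops, c("TAA", "TAG"))
  expect_equal(unname(code$map["AGA"]), "S")  # serine, not arginine
  expect_equal(unname(code$map["ATA"]), "M")
  expect_equal(unname(code$map["TGA"]), "W")
})

test_that("codon counting pools full codons and drops trailing remainders", {
  feats <- tibble::tibble(name = "COX1", category = "PCG", start = 0L,
                          end = 9L, strand = "+")
  g <- mito_genome("one", "ATGTTTTAA", feats, "linear")
  cc <- codon_counts(g)
  expect_equal(cc$count[cc$codon %in% c("ATG", "TTT", "TAA")], c(1L, 1L, 1L))
  expect_equal(sum(cc$count), 3L)
  # a 7-base gene contributes only 2 codons: the final single base is no codon
  feats7 <- tibble::tibble(name = "ND2", category = "PCG", start = 0L,
                           end = 7L, strand = "+")
  g7 <- mito_genome("seven", "ATGTTTT", feats7, "linear")
  expect_equal(sum(codon_counts(g7)$count), 2L)
})

test_that("codon counts reproduce the generator's emission tally", {
  res <- generate_genome(synthetic_spec(seed = 4))
  cc <- codon_counts(res$genome)
  man <- res$manifest$codon_counts
  expect_equal(cc$count[match(man$codon, cc$codon)], man$count)
  # count/translation consistency: every PCG contributes floor(len/3) codons
  lens <- res$genome$features$end[res$genome$features$category == "PCG"] -
    res$genome$features$start[res$genome$features$category == "PCG"]
  expect_equal(sum(cc$count), sum(lens %/% 3L))
})

test_that("RSCU matches hand calculations and the family oracle", {
  code <- genetic_code("5")
  counts <- tibble::tibble(codon = names(code$map), count = 0L)
  counts$count[counts$codon == "TTT"] <- 3L
  counts$count[counts$codon == "TTC"] <- 1L
  rs <- rscu(counts, code)
  expect_equal(rs$rscu[rs$codon == "UUU"], 1.5)
  expect_equal(rs$rscu[rs$codon == "UUC"], 0.5)
  # uniform counts give RSCU 1 everywhere
  uni <- tibble::tibble(codon = names(code$map), count = 2L)
  expect_equal(rscu(uni, code)$rscu, rep(1, 62))
  # random counts equal an independently coded per-family oracle
  set.seed(99)
  for (rep in 1:5) {
    rnd <- tibble::tibble(codon = names(code$map),
                          count = as.integer(rpois(length(code$map), 7)))
    rs <- rscu(rnd, code)
    oracle <- oracle_rscu(rnd, code)
    expect_equal(rs$rscu, unname(oracle[chartr("U", "T", rs$codon)]),
                 tolerance = 1e-12)
    # family conservation: RSCU sums to family size when the family is used
    sums <- tapply(rs$rscu, code$map[chartr("U", "T", rs$codon)], sum)
    sizes <- table(code$map[code$map != "*"])
    used <- !is.na(sums)
    expect_equal(as.numeric(sums[used]), as.numeric(sizes[names(sums)[used]]))
  }
})

test_that("split-family normalization is available and differs for Leu/Ser", {
  code <- genetic_code("5")
  counts <- tibble::tibble(codon = names(code$map), count = 0L)
  counts$count[counts$codon %in% c("TTA", "CTA")] <- c(6L, 2L)
  joint <- rscu(counts, code)
  split <- rscu(counts, code, split_families = TRUE)
  # jointly, both leucine codons share one 6-codon family
  expect_equal(joint$rscu[joint$codon == "UUA"], 6 / (8 / 6))
  # split, UUA is alone in the used part of the 2-codon UUR class
  expect_equal(split$rscu[split$codon == "UUA"], 6 / (6 / 2))
  expect_equal(joint$family[joint$codon == "UUA"], "Leu2")
  expect_equal(joint$family[joint$codon == "CUA"], "Leu1")
  expect_equal(joint$family[joint$codon == "AGA"], "Ser1")
  expect_equal(joint$family[joint$codon == "UCA"], "Ser2")
})

test_that("start/stop census classifies complete and incomplete terminators", {
  mk <- function(seqs) {
    feats <- tibble::tibble(
      name = pcg_tokens()[seq_along(seqs)], category = "PCG",
      start = c(0L, cumsum(nchar(seqs)))[seq_along(seqs)],
      end = cumsum(nchar(seqs)), strand = "+")
    mito_genome("census", paste(seqs, collapse = ""), feats, "linear")
  }
  g <- mk(c("ATGTTTTAA", "ATTTTTTA", "TTGTTTTAA"))
  cen <- start_stop_census(g)
  expect_equal(cen$start_codon, c("ATG", "ATT", "TTG"))
  expect_equal(cen$stop_codon, c("TAA", "TA", "TAA"))
  expect_equal(cen$is_atn_start, c(TRUE, TRUE, FALSE))
  expect_equal(cen$is_incomplete_stop, c(FALSE, TRUE, FALSE))
  # a complete final triplet that is not a stop is flagged 'other'
  expect_warning(cen2 <- start_stop_census(mk("ATGTTTAAA")), "possible misannotation")
  expect_equal(cen2$stop_codon, "other")
})

test_that("rank_codons orders by RSCU with alphabetical ties and can be empty", {
  tbl <- tibble::tibble(
    codon = c("UUA", "UCA", "CGA", "GGA", "AAA"),
    amino_acid = "X", family = "X", count = 1L,
    rscu = c(3.1, 2.4, 2.2, 2.2, 0.5))
  class(tbl) <- c("mito_rscu", class(tbl))
  top <- rank_codons(tbl, 2)
  expect_equal(top$codon, c("UUA", "UCA", "CGA", "GGA"))  # CGA before GGA: tie
  expect_equal(nrow(rank_codons(tbl, 5)), 0)
})

test_that("AT-biased generation favours A/U-ending codons at the top ranks", {
  res <- generate_genome(synthetic_spec(seed = 2))
  rs <- rscu(codon_counts(res$genome))
  top <- rank_codons(rs, 1.2)
  expect_gt(nrow(top), 3)
  third <- stringr::str_sub(top$codon, 3, 3)
  expect_gt(mean(third %in% c("A", "U")), 0.8)
})
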