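test_that("extracted order of an unedited synthetic genome is ancestral", {
  res <- generate_genome(synthetic_spec(seed = 7))
  o <- extract_gene_order(res$genome)
  anc <- ancestral_insect_order()
  expect_equal(o$gene, anc$gene)
  expect_equal(o$strand, anc$strand)
  expect_equal(nrow(diff_against(o, anc)), 0)
  expect_equal(breakpoint_count(o, anc), 0)
})

test_that("a coordinate swap of trnK/trnD surfaces as one anchored shuffle", {
  res <- generate_genome(synthetic_spec(seed = 7))
  g <- res$genome
  i <- which(g$features$name == "trnK")
  j <- which(g$features$name == "trnD")
  tmp <- g$features$name[i]
  g$features$name[i] <- g$features$name[j]; g$features$name[j] <- tmp
  ev <- diff_against(extract_gene_order(g), ancestral_insect_order())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "shuffle")
  expect_equal(ev$anchor, "COX2")
  expect_equal(ev$ancestral, "COX2-trnK-trnD")
  expect_equal(ev$derived, "COX2-trnD-trnK")
})

test_that("circular comparison is rotation invariant", {
  anc <- ancestral_insect_order()
  der <- mitocompare:::apply_edit(anc, list(kind = "shuffle",
                                            cluster = c("trnK", "trnD")))
  for (off in c(0, 5, 20, 37)) {
    rot <- mitocompare:::rotate_order(der, off)
    ev <- diff_against(rot, anc)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$kind, "shuffle")
    expect_equal(breakpoint_count(rot, anc), breakpoint_count(der, anc))
  }
  # a rotated but unrearranged order is reported identical
  expect_equal(nrow(diff_against(mitocompare:::rotate_order(anc, 10), anc)), 0)
})

test_that("the four rearrangement types are classified from order and sign", {
  anc <- ancestral_insect_order()
  cases <- list(
    list(edit = list(kind = "shuffle", cluster = c("trnK", "trnD")),
         kind = "shuffle"),
    list(edit = list(kind = "transposition", cluster = c("trnI", "trnQ", "trnM")),
         kind = "transposition"),
    list(edit = list(kind = "inversion", cluster = c("trnA", "trnR", "trnN")),
         kind = "inversion"),
    list(edit = list(kind = "inverse_transposition",
                     cluster = c("ATP8", "ATP6", "COX3")),
         kind = "inverse_transposition")
  )
  for (cs in cases) {
    der <- mitocompare:::apply_edit(anc, cs$edit)
    ev <- diff_against(der, anc)
    expect_equal(nrow(ev), 1, info = cs$kind)
    expect_equal(ev$kind, cs$kind)
    expect_setequal(ev$genes[[1]], cs$edit$cluster)
  }
  # the canonical trnI-trnQ-trnM -> trnM-trnI-trnQ change is a transposition
  der <- mitocompare:::apply_edit(anc, list(kind = "transposition",
                                            cluster = c("trnI", "trnQ", "trnM")))
  ev <- diff_against(der, anc)
  expect_equal(ev$derived, "trnM-trnI-trnQ(-)")
  # a single sign flip is an inversion
  flip <- anc
  flip$strand[flip$gene == "trnR"] <- "-"
  expect_equal(diff_against(flip, anc)$kind, "inversion")
})

test_that("event clusters substituted into the reference rebuild the derived order", {
  anc <- ancestral_insect_order()
  for (o in halictid_gene_orders()) {
    ev <- diff_against(o, anc)
    rebuilt <- anc
    for (i in seq_len(nrow(ev))) {
      genes <- ev$genes[[i]]
      pos <- match(genes, rebuilt$gene)
      span <- seq(min(pos), max(pos))
      der <- strsplit(ev$derived[i], "-(?!\\))", perl = TRUE)[[1]]
      if (!is.na(ev$anchor[i])) der <- der[-1]
      rebuilt$gene[span] <- sub("\\(-\\)$", "", der)
      rebuilt$strand[span] <- ifelse(grepl("\\(-\\)$", der), "-", "+")
    }
    expect_equal(rebuilt$gene, o$gene, info = attr(o, "taxon"))
    expect_equal(rebuilt$strand, o$strand, info = attr(o, "taxon"))
  }
})

test_that("breakpoint count matches hand and brute-force oracles", {
  # linear 5-gene toy, adjacent swap of two plus-strand genes -> 3 breakpoints
  ref <- perm_order(1:5)
  swp <- perm_order(c(1, 3, 2, 4, 5))
  expect_equal(breakpoint_count(ref, ref), 0)
  expect_equal(breakpoint_count(swp, ref), 3)
  # random signed permutations against the adjacency-set oracle
  set.seed(123)
  ref7 <- perm_order(1:7)
  for (i in 1:50) {
    p <- sample(7) * sample(c(-1, 1), 7, replace = TRUE)
    o <- perm_order(p)
    expect_equal(breakpoint_count(o, ref7),
                 oracle_breakpoints(signed_vec(o), signed_vec(ref7)))
  }
})

test_that("missing genes are excluded pairwise with a message", {
  anc <- ancestral_insect_order()
  partial <- anc[anc$gene != "trnK", ]
  attr(partial, "taxon") <- "partial"; attr(partial, "topology") <- "circular"
  class(partial) <- class(anc)
  expect_message(ev <- diff_against(partial, anc), "absent")
  expect_equal(nrow(ev), 0)
})

test_that("the halictid fixture orders carry the reported clusters", {
  ords <- halictid_gene_orders()
  joined <- vapply(ords, function(o) paste(o$gene, collapse = ","), character(1))
  # COX2 followed by trnD then trnK in all four taxa
  for (nm in names(ords)) {
    expect_true(grepl("COX2,trnD,trnK", joined[[nm]]), info = nm)
  }
  # the novel ND4-trnP-ND4L-trnT run only in L. guihongi
  has_novel <- grepl("ND4,trnP,ND4L,trnT", joined)
  expect_equal(names(ords)[has_novel], "Lipotriches guihongi")
  # no trnR/trnA swap in the Rophitinae species
  expect_true(grepl("trnA,trnR", joined[["Dufourea subclavicrus"]]))
  expect_true(grepl("trnR,trnA", joined[["Nomia thoracica"]]))
})

test_that("pattern catalog uses set semantics over canonical patterns", {
  anc <- ancestral_insect_order()
  # four ancestral copies: no patterns
  copies <- lapply(1:4, function(i) {
    o <- anc; attr(o, "taxon") <- paste0("t", i); o
  })
  expect_equal(nrow(catalog_patterns(copies)), 0)
  # two taxa sharing one derived cluster collapse to one pattern with both
  d1 <- mitocompare:::apply_edit(anc, list(kind = "shuffle", cluster = c("trnK", "trnD")))
  d2 <- d1
  attr(d1, "taxon") <- "a"; attr(d2, "taxon") <- "b"
  pats <- catalog_patterns(list(d1, d2))
  expect_equal(nrow(pats), 1)
  expect_setequal(pats$taxa[[1]], c("a", "b"))
  expect_equal(pats$n_taxa, 2L)
})

test_that("gene-order text files round trip", {
  ords <- halictid_gene_orders()
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_orders(ords, path)
  back <- read_gene_orders(path)
  expect_equal(names(back), names(ords))
  for (nm in names(ords)) {
    expect_equal(back[[nm]]$gene, ords[[nm]]$gene)
    expect_equal(back[[nm]]$strand, ords[[nm]]$strand)
  }
})
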