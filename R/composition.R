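#' Count bases in a DNA/RNA string
#'
#' Case-insensitive; `U` is counted as `T`; every character is classified
#' exactly once, with anything outside `A`/`T`/`G`/`C` (ambiguity codes,
#' gaps) pooled under `other`.
#'
#' @param seq Character scalar (DNA or RNA).
#' @return One-row tibble with integer columns `a`, `t`, `g`, `c`, `other`.
#' @export
count_bases <- function(seq) {
  s <- as_dna(seq)
  n <- nchar(s)
  a <- stringr::str_count(s, stringr::fixed("A"))
  t <- stringr::str_count(s, stringr::fixed("T"))
  g <- stringr::str_count(s, stringr::fixed("G"))
  c <- stringr::str_count(s, stringr::fixed("C"))
  tibble(a = a, t = t, g = g, c = c, other = n - a - t - g - c)
}

#' AT and GC strand-skew statistics
#'
#' `at_skew` is (A − T)/(A + T) and `gc_skew` is (G − C)/(G + C). Both are
#' scale-invariant, so raw counts and percentages are equally valid inputs.
#' A zero denominator yields `NA` with a warning (never 0, never an error).
#'
#' @param a,t,g,c Non-negative counts or percentages (vectorized).
#' @return Numeric vector in \[-1, 1\] (or `NA` where undefined).
#' @export
at_skew <- function(a, t) {
  denom <- a + t
  if (any(denom == 0, na.rm = TRUE)) {
    warn("A + T is zero for some input; AT-skew is undefined there (NA)")
  }
  ifelse(denom == 0, NA_real_, (a - t) / denom)
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  denom <- g + c
  if (any(denom == 0, na.rm = TRUE)) {
    warn("G + C is zero for some input; GC-skew is undefined there (NA)")
  }
  ifelse(denom == 0, NA_real_, (g - c) / denom)
}

# Collapse overlapping same-category spans so no genomic position is counted
# twice within a region class. Features are processed in genomic order; a
# later feature overlapping an earlier one is trimmed at its leading edge.
trim_category_overlaps <- function(feats) {
  feats <- feats[order(feats$start, feats$end), ]
  covered_end <- -1L
  keep <- logical(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    s <- feats$start[i]; e <- feats$end[i]
    if (e <= covered_end) next
    if (s < covered_end) {
      warn(paste0("overlapping features within category '", feats$category[i],
                  "'; overlap counted once"))
      feats$start[i] <- covered_end
    }
    covered_end <- max(covered_end, e)
    keep[i] <- TRUE
  }
  feats[keep, ]
}

#' Region- and codon-position-resolved nucleotide composition
#'
#' Computes, for a single genome, the eight standard rows of a mitogenome
#' composition table: the whole genome, the concatenated protein-coding
#' genes (PCGs), the first/second/third codon positions across all PCGs, the
#' concatenated tRNAs, rRNAs, and the control region. Gene regions are taken
#' in reading orientation; the whole-genome row covers every genomic
#' position exactly once. Codon positions are assigned per gene — the
#' counter restarts at each PCG's first base and cycles 1→2→3 through the
#' annotated CDS *including* any incomplete terminal codon, so
#' `site1 + site2 + site3` always equals the PCG total length.
#'
#' @param genome A [mito_genome()].
#' @return Tibble with one row per region: raw counts (`a`, `t`, `g`, `c`,
#'   `other`), `length` (bp), percentages over the unambiguous bases
#'   (`pct_a` ...), `at_content`, `gc_content`, `at_skew`, `gc_skew`.
#'   Site rows are omitted (with a warning) when the genome has no PCGs.
#' @export
composition_table <- function(genome) {
  len <- nchar(genome$sequence)
  rows <- list(region_counts("whole_genome", genome$sequence))

  pcgs <- trim_category_overlaps(
    genome$features[genome$features$category == "PCG", ])
  if (nrow(pcgs) == 0) {
    warn("genome has no annotated PCGs; PCG and codon-position rows omitted")
  } else {
    # feature order along the genome; counts are order-independent
    pcg_seqs <- vapply(seq_len(nrow(pcgs)),
                       function(i) region_sequence(genome, pcgs[i, ]),
                       character(1))
    rows <- c(rows, list(region_counts("PCGs", paste(pcg_seqs, collapse = ""))))
    site_seq <- codon_position_split(pcg_seqs)
    rows <- c(rows, list(region_counts("site1", site_seq[[1]]),
                         region_counts("site2", site_seq[[2]]),
                         region_counts("site3", site_seq[[3]])))
  }
  for (cat in c("tRNA", "rRNA", "CR")) {
    feats <- trim_category_overlaps(
      genome$features[genome$features$category == cat, ])
    if (nrow(feats) == 0) next
    seqs <- vapply(seq_len(nrow(feats)),
                   function(i) region_sequence(genome, feats[i, ]),
                   character(1))
    rows <- c(rows, list(region_counts(cat, paste(seqs, collapse = ""))))
  }
  dplyr::bind_rows(rows)
}

# Split per-gene reading-orientation CDS strings into the three codon-site
# strings, restarting the 1-2-3 cycle at each gene's first base.
codon_position_split <- function(pcg_seqs) {
  sites <- list(character(0), character(0), character(0))
  for (s in pcg_seqs) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- ((seq_along(chars) - 1L) %% 3L) + 1L
    for (k in 1:3) sites[[k]] <- c(sites[[k]], chars[pos == k])
  }
  lapply(sites, paste, collapse = "")
}

region_counts <- function(region, seq) {
  bc <- count_bases(seq)
  atgc <- bc$a + bc$t + bc$g + bc$c
  dplyr::bind_cols(
    tibble(region = region, length = nchar(seq)),
    bc,
    tibble(
      pct_a = 100 * bc$a / atgc, pct_t = 100 * bc$t / atgc,
      pct_g = 100 * bc$g / atgc, pct_c = 100 * bc$c / atgc,
      at_content = 100 * (bc$a + bc$t) / atgc,
      gc_content = 100 * (bc$g + bc$c) / atgc,
      at_skew = suppressWarnings(at_skew(bc$a, bc$t)),
      gc_skew = suppressWarnings(gc_skew(bc$g, bc$c))
    )
  )
}

#' Format a composition table for reporting
#'
#' Rounds to the conventional precisions of printed mitogenome tables
#' (percentages to 2 decimals, skews to 3, rounding half away from zero) and
#' orders the columns Regions, Length(bp), a, t, c, g, AT, GC, AT-Skew,
#' GC-Skew.
#'
#' @param tbl Output of [composition_table()].
#' @return Tibble ready for TSV export.
#' @export
format_composition <- function(tbl) {
  tibble(
    Regions = tbl$region,
    `Length(bp)` = tbl$length,
    a = round_half_away(tbl$pct_a, 2),
    t = round_half_away(tbl$pct_t, 2),
    c = round_half_away(tbl$pct_c, 2),
    g = round_half_away(tbl$pct_g, 2),
    AT = round_half_away(tbl$at_content, 2),
    GC = round_half_away(tbl$gc_content, 2),
    `AT-Skew` = round_half_away(tbl$at_skew, 3),
    `GC-Skew` = round_half_away(tbl$gc_skew, 3)
  )
}
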