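#' Genetic code descriptor
#'
#' Wraps a Biostrings translation table into the structure the codon-usage
#' operations consume. The default is NCBI translation table 5 (invertebrate
#' mitochondrial): 62 sense codons, stops TAA/TAG, AGA/AGG coding serine and
#' ATA methionine.
#'
#' @param id NCBI translation table id as a string (default `"5"`).
#' @return List with elements `id`, `map` (named character: DNA codon →
#'   amino-acid letter, `*` for stop), `stops`, `sense`.
#' @export
genetic_code <- function(id = "5") {
  map <- Biostrings::getGeneticCode(id)
  list(
    id = id,
    map = map,
    stops = names(map)[map == "*"],
    sense = names(map)[map != "*"]
  )
}

aa_display_names <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", K = "Lys", M = "Met",
  F = "Phe", P = "Pro", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  L = "Leu", S = "Ser"
)

# Display family label: Leu and Ser are split by codon class for reporting
# (Leu1 = CUN, Leu2 = UUR, Ser1 = AGN, Ser2 = UCN), as codon-usage figures
# conventionally do.
display_family <- function(codon, aa) {
  dplyr::case_when(
    aa == "L" & startsWith(codon, "CT") ~ "Leu1",
    aa == "L" ~ "Leu2",
    aa == "S" & startsWith(codon, "AG") ~ "Ser1",
    aa == "S" ~ "Ser2",
    TRUE ~ unname(aa_display_names[aa])
  )
}

#' Pooled codon counts over a genome's protein-coding genes
#'
#' Each annotated PCG is extracted in reading orientation and decomposed
#' into consecutive triplets from its first base; a trailing incomplete
#' codon (length mod 3 ≠ 0) is excluded from counting. Counts are pooled
#' across all PCGs. Stop codons are included in the counts (RSCU later
#' ignores them); genes shorter than one codon are skipped with a warning.
#'
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @return Tibble with one row per possible codon (DNA alphabet, 64 rows):
#'   `codon`, `count`.
#' @export
codon_counts <- function(genome, code = genetic_code()) {
  pcgs <- genome$features[genome$features$category == "PCG", ]
  all_codons <- names(code$map)
  counts <- stats::setNames(integer(length(all_codons)), all_codons)
  for (i in seq_len(nrow(pcgs))) {
    s <- region_sequence(genome, pcgs[i, ])
    if (nchar(s) < 3) {
      warn(paste0("PCG '", pcgs$name[i], "' shorter than one codon; skipped"))
      next
    }
    n_full <- nchar(s) %/% 3L
    cods <- substring(s, 3L * seq_len(n_full) - 2L, 3L * seq_len(n_full))
    tab <- table(cods)
    known <- intersect(names(tab), all_codons)
    counts[known] <- counts[known] + as.integer(tab[known])
  }
  tibble(codon = all_codons, count = unname(counts))
}

#' Relative synonymous codon usage
#'
#' RSCU of codon *c* in synonymous family *F* is its observed count divided
#' by the mean count over *F*: `count(c) / (sum(F) / |F|)`. A value of 1
#' means no bias; an unused codon has RSCU 0; a family with zero total count
#' gets `NA`. Stop codons are excluded. By default leucine and serine are
#' each normalized as one family (all codons coding the amino acid), while
#' the `family` column still reports the conventional split labels
#' (Leu1/Leu2/Ser1/Ser2); set `split_families = TRUE` to normalize within
#' the split classes instead.
#'
#' @param counts Tibble from [codon_counts()] (columns `codon`, `count`).
#' @param code A [genetic_code()].
#' @param split_families Normalize Leu/Ser within split classes?
#' @return Tibble of class `mito_rscu`: `codon` (RNA alphabet),
#'   `amino_acid`, `family`, `count`, `rscu`.
#' @export
rscu <- function(counts, code = genetic_code(), split_families = FALSE) {
  tbl <- counts |>
    dplyr::filter(.data$codon %in% code$sense) |>
    dplyr::mutate(
      amino_acid = unname(code$map[.data$codon]),
      family = display_family(.data$codon, .data$amino_acid),
      norm_family = if (split_families) .data$family else unname(aa_display_names[.data$amino_acid])
    ) |>
    dplyr::group_by(.data$norm_family) |>
    dplyr::mutate(
      rscu = if (sum(.data$count) > 0) {
        .data$count / (sum(.data$count) / dplyr::n())
      } else {
        rep(NA_real_, dplyr::n())
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(codon = dna_to_rna(.data$codon)) |>
    dplyr::select("codon", "amino_acid", "family", "count", "rscu")
  class(tbl) <- c("mito_rscu", class(tbl))
  tbl
}

#' Codons above an RSCU threshold
#'
#' @param table A [rscu()] table.
#' @param threshold RSCU cutoff (strictly greater than).
#' @return Tibble of codons with `rscu > threshold`, ordered by descending
#'   RSCU; ties broken alphabetically by codon.
#' @export
rank_codons <- function(table, threshold = 2) {
  table |>
    dplyr::filter(!is.na(.data$rscu), .data$rscu > threshold) |>
    dplyr::arrange(dplyr::desc(.data$rscu), .data$codon)
}

#' Start- and stop-codon census of the protein-coding genes
#'
#' The start codon is the first triplet of each PCG in reading orientation.
#' The stop codon is the final triplet when the length is divisible by 3,
#' otherwise the 1- or 2-base remainder after the last full codon — an
#' incomplete termination codon (`TA` or `T`) of the kind completed by
#' post-transcriptional polyadenylation. A full final triplet that is not a
#' stop of the genetic code is classified `"other"` with a warning
#' (possible misannotation).
#'
#' @param genome A [mito_genome()].
#' @param code A [genetic_code()].
#' @return Tibble: `gene`, `start_codon`, `stop_codon`, `is_atn_start`
#'   (start matches `AT[ACGT]`), `is_incomplete_stop`.
#' @export
start_stop_census <- function(genome, code = genetic_code()) {
  pcgs <- genome$features[genome$features$category == "PCG", ]
  rows <- lapply(seq_len(nrow(pcgs)), function(i) {
    s <- region_sequence(genome, pcgs[i, ])
    n <- nchar(s)
    if (n < 4) {
      warn(paste0("PCG '", pcgs$name[i], "' shorter than 4 bases; skipped"))
      return(NULL)
    }
    start <- substr(s, 1, 3)
    rem <- n %% 3L
    if (rem == 0L) {
      stop_c <- substr(s, n - 2L, n)
      if (!stop_c %in% code$stops) {
        warn(paste0("PCG '", pcgs$name[i], "' ends in '", stop_c,
                    "', not a stop codon of table ", code$id,
                    "; classified 'other' (possible misannotation)"))
        stop_c <- "other"
      }
      incomplete <- FALSE
    } else {
      stop_c <- substr(s, n - rem + 1L, n)
      incomplete <- TRUE
    }
    tibble(gene = pcgs$name[i], start_codon = start, stop_codon = stop_c,
           is_atn_start = grepl("^AT[ACGT]$", start),
           is_incomplete_stop = incomplete)
  })
  dplyr::bind_rows(rows)
}
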