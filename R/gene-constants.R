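#' Canonical mitochondrial gene tokens
#'
#' The 37 genes of the typical animal mitogenome plus the control region,
#' under the normalized nomenclature used throughout the package: 13
#' protein-coding genes (`COX1`..`ND6`, `ATP6`, `ATP8`, `CYTB`), 22 tRNAs
#' (`trnA`..`trnV`, with the duplicated leucine and serine tRNAs
#' distinguished as `trnL1`/`trnL2` and `trnS1`/`trnS2`), the two rRNAs
#' (`rrnL`, `rrnS`) and `CR`.
#'
#' @return Character vector of 38 tokens.
#' @export
canonical_gene_tokens <- function() {
  c(pcg_tokens(), trna_tokens(), rrna_tokens(), "CR")
}

pcg_tokens <- function() {
  c("COX1", "COX2", "COX3", "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5",
    "ND6", "ATP6", "ATP8", "CYTB")
}

trna_tokens <- function() {
  c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI", "trnK",
    "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR", "trnS1",
    "trnS2", "trnT", "trnV", "trnW", "trnY")
}

rrna_tokens <- function() c("rrnL", "rrnS")

#' Gene category for a canonical token
#'
#' @param token Character vector of canonical gene tokens.
#' @return Character vector over `{"PCG", "tRNA", "rRNA", "CR"}` (`NA` for
#'   unrecognized tokens).
#' @export
gene_category <- function(token) {
  dplyr::case_when(
    token %in% pcg_tokens() ~ "PCG",
    token %in% trna_tokens() ~ "tRNA",
    token %in% rrna_tokens() ~ "rRNA",
    token == "CR" ~ "CR",
    TRUE ~ NA_character_
  )
}

#' Ancestral insect mitochondrial gene order
#'
#' The *Drosophila yakuba* gene arrangement conventionally used as the
#' ancestral state for insect gene-order comparisons: 37 genes plus the
#' control region, with the strand of each gene relative to the majority
#' strand.
#'
#' @return A [gene_order()] object (tibble with columns `gene`, `strand`)
#'   for taxon `"ancestral"`, circular topology.
#' @export
ancestral_insect_order <- function() {
  genes <- c(
    "trnI", "trnQ", "trnM", "ND2", "trnW", "trnC", "trnY", "COX1", "trnL2",
    "COX2", "trnK", "trnD", "ATP8", "ATP6", "COX3", "trnG", "ND3", "trnA",
    "trnR", "trnN", "trnS1", "trnE", "trnF", "ND5", "trnH", "ND4", "ND4L",
    "trnT", "trnP", "ND6", "CYTB", "trnS2", "ND1", "trnL1", "rrnL", "trnV",
    "rrnS", "CR"
  )
  minus <- c(
    "trnQ", "trnC", "trnY", "trnF", "ND5", "trnH", "ND4", "ND4L", "trnP",
    "ND1", "trnL1", "rrnL", "trnV", "rrnS"
  )
  gene_order(genes, ifelse(genes %in% minus, "-", "+"),
             taxon = "ancestral", topology = "circular")
}

# Synonym table shipped under inst/extdata; loaded once per session.
the <- new.env(parent = emptyenv())

gene_synonym_table <- function() {
  if (is.null(the$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocompare")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    the$synonyms <- stats::setNames(tab$token, tab$synonym)
  }
  the$synonyms
}

aa3_to_1 <- c(
  ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", gln = "Q",
  glu = "E", gly = "G", his = "H", ile = "I", leu = "L", lys = "K",
  met = "M", phe = "F", pro = "P", ser = "S", thr = "T", trp = "W",
  tyr = "Y", val = "V"
)

# Leucine/serine isoacceptor disambiguation by codon-family or anticodon
# qualifier (DNA or RNA alphabet): trnL1 reads CUN codons (anticodon UAG),
# trnL2 reads UUR (anticodon UAA); trnS1 reads AGN (anticodon GCU/UCU),
# trnS2 reads UCN (anticodon UGA).
ls_qualifier_map <- c(
  uur = "L2", uua = "L2", uaa = "L2", taa = "L2", ttr = "L2",
  cun = "L1", uag = "L1", tag = "L1", ctn = "L1",
  ucn = "S2", uga = "S2", tga = "S2", tcn = "S2",
  agn = "S1", agy = "S1", gcu = "S1", gct = "S1", ucu = "S1", tct = "S1"
)

#' Normalize a raw gene name to a canonical token
#'
#' Deterministic, table-driven normalization of the gene-name spellings found
#' in GenBank records and the literature (`COI` vs `COX1`, `nad4l` vs `ND4L`,
#' `l-rRNA` vs `rrnL`, `tRNA-Leu(UUR)` vs `trnL2`, `D-loop` vs `CR`, ...).
#' Leucine/serine tRNAs are resolved through their codon-family or anticodon
#' qualifier; a bare `trnL`/`trnS` is ambiguous and maps to `"unknown"`.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of canonical tokens; unmappable names yield the
#'   explicit sentinel `"unknown"`, never a guess.
#' @examples
#' normalize_gene_name(c("COI", "nad4l", "tRNA-Ser(UCN)", "D-loop"))
#' @export
normalize_gene_name <- function(raw) {
  vapply(raw, normalize_one_name, character(1), USE.NAMES = FALSE)
}

normalize_one_name <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) return("unknown")
  key <- tolower(gsub("[ _]", "", trimws(raw)))
  syn <- gene_synonym_table()
  if (key %in% names(syn)) return(unname(syn[[key]]))

  # tRNA spellings: trnX / trnX1 / trnX(qual) / trna-leu(qual) / trn-leu ...
  m <- regmatches(key, regexec("^trna?-?([a-z]{3}|[a-z])([12])?(\\(([a-z]{3})\\))?$", key))[[1]]
  if (length(m)) {
    body <- m[2]
    num <- m[3]
    qual <- m[5]
    letter <- if (nchar(body) == 3) unname(aa3_to_1[body]) else toupper(body)
    if (is.na(letter) || !nzchar(letter)) return("unknown")
    if (letter %in% c("L", "S")) {
      if (nzchar(num)) return(paste0("trn", letter, num))
      if (nzchar(qual) && qual %in% names(ls_qualifier_map)) {
        cls <- ls_qualifier_map[[qual]]
        if (substr(cls, 1, 1) == letter) return(paste0("trn", cls))
      }
      return("unknown")
    }
    if (paste0("trn", letter) %in% trna_tokens()) return(paste0("trn", letter))
    return("unknown")
  }
  "unknown"
}
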