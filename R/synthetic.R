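#' Specification for a synthetic annotated mitogenome
#'
#' Describes a simulated insect-style mitogenome: the 37-gene + control
#' region ancestral plan, per-codon-position base composition for the
#' protein-coding genes, an overall AT target for the RNA/CR regions, and an
#' optional list of gene-order edits applied to the plan before emission.
#' The defaults mirror the magnitudes of recently sequenced halictid bee
#' mitogenomes: a PCG complement totalling 11,114 bp in which `ND5`
#' (1718 bp) carries an incomplete `TA` stop, 22 tRNAs of 66 bp, rRNAs of
#' 1300/797 bp, a 2755 bp control region and ~85% AT overall.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @param at_target Target AT fraction for tRNA/rRNA/CR/spacer emission.
#' @param site_composition 3×4 matrix of per-codon-position probabilities
#'   over A, T, G, C (rows = codon positions 1..3, each summing to 1).
#' @param codon_weights Optional named multiplier vector over DNA codons,
#'   applied on top of the positional composition (codon-usage bias dial).
#' @param start_codon_weights Sampling weights for PCG start codons.
#' @param pcg_lengths Named integer vector of the 13 PCG lengths in bp.
#'   Length mod 3 selects the stop: 0 → full TAA/TAG, 2 → incomplete `TA`,
#'   1 → incomplete `T`.
#' @param trna_length tRNA gene length in bp (50–77), recycled to 22.
#' @param rrna_lengths Named vector with `rrnL` and `rrnS` lengths.
#' @param cr_length Control-region length in bp (insect CRs span roughly
#'   1.5–6.6 kb).
#' @param spacer_max Maximum intergenic spacer (bp, uniform on 0..max).
#' @param rearrangement_edits List of edits, each
#'   `list(kind = , cluster = )` with `kind` one of `"shuffle"`,
#'   `"transposition"`, `"inversion"`, `"inverse_transposition"` and
#'   `cluster` a contiguous run of genes in the ancestral order. Clusters
#'   must be disjoint and separated by at least one untouched gene (so that
#'   event recovery is well-posed); `CR` may not be edited.
#' @param topology `"circular"` or `"linear"`.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           at_target = 0.85,
                           site_composition = default_site_composition(),
                           codon_weights = NULL,
                           start_codon_weights = c(ATG = 0.3, ATA = 0.3,
                                                   ATT = 0.3, ATC = 0.1),
                           pcg_lengths = default_pcg_lengths(),
                           trna_length = 66L,
                           rrna_lengths = c(rrnL = 1300L, rrnS = 797L),
                           cr_length = 2755L,
                           spacer_max = 20L,
                           rearrangement_edits = list(),
                           topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.matrix(site_composition) || !identical(dim(site_composition), c(3L, 4L))) {
    abort("site_composition must be a 3x4 matrix (codon positions x A,T,G,C)")
  }
  if (any(abs(rowSums(site_composition) - 1) > 1e-8) || any(site_composition < 0)) {
    abort("each site_composition row must be a probability vector summing to 1")
  }
  if (at_target <= 0 || at_target >= 1) abort("at_target must be in (0, 1)")
  if (!setequal(names(pcg_lengths), pcg_tokens())) {
    abort("pcg_lengths must name exactly the 13 PCG tokens")
  }
  if (any(pcg_lengths < 6)) abort("PCG lengths must allow a start and a stop")
  trna_length <- rep_len(as.integer(trna_length), 22L)
  if (any(trna_length < 50L | trna_length > 77L)) {
    abort("tRNA lengths must lie within [50, 77] bp")
  }
  if (!all(c("rrnL", "rrnS") %in% names(rrna_lengths))) {
    abort("rrna_lengths must name rrnL and rrnS")
  }
  if (cr_length <= 0) abort("cr_length must be positive")
  validate_edits(rearrangement_edits)
  structure(
    list(seed = as.integer(seed), at_target = at_target,
         site_composition = site_composition, codon_weights = codon_weights,
         start_codon_weights = start_codon_weights,
         pcg_lengths = pcg_lengths, trna_length = trna_length,
         rrna_lengths = rrna_lengths, cr_length = as.integer(cr_length),
         spacer_max = as.integer(spacer_max),
         rearrangement_edits = rearrangement_edits, topology = topology),
    class = "synthetic_spec"
  )
}

# Per-codon-position base frequencies (A, T, G, C) echoing observed halictid
# Site 1/2/3 compositions.
default_site_composition <- function() {
  m <- rbind(
    c(0.4169, 0.4046, 0.1017, 0.0768),
    c(0.2541, 0.5150, 0.0954, 0.1355),
    c(0.4823, 0.4699, 0.0125, 0.0353)
  )
  m <- m / rowSums(m)
  colnames(m) <- c("A", "T", "G", "C")
  m
}

# PCG length plan totalling 11,114 bp; ND5 is 2 mod 3, i.e. it ends in an
# incomplete TA stop, so codon-position totals split 3705/3705/3704.
default_pcg_lengths <- function() {
  c(ND2 = 1023L, COX1 = 1536L, COX2 = 684L, ATP8 = 159L, ATP6 = 678L,
    COX3 = 789L, ND3 = 354L, ND5 = 1718L, ND4 = 1341L, ND4L = 291L,
    ND6 = 522L, CYTB = 1137L, ND1 = 882L)
}

validate_edits <- function(edits) {
  if (!length(edits)) return(invisible(edits))
  anc <- ancestral_insect_order()$gene
  spans <- lapply(edits, function(e) {
    if (!is.list(e) || is.null(e$kind) || is.null(e$cluster)) {
      abort("each edit must be list(kind =, cluster =)")
    }
    if (!e$kind %in% c("shuffle", "transposition", "inversion",
                       "inverse_transposition")) {
      abort(paste0("unknown edit kind '", e$kind, "'"))
    }
    if ("CR" %in% e$cluster) abort("the control region cannot be edited")
    pos <- match(e$cluster, anc)
    if (anyNA(pos)) abort("edit cluster contains unknown gene tokens")
    if (!identical(sort(pos), seq(min(pos), max(pos)))) {
      abort("edit cluster must be a contiguous run of the ancestral order")
    }
    if (e$kind == "shuffle" && length(pos) != 2) {
      abort("a shuffle edit needs a cluster of exactly 2 genes")
    }
    if (e$kind %in% c("transposition", "inverse_transposition") && length(pos) < 3) {
      abort("a (inverse) transposition edit needs a cluster of >= 3 genes")
    }
    range(pos)
  })
  spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
  for (i in seq_along(spans)[-1]) {
    if (spans[[i]][1] <= spans[[i - 1]][2] + 1L) {
      abort("edit clusters overlap or touch; they must be separated by at least one gene")
    }
  }
  invisible(edits)
}

# Apply one edit to a gene_order; cluster is given in ancestral spelling but
# located in the current order (edits are disjoint so runs stay contiguous).
apply_edit <- function(o, edit) {
  pos <- match(edit$cluster, o$gene)
  span <- seq(min(pos), max(pos))
  g <- o$gene[span]; s <- o$strand[span]
  n <- length(span)
  switch(edit$kind,
    shuffle = { g <- g[c(2, 1)]; s <- s[c(2, 1)] },
    inversion = { g <- rev(g); s <- flip_strand(rev(s)) },
    transposition = { g <- g[c(n, seq_len(n - 1))]; s <- s[c(n, seq_len(n - 1))] },
    inverse_transposition = {
      g <- g[c(n, seq_len(n - 1))]
      s <- c(flip_strand(s[n]), s[seq_len(n - 1)])
    }
  )
  o$gene[span] <- g
  o$strand[span] <- s
  o
}

base_letters <- c("A", "T", "G", "C")

draw_iid_region <- function(len, at) {
  p <- c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  draws <- sample.int(4L, len, replace = TRUE, prob = p)
  list(seq = paste(base_letters[draws], collapse = ""),
       counts = tabulate(draws, nbins = 4L))
}

complement_counts <- function(cnt) cnt[c(2L, 1L, 4L, 3L)]  # A<->T, G<->C

#' Generate a synthetic annotated mitogenome with a ground-truth manifest
#'
#' Emits genes along the (possibly edited) ancestral plan with intergenic
#' spacers, drawing PCG codons from the per-position composition (stop
#' codons never internal; start codon from the configured ATN/ATG pool;
#' terminal stop complete or incomplete according to the gene length),
#' tRNA/rRNA/CR bases i.i.d. at their AT targets, and minus-strand genes of
#' the plan reverse-complemented into the genome. All draws are tallied
#' independently of the analysis code, so the manifest is a ground-truth
#' oracle for composition, codon usage and event recovery. The sequence
#' model is i.i.d. within each region class — adequate for validating
#' counting, skew and RSCU code, not a biological simulator.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `genome` (a [mito_genome()]) and `manifest`
#'   (list: `seed`, `base_counts` tibble per region, `codon_counts` tibble,
#'   `site_counts` tibble, `events` tibble, `gene_order` signed-token
#'   string, `gene_plan`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  code <- genetic_code("5")
  plan <- ancestral_insect_order()
  events <- list()
  for (e in spec$rearrangement_edits) {
    before <- plan
    plan <- apply_edit(plan, e)
    pos <- match(e$cluster, before$gene)
    span <- seq(min(pos), max(pos))
    events[[length(events) + 1L]] <- tibble(
      kind = e$kind,
      genes = list(before$gene[span]),
      ancestral = paste(display_tokens(before[span, ]), collapse = "-"),
      derived = paste(display_tokens(plan[span, ]), collapse = "-")
    )
  }
  events <- if (length(events)) dplyr::bind_rows(events) else {
    tibble(kind = character(), genes = list(), ancestral = character(),
           derived = character())
  }

  # codon sampling distribution: product of positional probabilities times
  # optional per-codon weights, stops excluded, renormalized
  sense <- code$sense
  codon_prob <- vapply(sense, function(cod) {
    b <- match(strsplit(cod, "")[[1]], base_letters)
    p <- spec$site_composition[1, b[1]] * spec$site_composition[2, b[2]] *
      spec$site_composition[3, b[3]]
    w <- if (!is.null(spec$codon_weights)) spec$codon_weights[cod] else 1
    p * (if (is.na(w)) 1 else w)
  }, numeric(1))
  codon_prob <- codon_prob / sum(codon_prob)

  trna_plan <- stats::setNames(spec$trna_length, trna_tokens())
  region_tally <- matrix(0L, nrow = 8, ncol = 4,
                         dimnames = list(c("whole_genome", "PCGs", "site1",
                                           "site2", "site3", "tRNA", "rRNA",
                                           "CR"), base_letters))
  codon_tally <- stats::setNames(integer(length(code$map)), names(code$map))

  add_codons <- function(codons) {
    tab <- table(factor(codons, levels = names(codon_tally)))
    codon_tally <<- codon_tally + as.integer(tab)
  }
  count_chars <- function(s) {
    ch <- strsplit(s, "")[[1]]
    tabulate(match(ch, base_letters), nbins = 4L)
  }

  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_len(nrow(plan))) {
    gene <- plan$gene[i]
    strand <- plan$strand[i]
    cat <- gene_category(gene)
    if (cat == "PCG") {
      L <- spec$pcg_lengths[[gene]]
      stop_len <- c(3L, 1L, 2L)[(L %% 3L) + 1L]
      n_internal <- (L - 3L - stop_len) %/% 3L
      start <- sample(names(spec$start_codon_weights), 1L,
                      prob = spec$start_codon_weights)
      internals <- sample(sense, n_internal, replace = TRUE, prob = codon_prob)
      p3 <- spec$site_composition[3, c("A", "G")]
      full_stop <- sample(c("TAA", "TAG"), 1L, prob = p3 / sum(p3))
      if (stop_len == 3L) {
        reading <- paste0(start, paste(internals, collapse = ""), full_stop)
        add_codons(c(start, internals, full_stop))
        partial <- ""
      } else {
        partial <- substr("TA", 1L, stop_len)
        reading <- paste0(start, paste(internals, collapse = ""), partial)
        add_codons(c(start, internals))
      }
      stopifnot(nchar(reading) == L)
      cnt <- count_chars(reading)
      region_tally["PCGs", ] <- region_tally["PCGs", ] + cnt
      # codon-position tallies, incomplete terminal codon included
      full <- c(start, internals, if (stop_len == 3L) full_stop)
      bases <- strsplit(paste(full, collapse = ""), "")[[1]]
      for (k in 1:3) {
        region_tally[paste0("site", k), ] <-
          region_tally[paste0("site", k), ] +
          tabulate(match(bases[seq(k, length(bases), by = 3L)], base_letters), 4L)
      }
      if (stop_len < 3L) {
        pb <- strsplit(partial, "")[[1]]
        for (k in seq_len(stop_len)) {
          region_tally[paste0("site", k), ] <-
            region_tally[paste0("site", k), ] +
            tabulate(match(pb[k], base_letters), 4L)
        }
      }
    } else if (cat == "tRNA") {
      d <- draw_iid_region(trna_plan[[gene]], spec$at_target)
      reading <- d$seq
      region_tally["tRNA", ] <- region_tally["tRNA", ] + d$counts
      cnt <- d$counts
    } else if (cat == "rRNA") {
      d <- draw_iid_region(spec$rrna_lengths[[gene]],
                           min(spec$at_target + 0.01, 0.99))
      reading <- d$seq
      region_tally["rRNA", ] <- region_tally["rRNA", ] + d$counts
      cnt <- d$counts
    } else { # CR
      d <- draw_iid_region(spec$cr_length, min(spec$at_target + 0.04, 0.98))
      reading <- d$seq
      region_tally["CR", ] <- region_tally["CR", ] + d$counts
      cnt <- d$counts
    }
    genome_seg <- if (strand == "-") revcomp(reading) else reading
    region_tally["whole_genome", ] <- region_tally["whole_genome", ] +
      (if (strand == "-") complement_counts(cnt) else cnt)
    feats[[length(feats) + 1L]] <- tibble(
      name = gene, category = cat, start = pos,
      end = pos + nchar(genome_seg), strand = strand, raw_name = gene)
    pieces <- c(pieces, genome_seg)
    pos <- pos + nchar(genome_seg)
    spacer_len <- sample.int(spec$spacer_max + 1L, 1L) - 1L
    if (spacer_len > 0) {
      sp <- draw_iid_region(spacer_len, spec$at_target)
      pieces <- c(pieces, sp$seq)
      region_tally["whole_genome", ] <- region_tally["whole_genome", ] + sp$counts
      pos <- pos + spacer_len
    }
  }
  sequence <- paste(pieces, collapse = "")
  genome <- mito_genome(paste0("synthetic_seed", spec$seed), sequence,
                        dplyr::bind_rows(feats), spec$topology)

  # generation-time self-check: the tally must equal the emitted sequence
  bc <- count_bases(sequence)
  stopifnot(identical(as.integer(region_tally["whole_genome", ]),
                      c(bc$a, bc$t, bc$g, bc$c)))

  manifest <- list(
    seed = spec$seed,
    base_counts = tibble(
      region = rownames(region_tally),
      a = unname(region_tally[, "A"]), t = unname(region_tally[, "T"]),
      g = unname(region_tally[, "G"]), c = unname(region_tally[, "C"])
    ),
    codon_counts = tibble(codon = names(codon_tally),
                          count = unname(codon_tally)),
    events = events,
    gene_order = paste(signed_tokens(plan), collapse = ","),
    gene_plan = plan
  )
  list(genome = genome, manifest = manifest)
}

#' Sample non-overlapping rearrangement edits
#'
#' Draws `n` random edits over the 37 genes of the ancestral plan (never the
#' control region), with kinds drawn uniformly from the four rearrangement
#' types and clusters disjoint and separated by at least one untouched gene,
#' so diff-based recovery is well-posed.
#'
#' @param n Number of edits.
#' @return List of edits suitable for [synthetic_spec()]
#'   (`rearrangement_edits`). Uses the current RNG stream.
#' @export
sample_rearrangement_edits <- function(n) {
  anc <- ancestral_insect_order()$gene
  usable <- which(anc != "CR")
  taken <- integer(0)
  edits <- list()
  kinds <- c("shuffle", "transposition", "inversion", "inverse_transposition")
  attempts <- 0L
  while (length(edits) < n && attempts < 500L) {
    attempts <- attempts + 1L
    kind <- sample(kinds, 1L)
    len <- switch(kind, shuffle = 2L, inversion = sample(1:3, 1L),
                  sample(3:4, 1L))
    start <- sample(seq_len(length(usable) - len + 1L), 1L)
    span <- usable[start:(start + len - 1L)]
    if (any(diff(span) != 1L)) next
    guard <- c(span[1] - 1L, span, span[length(span)] + 1L)
    if (any(guard %in% taken)) next
    taken <- c(taken, span)
    edits[[length(edits) + 1L]] <- list(kind = kind, cluster = anc[span])
  }
  if (length(edits) < n) abort("could not place the requested number of edits")
  edits
}
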