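#' Bidirectional-best-hit orthologs
#'
#' `(a, b)` is an ortholog pair iff `b` is `a`'s best-scoring hit and `a` is
#' `b`'s best-scoring hit. Score ties are broken toward the
#' lexicographically smallest partner id and flagged in the output.
#'
#' @param similarity A tibble of candidate hits: `gene_a`, `gene_b`,
#'   `score` (higher is better, comparable within each gene's hit list).
#' @return A tibble of mutual best hits: `gene_a`, `gene_b`, `score`,
#'   `tie_a`, `tie_b` (was the best hit tied on either side?).
#' @export
bbh_orthologs <- function(similarity) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(similarity)))
  best_of <- function(df, from, to) {
    df %>%
      group_by(.data[[from]]) %>%
      arrange(desc(.data$score), .data[[to]], .by_group = TRUE) %>%
      summarise(
        best = first(.data[[to]]),
        tie = sum(.data$score == max(.data$score)) > 1L,
        score = max(.data$score),
        .groups = "drop"
      )
  }
  best_a <- best_of(similarity, "gene_a", "gene_b")
  best_b <- best_of(similarity, "gene_b", "gene_a")
  best_a %>%
    inner_join(best_b, by = c("best" = "gene_b"),
               suffix = c("_a", "_b")) %>%
    filter(.data$gene_a == .data$best_b) %>%
    transmute(
      gene_a = .data$gene_a,
      gene_b = .data$best,
      score = .data$score_a,
      tie_a = .data$tie_a,
      tie_b = .data$tie_b
    ) %>%
    arrange(.data$gene_a)
}

# Internal: keep maximal TUs (drop any TU whose gene set is contained in
# another's); reference collections may carry nested alternative TUs.
maximal_tus <- function(tus) {
  sets <- tus$gene_ids
  n <- length(sets)
  contained <- purrr::map_lgl(seq_len(n), function(i) {
    any(purrr::map_lgl(seq_len(n), function(j) {
      i != j && all(sets[[i]] %in% sets[[j]]) &&
        (length(sets[[i]]) < length(sets[[j]]) || i > j)
    }))
  })
  tus[!contained, , drop = FALSE]
}

#' Five-class typing of TUs against a reference map
#'
#' Classifies each transcription unit of genome A by how its genes' reference
#' orthologs are organized. With `E` the set of reference TUs containing
#' orthologs of the TU's genes:
#' * `identical` -- one reference TU, gene sets in exact correspondence;
#' * `similar` -- one reference TU, longer, and none of its extra genes has
#'   an ortholog anywhere in genome A (pure gene loss/acquisition);
#' * `split` -- one reference TU, longer, and at least one extra gene's
#'   ortholog lives in another A TU (the reference TU is split across A TUs);
#' * `merged` -- several reference TUs and none of their leftover genes has
#'   an ortholog elsewhere in A;
#' * `reorganized` -- several reference TUs with at least one leftover
#'   ortholog elsewhere in A;
#' * `unclassifiable` -- no gene of the TU has a reference ortholog.
#'
#' Nested alternative reference TUs are reduced to maximal ones first.
#'
#' @param map_a The `operon_map` of genome A.
#' @param ref_tus Reference TUs: a tibble with `tu_id` and `gene_ids`
#'   (list column), e.g. from [read_known_tus()] or an `operon_map`'s `tus`.
#' @param orth One-to-one orthology: tibble with `gene_a` (genome A ids) and
#'   `gene_b` (reference ids or `NA`).
#' @return A tibble, one row per A TU: `tu_id`, `tu_type`, `n_genes`,
#'   `n_ref_tus`, `ref_tus` (comma string), `extra_ref_genes`,
#'   `evidence`.
#' @export
classify_tu_types <- function(map_a, ref_tus, orth) {
  stopifnot(inherits(map_a, "operon_map"))
  ref_tus <- maximal_tus(as_tibble(ref_tus))
  ref_gene_to_tu <- tibble(
    ref_tu = rep(ref_tus$tu_id, lengths(ref_tus$gene_ids)),
    gene = unlist(ref_tus$gene_ids)
  )
  a2b <- stats::setNames(orth$gene_b, orth$gene_a)
  b2a <- orth %>% filter(!is.na(.data$gene_b))
  b2a <- stats::setNames(b2a$gene_a, b2a$gene_b)
  mapped_b <- names(b2a)
  bad <- setdiff(mapped_b, ref_gene_to_tu$gene)
  if (length(bad) > 0) {
    stop_dister(sprintf(
      "ortholog(s) point to gene(s) absent from the reference map: %s.",
      paste(utils::head(bad, 5), collapse = ", ")),
      class = "dister_consistency_error")
  }
  a_gene_to_tu <- stats::setNames(
    rep(map_a$tus$tu_id, lengths(map_a$tus$gene_ids)),
    unlist(map_a$tus$gene_ids))

  purrr::map_dfr(seq_len(nrow(map_a$tus)), function(i) {
    tu_id <- map_a$tus$tu_id[i]
    genes <- map_a$tus$gene_ids[[i]]
    orth_b <- unname(a2b[genes])
    orth_b <- orth_b[!is.na(orth_b)]
    base <- tibble(tu_id = tu_id, n_genes = length(genes))
    if (length(orth_b) == 0) {
      return(mutate(base, tu_type = "unclassifiable", n_ref_tus = 0L,
                    ref_tus = NA_character_, extra_ref_genes = NA_character_,
                    evidence = "no gene has a reference ortholog"))
    }
    e_tus <- unique(ref_gene_to_tu$ref_tu[ref_gene_to_tu$gene %in% orth_b])
    e_genes <- ref_gene_to_tu$gene[ref_gene_to_tu$ref_tu %in% e_tus]
    extras <- setdiff(e_genes, orth_b)
    extras_in_a <- unname(b2a[extras])
    extras_in_a <- extras_in_a[!is.na(extras_in_a)]
    relocated <- length(extras_in_a) > 0
    tu_type <- if (length(e_tus) == 1L) {
      if (length(extras) == 0L) "identical"
      else if (relocated) "split"
      else "similar"
    } else {
      if (relocated) "reorganized" else "merged"
    }
    ev <- character(0)
    orphans <- genes[is.na(a2b[genes])]
    if (length(orphans) > 0) {
      ev <- c(ev, sprintf("A genes without ortholog: %s",
                          paste(orphans, collapse = ",")))
    }
    if (relocated) {
      ev <- c(ev, sprintf("relocated ortholog(s) in A TU(s): %s",
                          paste(unique(a_gene_to_tu[extras_in_a]),
                                collapse = ",")))
    }
    mutate(base,
           tu_type = tu_type,
           n_ref_tus = length(e_tus),
           ref_tus = paste(sort(e_tus), collapse = ","),
           extra_ref_genes = if (length(extras) > 0)
             paste(sort(extras), collapse = ",") else NA_character_,
           evidence = if (length(ev) > 0) paste(ev, collapse = "; ")
                      else NA_character_) %>%
      select("tu_id", "tu_type", "n_genes", "n_ref_tus", "ref_tus",
             "extra_ref_genes", "evidence")
  })
}

#' Per-type TU composition summary
#'
#' Aggregates [classify_tu_types()] calls into one row per TU type: number
#' of TUs, genes, monocistronic and polycistronic units.
#'
#' @param type_calls Output of [classify_tu_types()].
#' @return A tibble with columns `tu_type`, `n_tus`, `n_genes`, `n_mono`,
#'   `n_poly`.
#' @export
tu_type_summary <- function(type_calls) {
  type_calls %>%
    group_by(.data$tu_type) %>%
    summarise(
      n_tus = n(),
      n_mono = sum(.data$n_genes == 1L),
      n_poly = sum(.data$n_genes > 1L),
      n_genes = sum(.data$n_genes),
      .groups = "drop"
    ) %>%
    select("tu_type", "n_tus", "n_genes", "n_mono", "n_poly")
}

# Internal: unordered adjacency lookup keys for a pair table.
adjacency_keys <- function(pairs) {
  paste(pmin(pairs$upstream, pairs$downstream),
        pmax(pairs$upstream, pairs$downstream), sep = "\r")
}

#' Flag ancestral gene pairs
#'
#' An adjacent pair of genome A is *ancestral* when its two genes'
#' orthologs are also adjacent in the reference genome B (any relative
#' orientation) or, failing that, in any supplied outgroup. With
#' `strict = TRUE` the reference check instead demands syntenic adjacency:
#' the orthologs adjacent in the same order (`orth(upstream)` immediately
#' upstream of `orth(downstream)`).
#'
#' @param pairs Adjacent pairs of genome A (columns `upstream`,
#'   `downstream`), in chromosomal order as produced by
#'   [enumerate_adjacent_pairs()].
#' @param orth Orthology tibble `gene_a` -> `gene_b` for the reference.
#' @param ref_pairs Adjacent pairs of the reference genome.
#' @param outgroups Optional list; each element a list with components
#'   `orth` (A -> outgroup orthology) and `pairs` (outgroup adjacency).
#' @param strict Require order-preserving (syntenic) adjacency in the
#'   reference?
#' @return The pair tibble with logical `ancestral` and character
#'   `ancestral_source` (`"reference"`, `"outgroup"`, or `NA`) appended.
#' @export
ancestral_pairs <- function(pairs, orth, ref_pairs, outgroups = list(),
                            strict = FALSE) {
  adjacent_in <- function(o, other_pairs, ordered) {
    a2b <- stats::setNames(o$gene_b, o$gene_a)
    up_b <- unname(a2b[pairs$upstream])
    dn_b <- unname(a2b[pairs$downstream])
    ok <- !is.na(up_b) & !is.na(dn_b)
    hit <- rep(FALSE, nrow(pairs))
    if (ordered) {
      keys <- paste(other_pairs$upstream, other_pairs$downstream, sep = "\r")
      hit[ok] <- paste(up_b[ok], dn_b[ok], sep = "\r") %in% keys
    } else {
      keys <- adjacency_keys(other_pairs)
      hit[ok] <- paste(pmin(up_b[ok], dn_b[ok]),
                       pmax(up_b[ok], dn_b[ok]), sep = "\r") %in% keys
    }
    hit
  }
  in_ref <- adjacent_in(orth, ref_pairs, ordered = strict)
  in_out <- rep(FALSE, nrow(pairs))
  for (og in outgroups) {
    in_out <- in_out | adjacent_in(og$orth, og$pairs, ordered = FALSE)
  }
  pairs %>%
    mutate(
      ancestral = in_ref | in_out,
      ancestral_source = case_when(
        in_ref ~ "reference",
        in_out ~ "outgroup",
        TRUE ~ NA_character_
      )
    )
}

#' Group ancestral pairs into fragments
#'
#' Ancestral pairs conglomerate on fragments: maximal runs of consecutive
#' ancestral pairs along the chromosome. A fragment of `k` pairs spans
#' `k + 1` genes (the whole-circle fragment, should every pair be ancestral,
#' spans `k` genes). On a circular replicon the first and last runs merge
#' when both wrap-adjacent pairs are ancestral.
#'
#' @param pairs Pair tibble with an `ancestral` logical column, in
#'   chromosomal order ([ancestral_pairs()] output).
#' @param circular Treat the pair sequence as circular (default `TRUE`)?
#' @return A tibble, one row per fragment: `fragment_id`, `n_pairs`,
#'   `n_genes`, `first_gene`.
#' @export
ancestral_fragments <- function(pairs, circular = TRUE) {
  anc <- pairs$ancestral
  n <- length(anc)
  if (!any(anc)) {
    return(tibble(fragment_id = integer(0), n_pairs = integer(0),
                  n_genes = integer(0), first_gene = character(0)))
  }
  if (circular && all(anc)) {
    return(tibble(fragment_id = 1L, n_pairs = n, n_genes = n,
                  first_gene = pairs$upstream[1]))
  }
  # run-length over the (possibly rotated) circular sequence
  start_at <- if (circular) which(!anc)[1] %% n + 1L else 1L
  ord <- if (circular) c(seq(start_at, n), seq_len(start_at - 1L))
         else seq_len(n)
  r <- rle(anc[ord])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  frag <- which(r$values)
  tibble(
    fragment_id = seq_along(frag),
    n_pairs = r$lengths[frag],
    n_genes = r$lengths[frag] + 1L,
    first_gene = pairs$upstream[ord[starts[frag]]]
  )
}

#' Status of pairs conserved between two genomes
#'
#' Restricts genome A's adjacent pairs to those whose orthologs are also
#' adjacent in genome B (the conserved, lineage-shared pairs) and compares
#' their co-transcription status in the two genomes: both co-transcribed
#' (`STU`), both not (`DTU`), or `opposite`.
#'
#' @param pairs_a Genome A pairs with a `call` column (`STU`/`DTU`).
#' @param pairs_b Genome B pairs with a `call` column.
#' @param orth Orthology tibble `gene_a` -> `gene_b`.
#' @return The conserved subset of `pairs_a` with columns `call_b` and
#'   `status` (`"STU"`, `"DTU"`, `"opposite"`) appended.
#' @export
conserved_pair_status <- function(pairs_a, pairs_b, orth) {
  stopifnot("call" %in% names(pairs_a), "call" %in% names(pairs_b))
  a2b <- stats::setNames(orth$gene_b, orth$gene_a)
  up_b <- unname(a2b[pairs_a$upstream])
  dn_b <- unname(a2b[pairs_a$downstream])
  key_b <- adjacency_keys(pairs_b)
  ok <- !is.na(up_b) & !is.na(dn_b)
  want <- paste(pmin(up_b, dn_b), pmax(up_b, dn_b), sep = "\r")
  idx <- match(ifelse(ok, want, NA_character_), key_b)
  conserved <- !is.na(idx)
  out <- pairs_a[conserved, , drop = FALSE]
  out$call_b <- pairs_b$call[idx[conserved]]
  out %>%
    mutate(status = case_when(
      .data$call == "STU" & .data$call_b == "STU" ~ "STU",
      .data$call == "DTU" & .data$call_b == "DTU" ~ "DTU",
      TRUE ~ "opposite"
    ))
}

#' Six-class coding-sequence length evolution
#'
#' Compares each gene's length in genome A (e.g. the reduced genome), the
#' reference genome and an outgroup, and assigns the printed six-class
#' scheme. With `d_ref = L_ref - L_a`, `d1 = |L_ext - L_a|` and
#' `d2 = |L_ref - L_ext|`:
#' class 1 `d_ref = 0`; class 2 `d1 < d2` and `d_ref > 0`; class 3
#' `d1 < d2` and `d_ref < 0`; class 4 `d1 > d2` and `d_ref > 0`; class 5
#' `d1 > d2` and `d_ref < 0`; class 6 `d1 = d2` and `d_ref != 0` (lineage
#' of change unidentifiable). The six classes partition all complete
#' triples; a missing outgroup length yields `NA`, never a silent class.
#'
#' @param l_a,l_ref,l_ext Positive sequence lengths (bp or codons),
#'   vectorized.
#' @return Integer class in `1:6`, or `NA` where `l_ext` is missing.
#' @export
length_evolution_class <- function(l_a, l_ref, l_ext) {
  if (any(c(l_a, l_ref) <= 0, na.rm = TRUE) ||
      any(l_ext <= 0, na.rm = TRUE)) {
    stop_dister("sequence lengths must be positive.")
  }
  d_ref <- l_ref - l_a
  d1 <- abs(l_ext - l_a)
  d2 <- abs(l_ref - l_ext)
  out <- case_when(
    d_ref == 0 ~ 1L,
    is.na(l_ext) ~ NA_integer_,
    d1 < d2 & d_ref > 0 ~ 2L,
    d1 < d2 & d_ref < 0 ~ 3L,
    d1 > d2 & d_ref > 0 ~ 4L,
    d1 > d2 & d_ref < 0 ~ 5L,
    TRUE ~ 6L
  )
  out[is.na(l_a) | is.na(l_ref)] <- NA_integer_
  out
}

#' Attribute the absence of a reference gene
#'
#' For a reference-genome gene with no ortholog in genome A: if the gene is
#' present in the reconstructed ancestor or any outgroup, it was present
#' ancestrally and lost in the A lineage; if absent everywhere outside the
#' reference, it was acquired in the reference lineage; with no usable
#' evidence the call is ambiguous.
#'
#' @param presence A logical matrix or data frame, one row per gene and one
#'   column per evidence source (ancestor reconstruction, outgroups); `NA`
#'   means the source is uninformative for that gene.
#' @return Character vector over `"lost_in_a"`, `"acquired_in_reference"`,
#'   `"ambiguous"`.
#' @export
loss_attribution <- function(presence) {
  m <- as.matrix(as.data.frame(presence))
  apply(m, 1L, function(row) {
    if (any(row, na.rm = TRUE)) "lost_in_a"
    else if (any(!is.na(row))) "acquired_in_reference"
    else "ambiguous"
  })
}

#' Chi-square test on a 2x2 flag contingency
#'
#' Generic utility for conservation-vs-regulation style questions: cross two
#' logical flags over genes and test association.
#'
#' @param flag_a,flag_b Logical vectors of equal length (`NA` rows dropped).
#' @param correct Apply continuity correction (default `FALSE`, matching the
#'   plain chi-square on large tables).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, the four cell
#'   counts `n_tt`, `n_tf`, `n_ft`, `n_ff`, and `method`.
#' @export
flag_contingency_test <- function(flag_a, flag_b, correct = FALSE) {
  keep <- !is.na(flag_a) & !is.na(flag_b)
  a <- flag_a[keep]
  b <- flag_b[keep]
  tab <- table(factor(a, levels = c(TRUE, FALSE)),
               factor(b, levels = c(TRUE, FALSE)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n_tt = tab[1, 1], n_tf = tab[1, 2], n_ft = tab[2, 1], n_ff = tab[2, 2],
    method = "Pearson chi-square on a 2x2 contingency"
  )
}
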