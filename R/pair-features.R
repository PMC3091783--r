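#' Enumerate adjacent gene pairs on a (circular) replicon
#'
#' Walks the genes in coordinate order and emits one row per adjacent pair.
#' On a circular replicon the wrap-around pair (last gene, first gene) is
#' included, so N genes yield exactly N pairs; a linear replicon yields N-1.
#' Orientation is derived from the two strands: `same_strand` when they are
#' equal, `convergent` for `+` upstream meeting `-` downstream, `divergent`
#' for `-` meeting `+`. The intergenic distance is the number of base pairs
#' strictly between the two coding sequences, negative when they overlap.
#'
#' @param annotation A [genome_annotation()] with at least two genes.
#' @return A tibble with columns `upstream`, `downstream`, `orientation`,
#'   `distance`, `distance_bin` (10-bp bins, `floor(distance / 10)`),
#'   `term_present` (all `FALSE` until [assign_terminators()] is applied),
#'   `term_score_class`, `term_confidence`, `label` (all `"unlabeled"`).
#' @export
#' @examples
#' ann <- genome_annotation(
#'   tibble::tibble(gene_id = c("a", "b", "c", "d"),
#'                  start = c(1, 501, 1001, 1501),
#'                  end = c(400, 900, 1400, 1900),
#'                  strand = c("+", "+", "-", "+")),
#'   length = 2000
#' )
#' enumerate_adjacent_pairs(ann)
enumerate_adjacent_pairs <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  n <- nrow(g)
  if (n < 2) {
    stop_dister("need at least two genes to enumerate adjacent pairs.")
  }
  up <- seq_len(n)
  if (annotation$circular) {
    dn <- c(seq_len(n)[-1], 1L)
  } else {
    up <- up[-n]
    dn <- up + 1L
  }
  s_up <- g$strand[up]
  s_dn <- g$strand[dn]
  orientation <- case_when(
    s_up == s_dn ~ "same_strand",
    s_up == "+" ~ "convergent",
    TRUE ~ "divergent"
  )
  dist <- intergenic_distance_idx(g, up, dn, annotation)
  tibble(
    upstream = g$gene_id[up],
    downstream = g$gene_id[dn],
    orientation = orientation,
    distance = dist,
    distance_bin = bin_distance(dist),
    term_present = FALSE,
    term_score_class = "absent",
    term_confidence = NA_real_,
    label = "unlabeled"
  )
}

# Vectorized distance over gene indices; the wrap-around pair unrolls the
# downstream start by the replicon length.
intergenic_distance_idx <- function(genes, up, dn, annotation) {
  start_dn <- genes$start[dn]
  wrap <- dn <= up  # only the last->first pair on a circular replicon
  start_dn[wrap] <- start_dn[wrap] + annotation$length
  as.integer(start_dn - genes$end[up] - 1L)
}

#' Intergenic distance between two adjacent genes
#'
#' `start(downstream) - end(upstream) - 1`: the count of base pairs strictly
#' separating the two coding sequences, negative (`-k` for a k-bp overlap)
#' when they overlap. The wrap-around pair of a circular replicon unrolls the
#' downstream coordinate by the replicon length.
#'
#' @param upstream,downstream Gene ids, adjacent in the annotation's
#'   coordinate order.
#' @param annotation A [genome_annotation()].
#' @return Integer distance in bp.
#' @export
intergenic_distance <- function(upstream, downstream, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  i <- match(upstream, g$gene_id)
  j <- match(downstream, g$gene_id)
  if (anyNA(c(i, j))) {
    stop_dister("gene id not found in annotation.")
  }
  n <- nrow(g)
  adjacent <- (j == i + 1L) | (annotation$circular & i == n & j == 1L)
  if (!all(adjacent)) {
    stop_dister("genes are not adjacent in the annotation order.",
                class = "dister_contract_error")
  }
  intergenic_distance_idx(g, i, j, annotation)
}

#' Bin an intergenic distance into 10-bp intervals
#'
#' `floor(distance / 10)`: distances 0-9 fall in bin 0, 10-19 in bin 1, and
#' -10..-1 in bin -1. At prediction time bins outside a model's trained range
#' are clamped to the nearest trained edge bin (see [predict.dister_model()]).
#'
#' @param distance Integer distance(s) in bp.
#' @return Integer bin index (vectorized).
#' @export
bin_distance <- function(distance) {
  as.integer(floor(distance / 10))
}

#' Attach terminator evidence to adjacent pairs
#'
#' A terminator call counts for a pair iff its `[start, end]` interval
#' intersects the open intergenic interval between the two genes *and* its
#' strand equals the upstream gene's strand (a Rho-independent terminator
#' acts at the 3' end of the upstream transcription unit). Among several
#' matching calls the highest-confidence one is kept. Score classes follow
#' TransTermHP confidence conventions: `low` < 76, `mid` 76-90, `high` > 90;
#' `absent` iff no call matches.
#'
#' @param pairs A pair tibble from [enumerate_adjacent_pairs()].
#' @param terminators A terminator tibble (see [read_terminators()]).
#' @param annotation The [genome_annotation()] the pairs came from.
#' @return The pair tibble with `term_present`, `term_score_class` and
#'   `term_confidence` filled in.
#' @export
assign_terminators <- function(pairs, terminators, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  i <- match(pairs$upstream, g$gene_id)
  j <- match(pairs$downstream, g$gene_id)
  if (anyNA(c(i, j))) {
    stop_dister("pair gene id not found in annotation.")
  }
  L <- annotation$length
  n_p <- nrow(pairs)
  best_conf <- rep(NA_real_, n_p)
  if (nrow(terminators) > 0) {
    # Open intergenic interval [end_up + 1, start_dn - 1]; empty when the
    # genes abut or overlap. The wrap pair's interval crosses the origin,
    # so terminator coordinates are duplicated one genome-length up.
    lo <- g$end[i] + 1L
    hi <- g$start[j] - 1L
    wrap <- j <= i
    hi[wrap] <- hi[wrap] + L
    open <- hi >= lo
    q <- IRanges::IRanges(start = lo[open], end = hi[open])
    s <- IRanges::IRanges(
      start = c(terminators$start, terminators$start + L),
      end = c(terminators$end, terminators$end + L)
    )
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) > 0) {
      pair_k <- which(open)[S4Vectors::queryHits(ov)]
      term_k <- (S4Vectors::subjectHits(ov) - 1L) %% nrow(terminators) + 1L
      keep <- terminators$strand[term_k] == g$strand[i[pair_k]]
      if (any(keep)) {
        hits <- tibble(pair = pair_k[keep],
                       conf = terminators$confidence[term_k[keep]]) %>%
          group_by(.data$pair) %>%
          summarise(conf = max(.data$conf), .groups = "drop")
        best_conf[hits$pair] <- hits$conf
      }
    }
  }
  pairs %>%
    mutate(
      term_confidence = best_conf,
      term_present = !is.na(best_conf),
      term_score_class = terminator_score_class(best_conf)
    )
}

#' Discretize terminator confidences into score classes
#'
#' @param confidence Numeric confidences in `[0, 100]`; `NA` means no
#'   terminator.
#' @return Character vector over `absent`, `low` (< 76), `mid` (76-90),
#'   `high` (> 90).
#' @export
terminator_score_class <- function(confidence) {
  case_when(
    is.na(confidence) ~ "absent",
    confidence < 76 ~ "low",
    confidence <= 90 ~ "mid",
    TRUE ~ "high"
  )
}

#' Label adjacent pairs from a known-TU table
#'
#' Implements the training-label rules used to build the classifier's
#' training set from curated transcription units:
#' * `STU` -- both genes belong, adjacently, to at least one
#'   experimentally-evidenced polycistronic TU (overlapping alternative TUs
#'   cannot demote an STU: one containing TU suffices);
#' * `DTU` -- the genes run in opposite directions, or exactly one of the two
#'   belongs to an experimental TU that does not also contain its partner;
#' * `NK` -- the only TU(s) containing both are computational predictions;
#' * `unlabeled` -- no rule fires.
#'
#' Pairs touching any gene of a leader-peptide-flagged TU are marked in the
#' `leader` column; [training_pairs()] drops them together with `NK` pairs,
#' since attenuation operons are structurally unrepresentative of genomes
#' that lack attenuation.
#'
#' @param pairs A pair tibble.
#' @param tus A known-TU tibble (see [read_known_tus()]).
#' @param annotation Annotation used to resolve TU gene ids; optional, but
#'   when given every TU gene id must resolve.
#' @return The pair tibble with `label` filled and a logical `leader` column.
#' @export
label_pairs <- function(pairs, tus, annotation = NULL) {
  if (!is.null(annotation)) validate_tus(tus, annotation)
  exp_tus <- tus[tus$evidence == "experimental", , drop = FALSE]
  comp_tus <- tus[tus$evidence == "computational", , drop = FALSE]
  exp_members <- unique(unlist(exp_tus$gene_ids))
  leader_genes <- unique(unlist(tus$gene_ids[tus$leader_peptide]))

  adjacent_in <- function(tu_list, a, b) {
    # is (a, b) an adjacent (unordered) pair inside any TU of the list?
    any(purrr::map_lgl(tu_list, function(gs) {
      ia <- match(a, gs)
      ib <- match(b, gs)
      !is.na(ia) && !is.na(ib) && abs(ia - ib) == 1L
    }))
  }
  in_tu_without <- function(tu_list, a, b) {
    # is `a` a member of some TU not containing `b`?
    any(purrr::map_lgl(tu_list, function(gs) a %in% gs && !(b %in% gs)))
  }

  labels <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$upstream[k]
    b <- pairs$downstream[k]
    if (pairs$orientation[k] != "same_strand") {
      labels[k] <- "DTU"
    } else if (adjacent_in(exp_tus$gene_ids, a, b)) {
      labels[k] <- "STU"
    } else {
      a_in <- in_tu_without(exp_tus$gene_ids, a, b)
      b_in <- in_tu_without(exp_tus$gene_ids, b, a)
      if (xor(a_in, b_in)) {
        labels[k] <- "DTU"
      } else if (adjacent_in(comp_tus$gene_ids, a, b)) {
        labels[k] <- "NK"
      } else {
        labels[k] <- "unlabeled"
      }
    }
  }
  pairs %>%
    mutate(
      label = labels,
      leader = .data$upstream %in% leader_genes |
        .data$downstream %in% leader_genes
    )
}

#' Extract the classifier training set from a labeled pair table
#'
#' Keeps same-strand pairs labeled `STU` or `DTU` and drops leader-peptide
#' pairs and `NK` pairs.
#'
#' @param pairs A labeled pair tibble from [label_pairs()].
#' @return The filtered tibble.
#' @export
training_pairs <- function(pairs) {
  out <- pairs %>%
    filter(.data$orientation == "same_strand",
           .data$label %in% c("STU", "DTU"))
  if ("leader" %in% names(out)) out <- filter(out, !.data$leader)
  out
}
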