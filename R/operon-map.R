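#' Construct an operon map
#'
#' An operon map is the genome-wide layout of transcription units: a set of
#' TUs that partitions the gene set (every gene in exactly one TU). Usually
#' built by [assemble_map()]; the constructor is exported for synthetic maps
#' and I/O.
#'
#' @param tus A tibble with columns `tu_id`, `gene_ids` (list column,
#'   transcription order), `strand`, `length`.
#' @param replicon_id Replicon identifier.
#' @param provenance Free-form list recording how the map was produced
#'   (predictor, threshold, ...).
#' @param degenerate Flag set when a single TU spans the whole circle.
#' @param validate Check the partition property (no gene in two TUs)?
#' @return An object of class `operon_map`.
#' @export
new_operon_map <- function(tus, replicon_id = "replicon",
                           provenance = list(), degenerate = FALSE,
                           validate = TRUE) {
  tus <- as_tibble(tus)
  if (!"length" %in% names(tus)) tus$length <- lengths(tus$gene_ids)
  stopifnot(all(c("tu_id", "gene_ids", "strand", "length") %in% names(tus)))
  all_genes <- unlist(tus$gene_ids)
  if (validate && anyDuplicated(all_genes)) {
    stop_dister("operon map is not a partition: gene in two TUs.",
                class = "dister_partition_error")
  }
  if (!all(tus$length == lengths(tus$gene_ids))) {
    stop_dister("TU length must equal its number of genes.")
  }
  structure(
    list(
      replicon_id = as.character(replicon_id),
      n_genes = length(all_genes),
      tus = tus,
      provenance = provenance,
      degenerate = isTRUE(degenerate)
    ),
    class = "operon_map"
  )
}

#' @export
print.operon_map <- function(x, ...) {
  s <- map_stats(x)
  cat(sprintf(
    "<operon_map> %s: %d genes in %d TUs (%d mono, %d poly)%s\n",
    x$replicon_id, s$n_genes, s$n_tus, s$n_mono, s$n_poly,
    if (x$degenerate) " [degenerate whole-circle TU]" else ""))
  invisible(x)
}

#' Assemble transcription units from per-pair calls
#'
#' Chains `STU`/`DTU` calls on adjacent pairs into maximal runs of
#' co-transcribed genes: a TU is a maximal run of consecutive same-strand
#' genes whose internal pairs are all called `STU`. On a circular replicon a
#' wrap-around `STU` call merges the first and last runs. Within a TU, gene
#' order follows the transcription direction (reversed chromosomal order on
#' the `-` strand). For a circular map with at least one `DTU` call,
#' `#TUs = #genes - #STU calls`.
#'
#' @param annotation A [genome_annotation()].
#' @param calls A pair tibble covering every adjacent pair of the
#'   annotation, with a `call` column (`"STU"`/`"DTU"`); the `call` column of
#'   [dister_classify()] output. `STU` on a non-same-strand pair is a
#'   contract violation.
#' @param provenance Optional provenance list stored on the map.
#' @return An `operon_map`.
#' @export
assemble_map <- function(annotation, calls, provenance = list()) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!"call" %in% names(calls)) {
    stop_dister("`calls` needs a `call` column (STU/DTU).")
  }
  ref <- enumerate_adjacent_pairs(annotation)
  key <- paste(ref$upstream, ref$downstream, sep = "\r")
  got <- match(key, paste(calls$upstream, calls$downstream, sep = "\r"))
  if (anyNA(got)) {
    miss <- ref[is.na(got), c("upstream", "downstream")]
    stop_dister(sprintf("calls missing for %d adjacent pair(s), e.g. %s-%s.",
                        nrow(miss), miss$upstream[1], miss$downstream[1]))
  }
  call_vec <- calls$call[got]
  if (!all(call_vec %in% c("STU", "DTU"))) {
    stop_dister("calls must be STU or DTU.")
  }
  bad <- call_vec == "STU" & ref$orientation != "same_strand"
  if (any(bad)) {
    stop_dister("STU call on a non-same-strand pair.",
                class = "dister_contract_error")
  }

  g <- annotation$genes
  n <- nrow(g)
  link <- call_vec == "STU"
  circular <- annotation$circular
  degenerate <- FALSE
  if (circular && all(link)) {
    grp <- rep(1L, n)
    degenerate <- TRUE
  } else {
    if (circular) {
      # rotate so that gene `rot` starts a TU (pair into it is a break)
      rot <- which(!link)[1] %% n + 1L
      ord <- c(seq(rot, n), seq_len(rot - 1L))
      # link[i] joins ord[i] to ord[i+1]; last link wraps back, a break
      link_ord <- link[c(ord[-n], ord[n])]
      grp_ord <- cumsum(c(TRUE, !link_ord[-n]))
      grp <- integer(n)
      grp[ord] <- grp_ord
    } else {
      interior <- if (n > 1) link[seq_len(n - 1L)] else logical(0)
      grp <- cumsum(c(TRUE, !interior))
    }
  }

  tus <- tibble(gene_idx = seq_len(n), grp = grp) %>%
    group_by(.data$grp) %>%
    summarise(gene_ids = list(.data$gene_idx), .groups = "drop")
  # restore chromosomal run order (groups were built in rotated order)
  tus <- purrr::map_dfr(tus$gene_ids, function(idx) {
    idx <- sort(idx)
    # a wrap TU is non-contiguous in sorted order; unroll across the origin
    if (length(idx) > 1 && any(diff(idx) > 1L)) {
      gap_at <- which(diff(idx) > 1L)[1]
      idx <- c(idx[(gap_at + 1L):length(idx)], idx[seq_len(gap_at)])
    }
    strand <- g$strand[idx[1]]
    if (strand == "-") idx <- rev(idx)
    tibble(
      gene_ids = list(g$gene_id[idx]),
      strand = strand,
      length = length(idx),
      first_pos = min(g$start[idx])
    )
  }) %>%
    arrange(.data$first_pos) %>%
    select(-"first_pos")
  tus <- mutate(tus,
                tu_id = paste0("TU_", purrr::map_chr(.data$gene_ids, 1)),
                .before = 1)
  new_operon_map(tus, replicon_id = annotation$replicon_id,
                 provenance = provenance, degenerate = degenerate)
}

#' Map-level summary statistics
#'
#' @param map An `operon_map`.
#' @return A one-row tibble: `n_genes`, `n_tus`, `n_mono`, `n_poly`,
#'   `mean_len` (genes per TU), `mean_poly_len` (genes per polycistronic TU;
#'   `NA` when the map has none).
#' @export
map_stats <- function(map) {
  stopifnot(inherits(map, "operon_map"))
  len <- map$tus$length
  n_mono <- sum(len == 1L)
  n_poly <- sum(len > 1L)
  tibble(
    n_genes = sum(len),
    n_tus = length(len),
    n_mono = n_mono,
    n_poly = n_poly,
    mean_len = sum(len) / length(len),
    mean_poly_len = if (n_poly > 0) (sum(len) - n_mono) / n_poly else NA_real_
  )
}

#' TU-length histogram
#'
#' @param map An `operon_map`.
#' @return A tibble with columns `length`, `n`; `sum(n)` equals the TU count.
#' @export
tu_length_distribution <- function(map) {
  stopifnot(inherits(map, "operon_map"))
  map$tus %>%
    count(length = .data$length, name = "n") %>%
    arrange(.data$length)
}

#' Compare two TU-length distributions
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test on the two maps' TU-length
#' vectors (independent samples).
#'
#' @param map_a,map_b `operon_map` objects, or bare numeric length vectors.
#' @return A one-row tibble: `statistic`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
compare_length_distributions <- function(map_a, map_b) {
  la <- if (inherits(map_a, "operon_map")) map_a$tus$length else map_a
  lb <- if (inherits(map_b, "operon_map")) map_b$tus$length else map_b
  wt <- suppressWarnings(
    stats::wilcox.test(la, lb, alternative = "two.sided", exact = FALSE)
  )
  tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_a = length(la),
    n_b = length(lb),
    method = "Wilcoxon rank-sum, two-sided"
  )
}

#' Fit a geometric distribution to TU lengths
#'
#' Moment estimate `p = (mean - 1) / mean` of the geometric TU-length
#' parameter, with observed-vs-expected length counts for goodness
#' inspection.
#'
#' @param map An `operon_map` or a numeric vector of TU lengths.
#' @return A list with `p_hat` and `counts`, a tibble of `length`,
#'   `observed`, `expected`.
#' @export
fit_geometric <- function(map) {
  len <- if (inherits(map, "operon_map")) map$tus$length else map
  p_hat <- estimate_prior_geometric(mean(len))
  lengths_seen <- seq_len(max(len))
  obs <- tabulate(len, nbins = max(len))
  expected <- length(len) * stats::dgeom(lengths_seen - 1L, prob = 1 - p_hat)
  list(
    p_hat = p_hat,
    counts = tibble(length = lengths_seen, observed = obs,
                    expected = expected)
  )
}

#' Per-orientation intergenic-region summaries
#'
#' Summarises distances and terminator evidence by pair orientation, one row
#' per region type (same strand, convergent, divergent): counts, terminator
#' fraction and distance statistics. With strand-matched terminator
#' assignment, divergent regions carry no terminators by construction (the
#' upstream gene of a divergent pair points away from the region).
#'
#' @param pairs A feature-complete pair tibble.
#' @return A tibble with columns `orientation`, `n`, `n_term`, `pct_term`,
#'   `mean_distance`, `median_distance`, `n_overlap`.
#' @export
intergenic_summaries <- function(pairs) {
  pairs %>%
    mutate(orientation = factor(.data$orientation,
                                levels = c("same_strand", "convergent",
                                           "divergent"))) %>%
    group_by(.data$orientation, .drop = FALSE) %>%
    summarise(
      n = n(),
      n_term = sum(.data$term_present),
      pct_term = ifelse(n() > 0, 100 * sum(.data$term_present) / n(),
                        NA_real_),
      mean_distance = mean(.data$distance),
      median_distance = stats::median(as.numeric(.data$distance)),
      n_overlap = sum(.data$distance < 0),
      .groups = "drop"
    ) %>%
    mutate(orientation = as.character(.data$orientation))
}

# Internal: unordered co-transcribed adjacent pairs implied by a map.
map_stu_pairs <- function(map) {
  pairs <- purrr::map_dfr(map$tus$gene_ids, function(gs) {
    if (length(gs) < 2) return(tibble(a = character(0), b = character(0)))
    tibble(a = gs[-length(gs)], b = gs[-1])
  })
  mutate(pairs,
         key = paste(pmin(.data$a, .data$b), pmax(.data$a, .data$b),
                     sep = "\r"))
}

#' List pair-level disagreements between two operon maps
#'
#' Reports adjacent gene pairs co-transcribed in one map but not the other.
#' Both maps must be over the same gene set.
#'
#' @param map_a,map_b `operon_map` objects.
#' @return A tibble with columns `gene1`, `gene2`, `in_a`, `in_b`, one row
#'   per disagreeing pair.
#' @export
map_diff <- function(map_a, map_b) {
  pa <- map_stu_pairs(map_a)
  pb <- map_stu_pairs(map_b)
  all_keys <- union(pa$key, pb$key)
  keys <- strsplit(all_keys, "\r", fixed = TRUE)
  tibble(
    gene1 = purrr::map_chr(keys, 1),
    gene2 = purrr::map_chr(keys, 2),
    in_a = all_keys %in% pa$key,
    in_b = all_keys %in% pb$key
  ) %>%
    filter(.data$in_a != .data$in_b)
}
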