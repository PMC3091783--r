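#' Configuration for the synthetic-genome generator
#'
#' Bundles the generative law for a circular genome partitioned into
#' transcription units with geometric length distribution, class-conditional
#' intergenic-distance and terminator distributions, and within-TU-correlated
#' expression. The defaults emulate the structure the classifier assumes in
#' reduced enterobacterial genomes: co-transcribed pairs tightly spaced
#' (10-bp distance bins -2..3, peaking just above zero, including overlaps),
#' different-TU pairs spread over bins 0..30, terminators rare inside TUs
#' (0.05) and common between them (0.6; 0.86 in convergent regions, never in
#' divergent ones). A terminator needs room between the genes, so the law
#' sets `P(terminator | class, bin < 0) = 0`: overlapping pairs cannot host
#' one. [bayes_optimal_rates()] enumerates exactly this law.
#'
#' @param n_genes Number of genes (>= 4).
#' @param p_stu Geometric TU-length parameter: `P(TU length = n) =
#'   p^(n-1) (1-p)`, mean `1 / (1 - p)`. Default 0.53.
#' @param stu_distance,dtu_distance Named numeric vectors: probability of
#'   each 10-bp distance bin (names are bin indices) for within-TU and
#'   between-TU pairs. Renormalized to sum to 1.
#' @param p_term_stu,p_term_dtu Probability that a (non-overlapping)
#'   within-TU / same-strand between-TU pair hosts a terminator.
#' @param p_term_convergent,p_term_divergent Terminator probability for
#'   convergent / divergent between-TU regions.
#' @param term_confidence Integer range (min, max) of terminator
#'   confidences, drawn uniformly.
#' @param gene_length Integer range (min, max) of gene lengths in bp.
#' @param between_tu_sd,within_tu_sd,rho Expression model: per-gene value
#'   `sqrt(rho) * between_tu_sd * b_TU + sqrt(1 - rho) * within_tu_sd * e`,
#'   with standard-normal TU effects `b_TU` and gene noise `e`. With equal
#'   sds, `rho` is exactly the within-TU correlation; `rho = 0` gives
#'   i.i.d. noise.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_genes = 1000,
    p_stu = 0.53,
    stu_distance = c(`-2` = 0.08, `-1` = 0.12, `0` = 0.30, `1` = 0.25,
                     `2` = 0.15, `3` = 0.10),
    dtu_distance = NULL,
    p_term_stu = 0.05,
    p_term_dtu = 0.6,
    p_term_convergent = 0.86,
    p_term_divergent = 0,
    term_confidence = c(50L, 100L),
    gene_length = c(300L, 1500L),
    between_tu_sd = 1,
    within_tu_sd = 1,
    rho = 0) {
  if (n_genes < 4) {
    stop_dister("`n_genes` must be >= 4.", class = "dister_domain_error")
  }
  check_prob(p_stu, "p_stu")
  if (p_stu >= 1) {
    stop_dister("`p_stu` must be < 1 (finite mean TU length).",
                class = "dister_domain_error")
  }
  if (is.null(dtu_distance)) {
    # right-skewed with mode at zero, the usual shape of between-TU spacing
    w <- 0.87^(0:30)
    dtu_distance <- stats::setNames(w / sum(w), as.character(0:30))
  }
  norm_model <- function(m, what) {
    if (is.null(names(m)) || any(m < 0) || sum(m) <= 0) {
      stop_dister(sprintf("`%s` must be a named non-negative vector.", what))
    }
    m / sum(m)
  }
  for (p in c(p_term_stu, p_term_dtu, p_term_convergent, p_term_divergent)) {
    check_prob(p, "terminator probability")
  }
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop_dister("`rho` must be in [0, 1).", class = "dister_domain_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      p_stu = p_stu,
      stu_distance = norm_model(stu_distance, "stu_distance"),
      dtu_distance = norm_model(dtu_distance, "dtu_distance"),
      p_term_stu = p_term_stu,
      p_term_dtu = p_term_dtu,
      p_term_convergent = p_term_convergent,
      p_term_divergent = p_term_divergent,
      term_confidence = as.integer(term_confidence),
      gene_length = as.integer(gene_length),
      between_tu_sd = between_tu_sd,
      within_tu_sd = within_tu_sd,
      rho = rho
    ),
    class = "simulation_config"
  )
}

# Internal: draw one bin per element from a named bin-probability vector,
# optionally conditioned on bin >= 0.
draw_bins <- function(model, n, non_negative = FALSE) {
  bins <- as.integer(names(model))
  probs <- unname(model)
  if (non_negative) {
    keep <- bins >= 0
    if (!any(keep)) {
      stop_dister("distance model has no non-negative bins to draw from.")
    }
    bins <- bins[keep]
    probs <- probs[keep] / sum(probs[keep])
  }
  if (length(bins) == 1L) rep(bins, n) else sample(bins, n, TRUE, probs)
}

#' Simulate a genome with known operon structure
#'
#' Draws TU lengths from the geometric law until `n_genes` are consumed
#' (the final TU is truncated at the chromosome end), assigns each TU a
#' random strand, lays gene coordinates so that every within-TU pair's
#' intergenic distance comes from the STU distance model and every
#' between-TU pair's from the DTU model, and places strand-matched
#' terminator calls per the class-conditional law of
#' [simulation_config()]. The wrap-around pair closing the circle draws its
#' distance from the non-negative part of its model so the layout closes.
#' Everything is a pure function of `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list: `annotation` ([genome_annotation()]), `truth_map`
#'   (`operon_map`), `pairs` (feature-complete pair tibble with truth
#'   `label`), `terminators` (terminator-call tibble), `config`, `seed`.
#' @export
simulate_genome <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  withr::with_seed(as.integer(seed), {
    # --- TU structure -----------------------------------------------------
    tu_len <- integer(0)
    total <- 0L
    while (total < n) {
      len <- 1L + stats::rgeom(1L, prob = 1 - config$p_stu)
      tu_len <- c(tu_len, min(len, n - total))
      total <- total + tu_len[length(tu_len)]
    }
    n_tus <- length(tu_len)
    tu_of_gene <- rep(seq_len(n_tus), tu_len)
    tu_strand <- sample(c("+", "-"), n_tus, replace = TRUE)
    strand <- tu_strand[tu_of_gene]

    # --- per-pair class, orientation, features ----------------------------
    nxt <- c(seq_len(n)[-1], 1L)
    within <- tu_of_gene == tu_of_gene[nxt]      # truth: co-transcribed
    s_up <- strand
    s_dn <- strand[nxt]
    orientation <- case_when(
      s_up == s_dn ~ "same_strand",
      s_up == "+" ~ "convergent",
      TRUE ~ "divergent"
    )
    bins <- integer(n)
    if (any(within)) {
      bins[within] <- draw_bins(config$stu_distance, sum(within))
    }
    if (any(!within)) {
      bins[!within] <- draw_bins(config$dtu_distance, sum(!within))
    }
    # wrap pair must leave non-negative room to close the circle
    wrap_model <- if (within[n]) config$stu_distance else config$dtu_distance
    bins[n] <- draw_bins(wrap_model, 1L, non_negative = TRUE)

    p_term <- case_when(
      within ~ config$p_term_stu,
      orientation == "same_strand" ~ config$p_term_dtu,
      orientation == "convergent" ~ config$p_term_convergent,
      TRUE ~ config$p_term_divergent
    )
    term <- stats::runif(n) < p_term & bins >= 0

    offsets <- sample(0:9, n, replace = TRUE)
    offsets[term & bins == 0L] <- sample(1:9, sum(term & bins == 0L), TRUE)
    dist <- bins * 10L + offsets

    # --- coordinates ------------------------------------------------------
    min_len <- max(config$gene_length[1],
                   10L * abs(min(as.integer(names(config$stu_distance)),
                                 as.integer(names(config$dtu_distance)))) +
                     11L)
    glen <- sample(seq(min_len, max(config$gene_length[2], min_len)), n,
                   replace = TRUE)
    starts <- integer(n)
    ends <- integer(n)
    starts[1] <- 1L
    for (i in seq_len(n)) {
      ends[i] <- starts[i] + glen[i] - 1L
      if (i < n) starts[i + 1L] <- ends[i] + dist[i] + 1L
    }
    genome_len <- ends[n] + dist[n]

    gene_ids <- sprintf("g%05d", seq_len(n))
    annotation <- genome_annotation(
      tibble(gene_id = gene_ids, start = starts, end = ends,
             strand = strand),
      replicon_id = "sim", length = genome_len, circular = TRUE
    )

    # --- terminator calls -------------------------------------------------
    t_idx <- which(term)
    terminators <- if (length(t_idx) == 0) {
      tibble(start = integer(0), end = integer(0), strand = character(0),
             confidence = numeric(0), hairpin_energy = numeric(0))
    } else {
      n_t <- length(t_idx)
      d <- dist[t_idx]
      w <- pmin(d, sample(15:25, n_t, replace = TRUE))
      off <- as.integer(floor(stats::runif(n_t) * (d - w + 1L)))
      ts <- ends[t_idx] + 1L + off
      tibble(start = ts, end = ts + w - 1L, strand = strand[t_idx],
             confidence = as.numeric(sample(
               seq(config$term_confidence[1], config$term_confidence[2]),
               n_t, replace = TRUE)),
             hairpin_energy = -round(stats::runif(n_t, 4, 20), 1))
    }

    # --- truth map and feature-complete pairs -----------------------------
    tus <- tibble(grp = seq_len(n_tus)) %>%
      mutate(
        gene_ids = purrr::map(.data$grp, function(t) {
          ids <- gene_ids[tu_of_gene == t]
          if (tu_strand[t] == "-") rev(ids) else ids
        }),
        strand = tu_strand,
        length = tu_len,
        tu_id = paste0("TU_", purrr::map_chr(.data$gene_ids, 1))
      ) %>%
      select("tu_id", "gene_ids", "strand", "length")
    truth_map <- new_operon_map(
      tus, replicon_id = "sim",
      provenance = list(source = "simulate_genome", seed = as.integer(seed)),
      degenerate = n_tus == 1L
    )

    pairs <- enumerate_adjacent_pairs(annotation) %>%
      assign_terminators(terminators, annotation) %>%
      mutate(label = ifelse(within, "STU", "DTU"))

    list(annotation = annotation, truth_map = truth_map, pairs = pairs,
         terminators = terminators, config = config,
         seed = as.integer(seed))
  })
}

#' Simulate within-TU-correlated expression for a known map
#'
#' Per-gene value `sqrt(rho) * between_tu_sd * b_TU +
#' sqrt(1 - rho) * within_tu_sd * e`, with `b_TU` a standard-normal TU
#' effect shared by co-transcribed genes and `e` i.i.d. standard normal.
#' With equal sds the within-TU correlation is exactly `rho`; `rho = 0`
#' reduces to i.i.d. noise.
#'
#' @param truth_map An `operon_map`.
#' @param config A [simulation_config()] (uses its expression fields).
#' @param seed Integer seed.
#' @return An expression tibble: `gene_id`, `value`.
#' @export
simulate_expression <- function(truth_map, config = simulation_config(),
                                seed = 1L) {
  stopifnot(inherits(truth_map, "operon_map"))
  withr::with_seed(as.integer(seed), {
    n_tus <- nrow(truth_map$tus)
    b <- stats::rnorm(n_tus)
    purrr::map_dfr(seq_len(n_tus), function(t) {
      gs <- truth_map$tus$gene_ids[[t]]
      tibble(
        gene_id = gs,
        value = sqrt(config$rho) * config$between_tu_sd * b[t] +
          sqrt(1 - config$rho) * config$within_tu_sd *
            stats::rnorm(length(gs))
      )
    })
  })
}

#' Analytic Bayes-optimal error rates of the generative law
#'
#' Enumerates every (distance bin, terminator) feature cell of a
#' [simulation_config()]'s class-conditional law -- no sampling -- and
#' computes the exact sensitivity and specificity of the true-posterior
#' classifier at a threshold. The default prior is the STU base rate among
#' *same-strand* adjacent pairs implied by the config: with TU strands
#' assigned at random, between-TU pairs are same-strand half the time, so
#' `P(STU | same strand) = p / (p + (1 - p) / 2)` for geometric parameter
#' `p`.
#'
#' @param config A [simulation_config()].
#' @param threshold Decision threshold (strict `>` call, default 0.5).
#' @param prior Optional STU prior overriding the derived same-strand base
#'   rate.
#' @return A one-row tibble: `se`, `sp`, `prior`.
#' @export
bayes_optimal_rates <- function(config = simulation_config(),
                                threshold = 0.5, prior = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  check_prob(threshold, "threshold")
  p <- config$p_stu
  prior <- prior %||% (p / (p + (1 - p) / 2))
  check_prob(prior, "prior")
  bins <- sort(union(as.integer(names(config$stu_distance)),
                     as.integer(names(config$dtu_distance))))
  p_bin <- function(model, b) {
    i <- match(as.character(b), names(model))
    ifelse(is.na(i), 0, unname(model[i]))
  }
  cells <- tidyr::expand_grid(bin = bins, term = c(FALSE, TRUE)) %>%
    mutate(
      p_term_stu = ifelse(.data$bin >= 0, config$p_term_stu, 0),
      p_term_dtu = ifelse(.data$bin >= 0, config$p_term_dtu, 0),
      l_stu = p_bin(config$stu_distance, .data$bin) *
        ifelse(.data$term, .data$p_term_stu, 1 - .data$p_term_stu),
      l_dtu = p_bin(config$dtu_distance, .data$bin) *
        ifelse(.data$term, .data$p_term_dtu, 1 - .data$p_term_dtu),
      posterior = ifelse(
        .data$l_stu + .data$l_dtu > 0,
        prior * .data$l_stu /
          (prior * .data$l_stu + (1 - prior) * .data$l_dtu),
        NA_real_
      ),
      call_stu = !is.na(.data$posterior) & .data$posterior > threshold
    )
  tibble(
    se = sum(cells$l_stu[cells$call_stu]),
    sp = sum(cells$l_dtu[!cells$call_stu]),
    prior = prior
  )
}
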