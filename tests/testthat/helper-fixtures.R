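suppressPackageStartupMessages(library(dplyr))

# Fixture builders shared across the suite. Everything is generated in code;
# no binary data.

# Annotation with evenly spaced genes; strands recycled over genes.
toy_annotation <- function(strands, gene_len = 400L, gap = 100L,
                           circular = TRUE, ids = NULL) {
  n <- length(strands)
  starts <- as.integer((seq_len(n) - 1L) * (gene_len + gap) + 1L)
  genome_annotation(
    tibble::tibble(
      gene_id = ids %||% sprintf("g%03d", seq_len(n)),
      start = starts,
      end = starts + gene_len - 1L,
      strand = strands
    ),
    replicon_id = "toy",
    length = n * (gene_len + gap),
    circular = circular
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Training pairs straight from feature values (no genome needed).
feature_pairs <- function(bins, term, label, confidence = NULL) {
  n <- length(bins)
  conf <- confidence %||% ifelse(term, 80, NA_real_)
  tibble::tibble(
    upstream = sprintf("u%04d", seq_len(n)),
    downstream = sprintf("d%04d", seq_len(n)),
    orientation = "same_strand",
    distance = as.integer(bins) * 10L,
    distance_bin = as.integer(bins),
    term_present = term,
    term_score_class = terminator_score_class(ifelse(term, conf, NA_real_)),
    term_confidence = ifelse(term, conf, NA_real_),
    label = label
  )
}

# Independent brute-force posterior: smoothed counts + Bayes' rule computed
# by direct enumeration over the trained grid, sharing no code with the
# model's table machinery.
brute_posterior <- function(train, query, config, alpha, prior) {
  bins <- seq(min(train$distance_bin), max(train$distance_bin))
  states <- if (config == 3) c("absent", "low", "mid", "high")
            else c("FALSE", "TRUE")
  state_of <- function(p) {
    if (config == 3) p$term_score_class else as.character(p$term_present)
  }
  cell_prob <- function(sub, b, s) {
    # P(bin = b, state = s | class) with add-alpha smoothing over the grid
    hits <- sum(sub$distance_bin == b & state_of(sub) == s)
    (hits + alpha) / (nrow(sub) + alpha * length(bins) * length(states))
  }
  marg_prob <- function(sub, value, values, getter) {
    (sum(getter(sub) == value) + alpha) /
      (nrow(sub) + alpha * length(values))
  }
  stu <- train[train$label == "STU", , drop = FALSE]
  dtu <- train[train$label == "DTU", , drop = FALSE]
  vapply(seq_len(nrow(query)), function(i) {
    q <- query[i, , drop = FALSE]
    b <- min(max(q$distance_bin, min(bins)), max(bins))
    s <- state_of(q)
    lik <- function(sub) {
      if (config == 1) {
        marg_prob(sub, b, bins, function(x) x$distance_bin) *
          marg_prob(sub, s, states, state_of)
      } else {
        cell_prob(sub, b, s)
      }
    }
    l1 <- lik(stu)
    l0 <- lik(dtu)
    prior * l1 / (prior * l1 + (1 - prior) * l0)
  }, numeric(1))
}

# Random labeled training set over a small feature grid.
random_training_set <- function(n, seed, config = 2) {
  withr::with_seed(seed, {
    label <- sample(c("STU", "DTU"), n, replace = TRUE)
    while (length(unique(label)) < 2) {
      label <- sample(c("STU", "DTU"), n, replace = TRUE)
    }
    bins <- ifelse(label == "STU",
                   sample(-2:3, n, replace = TRUE),
                   sample(0:8, n, replace = TRUE))
    term <- stats::runif(n) < ifelse(label == "STU", 0.1, 0.6)
    conf <- sample(50:100, n, replace = TRUE)
    feature_pairs(bins, term, label, confidence = conf)
  })
}

# An operon map built directly from a vector of TU lengths (for expression
# tests): poly TUs laid consecutively, all on "+".
map_from_lengths <- function(tu_lengths, prefix = "m") {
  ids <- sprintf("%s%04d", prefix, seq_len(sum(tu_lengths)))
  stops <- cumsum(tu_lengths)
  starts <- stops - tu_lengths + 1L
  new_operon_map(
    tibble::tibble(
      tu_id = paste0("TU_", ids[starts]),
      gene_ids = purrr::map2(starts, stops, function(s, e) ids[s:e]),
      strand = "+",
      length = as.integer(tu_lengths)
    ),
    replicon_id = "toy"
  )
}

# The known-TU table used across labeling tests:
#   t_exp  experimental polycistronic TU g001-g002-g003
#   t_mono experimental monocistronic    g005
#   t_comp computational TU              g009-g010
#   t_lead experimental leader-peptide   g007-g008
toy_tus <- function() {
  tibble::tibble(
    tu_id = c("t_exp", "t_mono", "t_comp", "t_lead"),
    gene_ids = list(c("g001", "g002", "g003"), "g005",
                    c("g009", "g010"), c("g007", "g008")),
    evidence = c("experimental", "experimental", "computational",
                 "experimental"),
    leader_peptide = c(FALSE, FALSE, FALSE, TRUE)
  )
}
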