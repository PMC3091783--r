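#' Geometric transcription-unit-length prior
#'
#' Under a geometric model for the number of genes per transcription unit,
#' `P(L = n) = p^(n-1) (1 - p)` where `p` is the probability that an adjacent
#' same-strand pair is co-transcribed. The mean TU length is `1 / (1 - p)`,
#' so the prior is recovered from the mean as `p = (mean - 1) / mean`.
#'
#' @param mean_tu_length Mean number of genes per TU (>= 1).
#' @return The prior probability `p` that an adjacent pair is co-transcribed.
#' @export
#' @examples
#' estimate_prior_geometric(2.1277) # ~0.53
estimate_prior_geometric <- function(mean_tu_length) {
  if (!is.numeric(mean_tu_length) || any(is.na(mean_tu_length)) ||
      any(mean_tu_length < 1)) {
    stop_dister("`mean_tu_length` must be >= 1.",
                class = "dister_domain_error")
  }
  (mean_tu_length - 1) / mean_tu_length
}

#' Mean length of the experimentally-evidenced training TUs
#'
#' The geometric prior is estimated from the curated TUs that actually enter
#' training: experimentally-evidenced units, leader-peptide operons excluded.
#'
#' @param tus A known-TU tibble (see [read_known_tus()]).
#' @return Mean number of genes per training TU.
#' @export
mean_tu_length <- function(tus) {
  keep <- tus$evidence == "experimental" & !tus$leader_peptide
  if (!any(keep)) {
    stop_dister("no experimental, non-leader TUs to average.",
                class = "dister_domain_error")
  }
  mean(lengths(tus$gene_ids[keep]))
}

term_states_for <- function(config) {
  switch(as.character(config),
    "1" = c("FALSE", "TRUE"),
    "2" = c("FALSE", "TRUE"),
    "3" = c("absent", "low", "mid", "high")
  )
}

pair_term_state <- function(pairs, config) {
  if (config == 3) pairs$term_score_class
  else as.character(pairs$term_present)
}

#' Fit the distance-terminator Bayes classifier
#'
#' Fits class-conditional feature distributions for the two pair classes
#' (`STU` = co-transcribed, `DTU` = not) over the grid spanned by the
#' training data, with add-alpha smoothing so that cells unseen in training
#' keep non-zero likelihood. Three configurations are supported:
#'
#' 1. independent marginals of the distance bin and terminator presence;
#' 2. the joint distribution of distance bin and terminator presence;
#' 3. the joint distribution of distance bin and the four-level terminator
#'    score class (`absent`/`low`/`mid`/`high`).
#'
#' The class prior is either the geometric TU-length prior
#' ([estimate_prior_geometric()] at the supplied mean training TU length) or
#' the empirical STU fraction of the training pairs.
#'
#' @param pairs Labeled same-strand training pairs (columns `distance_bin`,
#'   `term_present`, `term_score_class`, `label` with values `STU`/`DTU`).
#'   Pairs of other orientations are dropped with a warning.
#' @param config Model configuration: 1, 2 (default) or 3.
#' @param alpha Add-alpha smoothing pseudo-count (>= 0, default 1).
#' @param prior `"geometric"` (default) or `"empirical"`.
#' @param mean_tu_len Mean training TU length for the geometric prior
#'   (see [mean_tu_length()]). Required when `prior = "geometric"`.
#' @param threshold Default decision threshold stored on the model (0.5).
#' @return A `dister_model` object.
#' @export
dister_fit <- function(pairs, config = 2, alpha = 1,
                       prior = c("geometric", "empirical"),
                       mean_tu_len = NULL, threshold = 0.5) {
  prior <- match.arg(prior)
  if (!config %in% c(1, 2, 3)) {
    stop_dister("`config` must be 1, 2 or 3.", class = "dister_domain_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    stop_dister("`alpha` must be a single number >= 0.",
                class = "dister_domain_error")
  }
  check_prob(threshold, "threshold")
  off <- pairs$orientation != "same_strand"
  if (any(off)) {
    warn(sprintf("dropping %d non-same-strand pair(s) from training.",
                 sum(off)))
    pairs <- pairs[!off, , drop = FALSE]
  }
  if (!all(pairs$label %in% c("STU", "DTU"))) {
    stop_dister("training labels must be STU or DTU (exclude NK upstream).")
  }
  n_stu <- sum(pairs$label == "STU")
  n_dtu <- sum(pairs$label == "DTU")
  if (n_stu == 0 || n_dtu == 0) {
    stop_dister("training set needs at least one STU and one DTU pair.",
                class = "dister_unfittable_error")
  }

  bins <- seq(min(pairs$distance_bin), max(pairs$distance_bin))
  states <- term_states_for(config)
  term_obs <- pair_term_state(pairs, config)

  fit_class <- function(sub) {
    sub_term <- pair_term_state(sub, config)
    if (config == 1) {
      bin_counts <- table(factor(sub$distance_bin, levels = bins))
      term_counts <- table(factor(sub_term, levels = states))
      list(
        bin = as.numeric(bin_counts + alpha) /
          sum(bin_counts + alpha),
        term = as.numeric(term_counts + alpha) /
          sum(term_counts + alpha)
      )
    } else {
      joint <- table(factor(sub$distance_bin, levels = bins),
                     factor(sub_term, levels = states))
      m <- matrix(as.numeric(joint + alpha), nrow = length(bins),
                  dimnames = list(as.character(bins), states))
      m / sum(m)
    }
  }

  tables <- list(
    STU = fit_class(pairs[pairs$label == "STU", , drop = FALSE]),
    DTU = fit_class(pairs[pairs$label == "DTU", , drop = FALSE])
  )
  if (config == 1) {
    for (cl in names(tables)) {
      names(tables[[cl]]$bin) <- as.character(bins)
      names(tables[[cl]]$term) <- states
    }
  }

  p_stu <- if (prior == "geometric") {
    if (is.null(mean_tu_len)) {
      stop_dister(paste0("geometric prior needs `mean_tu_len` ",
                         "(see mean_tu_length())."),
                  class = "dister_domain_error")
    }
    estimate_prior_geometric(mean_tu_len)
  } else {
    n_stu / (n_stu + n_dtu)
  }

  structure(
    list(
      config = as.integer(config),
      p_stu_prior = p_stu,
      prior_mode = prior,
      mean_tu_len = if (prior == "geometric") mean_tu_len else NA_real_,
      alpha = alpha,
      bins = as.integer(bins),
      term_states = states,
      tables = tables,
      threshold = threshold,
      n_train = c(STU = n_stu, DTU = n_dtu)
    ),
    class = "dister_model"
  )
}

#' @export
print.dister_model <- function(x, ...) {
  cat(sprintf(
    paste0("<dister_model> config %d | prior P(STU) = %.4f (%s) | ",
           "alpha = %g\n  trained on %d STU + %d DTU pairs, ",
           "bins %d..%d, threshold %.2f\n"),
    x$config, x$p_stu_prior, x$prior_mode, x$alpha,
    x$n_train[["STU"]], x$n_train[["DTU"]],
    min(x$bins), max(x$bins), x$threshold))
  invisible(x)
}

# Class-conditional likelihood of each pair's feature cell, vectorized.
# Bins outside the trained range are clamped to the nearest edge bin.
model_likelihood <- function(model, pairs, class) {
  b <- pmin(pmax(pairs$distance_bin, min(model$bins)), max(model$bins))
  bi <- match(b, model$bins)
  st <- pair_term_state(pairs, model$config)
  if (model$config == 3) {
    st[is.na(st)] <- "absent"
  } else {
    st[is.na(st)] <- "FALSE"
  }
  si <- match(st, model$term_states)
  if (anyNA(si)) {
    stop_dister("pair has a terminator state unknown to the model.")
  }
  tb <- model$tables[[class]]
  if (model$config == 1) {
    unname(tb$bin[bi] * tb$term[si])
  } else {
    unname(tb[cbind(bi, si)])
  }
}

#' Posterior probability of co-transcription
#'
#' Bayes' rule over the two pair classes:
#' `p * L_STU / (p * L_STU + (1 - p) * L_DTU)` where `L_c` is the
#' class-conditional probability of the pair's feature cell and `p` the STU
#' prior. Only same-strand pairs have a posterior; pairs of other
#' orientations are different-TU by definition and raise a contract error.
#'
#' @param object A `dister_model`.
#' @param pairs A feature-complete pair tibble (same-strand pairs only).
#' @param type `"posterior"` (default) appends a `p_stu` column; `"class"`
#'   additionally appends a `call` column via the model's (or supplied)
#'   threshold.
#' @param threshold Decision threshold overriding the model's stored one.
#' @param ... Unused.
#' @return The pair tibble with `p_stu` (and possibly `call`) appended.
#' @export
predict.dister_model <- function(object, pairs,
                                 type = c("posterior", "class"),
                                 threshold = NULL, ...) {
  type <- match.arg(type)
  if (any(pairs$orientation != "same_strand")) {
    stop_dister(
      "posteriors are defined for same-strand pairs only; filter first.",
      class = "dister_contract_error")
  }
  p <- object$p_stu_prior
  l_stu <- model_likelihood(object, pairs, "STU")
  l_dtu <- model_likelihood(object, pairs, "DTU")
  post <- p * l_stu / (p * l_stu + (1 - p) * l_dtu)
  out <- mutate(pairs, p_stu = post)
  if (type == "class") {
    th <- threshold %||% object$threshold
    check_prob(th, "threshold")
    out <- mutate(out, call = ifelse(.data$p_stu > th, "STU", "DTU"))
  }
  out
}

#' Hard STU/DTU calls at a threshold
#'
#' A pair is called `STU` iff its posterior strictly exceeds the threshold;
#' ties at the threshold are called `DTU`.
#'
#' @param model A `dister_model`.
#' @param pairs A feature-complete same-strand pair tibble.
#' @param threshold Decision threshold in `[0, 1]`; defaults to the model's.
#' @return The pair tibble with `p_stu` and `call` columns.
#' @export
dister_classify <- function(model, pairs, threshold = NULL) {
  predict(model, pairs, type = "class", threshold = threshold)
}

#' Serialize a fitted model to JSON (and read it back)
#'
#' Model files are plain JSON with explicit bin indices as keys; reloading is
#' numerically exact, so posteriors from a round-tripped model equal the
#' original's.
#'
#' @param model A `dister_model`.
#' @param path Output path.
#' @return `dister_write()`: the model, invisibly. `dister_read()`: the
#'   reloaded `dister_model`.
#' @export
dister_write <- function(model, path) {
  stopifnot(inherits(model, "dister_model"))
  ser <- list(
    config = model$config,
    p_stu_prior = model$p_stu_prior,
    prior_mode = model$prior_mode,
    mean_tu_len = if (is.na(model$mean_tu_len)) NULL else model$mean_tu_len,
    alpha = model$alpha,
    bins = model$bins,
    term_states = model$term_states,
    threshold = model$threshold,
    n_train = as.list(model$n_train),
    tables = purrr::map(model$tables, function(tb) {
      if (model$config == 1) {
        list(bin = as.list(tb$bin), term = as.list(tb$term))
      } else {
        stats::setNames(
          lapply(seq_len(nrow(tb)), function(r) as.list(tb[r, ])),
          rownames(tb)
        )
      }
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(model)
}

#' @rdname dister_write
#' @export
dister_read <- function(path) {
  s <- jsonlite::read_json(path)
  config <- as.integer(s$config)
  bins <- as.integer(unlist(s$bins))
  states <- unlist(s$term_states)
  tables <- purrr::map(s$tables, function(tb) {
    if (config == 1) {
      list(
        bin = stats::setNames(as.numeric(unlist(tb$bin)), names(tb$bin)),
        term = stats::setNames(as.numeric(unlist(tb$term)), names(tb$term))
      )
    } else {
      m <- do.call(rbind, lapply(tb, function(r) as.numeric(unlist(r))))
      dimnames(m) <- list(names(tb), states)
      m
    }
  })
  structure(
    list(
      config = config,
      p_stu_prior = as.numeric(s$p_stu_prior),
      prior_mode = s$prior_mode,
      mean_tu_len = as.numeric(s$mean_tu_len %||% NA_real_),
      alpha = as.numeric(s$alpha),
      bins = bins,
      term_states = states,
      tables = tables,
      threshold = as.numeric(s$threshold),
      n_train = c(STU = as.integer(s$n_train$STU),
                  DTU = as.integer(s$n_train$DTU))
    ),
    class = "dister_model"
  )
}

#' Tidy the class-conditional tables of a fitted model
#'
#' @param x A `dister_model`.
#' @param ... Unused.
#' @return A long tibble with one row per (class, feature cell): columns
#'   `class`, `component` (`joint`, or `distance`/`terminator` for the
#'   independence configuration), `distance_bin`, `term_state`,
#'   `probability`.
#' @exportS3Method generics::tidy
tidy.dister_model <- function(x, ...) {
  if (x$config == 1) {
    purrr::map_dfr(names(x$tables), function(cl) {
      tb <- x$tables[[cl]]
      bind_rows(
        tibble(class = cl, component = "distance",
               distance_bin = x$bins, term_state = NA_character_,
               probability = unname(tb$bin)),
        tibble(class = cl, component = "terminator",
               distance_bin = NA_integer_, term_state = x$term_states,
               probability = unname(tb$term))
      )
    })
  } else {
    purrr::map_dfr(names(x$tables), function(cl) {
      m <- x$tables[[cl]]
      tidyr::expand_grid(distance_bin = x$bins,
                         term_state = x$term_states) %>%
        mutate(class = cl, component = "joint",
               probability = as.vector(m)[
                 (match(.data$term_state, x$term_states) - 1L) *
                   length(x$bins) +
                   match(.data$distance_bin, x$bins)]) %>%
        select("class", "component", "distance_bin", "term_state",
               "probability")
    })
  }
}

#' One-row summary of a fitted model
#'
#' @param x A `dister_model`.
#' @param ... Unused.
#' @return A one-row tibble: configuration, prior, smoothing, training
#'   counts, trained bin range and threshold.
#' @exportS3Method generics::glance
glance.dister_model <- function(x, ...) {
  tibble(
    config = x$config,
    p_stu_prior = x$p_stu_prior,
    prior_mode = x$prior_mode,
    alpha = x$alpha,
    n_stu = unname(x$n_train[["STU"]]),
    n_dtu = unname(x$n_train[["DTU"]]),
    min_bin = min(x$bins),
    max_bin = max(x$bins),
    threshold = x$threshold
  )
}
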