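# Internal: one-way F and R2 from a response and contiguous group sizes.
# `sizes` lays groups as consecutive blocks over `y`; returns c(F, R2).
f_stat_blocks <- function(y, sizes) {
  n <- length(y)
  g <- length(sizes)
  cs <- cumsum(y)
  ends <- cumsum(sizes)
  gs <- cs[ends] - c(0, cs[ends[-g]])
  ssb <- sum(gs^2 / sizes) - sum(y)^2 / n
  sst <- sum(y^2) - sum(y)^2 / n
  ssw <- sst - ssb
  f <- if (sst <= 0) 0                      # no variance at all
       else if (ssw <= 0) Inf               # perfect separation sentinel
       else (ssb / (g - 1)) / (ssw / (n - g))
  c(f = f, r2 = if (sst > 0) ssb / sst else 0)
}

# Internal: genes of polycistronic TUs in chromosomal order + TU sizes
# (block layout). Genes missing from the expression table are dropped with a
# warning; a TU reduced below 2 genes leaves the analysis.
poly_expression <- function(expr, map) {
  stopifnot(inherits(map, "operon_map"))
  poly <- map$tus[map$tus$length > 1L, , drop = FALSE]
  if (nrow(poly) == 0) {
    stop_dister("map has no polycistronic TUs.", class = "dister_domain_error")
  }
  vals <- stats::setNames(expr$value, expr$gene_id)
  blocks <- purrr::map(poly$gene_ids, function(gs) {
    v <- vals[gs]
    unname(v[!is.na(v)])
  })
  n_missing <- sum(lengths(poly$gene_ids)) - sum(lengths(blocks))
  if (n_missing > 0) {
    missing_ids <- setdiff(unlist(poly$gene_ids), names(vals))
    warn(sprintf(
      "%d mapped gene(s) without expression values excluded%s.", n_missing,
      if (length(missing_ids) > 0)
        paste0(" (e.g. ", utils::head(missing_ids, 3)[1], ")") else ""))
  }
  keep <- lengths(blocks) >= 2L
  blocks <- blocks[keep]
  if (length(blocks) < 2) {
    stop_dister("fewer than two polycistronic TUs with >= 2 expressed genes.",
                class = "dister_domain_error")
  }
  list(y = unlist(blocks), sizes = lengths(blocks))
}

#' One-way ANOVA of expression on TU membership
#'
#' Fits the one-way decomposition of per-gene log-expression with the
#' polycistronic transcription units as the qualitative factor
#' (monocistronic TUs are excluded first):
#' `F = (SSB / (g - 1)) / (SSW / (n - g))`, `R2 = SSB / SST`,
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - g)`. Perfect within-TU homogeneity
#' (`SSW = 0`) reports `F = Inf` as a perfect-separation sentinel.
#'
#' @param expr Expression tibble: `gene_id`, `value` (one log-scale value
#'   per gene). Mapped genes without a value are excluded with a warning.
#' @param map An `operon_map`.
#' @return A one-row tibble: `statistic` (F), `r2`, `r2_adj`, `n` (genes),
#'   `g` (TUs).
#' @export
anova_tu <- function(expr, map) {
  pe <- poly_expression(expr, map)
  n <- length(pe$y)
  g <- length(pe$sizes)
  if (n - g < 1) {
    stop_dister("zero within-group degrees of freedom.",
                class = "dister_domain_error")
  }
  fr <- f_stat_blocks(pe$y, pe$sizes)
  r2 <- unname(fr["r2"])
  tibble(
    statistic = unname(fr["f"]),
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - g),
    n = n,
    g = g
  )
}

#' Permutation p-value for expression coherence of a map
#'
#' Simulates operon maps under the null of no relation between TU borders
#' and expression, by shuffling TU labels while conserving the multiset of
#' TU lengths, and recomputes the one-way ANOVA F each time. The p-value is
#' the proportion of simulated F values strictly exceeding the observed F.
#'
#' Two shuffle modes:
#' * `blocks_in_order` (default): the polycistronic TU lengths are randomly
#'   permuted and re-laid as contiguous blocks over the chromosome-ordered
#'   genes of the polycistronic subset, so simulated co-members stay
#'   adjacent -- the null keeps gene proximity and destroys only the
#'   placement of TU borders;
#' * `free_relabel`: genes are permuted freely among groups of the conserved
#'   sizes, destroying proximity as well.
#'
#' @param expr Expression tibble (`gene_id`, `value`).
#' @param map An `operon_map`.
#' @param n_perm Number of simulated maps (default 10000).
#' @param seed Integer seed; runs are bit-reproducible.
#' @param shuffle_mode `"blocks_in_order"` or `"free_relabel"`.
#' @return A `tu_permutation` object: list with `observed_f`,
#'   `observed_r2_adj`, `n_perm`, `n_exceed`, `p_value`
#'   (`n_exceed / n_perm`), `seed`, `shuffle_mode`, `f_sim` (the simulated
#'   F values).
#' @export
permutation_pvalue <- function(expr, map, n_perm = 10000, seed = 1L,
                               shuffle_mode = c("blocks_in_order",
                                                "free_relabel")) {
  shuffle_mode <- match.arg(shuffle_mode)
  if (!is.numeric(n_perm) || n_perm < 1) {
    stop_dister("`n_perm` must be >= 1.", class = "dister_domain_error")
  }
  n_perm <- as.integer(n_perm)
  obs <- anova_tu(expr, map)
  pe <- suppressWarnings(poly_expression(expr, map))
  y <- pe$y
  sizes <- pe$sizes
  f_sim <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      if (shuffle_mode == "blocks_in_order") {
        f_stat_blocks(y, sample(sizes))[["f"]]
      } else {
        f_stat_blocks(sample(y), sizes)[["f"]]
      }
    }, numeric(1))
  })
  n_exceed <- sum(f_sim > obs$statistic)
  structure(
    list(
      observed_f = obs$statistic,
      observed_r2_adj = obs$r2_adj,
      n_perm = n_perm,
      n_exceed = n_exceed,
      p_value = n_exceed / n_perm,
      seed = as.integer(seed),
      shuffle_mode = shuffle_mode,
      f_sim = f_sim
    ),
    class = "tu_permutation"
  )
}

#' @export
print.tu_permutation <- function(x, ...) {
  p_txt <- if (x$n_exceed == 0) sprintf("< %g", 1 / x$n_perm)
           else format(x$p_value)
  cat(sprintf(
    paste0("<tu_permutation> F = %.3f, adj. R2 = %.3f, ",
           "p = %s (%d of %d simulated maps exceed; mode %s, seed %d)\n"),
    x$observed_f, x$observed_r2_adj, p_txt, x$n_exceed, x$n_perm,
    x$shuffle_mode, x$seed))
  invisible(x)
}

#' @rdname glance.dister_model
#' @exportS3Method generics::glance
glance.tu_permutation <- function(x, ...) {
  tibble(
    observed_f = x$observed_f,
    observed_r2_adj = x$observed_r2_adj,
    n_perm = x$n_perm,
    n_exceed = x$n_exceed,
    p_value = x$p_value,
    seed = x$seed,
    shuffle_mode = x$shuffle_mode
  )
}

#' @rdname tidy.dister_model
#' @exportS3Method generics::tidy
tidy.tu_permutation <- function(x, ...) {
  tibble(replicate = seq_len(x$n_perm), f = x$f_sim)
}
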