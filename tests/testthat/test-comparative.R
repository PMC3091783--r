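test_that("bidirectional best hits require mutual best scores", {
  sim <- tibble::tibble(
    gene_a = c("a1", "a1", "a2", "a2"),
    gene_b = c("b1", "b2", "b1", "b2"),
    score = c(90, 50, 95, 60)
  )
  # a1's best is b1, but b1's best is a2 -> only (a2, b1) survives
  bbh <- bbh_orthologs(sim)
  expect_equal(nrow(bbh), 1)
  expect_equal(bbh$gene_a, "a2")
  expect_equal(bbh$gene_b, "b1")
})

test_that("bbh matches an exhaustive double loop on random score tables", {
  brute_bbh <- function(sim) {
    hits <- list()
    for (a in unique(sim$gene_a)) {
      sa <- sim[sim$gene_a == a, ]
      sa <- sa[order(-sa$score, sa$gene_b), ]
      b <- sa$gene_b[1]
      sb <- sim[sim$gene_b == b, ]
      sb <- sb[order(-sb$score, sb$gene_a), ]
      if (sb$gene_a[1] == a) hits[[length(hits) + 1L]] <- c(a, b)
    }
    if (length(hits) == 0) return(character(0))
    sort(vapply(hits, paste, character(1), collapse = "->"))
  }
  for (seed in 1:50) {
    sim <- withr::with_seed(seed, {
      n <- sample(5:20, 1)
      tibble::tibble(
        gene_a = sample(sprintf("a%02d", 1:8), n, replace = TRUE),
        gene_b = sample(sprintf("b%02d", 1:8), n, replace = TRUE),
        score = sample(1:40, n, replace = TRUE)
      ) %>% dplyr::distinct(gene_a, gene_b, .keep_all = TRUE)
    })
    got <- bbh_orthologs(sim)
    expect_equal(sort(paste(got$gene_a, got$gene_b, sep = "->")),
                 brute_bbh(sim))
  }
})

# Shared scenery for TU typing: reference TUs over genes r*, A map over a*,
# orthology a_i <-> r_i unless stated otherwise.
ref_tus_fix <- function() {
  tibble::tibble(
    tu_id = c("R1", "R2", "R3"),
    gene_ids = list(c("r1", "r2"), c("r3", "r4", "r5"), c("r6", "r7")),
    evidence = "experimental",
    leader_peptide = FALSE
  )
}

a_map <- function(...) {
  tus <- list(...)
  new_operon_map(tibble::tibble(
    tu_id = paste0("A", seq_along(tus)),
    gene_ids = tus,
    strand = "+",
    length = lengths(tus)
  ))
}

orth_tbl <- function(pairs) {
  tibble::tibble(gene_a = names(pairs), gene_b = unname(pairs))
}

test_that("the five TU types fire exactly as defined", {
  orth <- orth_tbl(c(a1 = "r1", a2 = "r2", a3 = "r3", a4 = "r4",
                     a5 = "r6", a6 = "r7"))
  # identical: exact correspondence with R1
  m <- a_map(c("a1", "a2"), c("a3", "a4"), c("a5", "a6"))
  types <- classify_tu_types(m, ref_tus_fix(), orth)
  expect_equal(types$tu_type[1], "identical")
  # similar: R2 also holds r5, whose ortholog is nowhere in A
  expect_equal(types$tu_type[2], "similar")
  expect_equal(types$extra_ref_genes[2], "r5")
  # split: give r5 an A ortholog living in another A TU
  orth2 <- dplyr::bind_rows(orth_tbl(c(a1 = "r1", a2 = "r2", a3 = "r3",
                                       a4 = "r4", a7 = "r5")))
  m2 <- a_map(c("a3", "a4"), c("a7", "a1", "a2"))
  types2 <- classify_tu_types(m2, ref_tus_fix(), orth2)
  expect_equal(types2$tu_type[types2$tu_id == "A1"], "split")
  # merged: one A TU spans R1 and R3; leftover r2, r7 have no A ortholog
  orth3 <- orth_tbl(c(a1 = "r1", a2 = "r6"))
  m3 <- a_map(c("a1", "a2"))
  expect_equal(classify_tu_types(m3, ref_tus_fix(), orth3)$tu_type,
               "merged")
  # reorganized: as merged, but leftover r7's ortholog sits elsewhere in A
  orth4 <- orth_tbl(c(a1 = "r1", a2 = "r6", a3 = "r7"))
  m4 <- a_map(c("a1", "a2"), "a3")
  types4 <- classify_tu_types(m4, ref_tus_fix(), orth4)
  expect_equal(types4$tu_type[types4$tu_id == "A1"], "reorganized")
  # unclassifiable: no ortholog at all
  orth5 <- tibble::tibble(gene_a = c("a1", "a2"),
                          gene_b = c(NA_character_, NA_character_))
  expect_equal(classify_tu_types(a_map(c("a1", "a2")), ref_tus_fix(),
                                 orth5)$tu_type,
               "unclassifiable")
})

test_that("TU types are mutually exclusive and exhaustive under fuzzing", {
  ref <- ref_tus_fix()
  ref_genes <- unlist(ref$gene_ids)
  for (seed in 1:30) {
    scenario <- withr::with_seed(seed, {
      a_genes <- sprintf("a%02d", 1:10)
      mapped <- sample(ref_genes, sample(3:7, 1))
      orth <- tibble::tibble(
        gene_a = a_genes,
        gene_b = c(mapped, rep(NA_character_, 10 - length(mapped)))
      )
      cuts <- sort(sample(1:9, sample(1:4, 1)))
      bounds <- c(0, cuts, 10)
      tus <- purrr::map2((bounds[-length(bounds)] + 1), bounds[-1],
                         function(s, e) a_genes[s:e])
      list(orth = orth, map = do.call(a_map, tus))
    })
    types <- classify_tu_types(scenario$map, ref, scenario$orth)
    expect_equal(nrow(types), nrow(scenario$map$tus))
    expect_true(all(types$tu_type %in%
                      c("identical", "similar", "split", "merged",
                        "reorganized", "unclassifiable")))
    has_orth <- purrr::map_lgl(scenario$map$tus$gene_ids, function(gs) {
      any(gs %in% scenario$orth$gene_a[!is.na(scenario$orth$gene_b)])
    })
    expect_equal(types$tu_type == "unclassifiable", !has_orth)
  }
})

test_that("nested alternative reference TUs reduce to maximal ones", {
  ref <- tibble::tibble(
    tu_id = c("big", "nested"),
    gene_ids = list(c("r1", "r2", "r3"), c("r2", "r3")),
    evidence = "experimental", leader_peptide = FALSE
  )
  orth <- orth_tbl(c(a1 = "r1", a2 = "r2", a3 = "r3"))
  types <- classify_tu_types(a_map(c("a1", "a2", "a3")), ref, orth)
  expect_equal(types$tu_type, "identical")
  expect_equal(types$ref_tus, "big")
})

test_that("type summary mirrors the per-type composition", {
  calls <- tibble::tibble(
    tu_id = sprintf("t%d", 1:5),
    tu_type = c("identical", "identical", "merged", "similar", "merged"),
    n_genes = c(1L, 3L, 4L, 1L, 2L)
  )
  s <- tu_type_summary(calls)
  m <- s[s$tu_type == "merged", ]
  expect_equal(m$n_tus, 2L)
  expect_equal(m$n_genes, 6L)
  expect_equal(m$n_mono, 0L)
  expect_equal(m$n_poly, 2L)
})

test_that("ancestral pairs honour reference and outgroup adjacency", {
  pairs <- tibble::tibble(
    upstream = c("a1", "a2", "a3", "a4"),
    downstream = c("a2", "a3", "a4", "a1")
  )
  orth <- orth_tbl(c(a1 = "b1", a2 = "b2", a3 = "b3", a4 = "b4"))
  ref_pairs <- tibble::tibble(upstream = c("b2", "b9"),
                              downstream = c("b1", "b3"))
  out <- ancestral_pairs(pairs, orth, ref_pairs)
  # (a1,a2): orthologs adjacent in reference (reversed order still counts)
  expect_true(out$ancestral[1])
  expect_equal(out$ancestral_source[1], "reference")
  expect_false(any(out$ancestral[2:4]))
  # outgroup rescues (a3, a4)
  og <- list(orth = orth_tbl(c(a3 = "v3", a4 = "v4")),
             pairs = tibble::tibble(upstream = "v3", downstream = "v4"))
  out2 <- ancestral_pairs(pairs, orth, ref_pairs, outgroups = list(og))
  expect_true(out2$ancestral[3])
  expect_equal(out2$ancestral_source[3], "outgroup")
  # strict mode requires order-preserving adjacency
  strict <- ancestral_pairs(pairs, orth, ref_pairs, strict = TRUE)
  expect_false(strict$ancestral[1])
})

test_that("fragments are maximal runs with pairs + 1 genes", {
  flags <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  pairs <- tibble::tibble(
    upstream = sprintf("g%d", 1:8),
    downstream = sprintf("g%d", c(2:8, 1)),
    ancestral = flags
  )
  frags <- ancestral_fragments(pairs, circular = TRUE)
  # wrap: pair 8 (ancestral) joins pair 1's run -> runs of 4 and 1 pairs
  expect_equal(sort(frags$n_pairs), c(1L, 4L))
  expect_equal(frags$n_genes, frags$n_pairs + 1L)
  expect_equal(sum(frags$n_pairs), sum(flags))
  # chain of 3 consecutive ancestral pairs -> one fragment of 4 genes
  chain <- tibble::tibble(
    upstream = sprintf("g%d", 1:5), downstream = sprintf("g%d", c(2:5, 1)),
    ancestral = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(ancestral_fragments(chain)$n_genes, 4L)
  # no ancestral pairs -> no fragments
  none <- dplyr::mutate(chain, ancestral = FALSE)
  expect_equal(nrow(ancestral_fragments(none)), 0)
  # every pair ancestral on a circle -> one whole-circle fragment, k genes
  full <- dplyr::mutate(chain, ancestral = TRUE)
  expect_equal(ancestral_fragments(full)$n_genes, 5L)
})

test_that("conserved-pair status splits into STU/DTU/opposite", {
  pairs_a <- tibble::tibble(
    upstream = c("a1", "a2", "a3", "a9"),
    downstream = c("a2", "a3", "a4", "a10"),
    call = c("STU", "DTU", "STU", "STU")
  )
  pairs_b <- tibble::tibble(
    upstream = c("b1", "b2", "b3"),
    downstream = c("b2", "b3", "b4"),
    call = c("STU", "DTU", "DTU")
  )
  orth <- orth_tbl(c(a1 = "b1", a2 = "b2", a3 = "b3", a4 = "b4"))
  st <- conserved_pair_status(pairs_a, pairs_b, orth)
  expect_equal(nrow(st), 3)  # (a9, a10) has no orthologs: not conserved
  expect_equal(st$status, c("STU", "DTU", "opposite"))
})

test_that("length-evolution classes follow the printed inequalities", {
  expect_equal(length_evolution_class(300, 330, 300), 2L)
  expect_equal(length_evolution_class(270, 300, 300), 4L)
  expect_equal(length_evolution_class(300, 300, 270), 1L)
  expect_equal(length_evolution_class(300, 270, 300), 3L)
  expect_equal(length_evolution_class(330, 300, 300), 5L)
  expect_equal(length_evolution_class(270, 330, 300), 6L)
  expect_true(is.na(length_evolution_class(300, 330, NA)))
})

test_that("the six length classes partition random triples", {
  triples <- withr::with_seed(9, matrix(sample(50:500, 30000, TRUE),
                                        ncol = 3))
  cls <- length_evolution_class(triples[, 1], triples[, 2], triples[, 3])
  expect_false(anyNA(cls))
  expect_true(all(cls %in% 1:6))
})

test_that("loss attribution weighs ancestral evidence", {
  presence <- tibble::tibble(
    ancestor = c(TRUE, FALSE, NA, NA),
    outgroup1 = c(NA, FALSE, FALSE, NA),
    outgroup2 = c(FALSE, FALSE, TRUE, NA)
  )
  expect_equal(unname(loss_attribution(presence)),
               c("lost_in_a", "acquired_in_reference", "lost_in_a",
                 "ambiguous"))
})

test_that("the 2x2 contingency utility matches stats::chisq.test", {
  a <- withr::with_seed(5, stats::runif(200) < 0.4)
  b <- withr::with_seed(6, stats::runif(200) < 0.6)
  got <- flag_contingency_test(a, b)
  want <- suppressWarnings(stats::chisq.test(table(a, b), correct = FALSE))
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p_value, want$p.value)
  expect_equal(got$n_tt + got$n_tf + got$n_ft + got$n_ff, 200L)
})
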