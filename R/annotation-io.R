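#' Construct a genome annotation
#'
#' Bundles an ordered, stranded gene table with replicon metadata. This is the
#' in-memory representation used by every downstream step: adjacent-pair
#' enumeration, feature computation and operon-map assembly. Coordinates are
#' 1-based and inclusive (GenBank convention) on a single, optionally circular
#' replicon.
#'
#' @param genes A data frame with columns `gene_id` (unique character),
#'   `start`, `end` (integer bp, 1-based inclusive, `end >= start`), `strand`
#'   (`"+"` or `"-"`), and optionally `kind` (`"CDS"` or `"RNA"`, default
#'   `"CDS"`) and `name`.
#' @param replicon_id Replicon identifier string.
#' @param length Replicon length in bp. Defaults to the maximum gene end.
#' @param circular Is the replicon circular? Bacterial chromosomes are, and
#'   that is the default.
#'
#' @return An object of class `genome_annotation`: a list with fields
#'   `replicon_id`, `length`, `circular` and `genes` (a tibble sorted by
#'   `start`).
#' @export
#' @examples
#' ann <- genome_annotation(
#'   tibble::tibble(
#'     gene_id = c("g1", "g2", "g3"),
#'     start = c(1L, 500L, 1200L),
#'     end = c(400L, 1100L, 1900L),
#'     strand = c("+", "+", "-")
#'   ),
#'   replicon_id = "chr", length = 2100L
#' )
#' ann
genome_annotation <- function(genes, replicon_id = "replicon",
                              length = NULL, circular = TRUE) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop_dister(sprintf("`genes` is missing column(s): %s.",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) == 0) {
    stop_dister("annotation contains zero genes.",
                class = "dister_empty_annotation")
  }
  if (!"kind" %in% names(genes)) genes$kind <- "CDS"
  if (!"name" %in% names(genes)) genes$name <- NA_character_
  genes <- genes %>%
    mutate(
      gene_id = as.character(.data$gene_id),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand),
      kind = as.character(.data$kind),
      name = as.character(.data$name)
    )
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop_dister(sprintf("duplicate gene_id(s): %s.",
                        paste(unique(dup), collapse = ", ")),
                class = "dister_duplicate_id")
  }
  if (any(genes$start < 1L)) {
    stop_dister("gene starts must be >= 1.")
  }
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start]
    stop_dister(sprintf("end < start for gene(s): %s.",
                        paste(bad, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_dister("strand must be \"+\" or \"-\" for every gene.")
  }
  if (!all(genes$kind %in% c("CDS", "RNA"))) {
    stop_dister("kind must be \"CDS\" or \"RNA\" for every gene.")
  }
  if (is.null(length)) length <- max(genes$end)
  length <- as.integer(length)
  if (any(genes$end > length)) {
    stop_dister("gene coordinates exceed the replicon length.")
  }
  genes <- arrange(genes, .data$start, .data$end, .data$gene_id)
  structure(
    list(
      replicon_id = as.character(replicon_id),
      length = length,
      circular = isTRUE(circular),
      genes = genes
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes, %s bp, %s\n",
              x$replicon_id, nrow(x$genes), format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  print(x$genes, n = 5)
  invisible(x)
}

#' Number of genes in an annotation
#' @param annotation A `genome_annotation`.
#' @return Integer gene count.
#' @export
n_genes <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  nrow(annotation$genes)
}

#' Read a genome annotation from GFF3 or GenBank
#'
#' GFF3 files are parsed with \pkg{rtracklayer}; GenBank flat files with a
#' minimal built-in feature-table reader (LOCUS line for length/topology,
#' `CDS`/`tRNA`/`rRNA`/`ncRNA`/`tmRNA` features with plain or
#' `complement()` locations, `locus_tag`/`gene` qualifiers for ids). When the
#' file does not state the topology, the replicon is assumed circular, the
#' normal case for bacterial chromosomes.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"genbank"`. Default guesses from the file
#'   extension.
#' @param kinds Feature kinds to keep: `"CDS"`, `"RNA"` or both (default).
#'
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "genbank"),
                            kinds = c("CDS", "RNA")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_dister(sprintf("annotation file not found: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "gff3"
  }
  ann <- switch(format,
    gff3 = read_annotation_gff3(path),
    genbank = read_annotation_genbank(path)
  )
  keep <- ann$genes$kind %in% kinds
  if (!all(keep)) {
    ann <- genome_annotation(ann$genes[keep, , drop = FALSE],
                             replicon_id = ann$replicon_id,
                             length = ann$length, circular = ann$circular)
  }
  ann
}

rna_feature_types <- c("tRNA", "rRNA", "ncRNA", "tmRNA", "misc_RNA", "RNA")

read_annotation_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      stop_dister(sprintf("malformed GFF3 file %s: %s", path,
                          conditionMessage(e)),
                  class = "dister_parse_error")
    }
  )
  types <- as.character(gr$type)
  # a region feature, when present, states replicon length and topology
  region_len <- NA_integer_
  region_circ <- NA
  region <- gr[types == "region"]
  if (length(region) > 0) {
    region_len <- max(GenomicRanges::end(region))
    if (!is.null(region$Is_circular)) {
      rc <- tolower(as.character(region$Is_circular[1]))
      if (!is.na(rc)) region_circ <- rc == "true"
    }
  }
  keep_types <- c("gene", "CDS", rna_feature_types)
  gr <- gr[types %in% keep_types]
  types <- as.character(gr$type)
  # Prefer gene features when present; fall back to CDS/RNA records.
  if (any(types == "gene")) {
    sel <- types == "gene"
    # A gene feature does not say CDS vs RNA; use an explicit kind
    # attribute when present (our own exports carry one), else recover it
    # from RNA children via Parent links, else default CDS.
    kind <- rep("CDS", sum(sel))
    ids_sel <- feature_ids(gr[sel])
    if (!is.null(gr$kind)) {
      kind <- ifelse(is.na(gr$kind[sel]), "CDS", as.character(gr$kind[sel]))
    } else {
      rna <- gr[types %in% rna_feature_types]
      if (length(rna) > 0) {
        parents <- unlist(lapply(rna$Parent,
                                 function(p) p[1] %||% NA_character_))
        kind[ids_sel %in% parents] <- "RNA"
      }
    }
    gr <- gr[sel]
  } else {
    kind <- ifelse(types %in% rna_feature_types, "RNA", "CDS")
  }
  if (length(gr) == 0) {
    stop_dister(sprintf("no gene features found in %s.", path),
                class = "dister_empty_annotation")
  }
  ids <- feature_ids(gr)
  genes <- tibble(
    gene_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  )
  if (any(!genes$strand %in% c("+", "-"))) {
    stop_dister("GFF3 gene feature with unstranded location ('.' or '*').",
                class = "dister_parse_error")
  }
  si <- GenomeInfoDb::seqinfo(gr)
  len <- suppressWarnings(GenomeInfoDb::seqlengths(si)[1])
  if (is.na(len)) len <- region_len
  circ <- suppressWarnings(GenomeInfoDb::isCircular(si)[1])
  if (is.na(circ)) circ <- region_circ
  genome_annotation(
    genes,
    replicon_id = as.character(GenomeInfoDb::seqnames(gr)[1]),
    length = if (is.na(len)) max(genes$end) else as.integer(len),
    circular = if (is.na(circ)) TRUE else circ
  )
}

feature_ids <- function(gr) {
  ids <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag)
         else rep(NA_character_, length(gr))
  if (!is.null(gr$ID)) {
    ids <- ifelse(is.na(ids), as.character(gr$ID), ids)
  }
  if (!is.null(gr$Name)) {
    ids <- ifelse(is.na(ids), as.character(gr$Name), ids)
  }
  if (anyNA(ids)) {
    stop_dister("GFF3 feature without locus_tag/ID/Name attribute.",
                class = "dister_parse_error")
  }
  ids
}

read_annotation_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) {
    stop_dister(sprintf("%s: no LOCUS line; not a GenBank flat file.", path),
                class = "dister_parse_error")
  }
  locus_fields <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  replicon_id <- locus_fields[2]
  len <- suppressWarnings(as.integer(locus_fields[3]))
  circular <- grepl("\\bcircular\\b", locus[1], ignore.case = TRUE) ||
    !grepl("\\blinear\\b", locus[1], ignore.case = TRUE)
  f_start <- grep("^FEATURES", lines)
  if (length(f_start) == 0) {
    stop_dister(sprintf("%s: no FEATURES table.", path),
                class = "dister_parse_error")
  }
  f_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  f_end <- f_end[f_end > f_start[1]]
  f_end <- if (length(f_end) > 0) min(f_end) - 1L else length(lines)
  block <- lines[(f_start[1] + 1L):f_end]

  keep_keys <- c("CDS", rna_feature_types)
  feat_key <- character(0)
  feat_loc <- character(0)
  feat_quals <- list()
  cur <- NULL
  for (ln in block) {
    key_m <- regmatches(ln, regexec("^ {5}(\\S+) +(\\S.*)$", ln))[[1]]
    if (length(key_m) == 3 && !grepl("^/", key_m[2])) {
      if (!is.null(cur)) {
        feat_key <- c(feat_key, cur$key)
        feat_loc <- c(feat_loc, cur$loc)
        feat_quals <- c(feat_quals, list(cur$quals))
      }
      cur <- list(key = key_m[2], loc = key_m[3], quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (!grepl("\"", txt) && grepl("^[0-9.,()<>a-z]+$", txt)) {
        cur$loc <- paste0(cur$loc, txt)  # continued location line
      }
    }
  }
  if (!is.null(cur)) {
    feat_key <- c(feat_key, cur$key)
    feat_loc <- c(feat_loc, cur$loc)
    feat_quals <- c(feat_quals, list(cur$quals))
  }

  sel <- feat_key %in% keep_keys
  if (!any(sel)) {
    stop_dister(sprintf("%s: no CDS/RNA features found.", path),
                class = "dister_empty_annotation")
  }
  feat_key <- feat_key[sel]
  feat_loc <- feat_loc[sel]
  feat_quals <- feat_quals[sel]

  qual_value <- function(quals, name) {
    pat <- paste0("^/", name, "=\"?([^\"]*)\"?$")
    hit <- grep(pat, quals, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(pat, "\\1", hit[1])
  }

  genes <- purrr::map2_dfr(feat_loc, seq_along(feat_loc), function(loc, i) {
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 1) {
      stop_dister(sprintf("GenBank feature %d: unparseable location '%s'.",
                          i, loc),
                  class = "dister_parse_error")
    }
    tibble(
      gene_id = qual_value(feat_quals[[i]], "locus_tag") %||% NA_character_,
      name = qual_value(feat_quals[[i]], "gene"),
      start = min(nums), end = max(nums), strand = strand,
      kind = if (feat_key[i] == "CDS") "CDS" else "RNA"
    )
  })
  genes$gene_id <- ifelse(is.na(genes$gene_id), genes$name, genes$gene_id)
  if (anyNA(genes$gene_id)) {
    stop_dister("GenBank feature without locus_tag or gene qualifier.",
                class = "dister_parse_error")
  }
  genome_annotation(genes, replicon_id = replicon_id,
                    length = if (is.na(len)) max(genes$end) else len,
                    circular = circular)
}

#' Read Rho-independent terminator calls
#'
#' Accepts either TransTermHP plain-text output (the `TERM` lines carry
#' coordinates, strand, a 0-100 confidence and the hairpin free energy) or a
#' 5-column TSV (`start`, `end`, `strand`, `confidence`, `hairpin_energy`).
#' Coordinates are normalized so `start <= end`.
#'
#' @param path Path to the terminator file.
#' @param format `"transtermhp"`, `"tsv"`, or `"auto"` (default; guesses
#'   `tsv` for `.tsv`/`.txt` files containing a header row).
#' @return A tibble of terminator calls with columns `start`, `end`, `strand`,
#'   `confidence`, `hairpin_energy`, sorted by `start`.
#' @export
read_terminators <- function(path, format = c("auto", "transtermhp", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_dister(sprintf("terminator file not found: %s", path))
  }
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) > 0 && grepl("^start\\t", first))
      "tsv" else "transtermhp"
  }
  calls <- if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, na = ".") %>%
      select("start", "end", "strand", "confidence", "hairpin_energy")
  } else {
    lines <- grep("\\bTERM\\b", readLines(path, warn = FALSE), value = TRUE)
    if (length(lines) == 0) {
      tibble(start = integer(0), end = integer(0), strand = character(0),
             confidence = numeric(0), hairpin_energy = numeric(0))
    } else {
      pat <- paste0("TERM\\s+\\S+\\s+(\\d+)\\s*\\.\\.\\s*(\\d+)\\s+([+-])",
                    "\\s+\\S+\\s+(\\d+)\\s+(-?[0-9.]+)")
      m <- regmatches(lines, regexec(pat, lines))
      bad <- which(lengths(m) != 6)
      if (length(bad) > 0) {
        stop_dister(sprintf("unparseable TERM line (first: '%s').",
                            trimws(lines[bad[1]])),
                    class = "dister_parse_error")
      }
      purrr::map_dfr(m, function(g) {
        tibble(start = as.integer(g[2]), end = as.integer(g[3]),
               strand = g[4], confidence = as.numeric(g[5]),
               hairpin_energy = as.numeric(g[6]))
      })
    }
  }
  calls <- calls %>%
    mutate(
      start0 = pmin(.data$start, .data$end),
      end0 = pmax(.data$start, .data$end),
      start = as.integer(.data$start0), end = as.integer(.data$end0)
    ) %>%
    select(-"start0", -"end0")
  if (any(calls$confidence < 0 | calls$confidence > 100, na.rm = TRUE)) {
    stop_dister("terminator confidence outside [0, 100].",
                class = "dister_validation_error")
  }
  if (!all(calls$strand %in% c("+", "-"))) {
    stop_dister("terminator strand must be \"+\" or \"-\".",
                class = "dister_validation_error")
  }
  arrange(calls, .data$start, .data$end)
}

#' Read and write known transcription-unit tables
#'
#' The known-TU table is the training substrate for the pair classifier: one
#' row per transcription unit with its ordered gene list, the evidence class
#' (`experimental` or `computational`) and a leader-peptide flag (attenuation
#' operons are excluded from training because the target genomes lack
#' attenuation). The TSV dialect is tab-separated with a header row; gene
#' lists are comma-separated; missing values are `"."`.
#'
#' @param path Path of the TSV file.
#' @return `read_known_tus()`: a tibble with columns `tu_id`, `gene_ids`
#'   (list column of character vectors), `evidence`, `leader_peptide`.
#' @export
read_known_tus <- function(path) {
  if (!file.exists(path)) {
    stop_dister(sprintf("TU table not found: %s", path))
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE, na = ".",
                        col_types = readr::cols(.default = "c"))
  required <- c("tu_id", "genes", "evidence", "leader_peptide")
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols) > 0) {
    stop_dister(sprintf("TU table missing column(s): %s.",
                        paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    tu_id = tb$tu_id,
    gene_ids = strsplit(tb$genes, ",", fixed = TRUE),
    evidence = tb$evidence,
    leader_peptide = tolower(tb$leader_peptide) %in% c("true", "t", "1", "yes")
  )
  if (any(lengths(out$gene_ids) == 0)) {
    stop_dister("TU with an empty gene list.")
  }
  if (!all(out$evidence %in% c("experimental", "computational"))) {
    stop_dister("evidence must be 'experimental' or 'computational'.")
  }
  out
}

#' @rdname read_known_tus
#' @param tus A known-TU tibble as returned by `read_known_tus()`.
#' @return `write_known_tus()`: the input, invisibly.
#' @export
write_known_tus <- function(tus, path) {
  out <- tibble(
    tu_id = tus$tu_id,
    genes = purrr::map_chr(tus$gene_ids, paste, collapse = ","),
    evidence = tus$evidence,
    leader_peptide = ifelse(tus$leader_peptide, "true", "false")
  )
  readr::write_tsv(out, path)
  invisible(tus)
}

#' Check that TU gene ids resolve against an annotation
#'
#' @param tus A known-TU tibble.
#' @param annotation A [genome_annotation()].
#' @return The TU tibble, invisibly, if every gene id resolves.
#' @export
validate_tus <- function(tus, annotation) {
  known <- annotation$genes$gene_id
  offending <- setdiff(unique(unlist(tus$gene_ids)), known)
  if (length(offending) > 0) {
    stop_dister(sprintf("TU gene id(s) absent from the annotation: %s.",
                        paste(offending, collapse = ", ")),
                class = "dister_join_error")
  }
  invisible(tus)
}

#' Write an operon map to TSV or GFF3
#'
#' The TSV layout is one row per transcription unit (`tu_id`, comma-separated
#' `genes` in transcription order, `strand`, `length`). GFF3 export emits one
#' `transcript` feature per TU spanning its member genes, with the gene ids in
#' a `genes` attribute.
#'
#' @param map An `operon_map` (see [assemble_map()]).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @param annotation Required for GFF3 export: the [genome_annotation()] the
#'   map was assembled from (provides gene coordinates).
#' @return The map, invisibly.
#' @export
write_operon_map <- function(map, path, format = c("tsv", "gff3"),
                             annotation = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(map, "operon_map"))
  if (format == "tsv") {
    out <- tibble(
      tu_id = map$tus$tu_id,
      genes = purrr::map_chr(map$tus$gene_ids, paste, collapse = ","),
      strand = map$tus$strand,
      length = map$tus$length
    )
    readr::write_tsv(out, path)
  } else {
    if (is.null(annotation)) {
      stop_dister("GFF3 export needs the `annotation` the map was built from.")
    }
    coords <- annotation$genes %>% select("gene_id", "start", "end")
    spans <- purrr::map2_dfr(map$tus$tu_id, map$tus$gene_ids, function(id, gs) {
      g <- coords[coords$gene_id %in% gs, , drop = FALSE]
      tibble(tu_id = id, start = min(g$start), end = max(g$end))
    })
    gr <- GenomicRanges::GRanges(
      seqnames = map$replicon_id,
      ranges = IRanges::IRanges(start = spans$start, end = spans$end),
      strand = map$tus$strand
    )
    gr$type <- "transcript"
    gr$ID <- map$tus$tu_id
    gr$genes <- purrr::map_chr(map$tus$gene_ids, paste, collapse = ",")
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(map)
}

#' Read an operon map written by [write_operon_map()]
#'
#' @param path Path of the TSV file.
#' @param replicon_id Replicon id to attach (TSV does not carry it).
#' @return An `operon_map`.
#' @export
read_operon_map <- function(path, replicon_id = "replicon") {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  tus <- tibble(
    tu_id = tb$tu_id,
    gene_ids = strsplit(tb$genes, ",", fixed = TRUE),
    strand = tb$strand,
    length = lengths(strsplit(tb$genes, ",", fixed = TRUE))
  )
  new_operon_map(tus, replicon_id = replicon_id,
                 provenance = list(source = path))
}

#' Write and read feature-complete pair tables
#'
#' The pair-table TSV mirrors the columns produced by
#' [enumerate_adjacent_pairs()] and friends: `upstream`, `downstream`,
#' `orientation`, `distance`, `distance_bin`, `term_present`,
#' `term_score_class`, `term_confidence`, `label`.
#'
#' @param pairs A pair tibble.
#' @param path Output path.
#' @return `write_pairs()`: the input, invisibly; `read_pairs()`: the tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, na = ".")
  invisible(pairs)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = ".",
                  col_types = readr::cols(
                    upstream = "c", downstream = "c", orientation = "c",
                    distance = "i", distance_bin = "i", term_present = "l",
                    term_score_class = "c", term_confidence = "d",
                    label = "c"
                  ))
}

#' Read a per-gene expression table
#'
#' @param path TSV with columns `gene_id` and `value` (log-scale expression,
#'   one value per gene, replicates pre-averaged).
#' @return A tibble with columns `gene_id`, `value`.
#' @export
read_expression <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, na = ".")
  if (!all(c("gene_id", "value") %in% names(tb))) {
    stop_dister("expression table needs columns gene_id, value.")
  }
  if (any(!is.finite(tb$value))) {
    stop_dister("expression values must be finite.")
  }
  tibble(gene_id = as.character(tb$gene_id), value = as.numeric(tb$value))
}

#' Read an orthology table
#'
#' Tab-separated, one row per gene of genome A: `gene_a`, `gene_b` (ortholog
#' in genome B or `.`), optional per-outgroup presence flags
#' (`outgroup_*` columns, logical), optional lengths (`len_a`, `len_b`,
#' `len_ext`), optional `regulated_in_b` and `operondb_score`.
#'
#' @param path Path of the TSV file.
#' @return A tibble with one row per `gene_a`.
#' @export
read_orthology <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, na = ".")
  if (!all(c("gene_a", "gene_b") %in% names(tb))) {
    stop_dister("orthology table needs columns gene_a, gene_b.")
  }
  if (anyDuplicated(tb$gene_a)) {
    stop_dister("gene_a must be unique in an orthology table.")
  }
  bb <- tb$gene_b[!is.na(tb$gene_b)]
  if (anyDuplicated(bb)) {
    stop_dister("orthology must be at most one-to-one; duplicated gene_b.")
  }
  tb
}
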