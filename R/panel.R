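#' Panel definition: genes, exon regions, amplicons, pool assignment
#'
#' A `panel_def` models the genomic footprint of a dual-pool amplicon panel:
#' a table of exon regions (the units at which coverage is judged) and a
#' table of amplicons, each assigned to exactly one of the two primer pools
#' A and B.  All intervals use the BED convention (0-based, half-open); the
#' conversion from 1-based variant positions happens once, at the lookup
#' boundary.
#'
#' @name panel_def
NULL

# Per-gene topology of the bundled 26-gene panel: exon regions, the exons
# each region spans, and the number of amplicons covering it.  Region labels
# carry the split/group structure: an exon split into sub-regions gets
# suffixed labels ("15.1"), exons grouped under shared amplicons get a
# composite label ("2_3_4").  Gene totals: 178 amplicons over 82 distinct
# exons (83 region records).  Where only a per-gene amplicon total is known,
# the per-region split is illustrative but fixed.
tst26_topology <- function() {
  tribble(
    ~gene, ~accession, ~exon_label, ~exons, ~n_amplicons,
    "AKT1", "NG_012188.1", "2", "2", 1L,
    "ALK", "NG_009445.1", "23", "23", 1L,
    "APC", "NG_008481.4", "15.1", "15", 2L,
    "APC", "NG_008481.4", "15.2", "15", 2L,
    "APC", "NG_008481.4", "15.3", "15", 10L,
    "BRAF", "NG_007873.3", "11", "11", 1L,
    "BRAF", "NG_007873.3", "15", "15", 2L,
    "CDH1", "NG_008021.1", "8", "8", 2L,
    "CDH1", "NG_008021.1", "9", "9", 2L,
    "CDH1", "NG_008021.1", "12", "12", 2L,
    "CTNNB1", "NG_013302.2", "2", "2", 2L,
    "EGFR", "NG_007726.3", "18", "18", 2L,
    "EGFR", "NG_007726.3", "19", "19", 2L,
    "EGFR", "NG_007726.3", "20", "20", 1L,
    "EGFR", "NG_007726.3", "21", "21", 2L,
    "ERBB2", "NG_007503.1", "20", "20", 2L,
    "FBXW7", "NG_029466.2", "7", "7", 3L,
    "FBXW7", "NG_029466.2", "8", "8", 3L,
    "FBXW7", "NG_029466.2", "9", "9", 3L,
    "FBXW7", "NG_029466.2", "10", "10", 2L,
    "FBXW7", "NG_029466.2", "11", "11", 2L,
    "FGFR2", "NG_012449.2", "6", "6", 2L,
    "FOXL2", "NG_012454.1", "1", "1", 1L,
    "GNAQ", "NG_027904.2", "4", "4", 2L,
    "GNAQ", "NG_027904.2", "5", "5", 2L,
    "GNAQ", "NG_027904.2", "6", "6", 2L,
    "GNAS", "NG_016194.2", "6", "6", 1L,
    "GNAS", "NG_016194.2", "8", "8", 1L,
    "KIT", "NG_007456.1", "9", "9", 2L,
    "KIT", "NG_007456.1", "11", "11", 2L,
    "KIT", "NG_007456.1", "13", "13", 2L,
    "KIT", "NG_007456.1", "17", "17", 2L,
    "KIT", "NG_007456.1", "18", "18", 1L,
    "KRAS", "NG_007524.1", "1", "1", 2L,
    "KRAS", "NG_007524.1", "2", "2", 2L,
    "KRAS", "NG_007524.1", "3", "3", 2L,
    "KRAS", "NG_007524.1", "4", "4", 2L,
    "MAP2K1", "NG_008305.1", "2", "2", 1L,
    "MET", "NG_008996.1", "1", "1", 3L,
    "MET", "NG_008996.1", "4", "4", 3L,
    "MET", "NG_008996.1", "13", "13", 3L,
    "MET", "NG_008996.1", "15", "15", 3L,
    "MET", "NG_008996.1", "16", "16", 3L,
    "MET", "NG_008996.1", "17", "17", 3L,
    "MET", "NG_008996.1", "18", "18", 2L,
    "MET", "NG_008996.1", "20", "20", 2L,
    "MSH6", "NG_007111.1", "5", "5", 3L,
    "NRAS", "NG_007572.1", "1", "1", 2L,
    "NRAS", "NG_007572.1", "2", "2", 2L,
    "NRAS", "NG_007572.1", "3", "3", 2L,
    "NRAS", "NG_007572.1", "4", "4", 2L,
    "PDGFRA", "NG_009250.1", "11", "11", 2L,
    "PDGFRA", "NG_009250.1", "13", "13", 2L,
    "PDGFRA", "NG_009250.1", "17", "17", 1L,
    "PIK3CA", "NG_012113.2", "1", "1", 3L,
    "PIK3CA", "NG_012113.2", "2", "2", 3L,
    "PIK3CA", "NG_012113.2", "7", "7", 3L,
    "PIK3CA", "NG_012113.2", "9", "9", 3L,
    "PIK3CA", "NG_012113.2", "20", "20", 3L,
    "PTEN", "NG_007466.2", "1.1", "1", 1L,
    "PTEN", "NG_007466.2", "1.2", "1", 1L,
    "PTEN", "NG_007466.2", "2", "2", 2L,
    "PTEN", "NG_007466.2", "3", "3", 2L,
    "PTEN", "NG_007466.2", "4", "4", 2L,
    "PTEN", "NG_007466.2", "5.1", "5", 1L,
    "PTEN", "NG_007466.2", "5.2", "5", 1L,
    "PTEN", "NG_007466.2", "6.1", "6", 1L,
    "PTEN", "NG_007466.2", "6.2", "6", 1L,
    "PTEN", "NG_007466.2", "7", "7", 3L,
    "PTEN", "NG_007466.2", "9", "9", 2L,
    "SMAD4", "NG_013013.2", "8", "8", 3L,
    "SMAD4", "NG_013013.2", "11", "11", 2L,
    "SRC", "NG_023033.1", "10", "10", 2L,
    "STK11", "NG_007460.2", "1", "1", 2L,
    "STK11", "NG_007460.2", "4", "4", 2L,
    "STK11", "NG_007460.2", "6", "6", 1L,
    "STK11", "NG_007460.2", "8", "8", 2L,
    "TP53", "NG_017013.2", "2_3_4", "2,3,4", 6L,
    "TP53", "NG_017013.2", "5_6", "5,6", 4L,
    "TP53", "NG_017013.2", "7", "7", 1L,
    "TP53", "NG_017013.2", "8_9", "8,9", 3L,
    "TP53", "NG_017013.2", "10", "10", 1L,
    "TP53", "NG_017013.2", "11", "11", 1L
  )
}

tst26_chromosomes <- function() {
  c(
    AKT1 = "chr14", ALK = "chr2", APC = "chr5", BRAF = "chr7",
    CDH1 = "chr16", CTNNB1 = "chr3", EGFR = "chr7", ERBB2 = "chr17",
    FBXW7 = "chr4", FGFR2 = "chr10", FOXL2 = "chr3", GNAQ = "chr9",
    GNAS = "chr20", KIT = "chr4", KRAS = "chr12", MAP2K1 = "chr15",
    MET = "chr7", MSH6 = "chr2", NRAS = "chr1", PDGFRA = "chr4",
    PIK3CA = "chr3", PTEN = "chr10", SMAD4 = "chr18", SRC = "chr20",
    STK11 = "chr19", TP53 = "chr17"
  )
}

#' Construct the bundled 26-gene dual-pool panel
#'
#' Builds the default panel definition: 26 genes, 82 exons covered by
#' 178 amplicons in two primer pools.  Genomic coordinates are synthetic but
#' self-consistent (each gene occupies a disjoint 1 Mb block on its
#' chromosome); every computation in the package depends only on the
#' topology — which amplicon covers which exon region in which pool — not on
#' absolute positions.  Within a region, amplicons alternate pools starting
#' with A, so single-amplicon regions are covered by one pool only.
#'
#' @return A [panel_def] object with `$exons` and `$amplicons` tibbles.
#' @examples
#' panel <- tst26_panel()
#' glance(panel)
#' @export
tst26_panel <- function() {
  topo <- tst26_topology()
  chroms <- tst26_chromosomes()
  genes <- unique(topo$gene)
  region_len <- 250L
  amp_len <- 180L

  topo <- topo |>
    mutate(
      gene_index = match(.data$gene, genes),
      contig = unname(chroms[.data$gene])
    ) |>
    group_by(.data$gene) |>
    mutate(region_index = dplyr::row_number()) |>
    ungroup() |>
    mutate(
      start = .data$gene_index * 1000000L + (.data$region_index - 1L) * 10000L,
      end = .data$start + region_len
    )

  exons <- topo |>
    transmute(
      gene_symbol = .data$gene,
      accession = .data$accession,
      exon_label = .data$exon_label,
      exons = .data$exons,
      contig = .data$contig,
      start = .data$start,
      end = .data$end
    )

  amplicons <- topo |>
    mutate(k = purrr::map(.data$n_amplicons, seq_len)) |>
    tidyr::unnest("k") |>
    transmute(
      amplicon_id = sprintf("%s_ex%s_amp%02d", .data$gene, .data$exon_label,
                            .data$k),
      gene_symbol = .data$gene,
      exon_label = .data$exon_label,
      pool = ifelse(.data$k %% 2L == 1L, "A", "B"),
      contig = .data$contig,
      start = .data$start - 20L + (.data$k - 1L) * 10L,
      end = .data$start - 20L + (.data$k - 1L) * 10L + amp_len
    )

  new_panel_def("TsT26-like bundled panel", exons, amplicons)
}

new_panel_def <- function(name, exons, amplicons) {
  panel <- structure(
    list(name = name, exons = as_tibble(exons), amplicons = as_tibble(amplicons)),
    class = "panel_def"
  )
  validate_panel(panel)
}

validate_panel <- function(panel) {
  exons <- panel$exons
  amps <- panel$amplicons
  if (any(exons$start >= exons$end)) {
    abort("exon regions must satisfy start < end", class = "panelval_parse_error")
  }
  if (any(amps$start >= amps$end)) {
    abort("amplicons must satisfy start < end", class = "panelval_parse_error")
  }
  if (anyDuplicated(paste(exons$gene_symbol, exons$exon_label))) {
    abort("exon_label must be unique within gene", class = "panelval_validation_error")
  }
  bad_pool <- setdiff(unique(amps$pool), c("A", "B"))
  if (length(bad_pool) > 0) {
    abort(sprintf("unknown pool label(s): %s", paste(bad_pool, collapse = ", ")),
          class = "panelval_validation_error")
  }
  joined <- left_join(
    amps, exons,
    by = c("gene_symbol", "exon_label"), suffix = c("", ".exon")
  )
  if (any(is.na(joined$start.exon))) {
    orphan <- joined$amplicon_id[is.na(joined$start.exon)]
    abort(sprintf("amplicon(s) target unknown exon region: %s",
                  paste(head(orphan, 5), collapse = ", ")),
          class = "panelval_validation_error")
  }
  overlaps <- joined$start < joined$end.exon & joined$start.exon < joined$end &
    joined$contig == joined$contig.exon
  if (any(!overlaps)) {
    bad <- joined$amplicon_id[!overlaps]
    abort(sprintf("amplicon interval does not overlap its target exon: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "panelval_validation_error")
  }
  uncovered <- anti_join(exons, amps, by = c("gene_symbol", "exon_label"))
  if (nrow(uncovered) > 0) {
    abort(sprintf("exon region(s) covered by no amplicon: %s",
                  paste(head(paste(uncovered$gene_symbol, uncovered$exon_label), 5),
                        collapse = ", ")),
          class = "panelval_validation_error")
  }
  panel
}

#' @export
print.panel_def <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<panel_def> %s\n  %d genes, %d exons (%d regions), %d amplicons (pool A: %d, pool B: %d)\n",
    x$name, g$n_genes, g$n_exons, g$n_regions, g$n_amplicons,
    sum(x$amplicons$pool == "A"), sum(x$amplicons$pool == "B")
  ))
  invisible(x)
}

#' @describeIn tst26_panel One-row tibble of panel counts: genes, distinct
#'   exons, region records, amplicons.
#' @param x A `panel_def`.
#' @param ... Unused.
#' @method glance panel_def
#' @export
glance.panel_def <- function(x, ...) {
  exon_pairs <- x$exons |>
    mutate(exon = strsplit(.data$exons, ",", fixed = TRUE)) |>
    tidyr::unnest("exon") |>
    distinct(.data$gene_symbol, .data$exon)
  tibble(
    n_genes = dplyr::n_distinct(x$exons$gene_symbol),
    n_exons = nrow(exon_pairs),
    n_regions = nrow(x$exons),
    n_amplicons = nrow(x$amplicons)
  )
}

#' Read a panel manifest (BED + sidecar TSV)
#'
#' The manifest is a pair of plain-text files: a 4-column BED
#' (`contig`, `start`, `end`, `amplicon_id`; 0-based half-open) giving the
#' amplicon intervals, and a sidecar TSV keyed by `amplicon_id` carrying
#' `pool` (A/B), `gene`, `exon_label`, `accession` and the exon-region
#' coordinates `exon_start`/`exon_end` (plus `exons`, the comma-separated
#' exon numbers the region spans) so that the amplicon-covers-exon invariant
#' is checkable.
#'
#' @param bed_path Path to the amplicon BED file.
#' @param meta_path Path to the sidecar TSV.  Defaults to `bed_path` with the
#'   extension replaced by `.tsv`.
#' @param name Panel name stored on the object.
#' @return A validated [panel_def].
#' @examples
#' panel <- load_panel(tst26_manifest_path("bed"), tst26_manifest_path("tsv"))
#' glance(panel)
#' @export
load_panel <- function(bed_path, meta_path = NULL, name = basename(bed_path)) {
  if (!file.exists(bed_path)) {
    abort(sprintf("manifest BED not found: %s", bed_path),
          class = "panelval_io_error")
  }
  meta_path <- meta_path %||% sub("\\.bed$", ".tsv", bed_path)
  if (!file.exists(meta_path)) {
    abort(sprintf("manifest sidecar TSV not found: %s", meta_path),
          class = "panelval_io_error")
  }
  bed <- readr::read_tsv(
    bed_path,
    col_names = c("contig", "start", "end", "amplicon_id"),
    col_types = "ciic", progress = FALSE
  )
  bad <- which(is.na(bed$start) | is.na(bed$end) | bed$start >= bed$end)
  if (length(bad) > 0) {
    abort(sprintf("malformed interval in %s at line %d", bed_path, bad[1]),
          class = "panelval_parse_error")
  }
  meta <- readr::read_tsv(
    meta_path,
    col_types = readr::cols(exon_label = "c", exons = "c", pool = "c",
                            .default = readr::col_guess()),
    progress = FALSE
  )
  check_columns(meta, c("amplicon_id", "pool", "gene", "exon_label",
                        "accession", "exon_start", "exon_end"),
                "manifest sidecar")
  if (!"exons" %in% names(meta)) meta$exons <- as.character(meta$exon_label)
  unmatched <- setdiff(bed$amplicon_id, meta$amplicon_id)
  if (length(unmatched) > 0) {
    abort(sprintf("amplicon(s) missing from sidecar: %s",
                  paste(head(unmatched, 5), collapse = ", ")),
          class = "panelval_validation_error")
  }
  full <- inner_join(bed, meta, by = "amplicon_id")
  exons <- full |>
    distinct(
      gene_symbol = .data$gene, accession = .data$accession,
      exon_label = as.character(.data$exon_label),
      exons = as.character(.data$exons),
      contig = .data$contig,
      start = as.integer(.data$exon_start), end = as.integer(.data$exon_end)
    )
  amplicons <- full |>
    transmute(
      amplicon_id = .data$amplicon_id,
      gene_symbol = .data$gene,
      exon_label = as.character(.data$exon_label),
      pool = as.character(.data$pool),
      contig = .data$contig,
      start = .data$start, end = .data$end
    )
  new_panel_def(name, exons, amplicons)
}

#' Write a panel manifest
#'
#' Inverse of [load_panel()]: writes the BED and sidecar TSV so that
#' reloading reproduces identical intervals and pool labels.
#'
#' @param panel A [panel_def].
#' @param bed_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, bed_path, meta_path = sub("\\.bed$", ".tsv", bed_path)) {
  stopifnot(inherits(panel, "panel_def"))
  bed <- panel$amplicons |>
    select("contig", "start", "end", "amplicon_id")
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  meta <- panel$amplicons |>
    left_join(
      panel$exons |>
        select("gene_symbol", "exon_label", "accession", "exons",
               exon_start = "start", exon_end = "end"),
      by = c("gene_symbol", "exon_label")
    ) |>
    select("amplicon_id", "pool", gene = "gene_symbol", "exon_label",
           "accession", "exons", "exon_start", "exon_end")
  readr::write_tsv(meta, meta_path, progress = FALSE)
  invisible(c(bed_path, meta_path))
}

#' Path to the bundled panel manifest
#'
#' @param which `"bed"` or `"tsv"`.
#' @return File path inside the installed package.
#' @export
tst26_manifest_path <- function(which = c("bed", "tsv")) {
  which <- arg_match(which)
  system.file("extdata", paste0("tst26_amplicons.", which),
              package = "panelval", mustWork = TRUE)
}

#' Look up the amplicons covering an exon
#'
#' `exon_label` may name region labels directly (including composite labels
#' such as `"2_3_4"` for grouped exons or `"15.1"` for a split sub-region) or
#' plain exon numbers, in which case every region spanning one of those
#' exons is matched.  All pools are returned.
#'
#' @param panel A [panel_def].
#' @param gene Gene symbol.
#' @param exon_label Character vector of region labels or exon numbers.
#' @return Tibble of amplicons (one row each), both pools.
#' @examples
#' panel <- tst26_panel()
#' nrow(amplicons_for_exon(panel, "EGFR", c("18", "19", "20", "21")))  # 7
#' nrow(amplicons_for_exon(panel, "TP53", "2_3_4"))                    # 6
#' @export
amplicons_for_exon <- function(panel, gene, exon_label) {
  stopifnot(inherits(panel, "panel_def"))
  exon_label <- as.character(exon_label)
  gene_exons <- filter(panel$exons, .data$gene_symbol == gene)
  if (nrow(gene_exons) == 0) {
    abort(sprintf("unknown gene: %s", gene), class = "panelval_lookup_error")
  }
  hit <- gene_exons$exon_label %in% exon_label
  if (!any(hit)) {
    spanned <- purrr::map(strsplit(gene_exons$exons, ",", fixed = TRUE),
                          identity)
    hit <- purrr::map_lgl(spanned, ~ any(.x %in% exon_label))
  }
  if (!any(hit)) {
    abort(sprintf("gene %s has no exon region matching: %s",
                  gene, paste(exon_label, collapse = ", ")),
          class = "panelval_lookup_error")
  }
  labels <- gene_exons$exon_label[hit]
  panel$amplicons |>
    filter(.data$gene_symbol == gene, .data$exon_label %in% labels)
}
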