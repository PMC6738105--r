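#' Filter peaks by FDR
#'
#' Keeps peaks whose `score` (interpreted as the peak-calling FDR) is
#' strictly below `fdr_max`.
#'
#' @param peaks a `genomic_intervals` tibble of peak calls.
#' @param fdr_max FDR cut-off (strict `<`), default 0.05.
#' @return the filtered `genomic_intervals` tibble.
#' @export
filter_peaks <- function(peaks, fdr_max = 0.05) {
  stopifnot(is.data.frame(peaks))
  if (!"score" %in% names(peaks) || (nrow(peaks) > 0 && all(is.na(peaks$score)))) {
    abort(paste(
      "peaks carry no score column: the peak FDR must be in BED column 5",
      "(see read_bed())."
    ))
  }
  assert_scalar_number(fdr_max, "fdr_max", 0, 1)
  filter(peaks, !is.na(.data$score), .data$score < fdr_max)
}

#' Regulatory windows around gene models
#'
#' Expands each gene model to its putative regulatory window. With
#' `anchor = "cds"` (default) the window spans the whole model padded on both
#' sides: `[start - pad, end + pad)`. With `anchor = "tss"` the window is
#' centred on the strand-aware transcription start site (model start on `+`,
#' model end on `-`): `[tss - pad, tss + pad)`. Windows are clipped at
#' coordinate 0. Multiple models per gene yield multiple windows; a peak in
#' any of them marks the gene bound.
#'
#' @param gene_models a `genomic_intervals` tibble of gene models (`name` =
#'   gene identifier, meaningful `strand` required for `anchor = "tss"`).
#' @param pad window half-width in bp (default 2000).
#' @param anchor `"cds"` or `"tss"`.
#' @return a `genomic_intervals` tibble of windows, one per input model.
#' @export
gene_window <- function(gene_models, pad = 2000, anchor = c("cds", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(is.data.frame(gene_models))
  assert_scalar_number(pad, "pad", 0)
  if (anchor == "cds") {
    start <- pmax(gene_models$start - pad, 0)
    end <- gene_models$end + pad
  } else {
    if (any(!gene_models$strand %in% c("+", "-"))) {
      abort("anchor = 'tss' requires a '+' or '-' strand for every gene model.")
    }
    tss <- ifelse(gene_models$strand == "+", gene_models$start, gene_models$end)
    start <- pmax(tss - pad, 0)
    end <- tss + pad
  }
  genomic_intervals(
    chrom = gene_models$chrom, start = start, end = end,
    name = gene_models$name, score = NA_real_, strand = gene_models$strand
  )
}

as_granges0 <- function(x) {
  # 0-based half-open -> IRanges 1-based closed; >=1 bp overlap is preserved
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Annotate peak binding to genes
#'
#' Marks a gene as bound when at least one (already FDR-filtered) peak
#' overlaps one of its regulatory windows by >= 1 bp on the same chromosome
#' (half-open overlap test, computed with GenomicRanges). When the peaks
#' carry a `dataset` column (e.g. cell line x factor), binding is called per
#' dataset.
#'
#' @param peaks filtered `genomic_intervals` of peaks; optional `dataset`
#'   column.
#' @param gene_models `genomic_intervals` of gene models.
#' @inheritParams gene_window
#' @return tibble of class `binding_matrix`: `gene`, `dataset`, `bound`,
#'   `n_peaks`, `peaks` (list-column of supporting peak names).
#' @export
annotate_binding <- function(peaks, gene_models, pad = 2000, anchor = "cds") {
  windows <- gene_window(gene_models, pad = pad, anchor = anchor)
  datasets <- if ("dataset" %in% names(peaks)) unique(peaks$dataset) else "peaks"
  genes <- unique(gene_models$name)
  gr_win <- as_granges0(windows)
  out <- map(datasets, function(ds) {
    pk <- if ("dataset" %in% names(peaks)) filter(peaks, .data$dataset == ds) else peaks
    hits <- if (nrow(pk)) {
      # peaks on chromosomes without any window are simply non-overlapping
      suppressWarnings(
        GenomicRanges::findOverlaps(as_granges0(pk), gr_win, minoverlap = 1L)
      )
    } else {
      NULL
    }
    support <- vector("list", length(genes))
    names(support) <- genes
    if (!is.null(hits) && length(hits)) {
      gene_of_win <- windows$name[S4Vectors::subjectHits(hits)]
      peak_name <- pk$name[S4Vectors::queryHits(hits)]
      peak_name[is.na(peak_name)] <- sprintf("peak_%d", S4Vectors::queryHits(hits)[is.na(peak_name)])
      sup <- split(peak_name, gene_of_win)
      support[names(sup)] <- map(sup, unique)
    }
    tibble(
      gene = genes, dataset = ds,
      bound = lengths(support[genes]) > 0,
      n_peaks = lengths(support[genes]),
      peaks = unname(support[genes])
    )
  })
  out <- bind_rows(out)
  class(out) <- c("binding_matrix", class(out))
  out
}

#' Summarise binding over a query gene list
#'
#' For each dataset, counts how many query genes (restricted to those present
#' among the gene models) are bound, e.g. "84/94 bound in HeLa". Query genes
#' absent from the gene models are reported in the `"absent_genes"` attribute.
#'
#' @param binding a `binding_matrix` from [annotate_binding()].
#' @param query_genes character vector of genes of interest.
#' @return tibble: `dataset`, `n_bound`, `n_query`, `fraction`; absent query
#'   genes in `attr(, "absent_genes")`.
#' @export
binding_summary <- function(binding, query_genes) {
  stopifnot(is.data.frame(binding), all(c("gene", "dataset", "bound") %in% names(binding)))
  present <- intersect(norm_gene(query_genes), norm_gene(unique(binding$gene)))
  absent <- setdiff(norm_gene(query_genes), present)
  out <- binding |>
    filter(norm_gene(.data$gene) %in% present) |>
    group_by(.data$dataset) |>
    summarise(
      n_bound = sum(.data$bound), n_query = dplyr::n(),
      fraction = ifelse(dplyr::n() > 0, sum(.data$bound) / dplyr::n(), NA_real_),
      .groups = "drop"
    )
  structure(out, absent_genes = absent)
}
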