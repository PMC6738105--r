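#' Expression cohort container
#'
#' One cohort's log2-scale expression matrix (genes x samples) with a cohort
#' label. Values may contain `NA` for missing measurements; all non-missing
#' values must be finite. Gene and sample identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param cohort_id short cohort label.
#' @return an `expression_cohort` object.
#' @export
expression_cohort <- function(values, cohort_id) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (nrow(values) == 0 || ncol(values) == 0) abort("expression matrix is empty.")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    abort("expression matrix needs rownames (genes) and colnames (samples).")
  }
  if (anyDuplicated(genes)) abort("duplicate gene identifiers in expression matrix.")
  if (anyDuplicated(samples)) abort("duplicate sample identifiers in expression matrix.")
  if (any(is.infinite(values))) abort("expression values must be finite or NA.")
  if (!is.character(cohort_id) || length(cohort_id) != 1 || !nzchar(cohort_id)) {
    abort("`cohort_id` must be a non-empty string.")
  }
  structure(
    list(cohort_id = cohort_id, genes = genes, samples = samples, values = values),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf(
    "<expression_cohort '%s': %d genes x %d samples, %d missing values>\n",
    x$cohort_id, length(x$genes), length(x$samples), sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' @rdname expression_cohort
#' @param x an `expression_cohort`.
#' @param ... unused.
#' @export
as_tibble.expression_cohort <- function(x, ...) {
  as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "log2_expr") |>
    mutate(cohort_id = x$cohort_id, .before = 1)
}

#' Read an expression matrix from a tab-separated file
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#' Values are log2-scale expression; empty cells and `NA` are read as missing.
#' Duplicated gene rows are collapsed by keeping the row with the highest mean
#' expression (a warning reports how many were dropped).
#'
#' @param path file path.
#' @param cohort_id cohort label attached to the result.
#' @return an [expression_cohort()].
#' @export
read_expression <- function(path, cohort_id) {
  lines <- readr::read_lines(path)
  if (length(lines) < 2) abort(sprintf("%s: need a header plus at least one gene row.", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) abort(sprintf("%s:1: malformed header (no sample columns).", path))
  samples <- header[-1]
  n_col <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  genes <- character(length(fields))
  vals <- matrix(NA_real_, nrow = length(fields), ncol = n_col - 1)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != n_col) {
      abort(sprintf("%s:%d: expected %d fields, found %d.", path, i + 1L, n_col, length(f)))
    }
    genes[[i]] <- trimws(f[[1]])
    cell <- f[-1]
    cell[cell %in% c("", "NA", "na", "NaN")] <- NA
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad)) {
      abort(sprintf(
        "%s:%d: non-numeric value '%s' in column %d.",
        path, i + 1L, cell[[bad[[1]]]], bad[[1]] + 1L
      ))
    }
    vals[i, ] <- num
  }
  if (anyDuplicated(genes)) {
    keep <- order(-rowMeans(vals, na.rm = TRUE))
    keep <- keep[!duplicated(genes[keep])]
    n_drop <- length(genes) - length(keep)
    warn(sprintf(
      "%s: %d duplicated gene row(s) collapsed (kept highest-mean row).", path, n_drop
    ))
    keep <- sort(keep)
    genes <- genes[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- genes
  colnames(vals) <- samples
  expression_cohort(vals, cohort_id)
}

#' Write an expression cohort to a tab-separated file
#'
#' @param cohort an [expression_cohort()].
#' @param path output path.
#' @param gene_col name for the first (gene identifier) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(cohort, path, gene_col = "gene") {
  stopifnot(inherits(cohort, "expression_cohort"))
  df <- as.data.frame(cohort$values)
  df <- cbind(setNames(data.frame(cohort$genes), gene_col), df)
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Gene-set collections (GMT)
#'
#' A gene-set collection is a named list of character vectors of member genes,
#' with per-set descriptions kept in the `"descriptions"` attribute — the
#' structure of an MSigDB GMT file.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list of member vectors.")
  }
  if (anyDuplicated(names(sets))) abort("gene-set names must be unique.")
  if (any(lengths(sets) == 0)) abort("gene sets must be non-empty.")
  if (any(map_int(sets, anyDuplicated) > 0)) abort("gene sets must not contain duplicate members.")
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection: %d sets, sizes %d-%d>\n",
    length(x), min(lengths(x)), max(lengths(x))
  ))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are dropped with a warning; a line with fewer
#' than three fields is a fatal error.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("%s: empty GMT file.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("%s:%d: GMT line has fewer than 3 fields.", path, short[[1]]))
  }
  nms <- map_chr(fields, 1)
  if (anyDuplicated(nms)) abort(sprintf("%s: duplicated set name '%s'.", path, nms[duplicated(nms)][[1]]))
  desc <- setNames(map_chr(fields, 2), nms)
  sets <- setNames(map(fields, ~ .x[-(1:2)]), nms)
  n_dup <- sum(map_int(sets, ~ sum(duplicated(.x))))
  if (n_dup > 0) {
    warn(sprintf("%s: %d duplicate member(s) within sets dropped.", path, n_dup))
    sets <- map(sets, unique)
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- imap(unclass(collection), function(members, nm) {
    paste(c(nm, desc[[nm]] %||% "", members), collapse = "\t")
  })
  # strip attributes so write_lines sees a bare character vector
  readr::write_lines(unlist(lines, use.names = FALSE), path)
  invisible(path)
}

new_genomic_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand") %in% names(df)))
  if (any(!nzchar(df$chrom))) abort("chrom must be non-empty.")
  if (any(df$start < 0)) abort("negative interval coordinates.")
  if (any(df$start >= df$end)) abort("intervals must satisfy start < end.")
  structure(as_tibble(df), class = c("genomic_intervals", class(as_tibble(df))))
}

#' Build a genomic-interval tibble
#'
#' Internal coordinates are 0-based half-open `[start, end)` throughout the
#' package; conversion to and from 1-based closed conventions happens only at
#' I/O boundaries ([read_gene_models()] for GTF).
#'
#' @param chrom,start,end,name,score,strand interval fields; `score` carries
#'   the peak FDR when the intervals represent peak calls.
#' @return a tibble of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  new_genomic_intervals(tibble(
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    name = as.character(name), score = as.numeric(score),
    strand = as.character(strand)
  ))
}

#' Read a BED file of intervals
#'
#' BED3+ dialect: columns chrom, start, end and optionally name (4), score (5,
#' interpreted as peak FDR when present) and strand (6). BED coordinates are
#' already 0-based half-open and are kept as-is.
#'
#' @param path BED file path.
#' @return a `genomic_intervals` tibble.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track") &
    !startsWith(lines, "browser")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(fields)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  parse_one <- function(f, ln) {
    if (length(f) < 3) abort(sprintf("%s:%d: BED line needs >= 3 fields.", path, ln))
    start <- suppressWarnings(as.integer(f[[2]]))
    end <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(start) || is.na(end)) abort(sprintf("%s:%d: non-integer coordinates.", path, ln))
    if (start < 0) abort(sprintf("%s:%d: negative start coordinate.", path, ln))
    if (start >= end) abort(sprintf("%s:%d: start >= end.", path, ln))
    tibble(
      chrom = f[[1]], start = start, end = end,
      name = if (length(f) >= 4) f[[4]] else NA_character_,
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[[5]])) else NA_real_,
      strand = if (length(f) >= 6) f[[6]] else "."
    )
  }
  new_genomic_intervals(bind_rows(map2(fields, lineno, parse_one)))
}

#' Write intervals to BED
#'
#' @param intervals a `genomic_intervals` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- as.data.frame(intervals)[, c("chrom", "start", "end", "name", "score", "strand")]
  df$name[is.na(df$name)] <- "."
  df$score[is.na(df$score)] <- 0
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GTF
#'
#' Gene models are one interval per gene (the CDS span). BED6 input is used
#' as-is (column 4 = gene identifier). GTF input is filtered to `feature` rows
#' (default `"CDS"`, falling back to `"gene"` when no CDS rows exist), its
#' 1-based closed coordinates converted to 0-based half-open, and multiple
#' rows per gene aggregated to the spanning interval per chromosome/strand.
#'
#' @param path BED6 or GTF file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @param feature GTF feature type to use.
#' @return a `genomic_intervals` tibble with gene identifiers in `name` and
#'   meaningful `strand`.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf"), feature = "CDS") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  if (format == "bed") {
    out <- read_bed(path)
    if (any(is.na(out$name))) abort(sprintf("%s: gene models need a name column (BED6).", path))
    return(out)
  }
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  if (length(bad)) abort(sprintf("%s:%d: GTF line has fewer than 9 fields.", path, lineno[[bad[[1]]]]))
  feat <- map_chr(fields, 3)
  use <- feat == feature
  if (!any(use) && feature == "CDS") use <- feat == "gene"
  if (!any(use)) abort(sprintf("%s: no '%s' (or 'gene') features found.", path, feature))
  rows <- map2(fields[use], lineno[use], function(f, ln) {
    start1 <- suppressWarnings(as.integer(f[[4]]))
    end1 <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(start1) || is.na(end1)) abort(sprintf("%s:%d: non-integer coordinates.", path, ln))
    if (start1 < 1) abort(sprintf("%s:%d: GTF coordinates are 1-based; start < 1.", path, ln))
    if (start1 > end1) abort(sprintf("%s:%d: start > end.", path, ln))
    attrs <- f[[9]]
    gene <- stringr::str_match(attrs, 'gene_id\\s+"?([^";]+)"?')[, 2]
    if (is.na(gene)) gene <- stringr::str_match(attrs, 'gene_name\\s+"?([^";]+)"?')[, 2]
    if (is.na(gene)) abort(sprintf("%s:%d: no gene_id in GTF attributes.", path, ln))
    # 1-based closed -> 0-based half-open
    tibble(chrom = f[[1]], start = start1 - 1L, end = end1, name = gene,
           score = NA_real_, strand = f[[7]])
  })
  df <- bind_rows(rows) |>
    group_by(.data$name, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    mutate(score = NA_real_) |>
    select("chrom", "start", "end", "name", "score", "strand")
  new_genomic_intervals(df)
}

#' Read a survival table
#'
#' Tab-separated with mandatory columns `sample_id`, `time` (non-negative,
#' months) and `event` (0/1 or TRUE/FALSE); any further columns are covariates.
#'
#' @param path TSV path.
#' @return a tibble, one row per patient.
#' @export
read_survival <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("sample_id", "time", "event"), names(df))
  if (length(miss)) abort(sprintf("%s: missing column(s) %s.", path, toString(miss)))
  if (anyDuplicated(df$sample_id)) abort(sprintf("%s: duplicated sample_id.", path))
  if (any(!is.finite(df$time)) || any(df$time < 0)) abort(sprintf("%s: times must be >= 0.", path))
  df$event <- as.integer(df$event)
  if (!all(df$event %in% c(0L, 1L))) abort(sprintf("%s: event must be 0/1.", path))
  df
}

#' Read a differential-expression table
#'
#' Tab-separated with columns `gene`, `logFC`, `fdr`; genes must be unique and
#' `fdr` must lie in \[0, 1\].
#'
#' @param path TSV path.
#' @return a tibble.
#' @export
read_de_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("gene", "logFC", "fdr"), names(df))
  if (length(miss)) abort(sprintf("%s: missing column(s) %s.", path, toString(miss)))
  if (anyDuplicated(df$gene)) abort(sprintf("%s: duplicated gene in DE table.", path))
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) abort(sprintf("%s: fdr outside [0,1].", path))
  df
}
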