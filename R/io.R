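#' Exon-level count container
#'
#' Bundles an exon x sample count matrix with its exon-to-gene map and the
#' exon order within each gene (1-based along the gene). This is the input
#' currency of the differential exon usage stage and of exon atomization.
#'
#' @param counts integer matrix, exons x samples, with exon ids as rownames.
#' @param gene_of_exon character vector, one gene id per exon (same order as
#'   the rows of `counts`).
#' @param exon_order integer vector, position of each exon within its gene;
#'   must be unique within a gene.
#' @param exon_lengths optional numeric vector of exon lengths in bp.
#' @return An object of class `exon_counts`.
#' @export
exon_counts <- function(counts, gene_of_exon, exon_order,
                        exon_lengths = NULL) {
  assert_count_matrix(counts, "exon counts")
  if (length(gene_of_exon) != nrow(counts) ||
      length(exon_order) != nrow(counts)) {
    abort("`gene_of_exon` and `exon_order` must have one entry per exon row")
  }
  dup <- duplicated(paste(gene_of_exon, exon_order))
  if (any(dup)) {
    abort(sprintf("exon order not unique within gene (first offender: %s)",
                  rownames(counts)[which(dup)[1]]))
  }
  structure(
    list(counts = counts,
         gene_of_exon = setNames(as.character(gene_of_exon), rownames(counts)),
         exon_order = setNames(as.integer(exon_order), rownames(counts)),
         exon_lengths = exon_lengths),
    class = "exon_counts"
  )
}

#' @export
print.exon_counts <- function(x, ...) {
  cat(sprintf("<exon_counts> %d exons / %d genes x %d samples\n",
              nrow(x$counts), length(unique(x$gene_of_exon)),
              ncol(x$counts)))
  invisible(x)
}

#' Read a gene- or exon-level count table
#'
#' Gene-level files are TSV with a `gene_id` first column and one column per
#' sample. Exon-level files carry `gene_id`, `exon_id`, `exon_order` columns
#' before the sample columns. Entries must be non-negative integers.
#'
#' @param path file path.
#' @param level `"gene"` or `"exon"`.
#' @return A counts matrix (gene level) or an [exon_counts] object.
#' @export
read_counts <- function(path, level = c("gene", "exon")) {
  level <- match.arg(level)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_cols <- if (level == "gene") "gene_id" else
    c("gene_id", "exon_id", "exon_order")
  if (!all(meta_cols %in% names(df))) {
    abort(sprintf("%s: expected columns %s", path,
                  paste(meta_cols, collapse = ", ")))
  }
  sample_cols <- setdiff(names(df), meta_cols)
  m <- as.matrix(df[sample_cols])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "%s: non-integer or negative count at line %d, sample '%s'",
      path, bad[1, 1] + 1L, sample_cols[bad[1, 2]]))
  }
  storage.mode(m) <- "double"
  if (level == "gene") {
    if (anyDuplicated(df$gene_id)) {
      abort(sprintf("%s: duplicate gene_id '%s'", path,
                    df$gene_id[anyDuplicated(df$gene_id)]))
    }
    rownames(m) <- df$gene_id
    assert_count_matrix(m)
    m
  } else {
    if (anyDuplicated(df$exon_id)) {
      first <- df$exon_id[anyDuplicated(df$exon_id)]
      # the same exon id under two genes is an invariant violation
      genes <- unique(df$gene_id[df$exon_id == first])
      if (length(genes) > 1) {
        abort(sprintf("%s: exon '%s' maps to multiple genes (%s)",
                      path, first, paste(genes, collapse = ", ")))
      }
      abort(sprintf("%s: duplicate exon_id '%s'", path, first))
    }
    rownames(m) <- df$exon_id
    exon_counts(m, df$gene_id, df$exon_order)
  }
}

#' Write a count table as TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f))` restores the
#' object.
#'
#' @param x counts matrix or [exon_counts] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  if (inherits(x, "exon_counts")) {
    df <- data.frame(gene_id = unname(x$gene_of_exon),
                     exon_id = rownames(x$counts),
                     exon_order = unname(x$exon_order),
                     x$counts, check.names = FALSE)
  } else {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `genotype` (CC/CL/LL), `family`, `sex` and
#' optionally `tissue`.
#'
#' @param path file path.
#' @param genotypes allowed genotype levels.
#' @return A tibble, one row per sample.
#' @export
read_sample_table <- function(path, genotypes = c("CC", "CL", "LL")) {
  df <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("sample_id", "genotype", "family", "sex")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id")
  if (!all(df$genotype %in% genotypes)) {
    abort(sprintf("genotype outside {%s}", paste(genotypes, collapse = ", ")))
  }
  df$genotype <- factor(df$genotype, levels = genotypes)
  df
}

#' Read a GMT gene-set file
#'
#' Standard 3+ column dialect: term id, term name, then member gene ids.
#'
#' @param path file path.
#' @return Named list of character vectors; names are term ids, each vector
#'   carries a `term_name` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort(sprintf("GMT line with < 3 fields: %s", l))
    structure(unique(parts[-(1:2)]), term_name = parts[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Default low-expression sample threshold
#'
#' Generalises the 11-of-35 / 12-of-36 drop rule to other sample sizes by
#' scaling the 11/35 ratio and rounding up.
#'
#' @param n_samples number of samples.
#' @return Integer threshold.
#' @export
default_max_low_samples <- function(n_samples) {
  as.integer(ceiling(n_samples * 11 / 35))
}

#' Drop lowly expressed genes
#'
#' A gene is removed when it has fewer than `min_count` reads in
#' `max_low_samples` or more samples — the standard pre-filter before
#' dispersion estimation. With 35 samples the default removes genes with
#' < 10 counts in 11 or more samples; with 36, in 12 or more.
#'
#' @param counts genes x samples count matrix.
#' @param min_count count below which a sample is "low" for a gene.
#' @param max_low_samples drop a gene when at least this many samples are low.
#' @return The filtered matrix; attribute `kept` holds the logical keep mask.
#' @export
filter_low_expression <- function(counts, min_count = 10,
                                  max_low_samples = NULL) {
  assert_count_matrix(counts)
  n <- ncol(counts)
  max_low_samples <- max_low_samples %||% default_max_low_samples(n)
  if (max_low_samples > n) abort("`max_low_samples` exceeds sample count")
  n_low <- rowSums(counts < min_count)
  keep <- n_low < max_low_samples
  if (!any(keep)) warn("no genes survive the low-expression filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Restrict an exon matrix to the exons of surviving genes
#'
#' Exons are filtered by gene membership, not by their own counts: every exon
#' of a gene that passed the gene-level filter is retained.
#'
#' @param ec an [exon_counts] object.
#' @param kept_genes character vector of surviving gene ids.
#' @return A filtered [exon_counts] object.
#' @export
filter_exons_by_gene <- function(ec, kept_genes) {
  stopifnot(inherits(ec, "exon_counts"))
  keep <- ec$gene_of_exon %in% kept_genes
  exon_counts(ec$counts[keep, , drop = FALSE],
              ec$gene_of_exon[keep], ec$exon_order[keep],
              if (!is.null(ec$exon_lengths)) ec$exon_lengths[keep])
}
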