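#' Violin plot of a per-gene value across gene sets
#'
#' The connectivity / expression-level comparison figure: one violin per
#' gene category (e.g. all genes, DSG-only, DEG-only) with the median
#' marked, for a per-gene value such as kTotal or mean TPM.
#'
#' @param values named numeric vector over the gene universe.
#' @param sets named list of gene-id vectors; the full universe is added
#'   as `"all"` unless already present.
#' @param value_name axis label.
#' @return A ggplot object.
#' @export
plot_set_distributions <- function(values, sets, value_name = "kTotal") {
  if (!"all" %in% names(sets)) {
    sets <- c(list(all = names(values)), sets)
  }
  df <- purrr::imap_dfr(sets, function(ids, nm)
    tibble(set = nm, value = unname(values[ids])))
  df$set <- factor(df$set, levels = names(sets))
  ggplot2::ggplot(df, ggplot2::aes(.data$set, .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = median, geom = "point", shape = 23,
                          size = 3, fill = "white") +
    ggplot2::labs(x = NULL, y = value_name) +
    ggplot2::theme_minimal()
}

#' Module size bar chart
#'
#' @param net an `edanet_network`.
#' @return A ggplot object.
#' @export
plot_module_sizes <- function(net) {
  stopifnot(inherits(net, "edanet_network"))
  df <- net$module_table |>
    dplyr::count(.data$module, name = "n_genes")
  num <- suppressWarnings(as.integer(sub("^M", "", df$module)))
  df <- df[order(num), ]
  df$module <- factor(df$module, levels = df$module)
  ggplot2::ggplot(df, ggplot2::aes(.data$module, .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module", y = "genes") +
    ggplot2::theme_minimal()
}
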