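#' Counts-per-million normalisation
#'
#' Scales every sample column of a gene-by-sample count table so that it
#' sums to one million.
#'
#' @param counts Tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @return Tibble of the same shape with scaled columns.
#' @export
#' @examples
#' normalize_cpm(tibble::tibble(gene_id = "g1", s1 = 10))
normalize_cpm <- function(counts) {
  stopifnot("gene_id" %in% names(counts), ncol(counts) >= 2)
  samples <- setdiff(names(counts), "gene_id")
  sums <- vapply(counts[samples], sum, numeric(1))
  zero <- samples[sums == 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(zero, collapse = ", ")),
          class = "methexpr_zero_library")
  }
  counts %>% mutate(across(all_of(samples), ~ .x / sum(.x) * 1e6))
}

#' Built-in differential-expression test on a count matrix
#'
#' A transparent stand-in test for two groups of two or more samples
#' each. The fold change is computed on CPM-normalised means with a 0.5
#' pseudocount, (mean case + 0.5) / (mean control + 0.5); the p-value comes
#' from a two-sided negative-binomial score test of the group term in a
#' log-linear model with library-size offsets at a fixed, user-supplied
#' dispersion. Genes expressed in only one group are flagged
#' `exclusive_as` / `exclusive_ctrl`. Benjamini-Hochberg q-values are
#' reported as an extra column but play no role in classification, which
#' uses the raw p-value thresholds of [classify_de()].
#'
#' @param counts Tibble with `gene_id` plus integer sample columns.
#' @param groups Named character vector mapping every sample column to
#'   `"ctrl"` or `"as"` (see [simulated_groups()]).
#' @param dispersion Negative-binomial dispersion used by the score test;
#'   default 0.1.
#' @param p_cutoff,fc_up,fc_down Classification thresholds passed to
#'   [classify_de()].
#' @return An object of class `de_fit`; its `$table` is the DE tibble
#'   (`gene_id`, `fold_change`, `p_value`, `q_value`, `de_class`,
#'   `exclusivity`). Use [tidy()] / [glance()] / [autoplot()].
#' @export
de_test <- function(counts, groups, dispersion = 0.1,
                    p_cutoff = 0.005, fc_up = 1.5, fc_down = 0.6) {
  samples <- setdiff(names(counts), "gene_id")
  stopifnot(all(samples %in% names(groups)))
  grp <- unname(groups[samples])
  if (!setequal(unique(grp), c("ctrl", "as"))) {
    abort("`groups` must label samples as 'ctrl' and 'as'")
  }
  if (sum(grp == "ctrl") < 2 || sum(grp == "as") < 2) {
    abort(paste("the built-in test needs at least two samples per group;",
                "import an external DE table with read_de_table() instead"),
          class = "methexpr_design_error")
  }
  cpm <- normalize_cpm(counts)
  m_ctrl <- rowMeans(as.matrix(cpm[samples[grp == "ctrl"]]))
  m_as <- rowMeans(as.matrix(cpm[samples[grp == "as"]]))
  fc <- (m_as + 0.5) / (m_ctrl + 0.5)

  y <- as.matrix(counts[samples])
  p <- nb_score_test(y, grp == "as", dispersion)

  table <- tibble(
    gene_id = counts$gene_id,
    fold_change = fc,
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    exclusivity = case_when(m_ctrl == 0 & m_as > 0 ~ "exclusive_as",
                            m_as == 0 & m_ctrl > 0 ~ "exclusive_ctrl",
                            TRUE ~ "none")
  ) %>%
    classify_de(p_cutoff = p_cutoff, fc_up = fc_up, fc_down = fc_down)
  structure(
    list(table = table, dispersion = dispersion,
         thresholds = c(p = p_cutoff, fc_up = fc_up, fc_down = fc_down),
         n_samples = length(samples)),
    class = "de_fit"
  )
}

# Two-sided score test of the group effect in a NB log-linear model with
# library-size offsets and fixed dispersion phi (var = mu + phi mu^2).
# Efficient information for the group term accounts for the estimated
# common intercept. Returns two-sided normal p-values; all-zero genes get 1.
nb_score_test <- function(y, is_case, phi) {
  s <- colSums(y)
  s <- s / mean(s)
  x <- ifelse(is_case, 1, -1)
  tot <- rowSums(y)
  lam <- tot / sum(s)
  mu0 <- outer(lam, s)
  w <- mu0 / (1 + phi * mu0)
  resid <- (y - mu0) / (1 + phi * mu0)
  U <- drop(resid %*% x)
  j11 <- rowSums(w)
  j1x <- drop(w %*% x)
  jxx <- rowSums(w)
  info <- jxx - j1x^2 / j11
  z <- ifelse(info > 0, U / sqrt(info), 0)
  ifelse(tot > 0, 2 * pnorm(-abs(z)), 1)
}

#' Classify genes as up, down or not significant
#'
#' Strict threshold comparisons, as printed: up when p < `p_cutoff` and
#' fold change > `fc_up`; down when p < `p_cutoff` and fold change <
#' `fc_down`; otherwise ns. A gene at exactly a threshold is ns.
#'
#' @param de Tibble with `fold_change` and `p_value` columns.
#' @param p_cutoff P-value threshold; default 0.005.
#' @param fc_up Linear fold-change threshold for up; default 1.5.
#' @param fc_down Linear fold-change threshold for down; default 0.6.
#' @return The input with a `de_class` column.
#' @export
#' @examples
#' classify_de(tibble::tibble(fold_change = 2, p_value = 0.001))
classify_de <- function(de, p_cutoff = 0.005, fc_up = 1.5, fc_down = 0.6) {
  stopifnot(all(c("fold_change", "p_value") %in% names(de)))
  de %>% mutate(
    de_class = case_when(
      .data$p_value < p_cutoff & .data$fold_change > fc_up ~ "up",
      .data$p_value < p_cutoff & .data$fold_change < fc_down ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Import an externally computed DE table
#'
#' Accepts a TSV with header-mapped columns for gene, fold change (or
#' logFC) and p-value, so output of standard DE tools can be consumed
#' unchanged. A logFC column is exponentiated with the configured base
#' before the linear-scale thresholds are applied.
#'
#' @param path TSV file path.
#' @param gene_col,fc_col,logfc_col,p_col Column names in the file;
#'   exactly one of `fc_col` / `logfc_col` must be present.
#' @param logfc_base Base of the logFC column; default 2.
#' @param ... Thresholds forwarded to [classify_de()].
#' @return A `de_fit` whose table has `gene_id`, `fold_change`, `p_value`,
#'   `q_value`, `de_class`, `exclusivity` (`"none"` for imports).
#' @export
read_de_table <- function(path, gene_col = "gene", fc_col = "fold_change",
                          logfc_col = "logFC", p_col = "p_value",
                          logfc_base = 2, ...) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!gene_col %in% names(x) || !p_col %in% names(x)) {
    abort(sprintf("DE table %s lacks column '%s' or '%s'", path, gene_col, p_col))
  }
  fc <- if (fc_col %in% names(x)) {
    x[[fc_col]]
  } else if (logfc_col %in% names(x)) {
    logfc_base^x[[logfc_col]]
  } else {
    abort(sprintf("DE table %s has neither '%s' nor '%s'", path, fc_col, logfc_col))
  }
  table <- tibble(
    gene_id = as.character(x[[gene_col]]),
    fold_change = as.numeric(fc),
    p_value = as.numeric(x[[p_col]]),
    q_value = p.adjust(as.numeric(x[[p_col]]), method = "BH"),
    exclusivity = "none"
  ) %>% classify_de(...)
  structure(list(table = table, dispersion = NA_real_,
                 thresholds = NULL, n_samples = NA_integer_),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("<de_fit> %d genes: %d up, %d down\n", nrow(x$table),
              sum(x$table$de_class == "up"), sum(x$table$de_class == "down")))
  print(head(x$table))
  invisible(x)
}

#' @rdname de_test
#' @param x A `de_fit`.
#' @export
tidy.de_fit <- function(x, ...) x$table

#' @rdname de_test
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_up = sum(x$table$de_class == "up"),
    n_down = sum(x$table$de_class == "down"),
    n_exclusive_as = sum(x$table$exclusivity == "exclusive_as"),
    n_exclusive_ctrl = sum(x$table$exclusivity == "exclusive_ctrl"),
    dispersion = x$dispersion
  )
}

#' @rdname de_test
#' @param object A `de_fit`.
#' @param ... Unused.
#' @export
autoplot.de_fit <- function(object, ...) {
  d <- object$table %>%
    mutate(log2fc = log2(.data$fold_change),
           mlp = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$mlp,
                                  colour = .data$de_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (AS / control)",
                  y = "-log10 p", colour = NULL)
}

#' Write the DE table as TSV
#'
#' @param fit A `de_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(fit, path) {
  readr::write_tsv(tidy(fit), path)
  invisible(path)
}
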