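#' Build a case-normalized gene list
#'
#' @param symbols Character vector of gene symbols.
#' @param label List label.
#' @return A list with `label` and the deduplicated, case-normalized `genes`.
#' @export
gene_list <- function(symbols, label) {
  symbols <- unique(toupper(trimws(symbols)))
  symbols <- symbols[nzchar(symbols)]
  list(label = label, genes = symbols)
}

#' Read a gene list from a text file
#'
#' Accepts one-symbol-per-line text, or a two-column TSV (symbol, class) in
#' which case one list per class is returned.
#'
#' @param path File path.
#' @param label Label for a single-column file; defaults to the file name.
#' @return A single gene list, or a named list of gene lists for two-column
#'   input.
#' @export
read_gene_list <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) >= 2)) {
    sym <- vapply(parts, `[`, "", 1)
    cls <- vapply(parts, `[`, "", 2)
    return(purrr::imap(split(sym, cls), function(s, k) gene_list(s, k)))
  }
  gene_list(vapply(parts, `[`, "", 1),
            label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Overlap statistics between two gene lists
#'
#' @param list_a,list_b Gene lists (see [gene_list()]); both non-empty.
#' @return A one-row tibble: `label_a`, `label_b`, `n_a`, `n_b`, `n_overlap`,
#'   `pct_of_a`, `pct_of_b` (unrounded), and the integer-rounded
#'   `pct_of_a_rounded`, `pct_of_b_rounded` used for reporting.
#' @export
overlap_stats <- function(list_a, list_b) {
  if (length(list_a$genes) == 0 || length(list_b$genes) == 0) {
    abort("overlap_stats requires two non-empty gene lists")
  }
  n <- length(intersect(list_a$genes, list_b$genes))
  tibble(
    label_a = list_a$label, label_b = list_b$label,
    n_a = length(list_a$genes), n_b = length(list_b$genes),
    n_overlap = n,
    pct_of_a = 100 * n / length(list_a$genes),
    pct_of_b = 100 * n / length(list_b$genes),
    pct_of_a_rounded = round(100 * n / length(list_a$genes)),
    pct_of_b_rounded = round(100 * n / length(list_b$genes))
  )
}

#' Overlap report between classification classes and external gene lists
#'
#' One row per (class, external list) pair, plus one row per requested union
#' of external lists. Symbols present in several external lists are counted
#' in each (external lists may overlap); this is logged once.
#'
#' @param classes `xcr_classification` tibble (gene symbols are taken from
#'   its `name` column).
#' @param external_lists A list of gene lists.
#' @param statuses Classification statuses to report (default reactivated and
#'   escapee).
#' @param unions Optional named list; each element is a character vector of
#'   external-list labels whose union forms an extra comparison row.
#' @return A tibble of overlap rows (see [overlap_stats()]).
#' @export
multi_overlap_report <- function(classes, external_lists,
                                 statuses = c("reactivated", "escapee"),
                                 unions = NULL) {
  cl <- as_tibble(classes)
  ours <- purrr::map(statuses, function(s) {
    gene_list(cl$name[cl$status == s], s)
  })
  all_ext <- unlist(purrr::map(external_lists, "genes"))
  if (anyDuplicated(all_ext) > 0) {
    inform("some symbols appear in multiple external lists; counted in each")
  }
  targets <- external_lists
  if (!is.null(unions)) {
    for (nm in names(unions)) {
      members <- purrr::keep(external_lists,
                             function(l) l$label %in% unions[[nm]])
      targets <- c(targets,
                   list(gene_list(unlist(purrr::map(members, "genes")), nm)))
    }
  }
  purrr::map(ours, function(o) {
    purrr::map(targets, function(t) overlap_stats(o, t)) %>% bind_rows()
  }) %>% bind_rows()
}

#' Upper-tail hypergeometric enrichment of a gene-list overlap
#'
#' Probability of observing at least `n_overlap` common genes when `size_a`
#' and `size_b` genes are drawn from a universe of `universe_size`.
#'
#' @param n_overlap Observed overlap.
#' @param size_a,size_b List sizes.
#' @param universe_size Universe size.
#' @return The upper-tail p value `P(X >= n_overlap)`.
#' @export
hypergeometric_enrichment <- function(n_overlap, size_a, size_b,
                                      universe_size) {
  if (n_overlap > min(size_a, size_b) || max(size_a, size_b) > universe_size ||
      n_overlap < 0) {
    abort("inconsistent sizes: need n_overlap <= min(|A|, |B|) <= universe")
  }
  phyper(n_overlap - 1, size_b, universe_size - size_b, size_a,
         lower.tail = FALSE)
}
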