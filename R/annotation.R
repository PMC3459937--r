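# Function-group annotation of hit genes from a user-supplied term-mapping
# table, with the "first suitable group" priority rule, and whole-percent
# summaries that always total 100 via largest-remainder rounding.

#' Function groups in priority order
#'
#' A gene carrying several group labels is assigned the first of:
#' gene_expression, tumorigenesis_angiogenesis, cell_signaling, cell_cycle,
#' other, unknown.
#'
#' @return Character vector of group names, highest priority first.
#' @export
function_groups <- function() {
  c("gene_expression", "tumorigenesis_angiogenesis", "cell_signaling",
    "cell_cycle", "other", "unknown")
}

# Accept a long data.frame (gene_symbol, group) or a named list of
# character vectors; return the named-list form.
as_term_map <- function(term_map) {
  if (is.data.frame(term_map)) {
    stopifnot(all(c("gene_symbol", "group") %in% names(term_map)))
    term_map <- split(as.character(term_map$group),
                      as.character(term_map$gene_symbol))
  }
  stopifnot(is.list(term_map))
  bad <- setdiff(unique(unlist(term_map, use.names = FALSE)),
                 function_groups())
  if (length(bad) > 0L) {
    stop("unknown function group label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(function_groups(), collapse = ", "),
         call. = FALSE)
  }
  term_map
}

#' Assign genes to function groups
#'
#' Each gene gets the highest-priority group present in its label set;
#' genes absent from the map, or mapped to an empty set, are `"unknown"`.
#'
#' @param gene_symbol Character vector of genes.
#' @param term_map Mapping from gene to group labels: either a long
#'   data.frame with columns `gene_symbol` and `group`, or a named list of
#'   character vectors.
#' @return Character vector of assigned groups, one per gene.
#' @export
assign_group <- function(gene_symbol, term_map) {
  term_map <- as_term_map(term_map)
  groups <- function_groups()
  vapply(gene_symbol, function(g) {
    labels <- term_map[[g]]
    if (is.null(labels) || length(labels) == 0L) return("unknown")
    groups[min(match(labels, groups))]
  }, character(1), USE.NAMES = FALSE)
}

# Whole-percent rounding that preserves the 100 total: floor everything,
# then hand the leftover points to the largest remainders.
largest_remainder_percent <- function(counts) {
  if (sum(counts) == 0L) return(rep(0L, length(counts)))
  exact <- 100 * counts / sum(counts)
  base <- floor(exact)
  leftover <- 100L - sum(base)
  order_rem <- order(exact - base, decreasing = TRUE)
  base[order_rem[seq_len(leftover)]] <- base[order_rem[seq_len(leftover)]] + 1L
  as.integer(base)
}

#' Function-group composition of a hit list
#'
#' @param hit_genes Character vector of hit gene symbols (nonempty).
#' @param term_map See [assign_group()].
#' @return A tibble with `group`, `n` and whole-number `percent` columns;
#'   percentages sum to exactly 100.
#' @export
group_summary <- function(hit_genes, term_map) {
  if (length(hit_genes) == 0L) stop("hit list is empty", call. = FALSE)
  assigned <- assign_group(hit_genes, term_map)
  counts <- table(factor(assigned, levels = function_groups()))
  tibble::tibble(
    group = names(counts),
    n = as.integer(counts),
    percent = largest_remainder_percent(as.integer(counts))
  )
}
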