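#' Per-term 2x2 contingency tables between two gene groups
#'
#' For every GO term annotated to at least one gene in each group, counts
#' `a` = high-group genes with the term, `b` = without, `c` = void-group genes
#' with the term, `d` = without. Terms detected in only one group are excluded
#' (the both-groups rule); a gene contributes once per term regardless of how
#' many annotation lines it has.
#'
#' @param high,void Disjoint, non-empty character vectors of gene ids.
#' @param annotations Named list gene id -> character vector of GO ids, as
#'   from [read_go_annotations()].
#' @return Data frame with columns `term`, `a`, `b`, `c`, `d`.
#' @export
build_contingencies <- function(high, void, annotations) {
  high <- unique(high); void <- unique(void)
  if (length(high) == 0L || length(void) == 0L)
    stop("both gene groups must be non-empty")
  if (length(intersect(high, void)))
    stop("gene groups overlap: ", paste(utils::head(intersect(high, void), 3),
                                        collapse = ", "))
  terms_of <- function(ids) {
    ann <- annotations[intersect(ids, names(annotations))]
    gene <- rep(names(ann), lengths(ann))
    data.frame(gene = gene, term = unlist(ann, use.names = FALSE))
  }
  th <- terms_of(high); tv <- terms_of(void)
  if (nrow(th) == 0L || nrow(tv) == 0L)
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0)))
  shared <- sort(intersect(unique(th$term), unique(tv$term)))
  if (length(shared) == 0L)
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0)))
  a <- as.integer(table(factor(th$term, levels = shared)))
  cc <- as.integer(table(factor(tv$term, levels = shared)))
  data.frame(term = shared, a = a, b = length(high) - a,
             c = cc, d = length(void) - cc)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' The two-sided p is the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed the observed
#' table's (to within relative tolerance 1e-7), as computed by
#' [stats::fisher.test()].
#'
#' @param a,b,c,d Cell counts (term-positive / term-negative in each group).
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Compare GO-term frequencies between the high and void groups
#'
#' For each term present in both groups: its per-group frequencies (fraction
#' of group genes carrying the term), the enrichment ratio
#' `freq_high / freq_void`, the two-sided Fisher exact p-value, a
#' Benjamini-Hochberg adjusted q (reported for reference; selection uses the
#' raw asymmetric cut-offs), a direction, and whether the term is selected:
#' high-enriched terms at `p <= p_high`, void-enriched terms at `p <= p_void`.
#'
#' @inheritParams build_contingencies
#' @param p_high Raw p cut-off for high-enriched terms (default 0.01).
#' @param p_void Raw p cut-off for void-enriched terms (default 0.05).
#' @return A `go_comparison` data frame with columns `term`, `a`..`d`,
#'   `freq_high`, `freq_void`, `enrichment_ratio`, `p_value`, `bh_q`,
#'   `direction` (high-enriched / void-enriched / equal), `selected`.
#' @export
compare_go_terms <- function(high, void, annotations,
                             p_high = 0.01, p_void = 0.05) {
  ct <- build_contingencies(high, void, annotations)
  if (nrow(ct) == 0L) {
    out <- cbind(ct, freq_high = numeric(0), freq_void = numeric(0),
                 enrichment_ratio = numeric(0), p_value = numeric(0),
                 bh_q = numeric(0), direction = character(0),
                 selected = logical(0))
    class(out) <- c("go_comparison", "data.frame")
    return(out)
  }
  ct$freq_high <- ct$a / (ct$a + ct$b)
  ct$freq_void <- ct$c / (ct$c + ct$d)
  ct$enrichment_ratio <- ct$freq_high / ct$freq_void
  ct$p_value <- mapply(fisher_exact_p, ct$a, ct$b, ct$c, ct$d)
  ct$bh_q <- stats::p.adjust(ct$p_value, method = "BH")
  ct$direction <- ifelse(ct$enrichment_ratio > 1, "high-enriched",
                         ifelse(ct$enrichment_ratio < 1, "void-enriched",
                                "equal"))
  ct$selected <- (ct$direction == "high-enriched" & ct$p_value <= p_high) |
    (ct$direction == "void-enriched" & ct$p_value <= p_void)
  class(ct) <- c("go_comparison", "data.frame")
  attr(ct, "p_high") <- p_high
  attr(ct, "p_void") <- p_void
  ct
}

#' Select significantly different terms, per direction
#'
#' Splits a [compare_go_terms()] table into the high-enriched list (terms more
#' frequent among hydroxymethylated genes, `p <= p_high`) and the
#' void-enriched list (`p <= p_void`), each sorted by enrichment ratio
#' descending — the ordering used for treemap-style area scaling, where areas
#' are proportional to the relative increase in frequency.
#'
#' @param results A `go_comparison` data frame.
#' @param p_high,p_void Raw p cut-offs (defaults 0.01 and 0.05).
#' @return List with elements `high` and `void`, each a data frame.
#' @export
select_terms <- function(results, p_high = 0.01, p_void = 0.05) {
  stopifnot(inherits(results, "data.frame"))
  hi <- results[results$direction == "high-enriched" &
                  results$p_value <= p_high, , drop = FALSE]
  vo <- results[results$direction == "void-enriched" &
                  results$p_value <= p_void, , drop = FALSE]
  list(high = hi[order(-hi$enrichment_ratio, hi$term), , drop = FALSE],
       void = vo[order(-vo$enrichment_ratio, vo$term), , drop = FALSE])
}

#' @export
print.go_comparison <- function(x, ...) {
  cat("GO-term frequency comparison:", nrow(x), "terms detected in both groups;",
      sum(x$selected), "selected\n")
  print.data.frame(utils::head(x[order(x$p_value), ], 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}
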