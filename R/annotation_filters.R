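# Annotation hygiene: transposon-gene flagging by Pfam-description term
# majority, removal of genes with neither external support nor functional
# annotation, repeat-library relabeling by classification probability, and
# organelle pseudogene flagging by alignment-length fraction.

#' Default transposon-related description terms
#'
#' Matching is case-insensitive substring matching on the domain description.
#' @return character vector of terms.
#' @export
transposon_terms <- function() {
  c("transcriptase", "transposase", "gag", "env", "transposon",
    "repetitive element", "RNA-directed DNA polymerase", "pol protein",
    "non-LTR retrotransposon", "mobile element", "retroelement",
    "retrovirus", "Retroviral", "group-specific antigen")
}

#' Flag putative transposon genes by domain-description term majority
#'
#' A domain matches when its description contains any term
#' (case-insensitive substring). A gene is flagged when strictly more than
#' half of its domains match; genes without domains are never flagged.
#'
#' @param domains data.frame with `gene_id` and `description` (one row per
#'   domain occurrence; `accession` is ignored by the rule).
#' @param terms term list, default [transposon_terms()].
#' @return data.frame per gene: `gene_id`, `n_domains`, `n_matched`,
#'   `flagged`.
#' @export
flag_transposon_genes <- function(domains, terms = transposon_terms()) {
  stopifnot(all(c("gene_id", "description") %in% names(domains)),
            length(terms) > 0)
  lterms <- tolower(terms)
  desc <- tolower(domains$description)
  matched <- Reduce(`|`, lapply(lterms, function(tm)
    grepl(tm, desc, fixed = TRUE)), rep(FALSE, length(desc)))
  n_dom <- tapply(rep(1L, nrow(domains)), domains$gene_id, sum)
  n_hit <- tapply(as.integer(matched), domains$gene_id, sum)
  ids <- names(n_dom)
  data.frame(gene_id = ids,
             n_domains = as.integer(n_dom),
             n_matched = as.integer(n_hit[ids]),
             flagged = as.integer(n_hit[ids]) / as.integer(n_dom) > 0.5,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove genes lacking both external support and functional annotation
#'
#' A gene is removed only when it has neither external evidence (RNA-seq or
#' protein-alignment support) nor a functional annotation — the rule is a
#' conjunction, so either kind of evidence retains the gene.
#'
#' @param genes data.frame with logical columns `has_external_support` and
#'   `has_functional_annotation`.
#' @return the kept rows of `genes`.
#' @export
remove_unsupported_genes <- function(genes) {
  stopifnot(all(c("has_external_support", "has_functional_annotation") %in%
                  names(genes)))
  drop <- !genes$has_external_support & !genes$has_functional_annotation
  genes[!drop, , drop = FALSE]
}

#' Relabel a repeat library by classification probability
#'
#' An entry keeps its raw label when the larger of its Class I
#' (retrotransposon) and Class II (DNA transposon) classification
#' probabilities is at least 0.5; below that the entry becomes
#' `"unclassified"`. Entry count and order are preserved.
#'
#' @param entries data.frame with `raw_label`, `prob_class1`, `prob_class2`.
#' @return `entries` with an added `final_label` column.
#' @export
relabel_te_library <- function(entries) {
  p1 <- entries$prob_class1
  p2 <- entries$prob_class2
  if (anyNA(c(p1, p2)) || any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) {
    stop("classification probabilities must lie in [0, 1]")
  }
  entries$final_label <- ifelse(pmax(p1, p2) < 0.5, "unclassified",
                                entries$raw_label)
  entries
}

#' Build per-gene alignment-length profiles from a hit table
#'
#' For each gene, hits are grouped by subject genus; within each genus the
#' mean percent alignment length (relative to the query gene) is taken over
#' at most `max_hits_per_gene` top hits, and the profile records the mean of
#' those per-genus means plus the overall maximum.
#'
#' @param hits data.frame with `gene_id`, `genus`, `pct_len` (percent of the
#'   query length aligned; may exceed 100 for gapped alignments) and
#'   optionally `rank` for top-hit selection (lower is better).
#' @param max_hits_per_gene top hits retained per gene.
#' @return data.frame: `gene_id`, `mean_of_means`, `max_pct_len`, `n_hits`.
#' @export
build_gene_alignment_profiles <- function(hits, max_hits_per_gene = 20L) {
  stopifnot(all(c("gene_id", "genus", "pct_len") %in% names(hits)))
  out <- lapply(split(hits, hits$gene_id), function(h) {
    if (!is.null(h$rank)) h <- h[order(h$rank), , drop = FALSE]
    h <- utils::head(h, max_hits_per_gene)
    genus_means <- tapply(h$pct_len, h$genus, mean)
    data.frame(gene_id = h$gene_id[[1L]],
               mean_of_means = mean(genus_means),
               max_pct_len = max(h$pct_len),
               n_hits = nrow(h), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag pseudogene candidates by alignment-length fraction
#'
#' A gene is flagged when its mean-of-means or its maximum percent alignment
#' length falls below `threshold` (default: either below 75%). Genes without
#' hits are flagged with the distinct reason `no_hits`. The cutoff and the
#' OR/AND sense are deliberately configurable: truncation thresholds for
#' calling pseudogenes are a curation convention, not a biological constant.
#'
#' @param profiles result of [build_gene_alignment_profiles()]; genes with
#'   zero hits may be included with `n_hits = 0` and `NA` statistics.
#' @param threshold percent alignment-length cutoff.
#' @param rule `"or"` flags when either statistic is below the threshold,
#'   `"and"` only when both are.
#' @return data.frame: `gene_id`, `flagged`, `reason` (`mean`, `max`,
#'   `mean+max`, `no_hits` or `""`).
#' @export
flag_pseudogenes <- function(profiles, threshold = 75,
                             rule = c("or", "and")) {
  rule <- match.arg(rule)
  no_hits <- is.na(profiles$mean_of_means) | profiles$n_hits == 0
  low_mean <- !no_hits & profiles$mean_of_means < threshold
  low_max <- !no_hits & profiles$max_pct_len < threshold
  flagged <- if (rule == "or") low_mean | low_max else low_mean & low_max
  reason <- rep("", nrow(profiles))
  reason[flagged & low_mean & !low_max] <- "mean"
  reason[flagged & !low_mean & low_max] <- "max"
  reason[flagged & low_mean & low_max] <- "mean+max"
  reason[no_hits] <- "no_hits"
  data.frame(gene_id = profiles$gene_id,
             flagged = flagged | no_hits, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}
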