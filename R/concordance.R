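#' Cross-tabulate male versus female cluster labels
#'
#' Counts, for every pair of cluster labels (j, k), the genes whose male
#' profile was assigned to cluster j and female profile to cluster k. Only
#' genes labeled in both sexes contribute. The diagonal holds genes with
#' concordant (common) temporal profiles, the off-diagonal genes with
#' discordant profiles.
#'
#' @param male_labels,female_labels named integer vectors (names = gene ids,
#'   values = cluster labels in 1..K).
#' @param K number of clusters.
#' @return A K x K integer matrix; rows male clusters, columns female
#'   clusters.
#' @export
cross_tabulate <- function(male_labels, female_labels, K) {
  if (is.null(names(male_labels)) || is.null(names(female_labels)))
    fail("label maps must be named by gene id")
  all_labels <- c(male_labels, female_labels)
  if (any(all_labels < 1L | all_labels > K))
    fail("cluster label %d outside 1..%d", all_labels[all_labels < 1L | all_labels > K][1L], K)
  genes <- intersect(names(male_labels), names(female_labels))
  tab <- matrix(0L, K, K,
                dimnames = list(male = as.character(seq_len(K)),
                                female = as.character(seq_len(K))))
  if (length(genes) > 0L) {
    t0 <- table(factor(male_labels[genes], levels = seq_len(K)),
                factor(female_labels[genes], levels = seq_len(K)))
    tab[] <- as.integer(t0)
  }
  tab
}

#' Summarize a cluster cross-tabulation
#'
#' @param tab K x K non-negative integer matrix (male rows, female columns).
#' @return A list with \code{diagonal_total} (genes in the same cluster in
#'   both sexes), \code{offdiagonal_total}, \code{grand_total} and a
#'   \code{per_cell(j, k)} accessor.
#' @export
summarize_crosstab <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) fail("cross-tabulation must be square")
  if (any(tab < 0) || any(tab != round(tab)))
    fail("cross-tabulation must contain non-negative integers")
  diagonal <- sum(diag(tab))
  total <- sum(tab)
  list(diagonal_total = as.integer(diagonal),
       offdiagonal_total = as.integer(total - diagonal),
       grand_total = as.integer(total),
       per_cell = function(j, k) as.integer(tab[j, k]))
}

#' Partition genes into concordant and discordant sets
#'
#' A gene is concordant ("common") when its male and female profiles carry
#' the same cluster label, discordant otherwise. Genes labeled in only one
#' sex are excluded and reported.
#'
#' @param assignments data.frame from [assign_labels()] with \code{gene_id},
#'   \code{sex} (\code{"M"}/\code{"F"}) and \code{label}; or a list with
#'   \code{male}/\code{female} named label vectors.
#' @return A list of class \code{"concordance_partition"} with
#'   \code{common_genes}, \code{discordant_genes}, \code{labels} (data.frame
#'   gene_id/male_label/female_label) and \code{excluded} (gene ids labeled
#'   in one sex only).
#' @export
partition_genes <- function(assignments) {
  if (is.data.frame(assignments)) {
    male <- assignments$label[assignments$sex == "M"]
    names(male) <- assignments$gene_id[assignments$sex == "M"]
    female <- assignments$label[assignments$sex == "F"]
    names(female) <- assignments$gene_id[assignments$sex == "F"]
  } else {
    male <- assignments$male
    female <- assignments$female
  }
  genes <- intersect(names(male), names(female))
  excluded <- union(setdiff(names(male), genes), setdiff(names(female), genes))
  labels <- data.frame(gene_id = genes,
                       male_label = as.integer(male[genes]),
                       female_label = as.integer(female[genes]),
                       stringsAsFactors = FALSE)
  common <- labels$gene_id[labels$male_label == labels$female_label]
  structure(list(common_genes = common,
                 discordant_genes = setdiff(labels$gene_id, common),
                 labels = labels, excluded = excluded),
            class = "concordance_partition")
}

#' @export
print.concordance_partition <- function(x, ...) {
  n <- nrow(x$labels)
  cat(sprintf("concordance partition: %d genes (%d common, %d discordant)\n",
              n, length(x$common_genes), length(x$discordant_genes)))
  if (length(x$excluded) > 0L)
    cat(sprintf("  %d genes labeled in one sex only were excluded\n",
                length(x$excluded)))
  invisible(x)
}

#' Summarize gene sets against a concordance partition
#'
#' For each gene set, counts members on the common and discordant sides and
#' reports percentages of the set's dually-labeled members, rounded to the
#' nearest integer percent for display (exact fractions are retained).
#'
#' @param partition a \code{concordance_partition}.
#' @param sets named list of gene-id vectors (see [read_gene_sets()]).
#' @return A data.frame with one row per set: \code{set_name}, \code{total},
#'   \code{n_common}, \code{n_discordant}, \code{pct_common},
#'   \code{pct_discordant} (integer percents), \code{frac_common},
#'   \code{frac_discordant} (exact).
#' @export
gene_set_summary <- function(partition, sets) {
  stopifnot(inherits(partition, "concordance_partition"))
  rows <- lapply(names(sets), function(nm) {
    n_common <- length(intersect(sets[[nm]], partition$common_genes))
    n_disc <- length(intersect(sets[[nm]], partition$discordant_genes))
    total <- n_common + n_disc
    frac_common <- if (total > 0) n_common / total else 0
    data.frame(set_name = nm, total = total,
               n_common = n_common, n_discordant = n_disc,
               pct_common = if (total > 0) as.integer(round(100 * frac_common)) else 0L,
               pct_discordant = if (total > 0)
                 as.integer(round(100 * (1 - frac_common))) else 0L,
               frac_common = frac_common,
               frac_discordant = if (total > 0) 1 - frac_common else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-set overrepresentation test
#'
#' One-sided upper-tail hypergeometric test (the conventional "modified
#' Fisher exact" direction used by enrichment tools) of each set's overlap
#' with a query gene list against a background universe. Sets are
#' intersected with the background before testing; Benjamini-Hochberg
#' q-values are computed across sets.
#'
#' @param query character vector of gene ids (must be a subset of
#'   \code{background}).
#' @param sets named list of gene-id vectors.
#' @param background character vector: the gene universe.
#' @return A data.frame with \code{set_name}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{background_size},
#'   \code{p_value}, \code{q_value}, sorted by p-value.
#' @export
overrepresentation_test <- function(query, sets, background) {
  background <- unique(background)
  if (length(background) == 0L) fail("background universe is empty")
  query <- unique(query)
  if (!all(query %in% background))
    fail("query gene '%s' is not in the background", setdiff(query, background)[1L])
  N <- length(background)
  n_query <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), background)
    m <- length(set)
    overlap <- length(intersect(set, query))
    # P(X >= overlap), X ~ Hypergeometric(m set genes, N - m others, n_query draws)
    p <- stats::phyper(overlap - 1L, m, N - m, n_query, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = overlap, set_size = m,
               query_size = n_query, background_size = N,
               p_value = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
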