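# Step-one robust screening: two-test gene filtering, pathway expansion and
# hypergeometric enrichment, plus probe-to-gene collapsing.

#' Robust gene-wise screening with a two-test rule
#'
#' Keeps genes whose two-sample t-test p-value is at most `t_alpha`; among the
#' removed genes, any with a Wilcoxon rank-sum p-value below `w_alpha` is
#' moved back (rescued), so that heavy-tailed shifts missed by the t-test are
#' not lost.  Genes in `must_include` (e.g. known disease genes) are always
#' retained.
#'
#' @param X n x p expression matrix with gene ids as column names.
#' @param y 0/1 phenotype vector.
#' @param t_alpha t-test retention level (default 0.01).
#' @param w_alpha Wilcoxon rescue level (default 0.05).
#' @param must_include optional gene ids to force-keep.
#' @return list with `kept` (gene ids) and a `report` data frame
#'   (gene, t_p, w_p, kept, reason).
#' @export
gene_wise_filter <- function(X, y, t_alpha = 0.01, w_alpha = 0.05,
                             must_include = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("each phenotype class needs at least 2 samples")
  }
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(X)))
  g0 <- y == 0L
  t_p <- apply(X, 2L, function(x) {
    if (sd(x[g0]) == 0 && sd(x[!g0]) == 0) return(1)
    t.test(x[!g0], x[g0], var.equal = TRUE)$p.value
  })
  keep <- t_p <= t_alpha
  w_p <- rep(NA_real_, ncol(X))
  if (any(!keep)) {
    w_p[!keep] <- apply(X[, !keep, drop = FALSE], 2L, function(x)
      suppressWarnings(wilcox.test(x[!g0], x[g0], exact = FALSE)$p.value))
  }
  rescued <- !keep & !is.na(w_p) & w_p < w_alpha
  forced <- ids %in% must_include & !(keep | rescued)
  reason <- ifelse(keep, "t-test",
                   ifelse(rescued, "wilcoxon-rescue",
                          ifelse(forced, "must-include", "removed")))
  kept <- keep | rescued | forced
  list(kept = ids[kept],
       report = data.frame(gene = ids, t_p = t_p, w_p = w_p, kept = kept,
                           reason = reason, row.names = NULL))
}

#' Expand seed genes to their pathways and the grand signature set
#'
#' @param seed_genes gene ids retained by screening.
#' @param S membership matrix (genes x pathways, with dimnames) or a
#'   [pathway_structure()].
#' @return list with `pathways` (ids containing >= 1 seed gene), `genes` (the
#'   union of those pathways' members), and `orphans` (seed genes in no
#'   pathway, retained separately).
#' @export
pathway_expansion <- function(seed_genes, S) {
  if (inherits(S, "pathway_structure")) S <- S$S
  seed_in <- intersect(seed_genes, rownames(S))
  hit <- if (length(seed_in)) colSums(S[seed_in, , drop = FALSE] == 1L) > 0 else
    rep(FALSE, ncol(S))
  pathways <- colnames(S)[hit]
  genes <- if (any(hit)) rownames(S)[rowSums(S[, hit, drop = FALSE]) > 0] else
    character(0)
  orphans <- setdiff(seed_genes, rownames(S)[rowSums(S) > 0])
  list(pathways = pathways, genes = genes, orphans = orphans)
}

#' Hypergeometric gene-set enrichment
#'
#' For each pathway the p-value is `P(H >= x)` for
#' `H ~ Hypergeometric(N, K, n)` with `N` the universe size, `K` the pathway
#' size, `n` the seed-set size and `x` the observed overlap (network topology
#' is ignored).
#'
#' @param seed_genes character vector of seed gene ids.
#' @param pathways named list of pathway member id vectors, or a membership
#'   matrix / [pathway_structure()].
#' @param universe character vector of all assayed gene ids.
#' @param cutoff retention level on the enrichment p-value (default 0.05).
#' @return list with `table` (pathway, overlap, size, p) and `kept`
#'   (pathway ids with `p <= cutoff`).
#' @export
hypergeometric_enrichment <- function(seed_genes, pathways, universe,
                                      cutoff = 0.05) {
  if (inherits(pathways, "pathway_structure")) pathways <- pathways$S
  if (is.matrix(pathways)) {
    S <- pathways
    pathways <- lapply(seq_len(ncol(S)), function(k) rownames(S)[S[, k] == 1L])
    names(pathways) <- colnames(S)
  }
  N <- length(unique(universe))
  seed <- intersect(unique(seed_genes), universe)
  n <- length(seed)
  tab <- do.call(rbind, lapply(names(pathways), function(id) {
    members <- intersect(unique(pathways[[id]]), universe)
    K <- length(members)
    x <- length(intersect(members, seed))
    if (x > min(K, n)) stop("overlap exceeds min(pathway size, seed size)")
    p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = id, overlap = x, size = K, p = p)
  }))
  rownames(tab) <- NULL
  list(table = tab, kept = tab$pathway[tab$p <= cutoff])
}

#' Collapse probe sets to one representative probe per gene
#'
#' When several probes map to one gene, the probe with the smallest screening
#' p-value represents it; ties break by lexicographic probe id.
#'
#' @param probe_p named numeric vector of probe-level p-values.
#' @param probe2gene named character vector mapping probe id to gene id
#'   (probes mapping to no gene are dropped).
#' @return named character vector: gene id -> chosen probe id.
#' @export
collapse_probes <- function(probe_p, probe2gene) {
  probes <- intersect(names(probe_p), names(probe2gene))
  df <- data.frame(probe = probes, gene = unname(probe2gene[probes]),
                   p = unname(probe_p[probes]), stringsAsFactors = FALSE)
  df <- df[order(df$gene, df$p, df$probe), ]
  df <- df[!duplicated(df$gene), ]
  setNames(df$probe, df$gene)
}
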