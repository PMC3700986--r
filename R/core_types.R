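# Shared data model: standardized expression, pathway structure, selection
# states, and the configuration-validity rules.

#' Standardize an expression matrix gene-wise
#'
#' Centers and scales every gene (column) to mean zero and unit variance,
#' preserving gene and sample identifiers.
#'
#' @param raw numeric samples x genes matrix.
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `raw` (generated as `g1..gp` / `s1..sn` when absent).
#' @return numeric matrix of the same shape with columns standardized
#'   (variance uses the `n - 1` denominator) and dimnames set.
#' @examples
#' standardize_expression(cbind(a = c(1, 2, 3), b = c(4, 0, 2)))
#' @export
standardize_expression <- function(raw, gene_ids = NULL, sample_ids = NULL) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) stop("need at least 2 samples to standardize")
  if (anyNA(raw)) stop("expression matrix contains missing values")
  if (is.null(gene_ids)) gene_ids <- colnames(raw)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(raw)))
  if (is.null(sample_ids)) sample_ids <- rownames(raw)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(raw)))
  sds <- apply(raw, 2L, sd)
  if (any(sds == 0)) {
    stop("constant gene(s): ", paste(gene_ids[sds == 0], collapse = ", "))
  }
  out <- scale(raw)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  dimnames(out) <- list(sample_ids, gene_ids)
  out
}

#' Assemble a pathway structure (membership plus gene network)
#'
#' Bundles the p x K 0/1 pathway membership matrix `S` and the p x p symmetric
#' 0/1 gene-gene adjacency `R`.  Network edges between genes that never share a
#' pathway are dropped with a warning (public networks and gene-set collections
#' are routinely inconsistent); self-loops are removed and the adjacency is
#' symmetrized.
#'
#' @param membership p x K 0/1 matrix, or a named list of gene-id vectors
#'   (one element per pathway).
#' @param adjacency optional p x p 0/1 matrix; `NULL` means no edges.
#' @param gene_ids,pathway_ids identifiers; taken from dimnames when missing.
#' @return object of class `pathway_structure` with elements `S`, `R`,
#'   `gene_ids`, `pathway_ids`.
#' @export
pathway_structure <- function(membership, adjacency = NULL, gene_ids = NULL,
                              pathway_ids = NULL) {
  if (is.list(membership)) {
    if (is.null(pathway_ids)) pathway_ids <- names(membership)
    if (is.null(gene_ids)) gene_ids <- unique(unlist(membership))
    S <- matrix(0L, length(gene_ids), length(membership),
                dimnames = list(gene_ids, pathway_ids))
    for (k in seq_along(membership)) {
      g <- intersect(membership[[k]], gene_ids)
      S[g, k] <- 1L
    }
  } else {
    S <- as.matrix(membership)
    storage.mode(S) <- "integer"
    if (is.null(gene_ids)) gene_ids <- rownames(S)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(S)))
    if (is.null(pathway_ids)) pathway_ids <- colnames(S)
    if (is.null(pathway_ids)) pathway_ids <- paste0("pw", seq_len(ncol(S)))
    dimnames(S) <- list(gene_ids, pathway_ids)
  }
  if (any(colSums(S) == 0L)) {
    stop("empty pathway(s): ", paste(pathway_ids[colSums(S) == 0L], collapse = ", "))
  }
  p <- nrow(S)
  if (is.null(adjacency)) {
    R <- matrix(0L, p, p, dimnames = list(gene_ids, gene_ids))
  } else {
    R <- as.matrix(adjacency)
    storage.mode(R) <- "integer"
    if (!all(dim(R) == p)) stop("adjacency must be ", p, " x ", p)
    R <- pmax(R, t(R))         # symmetrize
    diag(R) <- 0L
    share <- (S %*% t(S)) > 0  # genes sharing >= 1 pathway
    bad <- R == 1L & !share
    if (any(bad)) {
      warning(sum(bad) / 2, " network edge(s) between genes sharing no pathway dropped")
      R[bad] <- 0L
    }
    dimnames(R) <- list(gene_ids, gene_ids)
  }
  structure(list(S = S, R = R, gene_ids = gene_ids, pathway_ids = pathway_ids),
            class = "pathway_structure")
}

#' @export
print.pathway_structure <- function(x, ...) {
  cat("pathway_structure:", nrow(x$S), "genes,", ncol(x$S), "pathways,",
      sum(x$R) / 2, "network edges\n")
  invisible(x)
}

#' Construct a selection state
#'
#' @param theta length-K 0/1 pathway indicator vector.
#' @param gamma length-p 0/1 gene indicator vector.
#' @return object of class `selection_state`.
#' @export
selection_state <- function(theta, gamma) {
  theta <- as.integer(theta)
  gamma <- as.integer(gamma)
  if (!all(theta %in% 0:1) || !all(gamma %in% 0:1)) {
    stop("indicators must be 0/1")
  }
  structure(list(theta = theta, gamma = gamma), class = "selection_state")
}

#' Check the validity constraints of a selection state
#'
#' A configuration is valid iff (a) every selected pathway contains at least
#' one selected gene, (b) every selected gene belongs to at least one selected
#' pathway, and (c) no two selected pathways have identical selected-gene
#' sets.  Invalid configurations receive zero prior mass.
#'
#' @param state a [selection_state()].
#' @param S p x K membership matrix or a `pathway_structure`.
#' @return list with `valid` (logical) and `code` (`NA` or the first violated
#'   rule, one of `"a"`, `"b"`, `"c"`).
#' @export
is_valid_configuration <- function(state, S) {
  if (inherits(S, "pathway_structure")) S <- S$S
  S <- as.matrix(S)
  theta <- state$theta
  gamma <- state$gamma
  stopifnot(length(theta) == ncol(S), length(gamma) == nrow(S))
  sel_pw <- which(theta == 1L)
  sel_sets <- lapply(sel_pw, function(k) which(S[, k] == 1L & gamma == 1L))
  if (any(lengths(sel_sets) == 0L)) {
    return(list(valid = FALSE, code = "a"))
  }
  covered <- if (length(sel_pw)) rowSums(S[, sel_pw, drop = FALSE]) > 0 else
    rep(FALSE, nrow(S))
  if (any(gamma == 1L & !covered)) {
    return(list(valid = FALSE, code = "b"))
  }
  if (length(sel_sets) >= 2L) {
    keys <- vapply(sel_sets, paste, character(1), collapse = ",")
    if (anyDuplicated(keys)) return(list(valid = FALSE, code = "c"))
  }
  list(valid = TRUE, code = NA_character_)
}

#' Network neighbors of a gene within the selected pathways
#'
#' Returns the genes adjacent to `j` in the network that share at least one
#' currently selected pathway with `j`; this is the neighbor set entering the
#' MRF prior.
#'
#' @param j gene index.
#' @param state a [selection_state()].
#' @param R p x p adjacency.
#' @param S p x K membership.
#' @return integer vector of gene indices (possibly empty).
#' @export
neighbors_within_selected <- function(j, state, R, S) {
  sel_pw <- which(state$theta == 1L)
  if (length(sel_pw) == 0L) return(integer(0))
  nb <- which(R[j, ] == 1L)
  if (length(nb) == 0L) return(integer(0))
  Ssel <- S[, sel_pw, drop = FALSE]
  share <- (Ssel[nb, , drop = FALSE] %*% Ssel[j, ]) > 0
  unname(nb[as.vector(share)])
}

#' Hyperparameters of the iBVS model
#'
#' @param c g-prior scale on pathway-level effects.  The default (50) is a
#'   moderate scale: large values sharpen Bayes factors but make the latent
#'   probit utilities cling to the current pathway components, which stalls
#'   moves that rotate a component; `NULL` means "set to the sample size at
#'   fit time".
#' @param h prior variance of the intercept; large by default (diffuse).
#' @param d MRF sparsity parameter (log-odds of selecting an isolated gene);
#'   the default `qlogis(0.05)` favors roughly one selected gene in twenty
#'   a priori.
#' @param f MRF smoothing parameter rewarding jointly selected network
#'   neighbors; must be nonnegative.
#' @param pi_theta prior inclusion probability of each pathway.
#' @return list of class `ibvs_hyper`.
#' @export
ibvs_hyper <- function(c = 50, h = 1e6, d = qlogis(0.05), f = 0.5,
                       pi_theta = 0.1) {
  if (!is.null(c) && c <= 0) stop("c must be positive")
  if (h <= 0) stop("h must be positive")
  if (f < 0) stop("f must be nonnegative")
  if (pi_theta <= 0 || pi_theta >= 1) stop("pi_theta must lie in (0,1)")
  structure(list(c = c, h = h, d = d, f = f, pi_theta = pi_theta),
            class = "ibvs_hyper")
}
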