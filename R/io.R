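# Readers/writers for the supported plain-text formats and the end-to-end
# pipeline gluing screen -> run -> evaluate.

#' Read a GMT gene-set file
#'
#' One pathway per line: set id, description, then tab-separated gene ids.
#' Duplicate genes within a line are de-duplicated with a warning.
#'
#' @param path file path.
#' @return named list of gene-id vectors (names = pathway ids, descriptions in
#'   attribute `"descriptions"`), in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) stop("malformed GMT line ", i, ": empty line")
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in pathway ", fields[1], " de-duplicated")
      genes <- unique(genes)
    }
    out[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  attr(out, "descriptions") <- desc
  out
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene-id vectors.
#' @param path destination.
#' @param descriptions optional per-set descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read a gene-gene network
#'
#' Accepts a two-column tab-separated edge list of gene ids (no header
#' required) or a square 0/1 CSV with matching header and row names.  Edges to
#' genes outside the universe are dropped with a warning; self-loops are
#' removed and the matrix symmetrized.
#'
#' @param path file path.
#' @param universe character vector of known gene ids.
#' @return symmetric 0/1 adjacency matrix over the universe.
#' @export
read_network <- function(path, universe) {
  first <- readLines(path, n = 1L)
  p <- length(universe)
  R <- matrix(0L, p, p, dimnames = list(universe, universe))
  if (grepl(",", first, fixed = TRUE)) {
    M <- as.matrix(read.table(path, sep = ",", header = TRUE, row.names = 1L,
                              check.names = FALSE))
    if (nrow(M) != ncol(M)) stop("square adjacency expected")
    bad <- M != t(M) & !(M %in% c(0L, 1L))
    if (any(M != t(M) & (M > 1 | t(M) > 1))) stop("asymmetric adjacency values")
    keep <- intersect(rownames(M), universe)
    dropped <- setdiff(rownames(M), universe)
    if (length(dropped)) warning(length(dropped), " unknown gene id(s) dropped")
    R[keep, keep] <- pmax(M[keep, keep], t(M[keep, keep]))
  } else {
    e <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("from", "to"), colClasses = "character")
    known <- e$from %in% universe & e$to %in% universe
    if (any(!known)) warning(sum(!known), " edge(s) with unknown gene ids dropped")
    e <- e[known & e$from != e$to, , drop = FALSE]
    if (nrow(e)) {
      R[cbind(e$from, e$to)] <- 1L
      R <- pmax(R, t(R))
    }
  }
  diag(R) <- 0L
  R
}

#' Write an edge-list network file
#'
#' @param R symmetric adjacency matrix with gene-id dimnames.
#' @param path destination (tab-separated, one undirected edge per line).
#' @export
write_network <- function(R, path) {
  idx <- which(R == 1L & upper.tri(R), arr.ind = TRUE)
  e <- data.frame(from = rownames(R)[idx[, 1]], to = colnames(R)[idx[, 2]])
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read an expression table
#'
#' Tab- or comma-separated; first column holds sample ids, header row holds
#' gene ids.
#'
#' @param path file path.
#' @return numeric samples x genes matrix with dimnames.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  as.matrix(read.table(path, sep = sep, header = TRUE, row.names = 1L,
                       check.names = FALSE))
}

#' Write an expression table (TSV)
#' @param X samples x genes matrix with dimnames.
#' @param path destination.
#' @export
write_expression <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype table
#'
#' Two tab-separated columns: sample id and 0/1 phenotype (no header, or a
#' header line starting with `sample`).
#'
#' @param path file path.
#' @param sample_ids optional ordering to align to.
#' @return named integer 0/1 vector.
#' @export
read_phenotype <- function(path, sample_ids = NULL) {
  first <- readLines(path, n = 1L)
  header <- grepl("^sample", first, ignore.case = TRUE)
  d <- read.table(path, sep = "\t", header = header,
                  col.names = c("sample_id", "y"))
  y <- setNames(as.integer(d$y), d$sample_id)
  if (!all(y %in% 0:1)) stop("phenotype must be 0/1")
  if (!is.null(sample_ids)) {
    if (!all(sample_ids %in% names(y))) stop("phenotype missing sample id(s)")
    y <- y[sample_ids]
  }
  y
}

#' Write one simulated replicate to plain-text files
#'
#' Emits the expression TSV, phenotype TSV, GMT, edge list and a truth CSV
#' (causal gene ids and effects) under `dir`.
#'
#' @param sim a [build_scenario()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of file paths.
#' @export
write_simulated_dataset <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, paste0(prefix, "_", x))
  rownames(sim$X) <- paste0("s", seq_len(nrow(sim$X)))
  write_expression(sim$X, f("expr.tsv"))
  write.table(data.frame(sample_id = rownames(sim$X), y = sim$y),
              f("pheno.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  sets <- lapply(seq_len(ncol(sim$structure$S)),
                 function(k) rownames(sim$structure$S)[sim$structure$S[, k] == 1L])
  names(sets) <- colnames(sim$structure$S)
  write_gmt(sets, f("sets.gmt"))
  write_network(sim$structure$R, f("edges.tsv"))
  write.table(data.frame(gene = colnames(sim$X)[sim$causal],
                         beta = sim$beta[sim$causal]),
              f("truth.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(expr = f("expr.tsv"), pheno = f("pheno.tsv"), gmt = f("sets.gmt"),
              network = f("edges.tsv"), truth = f("truth.csv")))
}

#' Run the full screen-then-select pipeline
#'
#' Stages: (1) load inputs; (2) robust gene screening plus pathway expansion;
#' (3) the iBVS sampler on the signature set; (4) marginal selection
#' probabilities; (5) optional ROC/AUC evaluation against a truth file.
#' Writes gene/pathway probability CSVs, a screening report and a JSON
#' manifest (seed, configuration hash, package version) under `out_dir`.
#'
#' @param config named list (or path to a YAML file) with sections
#'   `data` (`expr`, `pheno`, `gmt`, optional `network`, optional `truth`),
#'   `screen` (`enabled`, `t_alpha`, `w_alpha`), `model`
#'   (hyperparameters for [ibvs_hyper()]), and `sampler` (arguments for
#'   [sampler_config()]).
#' @param out_dir results directory.
#' @return invisibly, a list with the screening result, draws, marginal
#'   probabilities and (when truth is given) the AUC.
#' @export
ibvs_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  res <- tryCatch({
    dat <- config$data
    for (f in c("expr", "pheno", "gmt")) {
      if (is.null(dat[[f]]) || !file.exists(dat[[f]])) {
        stop("missing input file for '", f, "': ", dat[[f]])
      }
    }
    X <- read_expression(dat$expr)
    y <- read_phenotype(dat$pheno, rownames(X))
    sets <- read_gmt(dat$gmt)
    X <- standardize_expression(X)

    stage <- "screen"
    scr <- NULL
    sc <- config$screen
    if (!isFALSE(sc$enabled)) {
      scr <- gene_wise_filter(X, y,
                              t_alpha = sc$t_alpha %||% 0.01,
                              w_alpha = sc$w_alpha %||% 0.05,
                              must_include = sc$must_include)
      exp_sets <- lapply(sets, intersect, y = scr$kept)
      keep_pw <- lengths(exp_sets) > 0
      grand <- unique(unlist(sets[keep_pw]))
      genes <- union(intersect(grand, colnames(X)), scr$kept)
      X <- X[, genes, drop = FALSE]
      sets <- lapply(sets[keep_pw], intersect, y = genes)
      write.table(scr$report, file.path(out_dir, "screen_report.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
    }
    sets <- sets[lengths(sets) > 0]
    adj <- if (!is.null(dat$network)) read_network(dat$network, colnames(X)) else NULL
    structure <- pathway_structure(sets, adjacency = adj,
                                   gene_ids = colnames(X))

    stage <- "sample"
    hy <- do.call(ibvs_hyper, config$model %||% list())
    cfg <- do.call(sampler_config, config$sampler %||% list())
    draws <- run_chain(X, y, structure, hy, cfg)

    stage <- "summarize"
    probs <- marginal_selection_probs(draws)
    write.table(data.frame(gene = names(probs$gene), prob = probs$gene),
                file.path(out_dir, "gene_probs.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(pathway = names(probs$pathway), prob = probs$pathway),
                file.path(out_dir, "pathway_probs.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)

    stage <- "evaluate"
    auc <- NULL
    if (!is.null(dat$truth)) {
      truth <- read.table(dat$truth, sep = ",", header = TRUE)
      labels <- as.integer(names(probs$gene) %in% truth$gene)
      auc <- roc_auc(probs$gene, labels)$auc
      writeLines(sprintf("auc,%0.6f", auc), file.path(out_dir, "auc.csv"))
    }

    manifest <- list(
      package = "ibvs",
      version = as.character(utils::packageVersion("ibvs")),
      seed = cfg$seed,
      config_hash = .config_hash(config),
      n = nrow(X), p = ncol(X), K = ncol(structure$S))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(screen = scr, draws = draws, probs = probs, auc = auc)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
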