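#' Specify planted ground truth for a synthetic expression bundle
#'
#' The generator works on a latent log2 scale: every gene is Gaussian per
#' condition, planted co-expression pairs are bivariate Gaussian within
#' their active condition only (a Gaussian copula, so the Pearson
#' correlation needed for a target Spearman rho_s is 2*sin(pi*rho_s/6)),
#' regulatory targets are linear-in-TF plus noise with per-condition
#' coupling, and differential genes are mean-shifted. Linear-scale values
#' are 2^latent, so the normalization front end is exercised.
#'
#' @param planted_edges data frame `gene_a`, `gene_b`, `condition`,
#'   `rho` (target Spearman, |rho| in (0,1)), optional `mean_shift`
#'   (log2 units added to both genes within the active condition; gives the
#'   pair a separable, differentially expressed cluster; default 3).
#' @param planted_grn data frame `tf`, `target`, `condition`, `coupling`
#'   (correlation of target with TF within that condition, in [-1,1]).
#' @param planted_degs data frame `gene`, `condition`, `log2fc` (mean shift
#'   applied to `gene` within `condition`).
#' @param missingness data frame `gene`, `condition`, `rate` in [0,1].
#' @return object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(planted_edges = NULL, planted_grn = NULL,
                            planted_degs = NULL, missingness = NULL) {
  if (!is.null(planted_edges)) {
    stopifnot(all(c("gene_a", "gene_b", "condition", "rho") %in% names(planted_edges)))
    if (any(abs(planted_edges$rho) >= 1) || any(planted_edges$rho == 0))
      stop("target Spearman rho must satisfy 0 < |rho| < 1")
    if (is.null(planted_edges$mean_shift)) planted_edges$mean_shift <- 3
    g <- c(planted_edges$gene_a, planted_edges$gene_b)
    if (anyDuplicated(g))
      stop("a gene may appear in at most one planted edge")
  }
  if (!is.null(planted_grn)) {
    stopifnot(all(c("tf", "target", "condition", "coupling") %in% names(planted_grn)))
    if (any(abs(planted_grn$coupling) > 1)) stop("coupling must be in [-1,1]")
  }
  if (!is.null(missingness)) {
    stopifnot(all(c("gene", "condition", "rate") %in% names(missingness)))
    if (any(missingness$rate < 0 | missingness$rate > 1))
      stop("missingness rate outside [0,1]")
  }
  structure(list(planted_edges = planted_edges, planted_grn = planted_grn,
                 planted_degs = planted_degs, missingness = missingness),
            class = "synthetic_truth")
}

#' Generate a multi-condition expression bundle with planted structure
#'
#' Background genes are i.i.d. log-normal (linear scale) per condition;
#' planted structure follows the `truth` spec. Output is byte-identical
#' for a fixed seed.
#'
#' @param n_genes number of genes (ids `G0001`, `G0002`, ...). Genes named
#'   in `truth` must be within this pool.
#' @param samples_per_condition named integer vector, condition -> n samples.
#' @param truth a [synthetic_truth] object.
#' @param seed integer seed.
#' @param base_mean_range log2-mean range background genes are drawn from.
#' @param sd latent log2 standard deviation (per gene, per condition).
#' @return list (class `"synthetic_bundle"`) with `gem` (linear scale),
#'   `annotation`, `grn` (data frame `tf`, `target` or NULL) and `truth`.
#' @export
generate_dataset <- function(n_genes, samples_per_condition,
                             truth = synthetic_truth(), seed = 1L,
                             base_mean_range = c(3, 9), sd = 1) {
  stopifnot(length(samples_per_condition) >= 2L,
            !is.null(names(samples_per_condition)))
  conditions <- names(samples_per_condition)
  genes <- sprintf("G%04d", seq_len(n_genes))
  named <- unique(c(truth$planted_edges$gene_a, truth$planted_edges$gene_b,
                    truth$planted_grn$tf, truth$planted_grn$target,
                    truth$planted_degs$gene, truth$missingness$gene))
  if (length(setdiff(named, genes)))
    stop("truth references genes outside the pool: ",
         paste(utils::head(setdiff(named, genes), 5L), collapse = ", "))
  bad_cond <- setdiff(c(truth$planted_edges$condition,
                        truth$planted_grn$condition,
                        truth$planted_degs$condition,
                        truth$missingness$condition), conditions)
  if (length(bad_cond))
    stop("truth references unknown conditions: ", paste(bad_cond, collapse = ", "))

  set.seed(seed)
  n_total <- sum(samples_per_condition)
  samples <- unlist(lapply(conditions, function(co)
    sprintf("%s_S%03d", co, seq_len(samples_per_condition[[co]]))))
  cond_of <- rep(conditions, samples_per_condition)

  mu <- stats::runif(n_genes, base_mean_range[1], base_mean_range[2])
  names(mu) <- genes
  # latent log2 matrix, standardized residuals kept for coupling
  z <- matrix(stats::rnorm(n_genes * n_total), n_genes, n_total,
              dimnames = list(genes, samples))

  pe <- truth$planted_edges
  if (!is.null(pe)) for (i in seq_len(nrow(pe))) {
    sel <- cond_of == pe$condition[i]
    rho_p <- 2 * sin(pi * pe$rho[i] / 6)
    za <- z[pe$gene_a[i], sel]
    z[pe$gene_b[i], sel] <- rho_p * za + sqrt(1 - rho_p^2) * z[pe$gene_b[i], sel]
  }
  pg <- truth$planted_grn
  if (!is.null(pg)) for (i in seq_len(nrow(pg))) {
    sel <- cond_of == pg$condition[i]
    cp <- pg$coupling[i]
    z[pg$target[i], sel] <- cp * z[pg$tf[i], sel] +
      sqrt(1 - cp^2) * z[pg$target[i], sel]
  }

  lat <- mu[genes] + sd * z
  if (!is.null(pe)) for (i in seq_len(nrow(pe))) {
    sel <- cond_of == pe$condition[i]
    lat[pe$gene_a[i], sel] <- lat[pe$gene_a[i], sel] + pe$mean_shift[i]
    lat[pe$gene_b[i], sel] <- lat[pe$gene_b[i], sel] + pe$mean_shift[i]
  }
  pd <- truth$planted_degs
  if (!is.null(pd)) for (i in seq_len(nrow(pd))) {
    sel <- cond_of == pd$condition[i]
    lat[pd$gene[i], sel] <- lat[pd$gene[i], sel] + pd$log2fc[i]
  }

  g <- gem(2^lat, "linear")
  annot <- data.frame(sample = samples, condition = cond_of,
                      stringsAsFactors = FALSE)
  if (!is.null(truth$missingness))
    g <- inject_missingness(g, truth$missingness, annot, seed = seed + 1L)
  grn <- NULL
  if (!is.null(pg)) {
    grn <- unique(pg[, c("tf", "target")])
    rownames(grn) <- NULL
  }
  structure(list(gem = g, annotation = annot, grn = grn, truth = truth),
            class = "synthetic_bundle")
}

#' Mask cells at specified per-gene, per-condition rates
#'
#' @param gem a [gem].
#' @param spec data frame `gene`, `condition`, `rate`.
#' @param annot annotation mapping samples to conditions.
#' @param seed integer seed.
#' @return the GEM with additional cells set to `NA`.
#' @export
inject_missingness <- function(gem, spec, annot, seed = 1L) {
  stopifnot(is_gem(gem), all(c("gene", "condition", "rate") %in% names(spec)))
  if (any(spec$rate < 0 | spec$rate > 1)) stop("rate outside [0,1]")
  check_annotation(gem, annot)
  set.seed(seed)
  v <- gem$values
  cond_of <- annot$condition[match(colnames(v), annot$sample)]
  for (i in seq_len(nrow(spec))) {
    sel <- which(cond_of == spec$condition[i])
    hit <- sel[stats::runif(length(sel)) < spec$rate[i]]
    v[spec$gene[i], hit] <- NA
  }
  gem(v, gem$scale)
}

#' Default synthetic study bundle
#'
#' 200 genes over 4 conditions x 60 samples with 20 planted
#' condition-specific edges (Spearman 0.85, spread over the conditions), a
#' small TF->target regulatory layer coupled only in its active condition,
#' differential genes, and structured missingness on two genes. A compact
#' stand-in for a multi-cohort expression study with known answers.
#'
#' @param n_genes,samples_per_condition,rho,n_edges,seed overrides.
#' @return a `synthetic_bundle`.
#' @export
default_bundle <- function(n_genes = 200,
                           samples_per_condition = c(normal_a = 60, normal_b = 60,
                                                     tumor_a = 60, tumor_b = 60),
                           rho = 0.85, n_edges = 20, seed = 17L) {
  conditions <- names(samples_per_condition)
  idx <- seq_len(2 * n_edges)
  pe <- data.frame(
    gene_a = sprintf("G%04d", idx[seq_len(n_edges) * 2 - 1]),
    gene_b = sprintf("G%04d", idx[seq_len(n_edges) * 2]),
    condition = rep_len(conditions, n_edges),
    rho = rho, stringsAsFactors = FALSE)
  tf_idx <- 2 * n_edges + seq_len(4)
  # each TF regulates both endpoints of one planted edge (a true triangle)
  # plus one background gene, coupled only in the edge's condition
  pg <- do.call(rbind, lapply(seq_len(4), function(k) {
    data.frame(tf = sprintf("G%04d", tf_idx[k]),
               target = c(pe$gene_a[k], pe$gene_b[k],
                          sprintf("G%04d", 2 * n_edges + 4 + k)),
               condition = pe$condition[k], coupling = 0.8,
               stringsAsFactors = FALSE)
  }))
  deg_idx <- 2 * n_edges + 8 + seq_len(10)
  tumor_conds <- rev(conditions)[1:2]   # last two conditions play "tumor"
  pd <- data.frame(gene = sprintf("G%04d", deg_idx),
                   condition = rep(tumor_conds, 5),
                   log2fc = rep(c(2, -2, 1.5, -1.5, 3), each = 2),
                   stringsAsFactors = FALSE)
  # the triangle TFs are themselves differential in their edge's condition
  # (a rewired regulator is typically a DEG), alternating direction so all
  # four directional edge categories can occur
  pd <- rbind(pd, data.frame(gene = sprintf("G%04d", tf_idx),
                             condition = pe$condition[seq_len(4)],
                             log2fc = c(2, -2, -2, 2),
                             stringsAsFactors = FALSE))
  ms_idx <- max(deg_idx) + 1:2
  ms <- data.frame(gene = sprintf("G%04d", ms_idx),
                   condition = conditions[1:2], rate = c(0.5, 0.3),
                   stringsAsFactors = FALSE)
  generate_dataset(n_genes, samples_per_condition,
                   synthetic_truth(pe, pg, pd, ms), seed = seed)
}

#' Write a synthetic bundle to disk as plain-text fixtures
#'
#' Writes four files: `gem.tsv`, `annotation.tsv`, `grn.tsv`, `truth.tsv`
#' (manifest with a `type` column: `edge`, `grn`, `deg`, `missing`).
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the four paths.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("gem.tsv", "annotation.tsv", "grn.tsv", "truth.tsv"))
  write_gem(bundle$gem, paths[1])
  write_annotation(bundle$annotation, paths[2])
  grn <- bundle$grn
  if (is.null(grn)) grn <- data.frame(tf = character(), target = character())
  utils::write.table(grn, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_manifest(bundle$truth), paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(paths)
}

truth_manifest <- function(truth) {
  rows <- list()
  if (!is.null(truth$planted_edges))
    rows$edge <- data.frame(type = "edge",
                            a = truth$planted_edges$gene_a,
                            b = truth$planted_edges$gene_b,
                            condition = truth$planted_edges$condition,
                            value = truth$planted_edges$rho)
  if (!is.null(truth$planted_grn))
    rows$grn <- data.frame(type = "grn",
                           a = truth$planted_grn$tf,
                           b = truth$planted_grn$target,
                           condition = truth$planted_grn$condition,
                           value = truth$planted_grn$coupling)
  if (!is.null(truth$planted_degs))
    rows$deg <- data.frame(type = "deg",
                           a = truth$planted_degs$gene, b = NA,
                           condition = truth$planted_degs$condition,
                           value = truth$planted_degs$log2fc)
  if (!is.null(truth$missingness))
    rows$missing <- data.frame(type = "missing",
                               a = truth$missingness$gene, b = NA,
                               condition = truth$missingness$condition,
                               value = truth$missingness$rate)
  if (!length(rows))
    return(data.frame(type = character(), a = character(), b = character(),
                      condition = character(), value = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
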